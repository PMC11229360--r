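# Census statistics: per-family counts, co-occurrence, UpSet-style
# configurations, activator fractions, and the binomial GLM relating
# effector absence to multi-locus genomes.

#' Per-family locus counts
#'
#' Each locus contributes 1 to every distinct family it contains; the total
#' effector-instance count is the sum over families.
#'
#' @param census census tibble with a `families` list-column.
#' @return tibble with `family` and `n_loci`, sorted by decreasing count.
#' @export
count_families <- function(census) {
  fams <- census$families |> map(unique) |> unlist()
  if (is.null(fams) || length(fams) == 0) {
    out <- tibble(family = character(0), n_loci = integer(0))
  } else {
    out <- tibble(family = fams) |>
      count(.data$family, name = "n_loci") |>
      arrange(desc(.data$n_loci), .data$family)
  }
  class(out) <- c("census_counts", class(out))
  out
}

#' Family co-occurrence matrix and proportions
#'
#' `M[f, g]` counts loci containing both `f` and `g`; the per-family
#' co-occurrence proportion is the fraction of a family's loci that also
#' carry at least one other family.
#'
#' @param census census tibble with a `families` list-column.
#' @return list with `matrix` (symmetric, zero diagonal) and `proportion`
#'   (tibble: `family`, `n_loci`, `n_cooccurring`, `proportion`).
#' @export
cooccurrence_matrix <- function(census) {
  fams <- sort(unique(unlist(census$families)))
  M <- matrix(0L, length(fams), length(fams), dimnames = list(fams, fams))
  for (fs in census$families) {
    fs <- unique(fs)
    if (length(fs) >= 2) {
      for (pair in combn(sort(fs), 2, simplify = FALSE)) {
        M[pair[1], pair[2]] <- M[pair[1], pair[2]] + 1L
        M[pair[2], pair[1]] <- M[pair[2], pair[1]] + 1L
      }
    }
  }
  prop <- tibble(family = fams,
                 n_loci = map_int(fams, function(f) {
                   sum(map_lgl(census$families, ~ f %in% .x))
                 }),
                 n_cooccurring = map_int(fams, function(f) {
                   sum(map_lgl(census$families,
                               ~ f %in% .x && length(unique(.x)) >= 2))
                 })) |>
    mutate(proportion = .data$n_cooccurring / .data$n_loci)
  list(matrix = M, proportion = prop)
}

#' UpSet-style effector configurations
#'
#' Groups loci by their exact family set (the empty set counts effector-less
#' loci); counts partition the census. A per-configuration subtype breakdown
#' is attached as a list-column.
#'
#' @param census census tibble with `families` and `subtype`.
#' @return tibble with `configuration` (sorted families joined by `+`, `""`
#'   for none), `n`, and `subtype_breakdown` (list of tibbles).
#' @export
upset_configurations <- function(census) {
  census |>
    mutate(configuration = map_chr(.data$families,
                                   ~ paste(sort(unique(.x)), collapse = "+"))) |>
    group_by(.data$configuration) |>
    summarise(n = n(),
              subtype_breakdown = list(count(pick("subtype"), .data$subtype)),
              .groups = "drop") |>
    arrange(desc(.data$n), .data$configuration)
}

#' Fraction of effector instances using a given activator
#'
#' Sums the per-family counts of families mapped to `activator` and divides
#' by the total number of effector instances.
#'
#' @param counts tibble from [count_families()].
#' @param amap activator map (see [activator_map()]).
#' @param activator one of the activator molecules in `amap`.
#' @return fraction in `[0, 1]`.
#' @export
activator_fraction <- function(counts, amap = activator_map(), activator) {
  if (!activator %in% amap$activator) {
    abort(paste0("unknown activator: ", activator))
  }
  joined <- counts |> left_join(amap |> select("family", "activator"),
                                by = "family")
  if (any(is.na(joined$activator))) {
    abort(paste0("families without an activator mapping: ",
                 paste(joined$family[is.na(joined$activator)], collapse = ", ")))
  }
  sum(joined$n_loci[joined$activator == activator]) / sum(joined$n_loci)
}

#' Logistic regression of a binary response on a binary covariate
#'
#' Fitted by iteratively reweighted least squares (via `stats::glm.fit`,
#' binomial family) with a Wald z test and two-sided normal p-value. For a
#' binary covariate the fitted odds ratio equals the closed-form 2x2
#' cross-product ratio. Perfect separation (an empty cell in the 2x2 table)
#' is an error naming the degenerate margin.
#'
#' @param y binary response vector (0/1 or logical).
#' @param x binary covariate vector.
#' @return an object of class `census_glm` with `coefficient` (log-odds),
#'   `std_error`, `z`, `p_value`, `odds_ratio`, `n`.
#' @export
fit_logistic <- function(y, x) {
  y <- as.integer(y)
  x <- as.integer(x)
  n <- length(y)
  if (n < 4) abort("logistic fit requires n >= 4")
  if (length(unique(y)) < 2) abort("response has a single class")
  if (length(unique(x)) < 2) abort("covariate has a single class")
  cells <- table(factor(y, levels = 0:1), factor(x, levels = 0:1))
  if (any(cells == 0)) {
    bad <- which(cells == 0, arr.ind = TRUE)[1, ]
    abort(sprintf(
      "perfect separation: empty cell at y=%s, x=%s",
      rownames(cells)[bad[1]], colnames(cells)[bad[2]]))
  }
  fit <- glm.fit(cbind(`(Intercept)` = 1, x = x), y, family = binomial(),
                 control = list(epsilon = 1e-12, maxit = 100))
  beta <- fit$coefficients[["x"]]
  # Wald standard error from the final IRLS weights.
  X <- cbind(1, x)
  W <- fit$weights
  cov_beta <- solve(t(X) %*% (X * W))
  se <- sqrt(cov_beta[2, 2])
  z <- beta / se
  structure(list(coefficient = beta, std_error = se, z = z,
                 p_value = 2 * pnorm(-abs(z)), odds_ratio = exp(beta),
                 n = n, converged = fit$converged),
            class = "census_glm")
}

#' @export
print.census_glm <- function(x, ...) {
  cat(sprintf(paste0("Binomial GLM (logit link), n = %d\n",
                     "  coefficient = %.4f (SE %.4f)\n",
                     "  odds ratio  = %.3f\n",
                     "  Z = %.3f, P = %.3g\n"),
              x$n, x$coefficient, x$std_error, x$odds_ratio, x$z, x$p_value))
  invisible(x)
}

#' Tidy a census GLM fit
#' @param x a `census_glm` object.
#' @param ... unused.
#' @return one-row tibble with term, estimate, std.error, statistic,
#'   p.value.
#' @export
tidy.census_glm <- function(x, ...) {
  tibble(term = "x", estimate = x$coefficient, std.error = x$std_error,
         statistic = x$z, p.value = x$p_value)
}

#' Glance at a census GLM fit
#' @param x a `census_glm` object.
#' @param ... unused.
#' @return one-row tibble with odds.ratio, nobs, converged.
#' @export
glance.census_glm <- function(x, ...) {
  tibble(odds.ratio = x$odds_ratio, nobs = x$n, converged = x$converged)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Inter-locus signalling association
#'
#' Fits effector presence (response: the locus carries at least one known
#' effector family) against the multi-locus indicator (the genome carries
#' two or more type III loci). The result is reported both as fitted
#' (presence vs multi-locus) and inverted (`or_lacking` = odds-ratio for an
#' effector-lacking locus to sit in a multi-locus genome), the direction the
#' inter-locus signalling hypothesis is phrased in. Loci within one genome
#' are treated as independent observations; `note` flags this
#' non-independence.
#'
#' @param census census tibble with `families` and
#'   `n_type3_loci_in_genome`.
#' @param known_only count only the ten known families as effector presence
#'   (candidate families excluded by default).
#' @return a `census_glm` with extra fields `or_lacking` and `note`.
#' @export
interlocus_association <- function(census, known_only = TRUE) {
  fams <- if (known_only) known_families() else activator_map()$family
  y <- map_lgl(census$families, ~ any(.x %in% fams))
  x <- census$n_type3_loci_in_genome >= 2
  res <- fit_logistic(y, x)
  res$or_lacking <- 1 / res$odds_ratio
  res$note <- "loci within a genome treated as independent observations"
  res
}
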