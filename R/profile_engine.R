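# Position-specific scoring profiles with empirical Gumbel E-value
# calibration, plus greedy identity clustering. These are the package's own
# desk-scale stand-ins for profile-HMM scanning (hmmbuild/hmmscan) and
# CD-HIT: ungapped PSSM windows preserve the E-value-threshold semantics the
# census logic relies on, and the greedy clusterer reproduces the
# longest-first, representative-based behaviour of incremental clustering.

#' Build a position-specific scoring profile from a seed alignment
#'
#' Columns with more than 50% gaps are dropped; the remaining columns give a
#' log-odds matrix in bits:
#' `log2((count[i,a] + pseudocount * background[a]) / (n_i + pseudocount) / background[a])`
#' where `n_i` is the number of standard residues observed in column `i`.
#' The `X` column always scores 0.
#'
#' @param seed_alignment character vector of >= 2 equal-length, possibly
#'   gapped (`-`) aligned sequences.
#' @param name profile name.
#' @param family family label the profile belongs to (effector family, Cas10,
#'   ancillary, ...).
#' @param pseudocount total pseudocount mass added per column (default 1).
#' @param background length-21 residue frequency vector; see
#'   [profile_background()].
#' @return an object of class `aa_profile` (uncalibrated; see
#'   [calibrate_profile()]).
#' @export
build_profile <- function(seed_alignment, name = "profile", family = name,
                          pseudocount = 1, background = profile_background()) {
  if (length(seed_alignment) < 2) {
    abort("profile construction requires at least 2 seed sequences")
  }
  seed_alignment <- str_to_upper(seed_alignment)
  widths <- unique(nchar(seed_alignment))
  if (length(widths) != 1) {
    abort("seed alignment rows must have equal length")
  }
  mat <- do.call(rbind, strsplit(seed_alignment, "", fixed = TRUE))
  gap_frac <- colMeans(mat == "-" | mat == ".")
  keep <- which(gap_frac <= 0.5)
  if (length(keep) == 0) abort("all alignment columns were gap-dropped")
  mat <- mat[, keep, drop = FALSE]
  L <- ncol(mat)
  log_odds <- matrix(0, nrow = L, ncol = 21, dimnames = list(NULL, AA21))
  for (i in seq_len(L)) {
    col <- mat[, i]
    col <- col[col %in% AA20]
    n_i <- length(col)
    counts <- table(factor(col, levels = AA20))
    for (a in seq_along(AA20)) {
      bg <- background[a]
      log_odds[i, a] <- log2((counts[a] + pseudocount * bg) /
                               (n_i + pseudocount) / bg)
    }
  }
  prof <- structure(list(name = name, family = family, length = L,
                         log_odds = log_odds, pseudocount = pseudocount,
                         background = background,
                         gumbel_mu = NA_real_, gumbel_lambda = NA_real_),
                    class = "aa_profile")
  if (any(apply(log_odds[, 1:20, drop = FALSE], 1, max) <= 0)) {
    abort("degenerate profile: a column has no positively scoring residue")
  }
  prof
}

#' @export
print.aa_profile <- function(x, ...) {
  cat(sprintf("<aa_profile '%s' (family %s): %d columns, %s>\n",
              x$name, x$family, x$length,
              if (is.na(x$gumbel_lambda)) "uncalibrated"
              else sprintf("Gumbel mu=%.2f lambda=%.3f",
                           x$gumbel_mu, x$gumbel_lambda)))
  invisible(x)
}

#' Scan a sequence with a profile
#'
#' Slides the profile over every ungapped window and returns the best-scoring
#' window (leftmost on ties), or `NULL` when the sequence is shorter than the
#' profile.
#'
#' @param profile an `aa_profile`.
#' @param sequence amino-acid string.
#' @return a one-row tibble with `profile_name`, `bitscore`, `window_start`,
#'   `window_end` (0-based half-open), or `NULL`.
#' @export
scan_profile <- function(profile, sequence) {
  hit <- scan_best_cpp(profile$log_odds, aa_encode(sequence))
  if (is.null(hit)) return(NULL)
  tibble(profile_name = profile$name, bitscore = hit$bitscore,
         window_start = hit$window_start, window_end = hit$window_end)
}

#' Calibrate a profile's Gumbel E-value parameters
#'
#' Scores the best window on `n_shuffles` i.i.d. background sequences and
#' fits a Gumbel distribution by the method of moments:
#' `lambda = pi / (sd * sqrt(6))`, `mu = mean - gamma / lambda` with `gamma`
#' the Euler-Mascheroni constant. Deterministic given `seed`.
#'
#' @param profile an `aa_profile`.
#' @param n_shuffles number of null sequences (>= 100).
#' @param length length of each null sequence (>= profile length).
#' @param background residue frequencies used to draw null sequences.
#' @param seed integer RNG seed.
#' @return the profile with `gumbel_mu` and `gumbel_lambda` set.
#' @export
calibrate_profile <- function(profile, n_shuffles = 200, length = 400,
                              background = profile_background(), seed = 1L) {
  if (n_shuffles < 100) abort("calibration requires n_shuffles >= 100")
  if (length < profile$length) {
    abort("calibration length must be at least the profile length")
  }
  scores <- withr::with_seed(seed, {
    vapply(seq_len(n_shuffles), function(i) {
      s <- paste(sample(AA21, length, replace = TRUE, prob = background),
                 collapse = "")
      scan_best_cpp(profile$log_odds, aa_encode(s))$bitscore
    }, numeric(1))
  })
  if (sd(scores) == 0) abort("calibration failed: zero score variance")
  fit <- fit_gumbel_moments(scores)
  profile$gumbel_mu <- fit[["mu"]]
  profile$gumbel_lambda <- fit[["lambda"]]
  profile
}

# Method-of-moments Gumbel fit: lambda = pi/(sd*sqrt(6)),
# mu = mean - gamma/lambda.
fit_gumbel_moments <- function(scores) {
  lambda <- pi / (sd(scores) * sqrt(6))
  c(mu = mean(scores) - EULER_GAMMA / lambda, lambda = lambda)
}

#' E-value of a bitscore under a calibrated profile
#'
#' `E = db_size * (1 - exp(-exp(-lambda * (bitscore - mu))))`, the expected
#' number of null sequences in a database of `db_size` whose best window
#' scores at least `bitscore`. Monotonically decreasing in `bitscore`.
#'
#' @param bitscore numeric vector of bitscores.
#' @param profile a calibrated `aa_profile`.
#' @param db_size number of proteins in the current search set (>= 1).
#' @return numeric vector of E-values.
#' @export
profile_evalue <- function(bitscore, profile, db_size) {
  if (is.na(profile$gumbel_lambda)) {
    abort(paste0("profile '", profile$name, "' is not calibrated"))
  }
  if (db_size < 1) abort("db_size must be >= 1")
  db_size * -expm1(-exp(-profile$gumbel_lambda * (bitscore - profile$gumbel_mu)))
}

#' Scan many proteins against a profile library
#'
#' Convenience wrapper: best hit per (protein, profile) with E-values at the
#' stated database size. The database size defaults to the number of proteins
#' scanned, mirroring search-set-dependent E-values.
#'
#' @param profiles list of calibrated `aa_profile` objects.
#' @param proteins tibble with `protein_id` and `sequence`.
#' @param db_size database size for E-values.
#' @return tibble of hits: `protein_id`, `profile_name`, `family`,
#'   `bitscore`, `evalue`, `window_start`, `window_end`.
#' @export
scan_library <- function(profiles, proteins, db_size = nrow(proteins)) {
  if (length(profiles) == 0) abort("empty profile library")
  rows <- list()
  for (p in profiles) {
    for (k in seq_len(nrow(proteins))) {
      h <- scan_profile(p, proteins$sequence[k])
      if (is.null(h)) next
      rows[[length(rows) + 1L]] <-
        mutate(h, protein_id = proteins$protein_id[k], family = p$family,
               evalue = profile_evalue(h$bitscore, p, db_size))
    }
  }
  if (length(rows) == 0) {
    return(tibble(protein_id = character(0), profile_name = character(0),
                  family = character(0), bitscore = numeric(0),
                  evalue = numeric(0), window_start = integer(0),
                  window_end = integer(0)))
  }
  bind_rows(rows) |>
    select("protein_id", "profile_name", "family", "bitscore", "evalue",
           "window_start", "window_end")
}

#' Global pairwise sequence identity
#'
#' Needleman-Wunsch global alignment with match +1, mismatch 0 and linear
#' gap -1 (scores used for the alignment only); identity is the number of
#' matched positions divided by the alignment length.
#'
#' @param a,b amino-acid strings (non-empty).
#' @return identity in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) abort("pairwise_identity requires non-empty sequences")
  nw_identity_cpp(aa_encode(a), aa_encode(b))$identity
}

# k-mer set of a sequence, for the clustering word prefilter.
word_set <- function(seq, word_size) {
  n <- nchar(seq)
  if (n < word_size) return(character(0))
  unique(substring(seq, 1:(n - word_size + 1), word_size:n))
}

#' Greedy incremental identity clustering
#'
#' Sequences are sorted by decreasing length (ties broken by lexicographic
#' id) and assigned to the first existing cluster whose representative shares
#' at least one word of `word_size` letters (prefilter) and has
#' `pairwise_identity >= identity_threshold`; otherwise they found a new
#' cluster. Representatives are the longest members. Deterministic.
#'
#' @param seqs tibble with columns `id` and `sequence`.
#' @param identity_threshold identity cutoff in (0, 1].
#' @param word_size word length for the shared-word prefilter.
#' @return tibble with `id`, `cluster` (integer), `representative`,
#'   `is_representative`, ordered as processed.
#' @export
greedy_cluster <- function(seqs, identity_threshold, word_size) {
  stopifnot(identity_threshold > 0, identity_threshold <= 1)
  if (nrow(seqs) == 0) {
    return(tibble(id = character(0), cluster = integer(0),
                  representative = character(0), is_representative = logical(0)))
  }
  ord <- order(-nchar(seqs$sequence), seqs$id, method = "radix")
  seqs <- seqs[ord, ]
  rep_id <- character(0)
  rep_seq <- character(0)
  rep_words <- list()
  assign <- integer(nrow(seqs))
  for (k in seq_len(nrow(seqs))) {
    s <- seqs$sequence[k]
    w <- word_set(s, word_size)
    placed <- 0L
    for (ci in seq_along(rep_id)) {
      if (!any(w %in% rep_words[[ci]])) next
      if (pairwise_identity(s, rep_seq[ci]) >= identity_threshold) {
        placed <- ci
        break
      }
    }
    if (placed == 0L) {
      rep_id <- c(rep_id, seqs$id[k])
      rep_seq <- c(rep_seq, s)
      rep_words[[length(rep_words) + 1L]] <- w
      placed <- length(rep_id)
    }
    assign[k] <- placed
  }
  tibble(id = seqs$id, cluster = assign, representative = rep_id[assign],
         is_representative = seqs$id == rep_id[assign])
}
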