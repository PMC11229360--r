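# Independent oracles and small fixture builders shared across tests. The
# oracles are deliberately naive (plain R loops / full DP tables) and never
# call the implementation paths they check.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_seq <- function(n) paste(sample(AA, n, replace = TRUE), collapse = "")

# Brute-force best ungapped window of a log-odds matrix over a sequence.
oracle_scan <- function(log_odds, sequence) {
  codes <- match(strsplit(sequence, "")[[1]], c(AA, "X"))
  codes[is.na(codes)] <- 21L
  L <- nrow(log_odds)
  n <- length(codes)
  if (n < L) return(NULL)
  best <- -Inf
  best_off <- NA_integer_
  for (off in 0:(n - L)) {
    sc <- sum(log_odds[cbind(seq_len(L), codes[off + seq_len(L)])])
    if (sc > best) {
      best <- sc
      best_off <- off
    }
  }
  list(bitscore = best, window_start = best_off)
}

# Full-table Needleman-Wunsch (match +1 / mismatch 0 / gap -1) with the same
# tie preference (diagonal > up > left) and explicit traceback.
oracle_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av)
  m <- length(bv)
  S <- matrix(0, n + 1, m + 1)
  TB <- matrix(0L, n + 1, m + 1)
  S[, 1] <- -(0:n); TB[, 1] <- 1L
  S[1, ] <- -(0:m); TB[1, ] <- 2L
  for (i in 1:n) for (j in 1:m) {
    diag <- S[i, j] + (av[i] == bv[j])
    up <- S[i, j + 1] - 1
    left <- S[i + 1, j] - 1
    best <- diag; dir <- 0L
    if (up > best) { best <- up; dir <- 1L }
    if (left > best) { best <- left; dir <- 2L }
    S[i + 1, j + 1] <- best
    TB[i + 1, j + 1] <- dir
  }
  i <- n; j <- m; matches <- 0L; alen <- 0L
  while (i > 0 || j > 0) {
    dir <- TB[i + 1, j + 1]
    if (dir == 0L && i > 0 && j > 0) {
      if (av[i] == bv[j]) matches <- matches + 1L
      i <- i - 1; j <- j - 1
    } else if (dir == 1L && i > 0) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    alen <- alen + 1L
  }
  matches / alen
}

# Greedy clustering without the word prefilter, longest-first with
# lexicographic tie-break, identity via the package primitive under test is
# NOT used: the oracle recomputes identities itself.
oracle_cluster <- function(seqs, threshold) {
  ord <- order(-nchar(seqs$sequence), seqs$id, method = "radix")
  seqs <- seqs[ord, ]
  reps <- integer(0)
  assign <- integer(nrow(seqs))
  for (k in seq_len(nrow(seqs))) {
    placed <- 0L
    for (ci in seq_along(reps)) {
      if (oracle_identity(seqs$sequence[k], seqs$sequence[reps[ci]]) >= threshold) {
        placed <- ci
        break
      }
    }
    if (placed == 0L) {
      reps <- c(reps, k)
      placed <- length(reps)
    }
    assign[k] <- placed
  }
  split(seqs$id, assign)
}

# A tiny calibrated profile built from mutated copies of a base sequence.
toy_profile <- function(base, name = "toy", family = name, n_copies = 5,
                        rate = 0.05, seed = 1) {
  withr::with_seed(seed, {
    rows <- vapply(seq_len(n_copies), function(i) {
      ch <- strsplit(base, "")[[1]]
      hit <- runif(length(ch)) < rate
      ch[hit] <- sample(AA, sum(hit), replace = TRUE)
      paste(ch, collapse = "")
    }, character(1))
  })
  calibrate_profile(build_profile(rows, name = name, family = family),
                    seed = seed)
}

# Locus-level census tibble from a list of family sets.
census_from_sets <- function(sets, n_loci_in_genome = NULL) {
  n <- length(sets)
  tibble::tibble(
    locus_id = sprintf("L%03d", seq_len(n)),
    genome_id = sprintf("G%03d", seq_len(n)),
    subtype = "III-A",
    has_cyclase = TRUE,
    has_hd = FALSE,
    families = lapply(sets, as.character),
    candidates = rep(list(character(0)), n),
    activators = rep(list(character(0)), n),
    n_type3_loci_in_genome = n_loci_in_genome %||% rep(1L, n))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
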