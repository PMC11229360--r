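# Shared alphabet, encoding and small numeric helpers.

# 20 standard amino acids; X (index 21) is the catch-all unknown and always
# scores 0 in profiles.
AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA21 <- c(AA20, "X")

EULER_GAMMA <- 0.57721566490153286

#' Canonicalize an amino-acid sequence
#'
#' Uppercases, strips `*` stop characters from both ends, and maps ambiguous
#' residues other than `X` (B, Z, J, U, O, ...) to `X` with a warning, keeping
#' the 21-letter scoring alphabet closed.
#'
#' @param x character vector of amino-acid sequences.
#' @return character vector of the same length over the alphabet `A..Y, X`.
#' @export
canonicalize_aa <- function(x) {
  x <- str_to_upper(x)
  x <- gsub("^\\*+|\\*+$", "", x)
  bad <- grepl(paste0("[^", paste(AA21, collapse = ""), "]"), x)
  if (any(bad)) {
    warn(sprintf("%d sequence(s) contained ambiguous residues; mapped to X",
                 sum(bad)))
    x[bad] <- gsub(paste0("[^", paste(AA21, collapse = ""), "]"), "X", x[bad])
  }
  x
}

# Encode a sequence as 0-based integer codes for the C++ kernels (X -> 20).
aa_encode <- function(seq) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], AA21) - 1L
  codes[is.na(codes)] <- 20L
  codes
}

# Uniform background over the 20 standard residues; X carries no mass.
#' Default residue background frequencies
#'
#' Uniform over the 20 standard amino acids with zero mass on `X`, matching
#' the profile-scoring convention that `X` scores 0 bits everywhere.
#'
#' @return numeric vector of length 21, summing to 1.
#' @export
profile_background <- function() {
  setNames(c(rep(1 / 20, 20), 0), AA21)
}

# Draw a random background protein of length n (uniform 20-letter alphabet).
random_protein <- function(n) {
  paste(sample(AA20, n, replace = TRUE), collapse = "")
}

# Per-residue substitution noise, sparing protected (1-based) positions.
mutate_sequence <- function(seq, rate, protect = integer(0)) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  hit <- runif(length(chars)) < rate
  if (length(protect)) hit[protect] <- FALSE
  if (any(hit)) chars[hit] <- sample(AA20, sum(hit), replace = TRUE)
  paste(chars, collapse = "")
}

# Round half-up to whole percent, the convention used in reports.
percent_round <- function(x) floor(x * 100 + 0.5)

# Deterministic per-label seed derived from a base seed (kept < 2^31).
derive_seed <- function(seed, label) {
  h <- sum(utf8ToInt(label) * seq_along(utf8ToInt(label)))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
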