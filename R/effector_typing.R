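# Known-effector typing: locus neighbourhood extraction, hydropathy-based
# transmembrane segment prediction, profile-library typing with
# best-bitscore resolution and the Cam1/Csx1 transmembrane rule, plus
# cross-hit QC reporting.

#' The effector family to activator map
#'
#' The ten biochemically characterized families plus the four candidate
#' families. Candidate activator assignments are tentative
#' (guilt-by-association or prediction), flagged by `status`.
#'
#' @return tibble with `family`, `activator`, `status` (known/candidate).
#' @export
activator_map <- function() {
  tibble(
    family = c("Csx1", "Csm6", "Can1-2", "Cami1", "CalpL", "SAVED-CHAT",
               "NucC", "Cam1", "Csx23", "CorA",
               "TIR-SAVED", "Cam2", "Cam3", "Csm6-2"),
    activator = c("cA4", "cA6", "cA4", "cA4", "cA4", "cA3",
                  "cA3", "cA4", "cA4", "SAM-AMP",
                  "cA4", "cA3", "unknown", "cA6"),
    status = c(rep("known", 10), rep("candidate", 4))
  )
}

#' Known effector family names
#' @return character vector of the ten known families.
#' @export
known_families <- function() {
  activator_map() |> filter(.data$status == "known") |> pull("family")
}

#' Proteins in a locus neighbourhood
#'
#' Returns proteins on the locus contig whose gene interval intersects
#' `[operon_start - flank, operon_end + flank)`. Genes partially overlapping
#' the window count (intersection semantics).
#'
#' @param locus one-row tibble (or list) with `genome_id`, `contig_id`,
#'   `operon_start`, `operon_end`.
#' @param proteins tibble with `protein_id`, `genome_id`, `contig_id`,
#'   `start`, `end`, `sequence`.
#' @param flank window extension in nucleotides on each side.
#' @return the subset of `proteins` in the neighbourhood.
#' @export
locus_neighborhood <- function(locus, proteins, flank = 4000) {
  lo <- locus$operon_start - flank
  hi <- locus$operon_end + flank
  proteins |>
    filter(.data$genome_id == locus$genome_id,
           .data$contig_id == locus$contig_id,
           .data$start < hi, .data$end > lo)
}

# Kyte-Doolittle hydropathy index (X scores 0).
KD_INDEX <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
              E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
              M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
              Y = -1.3, V = 4.2, X = 0)

#' Predict transmembrane segments by hydropathy
#'
#' Kyte-Doolittle hydropathy averaged over 19-residue windows; maximal
#' non-overlapping windows with mean at or above the threshold are counted
#' as transmembrane segments (a desk-scale stand-in for dedicated TM
#' predictors, sufficient to separate planted TM helices from soluble
#' proteins).
#'
#' @param sequence amino-acid string.
#' @param window window length in residues.
#' @param threshold mean-hydropathy cutoff for calling a TM window.
#' @return integer count of TM segments (0 for sequences shorter than the
#'   window).
#' @export
predict_tm <- function(sequence, window = 19, threshold = 1.6) {
  n <- nchar(sequence)
  if (n < window) return(0L)
  h <- KD_INDEX[strsplit(sequence, "", fixed = TRUE)[[1]]]
  h[is.na(h)] <- 0
  means <- as.numeric(stats::filter(h, rep(1 / window, window), sides = 1))
  means <- means[window:n]                     # means[i] = window ending at i
  count <- 0L
  i <- 1L
  n_win <- length(means)
  while (i <= n_win) {
    if (means[i] >= threshold) {
      count <- count + 1L
      i <- i + window                          # non-overlapping
    } else {
      i <- i + 1L
    }
  }
  count
}

#' Resolve a Cam1/Csx1 cross-hit by the transmembrane rule
#'
#' Both families share CARF sensory domains and cross-annotate; the
#' membrane-bound Cam1 requires a TM segment while the soluble Csx1 requires
#' its absence.
#'
#' @param tm_count predicted TM segment count for the protein.
#' @return `"Cam1"` if `tm_count >= 1`, else `"Csx1"`.
#' @export
resolve_cam1_csx1 <- function(tm_count) {
  if (tm_count >= 1) "Cam1" else "Csx1"
}

#' Type known effectors in a neighbourhood
#'
#' Every protein is scanned against every family's profile library; families
#' with any profile at `E <= cutoff` are collected. A single family resolves
#' as `unique`; multiple families resolve by best bitscore
#' (`best_bitscore`), except that a Cam1/Csx1 cross-hit is first resolved by
#' the transmembrane rule (`tm_rule`). Exact bitscore ties go to the
#' lexicographically smaller family name. The activator molecule is attached
#' from [activator_map()].
#'
#' @param neighborhood tibble with `protein_id` and `sequence` (typically
#'   from [locus_neighborhood()]).
#' @param effector_libraries named list: family -> list of calibrated
#'   profiles. Family names must exist in [activator_map()].
#' @param cutoff E-value cutoff for a significant family hit.
#' @param db_size database size for E-values.
#' @return tibble of effector hits: `protein_id`, `family`, `bitscore`,
#'   `evalue`, `tm_count`, `resolution`, `activator`, `qc_warning`.
#' @export
type_effectors <- function(neighborhood, effector_libraries, cutoff = 1e-3,
                           db_size = NULL) {
  amap <- activator_map()
  unknown_fams <- setdiff(names(effector_libraries), amap$family)
  if (length(unknown_fams)) {
    abort(paste0("effector libraries for unmapped families: ",
                 paste(unknown_fams, collapse = ", ")))
  }
  raw <- effector_raw_hits(neighborhood, effector_libraries, cutoff, db_size)
  if (nrow(raw) == 0) {
    return(tibble(protein_id = character(0), family = character(0),
                  bitscore = numeric(0), evalue = numeric(0),
                  tm_count = integer(0), resolution = character(0),
                  activator = character(0), qc_warning = character(0)))
  }
  seqs <- setNames(neighborhood$sequence, neighborhood$protein_id)
  raw |>
    group_by(.data$protein_id) |>
    group_modify(function(hits, key) {
      tm <- predict_tm(seqs[[key$protein_id]])
      fams <- hits$family
      resolution <- "unique"
      qc <- NA_character_
      if (length(fams) > 1 && all(c("Cam1", "Csx1") %in% fams)) {
        keep_fam <- resolve_cam1_csx1(tm)
        drop_fam <- setdiff(c("Cam1", "Csx1"), keep_fam)
        hits <- hits |> filter(.data$family != drop_fam)
        resolution <- "tm_rule"
      } else if (length(fams) > 1) {
        resolution <- "best_bitscore"
      }
      best <- hits |>
        arrange(desc(.data$bitscore), .data$family) |>
        slice(1)
      if (resolution == "tm_rule" && nrow(hits) > 1 &&
          best$family != resolve_cam1_csx1(tm)) {
        resolution <- "best_bitscore"          # a third family outscored the pair
      }
      if (best$family == "Cam1" && tm == 0) {
        qc <- "Cam1 call without a predicted TM segment"
      }
      tibble(family = best$family, bitscore = best$bitscore,
             evalue = best$evalue, tm_count = tm, resolution = resolution,
             qc_warning = qc)
    }) |>
    ungroup() |>
    left_join(amap |> select("family", "activator"), by = "family")
}

# All (protein, family) pairs with any library profile at E <= cutoff;
# best profile per pair.
effector_raw_hits <- function(neighborhood, effector_libraries, cutoff,
                              db_size = NULL) {
  db <- db_size %||% nrow(neighborhood)
  rows <- list()
  for (fam in names(effector_libraries)) {
    hits <- scan_library(effector_libraries[[fam]], neighborhood, db)
    if (nrow(hits) == 0) next
    hits <- hits |>
      mutate(family = fam) |>
      filter(.data$evalue <= cutoff) |>
      group_by(.data$protein_id) |>
      slice_max(.data$bitscore, n = 1, with_ties = FALSE) |>
      ungroup()
    rows[[fam]] <- hits
  }
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(protein_id = character(0), family = character(0),
                  bitscore = numeric(0), evalue = numeric(0),
                  window_start = integer(0), window_end = integer(0)))
  }
  out |> select("protein_id", "family", "bitscore", "evalue",
                "window_start", "window_end")
}

#' Report cross-hits between effector libraries
#'
#' Lists every protein significant for two or more families before
#' resolution. Cam1/Csx1 pairs are marked auto-resolved (the TM rule handles
#' them); anything else indicates overlapping profile libraries and drives
#' seed-alignment trimming.
#'
#' @param raw_hits tibble from [effector_raw_hits()] (all significant
#'   protein-family pairs).
#' @return tibble with `protein_id`, `families`, `bitscores`,
#'   `auto_resolved`.
#' @export
detect_cross_hits <- function(raw_hits) {
  raw_hits |>
    group_by(.data$protein_id) |>
    filter(n() >= 2) |>
    arrange(desc(.data$bitscore), .by_group = TRUE) |>
    summarise(families = paste(.data$family, collapse = ","),
              bitscores = paste(sprintf("%.2f", .data$bitscore), collapse = ","),
              auto_resolved = setequal(.data$family, c("Cam1", "Csx1")),
              .groups = "drop")
}
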