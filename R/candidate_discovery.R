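# Novel-effector candidate discovery: flagging poorly annotated genes in
# effector-less loci, permissive clustering, cross-locus occurrence counting
# with guilt-by-association, CorA ancillary-protein detection, and
# domain-fusion calls.

#' Flag candidate effector genes
#'
#' A locus gene is flagged when it is annotated `Unknown` or its annotation
#' E-value is worse than `evalue_floor`, and its locus contains no known
#' effector hit (loci with known effectors are excluded: their unannotated
#' genes are less likely to be the missing effector). An explicit exclusion
#' list replaces manual curation.
#'
#' @param annotations tibble from [read_annotation_table()] (locus members
#'   have non-`NA` `locus_id`).
#' @param effector_hits tibble with at least `locus_id` and `family`
#'   (the known-effector assignments per locus).
#' @param evalue_floor annotations with E-value above this are considered
#'   poor.
#' @param exclude character vector of protein ids to drop (curated
#'   non-CRISPR genes), e.g. read from a plain-text exclusion list.
#' @return tibble of candidate records: `protein_id`, `locus_id`,
#'   `flag_reason` (`unknown_annotation` / `poor_evalue`), `sequence`.
#' @export
flag_candidates <- function(annotations, effector_hits, evalue_floor = 1e-7,
                            exclude = character(0)) {
  effector_loci <- unique(effector_hits$locus_id)
  annotations |>
    filter(!is.na(.data$locus_id),
           !(.data$locus_id %in% effector_loci),
           !(.data$protein_id %in% exclude),
           .data$annotation_label == "Unknown" |
             (!is.na(.data$annotation_evalue) &
                .data$annotation_evalue > evalue_floor)) |>
    transmute(protein_id = .data$protein_id, locus_id = .data$locus_id,
              flag_reason = if_else(.data$annotation_label == "Unknown",
                                    "unknown_annotation", "poor_evalue"),
              sequence = .data$sequence)
}

#' Cluster flagged candidates
#'
#' Permissive greedy clustering (identity 0.4, word size 2 by default) that
#' groups diverged homologs of the same putative family.
#'
#' @param flagged tibble from [flag_candidates()].
#' @param identity_threshold,word_size clustering settings.
#' @return `flagged` with `cluster`, `representative`, `is_representative`.
#' @export
cluster_candidates <- function(flagged, identity_threshold = 0.4,
                               word_size = 2) {
  cl <- greedy_cluster(tibble(id = flagged$protein_id,
                              sequence = flagged$sequence),
                       identity_threshold, word_size)
  flagged |>
    left_join(cl |> select(protein_id = "id", "cluster", "representative",
                           "is_representative"),
              by = "protein_id")
}

#' Search candidate representatives across all loci
#'
#' For each representative, counts the loci containing a protein with
#' pairwise identity at or above `identity_min` (an in-package similarity
#' screen in place of an external BLAST step), and collects
#' guilt-by-association candidates: `Unknown`-annotated neighbours that
#' recur in at least `min_recurrence` of the matched loci.
#'
#' @param representatives tibble with `protein_id`, `sequence` (cluster
#'   representatives).
#' @param loci_proteins tibble with `protein_id`, `locus_id`, `sequence`,
#'   `annotation_label` for all proteins assigned to loci.
#' @param identity_min minimum identity for a cross-locus match.
#' @param min_recurrence matched-locus count a neighbour must reach for
#'   guilt-by-association.
#' @param uncharacterized_labels annotation labels treated as
#'   uncharacterized for guilt-by-association (genes that slipped through
#'   the primary flagging because of a significant hit against an
#'   uncharacterized protein class such as CasR).
#' @param exclude_ids protein ids never emitted as guilt-by-association
#'   (defaults to the representatives; pass all flagged candidates to avoid
#'   re-emitting cluster members).
#' @return list with `occurrences` (tibble: `protein_id`,
#'   `occurrence_count`, `matched_loci` list-column) and
#'   `guilt_by_association` (tibble: `protein_id`, `locus_id`,
#'   `flag_reason`, `sequence`).
#' @export
cross_locus_search <- function(representatives, loci_proteins,
                               identity_min = 0.3, min_recurrence = 2,
                               uncharacterized_labels = c("Unknown", "CasR"),
                               exclude_ids = representatives$protein_id) {
  occ <- map(seq_len(nrow(representatives)), function(k) {
    rs <- representatives$sequence[k]
    hit <- map_lgl(loci_proteins$sequence,
                   ~ pairwise_identity(rs, .x) >= identity_min)
    sort(unique(loci_proteins$locus_id[hit]))
  })
  occurrences <- tibble(protein_id = representatives$protein_id,
                        occurrence_count = lengths(occ),
                        matched_loci = occ)
  matched <- sort(unique(unlist(occ)))
  neighbours <- loci_proteins |>
    filter(.data$locus_id %in% matched,
           .data$annotation_label %in% uncharacterized_labels,
           !(.data$protein_id %in% exclude_ids))
  gba <- tibble(protein_id = character(0), locus_id = character(0),
                flag_reason = character(0), sequence = character(0))
  if (nrow(neighbours) > 0) {
    ncl <- greedy_cluster(tibble(id = neighbours$protein_id,
                                 sequence = neighbours$sequence),
                          identity_threshold = 0.4, word_size = 2)
    recur <- neighbours |>
      left_join(ncl |> select(protein_id = "id", "cluster"),
                by = "protein_id") |>
      group_by(.data$cluster) |>
      filter(n_distinct(.data$locus_id) >= min_recurrence) |>
      ungroup()
    gba <- recur |>
      transmute(protein_id = .data$protein_id, locus_id = .data$locus_id,
                flag_reason = "guilt_by_association",
                sequence = .data$sequence)
  }
  list(occurrences = occurrences, guilt_by_association = gba)
}

#' Detect CorA ancillary proteins in a CorA-containing locus
#'
#' Similarity screen of locus proteins against reference sequences of the
#' SAM-AMP degrading ancillary families (NrN, DEDD, SAM-lyase); the best
#' identity per family above `identity_min` marks the family present.
#' Non-CorA loci are skipped with a warning (the screen is only meaningful
#' where CorA is present).
#'
#' @param locus_proteins tibble with `protein_id`, `locus_id`, `sequence`
#'   for one locus.
#' @param ancillary_refs named list: family -> character vector of reference
#'   sequences.
#' @param identity_min minimum identity to call a family present.
#' @param has_cora does this locus carry a CorA effector hit?
#' @return one-row tibble: `locus_id` plus one logical column per ancillary
#'   family, or `NULL` when skipped.
#' @export
detect_cora_ancillary <- function(locus_proteins, ancillary_refs,
                                  identity_min = 0.3, has_cora = TRUE) {
  if (!has_cora) {
    warn("locus without a CorA hit skipped in ancillary detection")
    return(NULL)
  }
  pres <- map_lgl(ancillary_refs, function(refs) {
    any(map_lgl(locus_proteins$sequence, function(s) {
      any(map_lgl(refs, ~ pairwise_identity(s, .x) >= identity_min))
    }))
  })
  bind_cols(tibble(locus_id = locus_proteins$locus_id[1]),
            as_tibble(as.list(pres)))
}

#' Detect multi-domain fusion proteins
#'
#' A fusion is called when at least two families hit the protein at
#' `E <= cutoff` with best windows that do not overlap; domains are reported
#' in N-to-C order. Overlapping windows are ambiguous cross-hits, not
#' fusions, and return `NULL`.
#'
#' @param protein one-row tibble with `protein_id` and `sequence`.
#' @param libraries named list: family -> list of calibrated profiles.
#' @param cutoff E-value cutoff.
#' @param db_size database size for E-values.
#' @return tibble of domains (`protein_id`, `family`, `window_start`,
#'   `window_end`, ordered N to C) or `NULL`.
#' @export
detect_fusions <- function(protein, libraries, cutoff = 1e-3, db_size = 1) {
  best <- list()
  for (fam in names(libraries)) {
    fam_best <- NULL
    for (p in libraries[[fam]]) {
      h <- scan_profile(p, protein$sequence)
      if (is.null(h)) next
      h$evalue <- profile_evalue(h$bitscore, p, db_size)
      if (is.null(fam_best) || h$bitscore > fam_best$bitscore) fam_best <- h
    }
    if (!is.null(fam_best) && fam_best$evalue <= cutoff) {
      best[[fam]] <- mutate(fam_best, family = fam)
    }
  }
  if (length(best) < 2) return(NULL)
  doms <- bind_rows(best) |> arrange(desc(.data$bitscore))
  kept <- doms[1, ]
  for (k in seq_len(nrow(doms))[-1]) {
    cand <- doms[k, ]
    overlaps <- any(cand$window_start < kept$window_end &
                      cand$window_end > kept$window_start)
    if (!overlaps) kept <- bind_rows(kept, cand)
  }
  if (nrow(kept) < 2) return(NULL)
  kept |>
    arrange(.data$window_start) |>
    transmute(protein_id = protein$protein_id, family = .data$family,
              window_start = .data$window_start,
              window_end = .data$window_end)
}

#' CorA tree with per-leaf ancillary metadata
#'
#' Neighbour-joining tree of CorA sequences (see [build_tree()]) plus a
#' metadata table recording, per leaf, the ancillary-family presence vector,
#' Csm6-2 association, and locus subtype.
#'
#' @param cora tibble with `id`, `sequence` and any metadata columns
#'   (`subtype`, ancillary presence flags, `csm6_2`).
#' @return list with `newick` (string) and `metadata` (tibble, one row per
#'   leaf).
#' @export
build_cora_tree <- function(cora) {
  nwk <- build_tree(cora |> select("id", "sequence"))
  list(newick = nwk, metadata = cora |> select(-"sequence"))
}
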