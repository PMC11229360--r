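# Cas10 identification and characterization: length/E-value screened profile
# search, dereplication, the two-stage cyclase rule (profile hit AND literal
# GGDD-variant motif), the positional HD rule, hybrid-locus filtering, and a
# neighbour-joining tree of representatives.

#' The cyclase motif variant table
#'
#' GGDD plus the nine variants observed in Cas10s from loci with a known
#' effector (and thus likely active cyclases).
#'
#' @return character vector of ten 4-mers.
#' @export
motif_variants <- function() {
  c("GGDD", "AGDD", "GGED", "GGDE", "SGDD", "DGDD",
    "AGDE", "EGDD", "KGDD", "GEDD")
}

#' Identify Cas10 proteins
#'
#' Only proteins of at least `min_len` residues are scanned (shorter proteins
#' are unlikely to be functional Cas10s); a protein qualifies when any Cas10
#' profile hit reaches `E <= cutoff`. The best profile by bitscore is
#' recorded.
#'
#' @param proteins tibble with `protein_id` and `sequence`.
#' @param cas10_profiles list of calibrated `aa_profile` objects.
#' @param min_len minimum protein length in residues.
#' @param cutoff E-value cutoff.
#' @param db_size database size for E-values; defaults to the number of
#'   proteins scanned.
#' @return tibble of provisional Cas10 records: `protein_id`,
#'   `best_cas10_profile`, `cas10_bitscore`, `cas10_evalue`.
#' @export
find_cas10 <- function(proteins, cas10_profiles, min_len = 500,
                       cutoff = 1e-20, db_size = NULL) {
  if (length(cas10_profiles) == 0) abort("empty Cas10 profile library")
  long <- proteins |> filter(nchar(.data$sequence) >= min_len)
  if (nrow(long) == 0) {
    return(tibble(protein_id = character(0), best_cas10_profile = character(0),
                  cas10_bitscore = numeric(0), cas10_evalue = numeric(0)))
  }
  hits <- scan_library(cas10_profiles, long, db_size %||% nrow(long))
  hits |>
    filter(.data$evalue <= cutoff) |>
    group_by(.data$protein_id) |>
    slice_max(.data$bitscore, n = 1, with_ties = FALSE) |>
    ungroup() |>
    transmute(protein_id = .data$protein_id,
              best_cas10_profile = .data$profile_name,
              cas10_bitscore = .data$bitscore,
              cas10_evalue = .data$evalue)
}

#' Dereplicate Cas10 proteins
#'
#' Greedy identity clustering at the dereplication settings (0.9 identity,
#' word size 5 by default), which collapses near-identical Cas10s from
#' redundant assemblies. Exactly one representative per cluster; downstream
#' census statistics are computed on representatives' loci only.
#'
#' @param cas10s tibble with `protein_id` and `sequence`.
#' @param identity_threshold identity cutoff.
#' @param word_size prefilter word size.
#' @return `cas10s` with `cluster` and `cluster_rep` columns.
#' @export
dereplicate_cas10 <- function(cas10s, identity_threshold = 0.9, word_size = 5) {
  cl <- greedy_cluster(tibble(id = cas10s$protein_id,
                              sequence = cas10s$sequence),
                       identity_threshold, word_size)
  cas10s |>
    left_join(cl |> select(protein_id = "id", "cluster",
                           cluster_rep = "is_representative"),
              by = "protein_id")
}

#' Detect the Cas10 cyclase (PALM) domain
#'
#' Two-stage rule: a cyclase-profile hit with `E <= cutoff` AND a literal
#' occurrence of one of the ten motif variants anywhere in the sequence.
#' A profile hit without a literal motif is called cyclase-negative (the
#' motif check removes false positives), as is a literal motif without a
#' profile hit. When several variants occur the first in N-to-C order is
#' recorded.
#'
#' @param cas10s tibble with `protein_id` and `sequence`.
#' @param cyclase_profiles list of calibrated profiles built from windows
#'   spanning 50 residues N-terminal and 100 residues C-terminal of the
#'   motif.
#' @param motif_table character vector of literal motifs; see
#'   [motif_variants()].
#' @param cutoff E-value cutoff.
#' @param db_size database size for E-values.
#' @return `cas10s` with `has_cyclase`, `cyclase_motif`, `cyclase_motif_pos`
#'   (0-based) and `cyclase_evalue` columns.
#' @export
detect_cyclase <- function(cas10s, cyclase_profiles,
                           motif_table = motif_variants(), cutoff = 1e-3,
                           db_size = NULL) {
  if (nrow(cas10s) == 0) {
    return(mutate(cas10s, has_cyclase = logical(0),
                  cyclase_motif = character(0),
                  cyclase_motif_pos = integer(0),
                  cyclase_evalue = numeric(0)))
  }
  db <- db_size %||% nrow(cas10s)
  res <- map(seq_len(nrow(cas10s)), function(k) {
    s <- cas10s$sequence[k]
    best_e <- Inf
    for (p in cyclase_profiles) {
      h <- scan_profile(p, s)
      if (!is.null(h)) best_e <- min(best_e, profile_evalue(h$bitscore, p, db))
    }
    loc <- str_locate(s, paste(motif_table, collapse = "|"))
    motif_found <- !is.na(loc[1, 1])
    list(has_cyclase = motif_found && best_e <= cutoff,
         cyclase_motif = if (motif_found) str_sub(s, loc[1, 1], loc[1, 2]) else NA_character_,
         cyclase_motif_pos = if (motif_found) as.integer(loc[1, 1] - 1L) else NA_integer_,
         cyclase_evalue = best_e)
  })
  cas10s |>
    mutate(has_cyclase = map_lgl(res, "has_cyclase"),
           cyclase_motif = map_chr(res, "cyclase_motif"),
           cyclase_motif_pos = map_int(res, "cyclase_motif_pos"),
           cyclase_evalue = map_dbl(res, "cyclase_evalue"))
}

#' Extract the sequence window around a cyclase motif
#'
#' Returns the stretch from 50 residues N-terminal of the motif to 100
#' residues C-terminal of it (clamped at the sequence ends); these windows
#' are what cyclase seed alignments are built from.
#'
#' @param sequence amino-acid string.
#' @param motif_pos 0-based start of the 4-mer motif.
#' @param upstream,downstream residues kept on each side of the motif.
#' @return the windowed subsequence.
#' @export
extract_motif_window <- function(sequence, motif_pos, upstream = 50,
                                 downstream = 100) {
  n <- nchar(sequence)
  from <- max(0L, motif_pos - upstream)         # 0-based half-open
  to <- min(n, motif_pos + 4L + downstream)
  str_sub(sequence, from + 1L, to)
}

#' Detect the Cas10 HD nuclease domain
#'
#' Positional two-stage rule: the literal dipeptide `HD` must start within
#' the first 50 residues (0-based start index <= 48, so the whole dipeptide
#' lies in residues 1-50), AND residues 10-40 (1-based inclusive) must hit
#' the HD profile at `E <= cutoff`. Sequences shorter than 40 residues are
#' HD-negative with a warning.
#'
#' @param cas10s tibble with `protein_id` and `sequence`.
#' @param hd_profile calibrated profile built from residues 10-40 of
#'   HD-positive training sequences.
#' @param cutoff E-value cutoff (relaxed, to accommodate HD-domain
#'   diversity).
#' @param db_size database size for E-values.
#' @param first_n window (in residues from the N terminus) within which the
#'   literal `HD` must occur.
#' @return `cas10s` with `has_hd` and `hd_evalue` columns.
#' @export
detect_hd <- function(cas10s, hd_profile, cutoff = 1e-1, db_size = NULL,
                      first_n = 50) {
  if (nrow(cas10s) == 0) {
    return(mutate(cas10s, has_hd = logical(0), hd_evalue = numeric(0)))
  }
  db <- db_size %||% nrow(cas10s)
  short <- nchar(cas10s$sequence) < 40
  if (any(short)) {
    warn(sprintf("%d Cas10 sequence(s) shorter than 40 residues: HD set to FALSE",
                 sum(short)))
  }
  res <- map(seq_len(nrow(cas10s)), function(k) {
    s <- cas10s$sequence[k]
    if (nchar(s) < 40) return(list(has_hd = FALSE, hd_evalue = NA_real_))
    head_region <- str_sub(s, 1L, first_n)
    hd_pos <- str_locate(head_region, "HD")[1, 1]        # 1-based or NA
    literal_ok <- !is.na(hd_pos) && (hd_pos - 1L) <= (first_n - 2L)
    slice <- str_sub(s, 10L, 40L)                        # residues 10-40
    h <- scan_profile(hd_profile, slice)
    e <- if (is.null(h)) Inf else profile_evalue(h$bitscore, hd_profile, db)
    list(has_hd = literal_ok && e <= cutoff, hd_evalue = e)
  })
  cas10s |>
    mutate(has_hd = map_lgl(res, "has_hd"),
           hd_evalue = map_dbl(res, "hd_evalue"))
}

# Does a subtype string name a type III (sub)type? Hybrid tags join component
# types with "/".
subtype_tokens <- function(subtype) strsplit(subtype, "/", fixed = TRUE)[[1]]

#' Filter hybrid and non-type-III loci
#'
#' Removes loci carrying two or more Cas10 genes (ambiguous hybrids), renames
#' surviving hybrids of a type III subtype with a non-III CRISPR type to the
#' type III subtype, and drops loci with no type III component.
#'
#' @param loci tibble from [build_locus_table()] (columns `subtype`,
#'   `n_cas10`, ...). Hybrid subtypes are encoded as `"III-B/I-C"`.
#' @return the filtered locus tibble with normalized `subtype`.
#' @export
filter_hybrid_loci <- function(loci) {
  loci |>
    filter(.data$n_cas10 < 2) |>
    mutate(subtype = map_chr(.data$subtype, function(st) {
      if (is.na(st)) return(NA_character_)
      tok <- subtype_tokens(st)
      iii <- tok[startsWith(tok, "III")]
      if (length(iii) == 0) NA_character_ else iii[1]
    })) |>
    filter(!is.na(.data$subtype))
}

#' Neighbour-joining tree of representative sequences
#'
#' Distances are `1 - pairwise_identity` over all pairs; the tree is built by
#' neighbour joining, negative branch lengths are clamped to zero, and the
#' tree is midpoint-rooted for display. Returns a Newick string whose leaf
#' set equals the input ids.
#'
#' @param representatives tibble with `id` and `sequence` (>= 3 rows).
#' @return a Newick string.
#' @export
build_tree <- function(representatives) {
  n <- nrow(representatives)
  if (n < 3) abort("tree construction requires at least 3 sequences")
  d <- matrix(0, n, n, dimnames = list(representatives$id, representatives$id))
  for (pair in combn(n, 2, simplify = FALSE)) {
    i <- pair[1]; j <- pair[2]
    d[i, j] <- d[j, i] <- 1 - pairwise_identity(representatives$sequence[i],
                                                representatives$sequence[j])
  }
  tr <- ape::nj(stats::as.dist(d))
  tr$edge.length[tr$edge.length < 0] <- 0
  tr <- phangorn::midpoint(tr)
  ape::write.tree(tr)
}
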