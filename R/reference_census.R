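# The printed count arithmetic of a published large-scale census of type III
# CRISPR-Cas loci (1113 loci from complete prokaryotic genomes), shipped as
# plain-text reference tables. The locus-level fixture rebuilt from them lets
# the counting, activator-fraction and co-occurrence operations reproduce the
# published summary percentages exactly.

#' Published per-family locus counts
#'
#' @return tibble with `family` and `n_loci` for the ten known effector
#'   families (summing to the published 908 effector instances).
#' @export
reference_family_counts <- function() {
  readr::read_tsv(system.file("extdata", "published_census_counts.tsv",
                              package = "cas10census"),
                  col_types = "ci", progress = FALSE)
}

#' Published census summary quantities
#'
#' Locus total, HD and cyclase counts, and the solo/co-occurring split of
#' Csx1.
#'
#' @return named integer vector.
#' @export
reference_census_summary <- function() {
  tab <- readr::read_tsv(system.file("extdata", "published_census_summary.tsv",
                                     package = "cas10census"),
                         col_types = "ci", progress = FALSE)
  setNames(tab$value, tab$key)
}

#' Locus-level fixture reproducing the published count arithmetic
#'
#' Reconstructs a census table whose per-family counts, Csx1 solo/co split,
#' HD count and cyclase count equal the published numbers. Which family the
#' co-occurring Csx1 loci pair with is immaterial for the count arithmetic;
#' Cami1 is used (the published Csx1+Cami1 configuration), and the remaining
#' Cami1 loci are solo. All other families are placed solo, and
#' effector-less loci pad the table to the published locus total.
#'
#' @return census tibble with `locus_id`, `genome_id`, `subtype`,
#'   `has_cyclase`, `has_hd`, `families` (list-column), `candidates`,
#'   `activators`, `n_type3_loci_in_genome`.
#' @export
reference_census <- function() {
  counts <- reference_family_counts()
  s <- reference_census_summary()
  cnt <- setNames(counts$n_loci, counts$family)
  fam_sets <- c(
    rep(list(c("Csx1", "Cami1")), s[["csx1_cooccurring"]]),
    rep(list("Csx1"), s[["csx1_solo"]]),
    rep(list("Cami1"), cnt[["Cami1"]] - s[["csx1_cooccurring"]]),
    unlist(lapply(setdiff(names(cnt), c("Csx1", "Cami1")),
                  function(f) rep(list(f), cnt[[f]])), recursive = FALSE),
    rep(list(character(0)), s[["n_loci"]] - s[["csx1_solo"]] -
          s[["csx1_cooccurring"]] -
          sum(cnt[setdiff(names(cnt), "Csx1")]) +
          s[["csx1_cooccurring"]])
  )
  n <- length(fam_sets)
  stopifnot(n == s[["n_loci"]])
  amap <- activator_map()
  tibble(locus_id = sprintf("ref_locus_%04d", seq_len(n)),
         genome_id = sprintf("ref_genome_%04d", seq_len(n)),
         subtype = "III-A",
         has_cyclase = seq_len(n) <= s[["n_cyclase"]],
         has_hd = seq_len(n) <= s[["n_hd"]],
         families = fam_sets,
         candidates = rep(list(character(0)), n),
         activators = map(fam_sets, function(fs) {
           sort(unique(amap$activator[amap$family %in% fs]))
         }),
         n_type3_loci_in_genome = 1L)
}
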