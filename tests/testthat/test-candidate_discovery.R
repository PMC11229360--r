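# Candidate flagging, permissive clustering, cross-locus search with
# guilt-by-association, CorA ancillary detection and fusion calls.

toy_annotations <- function() {
  withr::with_seed(61, {
    tibble::tibble(
      protein_id = sprintf("p%02d", 1:6),
      locus_id = c("L1", "L1", "L2", "L2", "L3", NA),
      annotation_label = c("Unknown", "Cas10", "Unknown", "CasR", "Csm3",
                           "Unknown"),
      annotation_evalue = c(NA, 1e-50, NA, 1e-5, 1e-9, NA),
      sequence = replicate(6, rand_seq(120)))
  })
}

test_that("candidate flagging excludes effector loci and good annotations", {
  ann <- toy_annotations()
  hits <- tibble::tibble(locus_id = "L1", family = "Csx1")
  flagged <- flag_candidates(ann, hits)
  # p01 (Unknown) sits in an effector locus; p03 (Unknown) and p04 (poor
  # E-value) are in effector-less L2; p05 passes the floor; p06 has no locus
  expect_setequal(flagged$protein_id, c("p03", "p04"))
  expect_equal(flagged$flag_reason[flagged$protein_id == "p03"],
               "unknown_annotation")
  expect_equal(flagged$flag_reason[flagged$protein_id == "p04"],
               "poor_evalue")

  # the curated exclusion list removes entries
  expect_setequal(flag_candidates(ann, hits, exclude = "p04")$protein_id,
                  "p03")
  # no candidate ever comes from a locus with a known effector
  expect_false(any(flagged$locus_id %in% hits$locus_id))
})

test_that("candidate clustering at 0.4/2 matches the brute-force oracle", {
  withr::with_seed(62, {
    base1 <- rand_seq(80)
    base2 <- rand_seq(80)
    mut <- function(s, k) {
      ch <- strsplit(s, "")[[1]]
      idx <- sample(length(ch), k)
      ch[idx] <- sample(AA, k, replace = TRUE)
      paste(ch, collapse = "")
    }
    seqs <- tibble::tibble(
      id = sprintf("c%02d", 1:10),
      sequence = c(base1, mut(base1, 30), mut(base1, 35), base2,
                   mut(base2, 30), replicate(5, rand_seq(80))))
  })
  flagged <- tibble::tibble(protein_id = seqs$id, locus_id = "LX",
                            flag_reason = "unknown_annotation",
                            sequence = seqs$sequence)
  got <- cluster_candidates(flagged)
  want <- oracle_cluster(seqs, 0.4)
  canon <- function(parts) {
    sort(vapply(parts, function(x) paste(sort(x), collapse = ","), character(1)))
  }
  expect_equal(canon(unname(split(got$protein_id, got$cluster))),
               canon(unname(want)))
  # ~45% identical pair lands in one cluster, unrelated pair in two
  pair <- cluster_candidates(flagged[c(1, 2), ])
  expect_equal(max(pair$cluster), 1)
  pair2 <- cluster_candidates(flagged[c(1, 4), ])
  expect_equal(max(pair2$cluster), 2)
})

test_that("cross-locus search counts planted occurrences and finds
           guilt-by-association partners", {
  withr::with_seed(63, {
    fam <- rand_seq(150)          # candidate family reference
    partner <- rand_seq(140)      # colocalized partner family
    mut <- function(s) {
      ch <- strsplit(s, "")[[1]]
      idx <- sample(length(ch), round(0.08 * length(ch)))
      ch[idx] <- sample(AA, length(idx), replace = TRUE)
      paste(ch, collapse = "")
    }
    loci_proteins <- dplyr::bind_rows(
      lapply(1:5, function(k) tibble::tibble(
        protein_id = sprintf("L%d_cand", k), locus_id = sprintf("L%d", k),
        sequence = mut(fam), annotation_label = "Unknown")),
      lapply(1:3, function(k) tibble::tibble(
        protein_id = sprintf("L%d_partner", k), locus_id = sprintf("L%d", k),
        sequence = mut(partner), annotation_label = "CasR")),
      tibble::tibble(protein_id = "L9_solo", locus_id = "L9",
                     sequence = rand_seq(150),
                     annotation_label = "Unknown"))
  })
  reps <- tibble::tibble(protein_id = c("L1_cand", "L9_solo"),
                         sequence = c(loci_proteins$sequence[1],
                                      loci_proteins$sequence[9]))
  # all flagged candidates are excluded from guilt-by-association, as in the
  # pipeline (not just the representatives)
  res <- cross_locus_search(reps, loci_proteins,
                            exclude_ids = c(sprintf("L%d_cand", 1:5),
                                            "L9_solo"))
  expect_equal(res$occurrences$occurrence_count[1], 5L)
  expect_equal(res$occurrences$occurrence_count[2], 1L)
  expect_setequal(res$occurrences$matched_loci[[1]],
                  sprintf("L%d", 1:5))
  # the partner recurs in 3 matched loci -> guilt-by-association
  expect_setequal(res$guilt_by_association$protein_id,
                  sprintf("L%d_partner", 1:3))
  expect_true(all(res$guilt_by_association$flag_reason ==
                    "guilt_by_association"))
  # raising the recurrence requirement above its count suppresses it
  res6 <- cross_locus_search(reps, loci_proteins, min_recurrence = 6,
                             exclude_ids = c(sprintf("L%d_cand", 1:5),
                                             "L9_solo"))
  expect_equal(nrow(res6$guilt_by_association), 0)
})

test_that("CorA ancillary detection screens reference families per locus", {
  withr::with_seed(64, {
    refs <- list(NrN = rand_seq(120), DEDD = rand_seq(120),
                 `SAM-lyase` = rand_seq(120))
    mut <- function(s) {
      ch <- strsplit(s, "")[[1]]
      idx <- sample(length(ch), 10)
      ch[idx] <- sample(AA, 10, replace = TRUE)
      paste(ch, collapse = "")
    }
    with_nrn <- tibble::tibble(
      protein_id = c("a", "b"), locus_id = "LC",
      sequence = c(mut(refs$NrN), rand_seq(130)))
    bare <- tibble::tibble(protein_id = "c", locus_id = "LB",
                           sequence = rand_seq(130))
  })
  r1 <- detect_cora_ancillary(with_nrn, refs)
  expect_true(r1$NrN)
  expect_false(r1$DEDD)
  expect_false(r1$`SAM-lyase`)
  r2 <- detect_cora_ancillary(bare, refs)
  expect_false(any(unlist(r2[, -1])))
  expect_warning(r3 <- detect_cora_ancillary(bare, refs, has_cora = FALSE),
                 "skipped")
  expect_null(r3)
})

test_that("fusion calls require two non-overlapping significant domains", {
  withr::with_seed(65, {
    sig_cora <- rand_seq(40)
    sig_csm62 <- rand_seq(40)
    ctx <- rand_seq(60)
  })
  libs <- list(CorA = list(toy_profile(sig_cora, "cora", "CorA", seed = 71)),
               `Csm6-2` = list(toy_profile(sig_csm62, "c62", "Csm6-2",
                                           seed = 72)))
  concatemer <- paste0(ctx, sig_cora, ctx, sig_csm62, ctx)
  fc <- detect_fusions(tibble::tibble(protein_id = "fus",
                                      sequence = concatemer), libs)
  expect_equal(nrow(fc), 2)
  expect_equal(fc$family, c("CorA", "Csm6-2"))  # N-to-C order
  expect_true(all(fc$window_end[1] <= fc$window_start[2]))

  # reversed construct: call presence unchanged, domain order follows N->C
  rev_cat <- paste0(ctx, sig_csm62, ctx, sig_cora, ctx)
  fr <- detect_fusions(tibble::tibble(protein_id = "rev",
                                      sequence = rev_cat), libs)
  expect_equal(fr$family, c("Csm6-2", "CorA"))

  single <- paste0(ctx, sig_cora, ctx)
  expect_null(detect_fusions(tibble::tibble(protein_id = "s",
                                            sequence = single), libs))

  # two libraries built on the same signature: overlapping windows, no call
  overlap_libs <- list(
    CorA = list(toy_profile(sig_cora, "a", "CorA", seed = 73)),
    NucC = list(toy_profile(sig_cora, "b", "NucC", seed = 74)))
  expect_null(detect_fusions(tibble::tibble(protein_id = "o",
                                            sequence = single), overlap_libs))
})

test_that("the CorA tree carries one metadata row per leaf with clade structure", {
  withr::with_seed(66, {
    famA <- rand_seq(120)
    famB <- rand_seq(120)
    mut <- function(s) {
      ch <- strsplit(s, "")[[1]]
      idx <- sample(length(ch), 8)
      ch[idx] <- sample(AA, 8, replace = TRUE)
      paste(ch, collapse = "")
    }
    cora <- tibble::tibble(
      id = sprintf("cora%d", 1:6),
      sequence = c(famA, mut(famA), mut(famA), famB, mut(famB), mut(famB)),
      subtype = "III-B",
      csm6_2 = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  })
  res <- build_cora_tree(cora)
  tr <- ape::read.tree(text = res$newick)
  expect_equal(nrow(res$metadata), length(tr$tip.label))
  coph <- ape::cophenetic.phylo(tr)
  # the two seeded families separate into clades; Csm6-2-associated leaves
  # cluster together
  expect_lt(max(coph[1:3, 1:3]), min(coph[1:3, 4:6]))
  expect_lt(max(coph[4:6, 4:6]), min(coph[4:6, 1:3]))
})
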