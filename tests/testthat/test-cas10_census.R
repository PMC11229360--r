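# Cas10 identification, the two-stage cyclase and HD rules, hybrid
# filtering and tree construction.

# shared fixtures: profiles from the synthetic seed machinery
cfg <- synth_config(n_genomes = 2, seed = 17)
alns <- make_seed_alignments(cfg)
cas10_prof <- calibrate_profile(build_profile(alns$Cas10, "Cas10", "Cas10"),
                                seed = 1)
cyc_prof <- calibrate_profile(
  build_profile(alns$Cas10_cyclase, "Cas10_cyclase", "Cas10_cyclase"),
  seed = 2)
hd_prof <- calibrate_profile(build_profile(alns$Cas10_HD, "Cas10_HD",
                                           "Cas10_HD"), seed = 3)
blocks <- cas10census:::cas10_blocks(cfg$seed)

planted_cas10 <- function(len = 600, sig_at = 60) {
  s <- rand_seq(len)
  stringr::str_sub(s, sig_at, sig_at + 59) <- blocks$signature
  s
}

test_that("Cas10 search applies the length filter and the E-value cutoff", {
  withr::with_seed(21, {
    prot <- tibble::tibble(
      protein_id = c("hit", "short", "noise"),
      sequence = c(planted_cas10(600),
                   substr(planted_cas10(600), 1, 499),
                   rand_seq(600)))
  })
  found <- find_cas10(prot, list(cas10_prof))
  expect_equal(found$protein_id, "hit")
  expect_equal(found$best_cas10_profile, "Cas10")
  expect_lte(found$cas10_evalue, 1e-20)
  expect_error(find_cas10(prot, list()), "empty")
})

test_that("dereplication collapses identical Cas10s and matches the oracle", {
  withr::with_seed(22, {
    a <- planted_cas10(550)
    b <- rand_seq(550)
  })
  two <- tibble::tibble(protein_id = c("g1_cas10", "g2_cas10"),
                        sequence = c(a, a))
  dr <- dereplicate_cas10(two)
  expect_equal(sum(dr$cluster_rep), 1)

  diff <- tibble::tibble(protein_id = c("x", "y"),
                         sequence = c(a, b))
  expect_equal(sum(dereplicate_cas10(diff)$cluster_rep), 2)

  withr::with_seed(23, {
    toy <- tibble::tibble(
      id = sprintf("t%d", 1:6),
      sequence = c(a, sub("^(.{100}).", "\\1W", a), b,
                   sub("^(.{200}).", "\\1W", b), rand_seq(540), rand_seq(530)))
  })
  got <- dereplicate_cas10(tibble::tibble(protein_id = toy$id,
                                          sequence = toy$sequence))
  want <- oracle_cluster(toy, 0.9)
  canon <- function(parts) {
    sort(vapply(parts, function(x) paste(sort(x), collapse = ","), character(1)))
  }
  expect_equal(canon(unname(split(got$protein_id, got$cluster))),
               canon(unname(want)))
})

test_that("the cyclase call requires both the profile hit and a literal motif", {
  withr::with_seed(24, {
    backbone <- rand_seq(500)
  })
  # scrub chance occurrences of motif variants from the backbone
  for (m in motif_variants()) backbone <- gsub(m, "PQPQ", backbone,
                                               fixed = TRUE)
  with_both <- backbone
  stringr::str_sub(with_both, 200, 353) <-
    cas10census:::place_motif(blocks$cyclase_context, "GGDD")
  # profile hit but motif slot wiped (no literal variant anywhere)
  ctx_no_motif <- blocks$cyclase_context
  stringr::str_sub(ctx_no_motif, 51, 54) <- "PPPP"
  profile_only <- backbone
  stringr::str_sub(profile_only, 200, 353) <- ctx_no_motif
  # literal motif in a sequence the profile does not recognise
  motif_only <- backbone
  stringr::str_sub(motif_only, 200, 203) <- "GGDD"

  tbl <- tibble::tibble(
    protein_id = c("both", "profile_only", "motif_only"),
    sequence = c(with_both, profile_only, motif_only))
  res <- detect_cyclase(tbl, list(cyc_prof))
  expect_equal(res$has_cyclase, c(TRUE, FALSE, FALSE))
  expect_equal(res$cyclase_motif[1], "GGDD")
  expect_equal(res$cyclase_motif_pos[1], 249)  # 0-based slot at 200+50-1

  # variant motifs count, and the first occurrence N->C is recorded
  v <- with_both
  stringr::str_sub(v, 250, 253) <- "KGDD"
  stringr::str_sub(v, 100, 103) <- "AGDE"
  rv <- detect_cyclase(tibble::tibble(protein_id = "v", sequence = v),
                       list(cyc_prof))
  expect_true(rv$has_cyclase)
  expect_equal(rv$cyclase_motif, "AGDE")

  # invariant to appending sequence after the profile-hit window
  withr::with_seed(25, {
    appended <- paste0(with_both, rand_seq(150))
  })
  ra <- detect_cyclase(tibble::tibble(protein_id = "app",
                                      sequence = appended), list(cyc_prof))
  expect_true(ra$has_cyclase)
})

test_that("motif windows clamp at sequence boundaries", {
  s <- strrep("A", 500)
  expect_equal(nchar(extract_motif_window(s, 200)), 154)
  expect_equal(nchar(extract_motif_window(s, 10)), 114)
  expect_equal(extract_motif_window(s, 10), substr(s, 1, 114))
  expect_equal(nchar(extract_motif_window(s, 480)), 70)  # 50 + 20 to the end
})

test_that("the HD call combines the positional literal rule with the profile", {
  withr::with_seed(26, {
    pos <- rand_seq(500)
  })
  stringr::str_sub(pos, 10, 40) <- blocks$hd_block   # HD at residues 13-14
  late <- gsub("HD", "QQ", rand_seq(500), fixed = TRUE)
  late <- paste0(substr(late, 1, 79), "HD", substr(late, 82, nchar(late)))
  none <- gsub("HD", "QQ", rand_seq(500), fixed = TRUE)

  tbl <- tibble::tibble(protein_id = c("pos", "late", "none"),
                        sequence = c(pos, late, none))
  res <- detect_hd(tbl, hd_prof)
  expect_equal(res$has_hd, c(TRUE, FALSE, FALSE))

  expect_warning(
    short <- detect_hd(tibble::tibble(protein_id = "s", sequence = "MHDAC"),
                       hd_prof),
    "shorter")
  expect_false(short$has_hd)
})

test_that("hybrid filtering drops multi-Cas10 loci and renames hybrids", {
  loci <- tibble::tibble(
    locus_id = c("two_cas10", "hybrid", "type1", "plain"),
    genome_id = "g",
    subtype = c("III-A", "III-B/I-C", "I-E", "III-D"),
    n_cas10 = c(2L, 1L, 0L, 1L))
  out <- filter_hybrid_loci(loci)
  expect_setequal(out$locus_id, c("hybrid", "plain"))
  expect_equal(out$subtype[out$locus_id == "hybrid"], "III-B")
  expect_equal(out$subtype[out$locus_id == "plain"], "III-D")
})

test_that("neighbour joining recovers forced topologies and exports valid Newick", {
  withr::with_seed(27, {
    a <- rand_seq(100)
    c_ <- rand_seq(100)
  })
  b <- sub("^(.{10})." , "\\1W", a)   # one substitution from a
  d <- sub("^(.{50})." , "\\1W", c_)
  tbl <- tibble::tibble(id = c("A", "B", "C", "D"),
                        sequence = c(a, b, c_, d))
  nwk <- build_tree(tbl)
  tr <- ape::read.tree(text = nwk)
  expect_setequal(tr$tip.label, c("A", "B", "C", "D"))
  expect_true(all(tr$edge.length >= 0))
  coph <- ape::cophenetic.phylo(tr)
  expect_lt(coph["A", "B"], coph["A", "C"])
  expect_lt(coph["C", "D"], coph["C", "A"])
  expect_error(build_tree(tbl[1:2, ]), "at least 3")
})
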