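# The PSSM/Gumbel/clustering primitives, checked against brute-force
# oracles and closed forms.

test_that("profile construction follows the pseudocount log-odds formula", {
  # identical seeds: observed letter scores positive and equal across columns
  p <- build_profile(rep("ACDEF", 3))
  obs <- diag(p$log_odds[, c("A", "C", "D", "E", "F")])
  expect_true(all(obs > 0))
  expect_equal(max(obs) - min(obs), 0)

  # monotonicity in counts: a 3/3 column scores its letter above a 1/3 column
  p2 <- build_profile(c("AADEF", "ACDEF", "ADDEF"))
  expect_gt(p2$log_odds[1, "A"], p2$log_odds[2, "A"])

  # two-sequence toy, hand-computed from the formula
  toy <- build_profile(c("ACDEF", "ACDEG"))
  expect_equal(unname(toy$log_odds[1, "A"]), log2((2 + 0.05) / 3 / 0.05))
  expect_equal(unname(toy$log_odds[5, "F"]), log2((1 + 0.05) / 3 / 0.05))
  expect_equal(unname(toy$log_odds[5, "G"]), log2((1 + 0.05) / 3 / 0.05))
  expect_equal(unname(toy$log_odds[1, "C"]), log2((0 + 0.05) / 3 / 0.05))
  expect_equal(unname(toy$log_odds[3, "X"]), 0)

  expect_error(build_profile("ACDEF"), "at least 2")
  expect_error(build_profile(c("--", "--", "AC")), "gap-dropped")
})

test_that("gap-heavy columns are dropped before matrix construction", {
  p <- build_profile(c("AGCDEF", "A-CDEF", "AGCDEF"))
  expect_equal(p$length, 6)  # one gap in 3 rows = 33% gaps, kept
  p2 <- build_profile(c("A-CDEF", "A-CDEF", "AGCDEF"))
  expect_equal(p2$length, 5)  # 2/3 gaps, dropped
})

test_that("scanning returns the brute-force best window", {
  base <- "MHQWKLYVDEACDEFGHIKL"
  p <- toy_profile(base, rate = 0)
  # consensus at offset 0: bitscore equals the column-max sum
  h <- scan_profile(p, base)
  expect_equal(h$window_start, 0)
  expect_equal(h$bitscore, sum(apply(p$log_odds, 1, max)))

  # consensus embedded at offset 17
  withr::with_seed(7, {
    emb <- paste0(rand_seq(17), base, rand_seq(30))
  })
  expect_equal(scan_profile(p, emb)$window_start, 17)

  # shorter than the profile
  expect_null(scan_profile(p, "MKL"))

  # exhaustive equivalence on random inputs
  withr::with_seed(42, {
    for (i in 1:15) {
      prof <- toy_profile(rand_seq(sample(6:25, 1)), seed = i)
      s <- rand_seq(sample(30:200, 1))
      got <- scan_profile(prof, s)
      want <- oracle_scan(prof$log_odds, s)
      expect_equal(got$bitscore, want$bitscore)
      expect_equal(got$window_start, want$window_start)
    }
  })
})

test_that("Gumbel calibration is deterministic and moment fitting recovers truth", {
  p <- build_profile(rep("ACDEFGHIKL", 3))
  c1 <- calibrate_profile(p, seed = 99)
  c2 <- calibrate_profile(p, seed = 99)
  expect_identical(c(c1$gumbel_mu, c1$gumbel_lambda),
                   c(c2$gumbel_mu, c2$gumbel_lambda))
  expect_error(calibrate_profile(p, n_shuffles = 10), "100")

  # moment estimator on a known Gumbel(mu = 0, lambda = 1) sample
  withr::with_seed(123, {
    x <- -log(-log(runif(10000)))
  })
  fit <- cas10census:::fit_gumbel_moments(x)
  expect_lt(abs(fit[["mu"]]), 0.05)
  expect_lt(abs(fit[["lambda"]] - 1), 0.05)
})

test_that("E-values follow the Gumbel closed form", {
  p <- toy_profile("ACDEFGHIKLMNPQ")
  # closed form at the location parameter
  expect_equal(profile_evalue(p$gumbel_mu, p, db_size = 1), 1 - exp(-1))
  # strict monotonicity
  expect_lt(profile_evalue(p$gumbel_mu + 10, p, 100),
            profile_evalue(p$gumbel_mu, p, 100))
  # exact linearity in db_size
  expect_equal(profile_evalue(12, p, 200), 2 * profile_evalue(12, p, 100))
  # uncalibrated profiles refuse
  expect_error(profile_evalue(10, build_profile(rep("ACDEF", 3)), 1),
               "not calibrated")
})

test_that("null E-values are approximately uniformly conservative", {
  p <- toy_profile("ACDEFGHIKLMNPQRSTVWY", seed = 3)
  withr::with_seed(31, {
    ev <- vapply(1:1000, function(i) {
      profile_evalue(scan_profile(p, rand_seq(400))$bitscore, p, db_size = 1)
    }, numeric(1))
  })
  for (prob in c(0.01, 0.05)) {
    expect_lte(mean(ev < prob), prob * 1.5)
  }
})

test_that("pairwise identity matches the exhaustive DP oracle", {
  expect_equal(pairwise_identity("ACDEF", "ACDEF"), 1)
  expect_equal(pairwise_identity("AAAA", "AAAT"), 0.75)
  expect_error(pairwise_identity("", "AC"), "non-empty")

  withr::with_seed(11, {
    for (i in 1:10) {
      a <- rand_seq(20)
      b <- rand_seq(20)
      expect_equal(pairwise_identity(a, b), oracle_identity(a, b))
    }
  })
})

test_that("greedy clustering obeys the prefilter and matches the brute-force oracle", {
  same <- tibble::tibble(id = c("a", "b", "c"),
                         sequence = rep("ACDEFGHIKL", 3))
  expect_equal(max(greedy_cluster(same, 0.9, 5)$cluster), 1)

  # zero shared words force separate clusters regardless of threshold
  nw <- tibble::tibble(id = c("a", "b"),
                       sequence = c("AAAAAAAA", "CCCCCCCC"))
  expect_equal(max(greedy_cluster(nw, 0.01, 5)$cluster), 2)

  # toy set built from shared words so the prefilter never rejects a true
  # >= 0.9 pair; partition must equal the oracle's
  withr::with_seed(5, {
    bases <- replicate(3, rand_seq(40))
    seqs <- tibble::tibble(
      id = sprintf("s%02d", 1:8),
      sequence = c(bases[1], sub("^(.{5})." , "\\1Q", bases[1]),
                   bases[2], sub("^(.{20}).", "\\1W", bases[2]),
                   sub("^(.{30}).", "\\1M", bases[2]),
                   bases[3], paste0(bases[3], "K"),
                   rand_seq(40)))
  })
  got <- greedy_cluster(seqs, 0.9, 5)
  want <- oracle_cluster(seqs, 0.9)
  canon <- function(parts) {
    sort(vapply(parts, function(x) paste(sort(x), collapse = ","), character(1)))
  }
  expect_equal(canon(unname(split(got$id, got$cluster))), canon(unname(want)))

  # every member reaches the threshold against its representative
  by_id <- setNames(seqs$sequence, seqs$id)
  expect_true(all(mapply(function(m, r) {
    pairwise_identity(by_id[[m]], by_id[[r]]) >= 0.9
  }, got$id, got$representative)))

  # determinism under fixed input order
  expect_identical(greedy_cluster(seqs, 0.9, 5), got)
})
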