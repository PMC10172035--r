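test_that("lambda solves the characteristic equation exactly", {
  residual <- function(lam, match, mismatch, bg = rep(0.25, 4)) {
    pm <- sum(bg^2)
    pm * exp(lam * match) + (1 - pm) * exp(lam * mismatch) - 1
  }
  for (scheme in list(c(1, -2), c(1, -1), c(2, -3), c(3, -4))) {
    lam <- solve_lambda(scheme[1], scheme[2])
    expect_gt(lam, 0)
    expect_lt(abs(residual(lam, scheme[1], scheme[2])), 1e-9)
  }
  # non-uniform background
  bg <- c(0.3, 0.2, 0.2, 0.3)
  lam <- solve_lambda(1, -2, bg)
  expect_lt(abs(residual(lam, 1, -2, bg)), 1e-9)
  # scale invariance: doubling both scores halves lambda
  expect_equal(solve_lambda(2, -4), solve_lambda(1, -2) / 2, tolerance = 1e-8)
  # +1/-1 at uniform background has expected score -0.5 (valid statistics)
  expect_gt(solve_lambda(1, -1), 0)
  # a scheme with non-negative expected score has no valid statistics
  expect_error(solve_lambda(3, -1), "non-negative")
})

test_that("off-target scan excludes the intended site and finds plants", {
  set.seed(301)
  scheme <- scoring_scheme()
  g <- h_rand_dna(2000)
  q <- h_rand_dna(24)
  # plant the seed verbatim once; exclude that site -> nothing perfect left
  g1 <- paste0(substr(g, 1, 500), q, substr(g, 525, 2000))
  hits <- scan_offtargets(nuc_seq(q, molecule = "DNA"),
                          nuc_seq(g1, id = "chr", molecule = "DNA"), scheme,
                          evalue_cutoff = 1e-3,
                          exclude = list(chrom = "chr", start = 500L, end = 524L))
  expect_equal(nrow(hits), 0)
  # plant twice, exclude one -> exactly the other, at full score
  g2 <- paste0(substr(g1, 1, 1200), q, substr(g1, 1225, 2000))
  hits <- scan_offtargets(nuc_seq(q, molecule = "DNA"),
                          nuc_seq(g2, id = "chr", molecule = "DNA"), scheme,
                          evalue_cutoff = 1e-3,
                          exclude = list(chrom = "chr", start = 500L, end = 524L))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$score, 24)
  expect_equal(hits$start, 1200L)
  # reverse-complement plants are found and reported on the forward strand
  g3 <- paste0(substr(g, 1, 800), rc_str(q), substr(g, 825, 2000))
  hits <- scan_offtargets(nuc_seq(q, molecule = "DNA"),
                          nuc_seq(g3, id = "chr", molecule = "DNA"), scheme,
                          evalue_cutoff = 1e-3)
  expect_true(any(hits$strand == "-" & hits$start == 800L & hits$score == 24))
  expect_error(scan_offtargets(nuc_seq(q, molecule = "DNA"),
                               nuc_seq(g, molecule = "DNA"), scheme,
                               word_size = 3L), "word_size")
})

test_that("top hit equals the DP oracle; E-values behave analytically", {
  set.seed(302)
  scheme <- scoring_scheme()
  for (i in 1:40) {
    g <- h_rand_dna(1000)
    q <- h_rand_dna(24)
    hits <- scan_offtargets(nuc_seq(q, molecule = "DNA"),
                            nuc_seq(g, id = "g", molecule = "DNA"),
                            scheme, evalue_cutoff = 1e12)
    expect_equal(max(hits$score), h_dp_best_ungapped(q, g))
  }
  # E strictly decreasing in score, linear in searched length
  e1 <- karlin_evalue(10:20, 24, 4000, scheme)
  expect_true(all(diff(e1) < 0))
  expect_equal(karlin_evalue(12, 24, 8000, scheme),
               2 * karlin_evalue(12, 24, 4000, scheme))
  # no reported hit ever overlaps the excluded interval (fuzzed)
  set.seed(303)
  for (i in 1:25) {
    g <- h_rand_dna(600)
    q <- h_rand_dna(20)
    ex <- sort(sample(0:600, 2))
    if (ex[1] == ex[2]) next
    hits <- scan_offtargets(nuc_seq(q, molecule = "DNA"),
                            nuc_seq(g, id = "g", molecule = "DNA"), scheme,
                            evalue_cutoff = 1e12,
                            exclude = list(chrom = "g", start = ex[1], end = ex[2]))
    if (nrow(hits))
      expect_true(all(hits$end <= ex[1] | hits$start >= ex[2]))
  }
})
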