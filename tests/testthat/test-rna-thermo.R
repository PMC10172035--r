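params <- nn_params()

test_that("duplex energy is the hand-sum of the shipped stack table", {
  # GGGG:CCCC -> 3 GG stacks + init, no AU ends
  res <- duplex_energy(nuc_seq("GGGG", molecule = "RNA"),
                       nuc_seq("CCCC", molecule = "RNA"), params)
  expect_equal(res$dG, params$duplex_init_dG37 + 3 * params$stacks[["GG"]])
  expect_equal(res$n_stacks, 3L)
  # length-1 duplex: init + end penalty only, zero stacks
  res1 <- duplex_energy(nuc_seq("A", molecule = "RNA"),
                        nuc_seq("U", molecule = "RNA"), params)
  expect_equal(res1$n_stacks, 0L)
  expect_equal(res1$dG, params$duplex_init_dG37 + params$terminal_AU_penalty)
  resG <- duplex_energy(nuc_seq("G", molecule = "RNA"),
                        nuc_seq("C", molecule = "RNA"), params)
  expect_equal(resG$dG, params$duplex_init_dG37)
  # reversing both strands leaves dG unchanged (duplex symmetry)
  set.seed(401)
  for (i in 1:50) {
    t <- h_rand_rna(sample(4:20, 1))
    s <- chartr("T", "U", rc_str(chartr("U", "T", t)))
    d1 <- duplex_energy(nuc_seq(s, molecule = "RNA"),
                        nuc_seq(t, molecule = "RNA"), params)$dG
    d2 <- duplex_energy(nuc_seq(t, molecule = "RNA"),
                        nuc_seq(s, molecule = "RNA"), params)$dG
    expect_equal(d1, d2)
  }
  # extending a GC duplex one pair at a time strictly lowers dG
  dgs <- vapply(2:12, function(L) {
    duplex_energy(nuc_seq(strrep("G", L), molecule = "RNA"),
                  nuc_seq(strrep("C", L), molecule = "RNA"), params)$dG
  }, 0)
  expect_true(all(diff(dgs) < 0))
  # an all-GC seed out-competes an all-AU seed of the same length
  dG_gc <- duplex_energy(nuc_seq(strrep("GC", 12), molecule = "RNA"),
                         nuc_seq(strrep("GC", 12), molecule = "RNA"), params)$dG
  dG_au <- duplex_energy(nuc_seq(strrep("AU", 12), molecule = "RNA"),
                         nuc_seq(strrep("AU", 12), molecule = "RNA"), params)$dG
  expect_lt(dG_gc, dG_au)
  # non-complementary input names the first mismatch
  expect_error(duplex_energy(nuc_seq("GGGG", molecule = "RNA"),
                             nuc_seq("CCCA", molecule = "RNA"), params),
               "position 1")
  # GU opposition only with the flag
  expect_error(duplex_energy(nuc_seq("G", molecule = "RNA"),
                             nuc_seq("U", molecule = "RNA"), params), "mismatch")
  expect_silent(duplex_energy(nuc_seq("G", molecule = "RNA"),
                              nuc_seq("U", molecule = "RNA"), params,
                              allow_gu = TRUE))
})

test_that("partition function matches exhaustive enumeration on short RNAs", {
  expect_true(all(partition_function(nuc_seq("AAAA", molecule = "RNA"),
                                     params)$p == 0))
  pf <- partition_function(nuc_seq("GGGAAAACCC", molecule = "RNA"), params)
  ut <- which(upper.tri(pf$p), arr.ind = TRUE)
  ord <- ut[order(pf$p[ut], decreasing = TRUE)[1:3], , drop = FALSE]
  got <- sort(paste(ord[, 1], ord[, 2]))
  expect_setequal(got, c("1 10", "2 9", "3 8"))
  en <- h_enum_pairprobs("GGGAAAACCC", params)
  expect_lt(max(abs(pf$p - en$p)), 1e-9)

  set.seed(402)
  for (i in 1:25) {
    s <- h_rand_rna(sample(5:12, 1))
    en <- h_enum_pairprobs(s, params)
    pf <- partition_function(nuc_seq(s, molecule = "RNA"), params)
    expect_lt(max(abs(pf$p - en$p)), 1e-9)
    expect_lt(abs(pf$Z - en$Z) / en$Z, 1e-12)
  }
})

test_that("higher temperature flattens the ensemble", {
  hot <- nn_params(temperature = 360.15)
  s <- nuc_seq("GGGGCAAAAGCCCC", molecule = "RNA")
  p37 <- max(partition_function(s, params)$p)
  p87 <- max(partition_function(s, hot)$p)
  expect_lt(p87, p37)
})

test_that("accessibility penalty is a non-negative constrained-ensemble cost", {
  pp <- partition_function(nuc_seq("AAAAAAA", molecule = "RNA"), params)
  expect_equal(accessibility_penalty(pp, c(0L, 7L)), 0)
  set.seed(403)
  for (i in 1:40) {
    s <- h_rand_rna(sample(6:14, 1))
    pp <- partition_function(nuc_seq(s, molecule = "RNA"), params)
    n <- nchar(s)
    a <- sample.int(n, 1) - 1L
    b <- a + sample.int(n - a, 1)
    expect_gte(accessibility_penalty(pp, c(a, b)), 0)
  }
  # exact against the enumeration oracle for n <= 12
  set.seed(404)
  for (i in 1:15) {
    s <- h_rand_rna(sample(8:12, 1))
    n <- nchar(s)
    en <- h_enum_pairprobs(s, params)
    pp <- partition_function(nuc_seq(s, molecule = "RNA"), params)
    a <- sample.int(n - 1, 1) - 1L
    b <- a + sample.int(n - a, 1)
    p_free <- en$p_region_unpaired(a + 1, b)
    expect_equal(accessibility_penalty(pp, c(a, b)),
                 max(0, -params$RT * log(p_free)), tolerance = 1e-9)
  }
})

test_that("pairing profiles are stochastic triples aligned by NW distance", {
  pp <- partition_function(nuc_seq("AAAAAAA", molecule = "RNA"), params)
  prof <- pairing_profile(pp)
  expect_true(all(prof[, "p_unpaired"] == 1))
  hp <- pairing_profile(partition_function(nuc_seq("GGGAAAACCC",
                                                   molecule = "RNA"), params))
  expect_true(all(abs(rowSums(hp) - 1) < 1e-6))
  expect_equal(as.numeric(hp[1, "p_upstream"]), 0)
  expect_equal(as.numeric(hp[10, "p_downstream"]), 0)
  expect_gt(hp[1, "p_downstream"], 0.9)

  expect_equal(profile_distance(hp, hp), 0)
  # pure length mismatch costs exactly the gap penalty per extra column
  a <- h_rand_profile(8); a[, ] <- 0; a[, 3] <- 1
  b <- h_rand_profile(10); b[, ] <- 0; b[, 3] <- 1
  expect_equal(profile_distance(a, b, gap_cost = 2), 4)
  set.seed(405)
  for (i in 1:60) {
    x <- h_rand_profile(sample(4:20, 1))
    y <- h_rand_profile(sample(4:20, 1))
    d <- profile_distance(x, y)
    expect_gte(d, 0)
    expect_equal(d, profile_distance(y, x))
  }
})

test_that("MFE structure is a valid argmax under the same model", {
  m <- mfe_structure(nuc_seq("GGGGAAAACCCC", molecule = "RNA"), params)
  expect_match(m$structure, "^\\(+\\.*\\(*\\.+\\)*\\.*\\)+$")
  expect_lt(m$dG, 0)
  # the reported dG equals the minimum over the enumerated ensemble
  set.seed(406)
  for (i in 1:15) {
    s <- h_rand_rna(sample(6:12, 1))
    r <- strsplit(s, "")[[1]]
    SS <- h_enum_structures(r)
    emin <- min(vapply(SS, h_struct_energy, 0, r = r, params = params))
    expect_equal(mfe_structure(nuc_seq(s, molecule = "RNA"), params)$dG,
                 min(emin, 0), tolerance = 1e-9)
  }
  expect_equal(mfe_structure(nuc_seq("AAAA", molecule = "RNA"),
                             params)$structure, "....")
})
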