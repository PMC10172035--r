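enz <- get_enzyme("BsaI")

test_that("annealing oligos reconstruct the intended sticky duplex", {
  part <- gg_part("demo", role = "seed",
                  seq = nuc_seq("AATTCCGGAA", molecule = "DNA"))
  oo <- design_anneal_oligos(part, "AATT", "GGCC")
  expect_equal(oo[[1]]$sequence, "AATTCCGGAA")
  expect_equal(oo[[2]]$sequence, rc_str("CCGGAAGGCC"))
  expect_equal(oo[[2]]$sequence, "GGCCTTCCGG")
  fr <- simulate_annealing(oo[[1]]$sequence, oo[[2]]$sequence, 4L)
  expect_equal(fr$tops, part$seq$residues)
  expect_equal(fr$lovh, "AATT")
  expect_equal(fr$rovh, "GGCC")

  tiny <- gg_part("tiny", role = "seed", seq = nuc_seq("AATT", molecule = "DNA"))
  expect_error(design_anneal_oligos(tiny, "AATT", "GGCC"), "zero-length core")
  long <- gg_part("long", role = "scaffold",
                  seq = nuc_seq(paste0("AATT", h_rand_dna(120)), molecule = "DNA"))
  expect_error(design_anneal_oligos(long, "AATT", "GGCC"), "pcr")

  set.seed(701)
  for (i in 1:150) {
    L <- sample(10:60, 1)
    s <- h_rand_dna(L)
    p <- gg_part("p", role = "other", seq = nuc_seq(s, molecule = "DNA"))
    up <- substr(s, 1, 4)
    down <- h_rand_dna(4)
    oo <- design_anneal_oligos(p, up, down)
    fr <- simulate_annealing(oo[[1]]$sequence, oo[[2]]$sequence, 4L)
    expect_identical(fr$tops, s)
    expect_identical(fr$lovh, up)
    expect_identical(fr$rovh, down)
  }
})

test_that("NN melting temperature is strand-symmetric and table-exact", {
  tab <- dna_nn_table()
  x <- "GCGTATACGC"
  # independent hand summation of the shipped table
  ch <- strsplit(x, "")[[1]]
  st <- paste0(ch[-10], ch[-1])
  dH <- sum(tab$dH[st]) + 2 * tab$dH[["init_GC"]]
  dS <- sum(tab$dS[st]) + 2 * tab$dS[["init_GC"]]
  hand <- dH * 1000 / (dS + 1.987 * log(0.25e-6 / 4)) - 273.15 +
    16.6 * log10(0.05)
  expect_equal(compute_tm(x), hand, tolerance = 1e-9)

  set.seed(702)
  for (i in 1:100) {
    s <- h_rand_dna(sample(8:30, 1))
    expect_equal(compute_tm(s), compute_tm(rc_str(s)), tolerance = 1e-9)
  }
  # appending GC raises Tm for any primer >= 8 nt
  for (i in 1:40) {
    s <- h_rand_dna(sample(8:25, 1))
    expect_gt(compute_tm(paste0(s, "GC")), compute_tm(s))
  }
  expect_error(compute_tm("ACGTACG"), "at least 8")
})

test_that("PCR amplicons release exactly the intended part on digestion", {
  set.seed(703)
  motif <- c(BsaI = enz$recognition)
  n_ok <- 0
  for (i in 1:150) {
    L <- sample(30:70, 1)
    s <- h_rand_clean_dna(L, motif)
    p <- gg_part("p", role = "other", seq = nuc_seq(s, molecule = "DNA"),
                 production = "pcr")
    up <- substr(s, 1, 4)
    down <- h_rand_dna(4)
    oo <- tryCatch(design_pcr_primers(p, up, down, enz, tm_target = 52),
                   error = function(e) NULL)
    if (is.null(oo)) next    # Tm unreachable for very AT-rich prefixes
    n_ok <- n_ok + 1
    # each primer carries exactly one recognition site
    for (o in oo) {
      expect_equal(nrow(scan_motifs(nuc_seq(o$sequence, molecule = "DNA"),
                                    motif, both_strands = FALSE)), 1)
    }
    expect_gte(oo[[1]]$tm_annealing, 52)
    frs <- digest(attr(oo, "amplicon"), enz)
    mid <- frs[[2]]
    expect_identical(mid$tops, s)
    expect_identical(mid$lovh, up)
    expect_identical(mid$rovh, down)
  }
  expect_gt(n_ok, 100)

  # growing the annealing region with GC never lowers Tm
  base <- paste0(h_rand_dna(14), "GC")
  tms <- vapply(0:6, function(k) compute_tm(paste0(base, strrep("GC", k))), 0)
  expect_true(all(diff(tms) > 0))

  # unreachable Tm target is a clean error
  atpart <- gg_part("at", role = "other",
                    seq = nuc_seq(paste0("CGCG", strrep("AT", 20)),
                                  molecule = "DNA"),
                    production = "pcr")
  expect_error(design_pcr_primers(atpart, "CGCG", "GGCC", enz,
                                  tm_target = 80), "unreachable")
})
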