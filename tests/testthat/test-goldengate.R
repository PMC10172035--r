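enz <- get_enzyme("BsaI")

test_that("enzyme lookup knows the shipped type IIS table", {
  tab <- type_iis_enzymes()
  expect_setequal(tab$name, c("BsaI", "BsmBI", "BbsI", "SapI", "PaqCI"))
  expect_true(all(tab$overhang_len %in% c(3L, 4L)))
  expect_equal(get_enzyme("SapI")$overhang_len, 3L)
  expect_error(get_enzyme("EcoRI"), "available")
})

test_that("digestion cuts at the enzyme offset and tracks 5' overhangs", {
  # linear molecule with one forward site: GGTCTC N | NNNN
  s <- nuc_seq("AAAAGGTCTCTACGTCCCCCGGGGG", molecule = "DNA")
  fr <- digest(s, enz)
  expect_length(fr, 2)
  expect_equal(fr[[1]]$tops, substr(s$residues, 1, 11))
  expect_equal(fr[[1]]$rovh, "ACGT")
  expect_equal(fr[[2]]$lovh, "ACGT")
  expect_equal(paste0(fr[[1]]$tops, fr[[2]]$tops), s$residues)
})

test_that("scarless plans draw junction overhangs from the construct itself", {
  set.seed(601)
  plan <- h_random_passing_plan(enz)
  for (t in 1:20) {
    if (!is.null(plan)) break
    plan <- h_random_passing_plan(enz)
  }
  expect_false(is.null(plan))
  expect_length(plan$junction_overhangs, 4)   # 4 parts -> 4 circular junctions
  # overhang = first 4 nt of the downstream part at insert junctions
  expect_equal(plan$junction_overhangs[2],
               substr(plan$ordered_parts[[3]]$seq$residues, 1, 4))
  # construct = backbone + inserts, free of recognition sites
  expect_equal(nchar(plan$expected_construct$residues),
               nchar(plan$backbone$tops) +
                 sum(vapply(plan$ordered_parts[-1],
                            function(p) nchar(p$seq$residues), 0)))
  expect_equal(nrow(scan_motifs(plan$expected_construct,
                                c(BsaI = enz$recognition))), 0)

  # incompatible plasmid-dictated overhang is an error, not a silent patch
  bad_insert <- gg_part("badstart", role = "promoter",
                        seq = nuc_seq(paste0("TTTT", h_rand_dna(20)),
                                      molecule = "DNA"))
  parts2 <- plan$ordered_parts
  if (substr(parts2[[2]]$seq$residues, 1, 4) != "TTTT") {
    parts2[[2]] <- bad_insert
    expect_error(plan_assembly(parts2, enz), "junction")
  }
  # internal sites in inserts are rejected with position and strand
  with_site <- gg_part("hasSite", role = "seed",
                       seq = nuc_seq(paste0(substr(parts2[[3]]$seq$residues, 1, 4),
                                            "GGTCTC", h_rand_dna(10)),
                                     molecule = "DNA"))
  parts3 <- plan$ordered_parts
  parts3[[3]] <- with_site
  expect_error(plan_assembly(parts3, enz), "internal BsaI site")
})

test_that("fidelity verdicts follow the duplicate/rc/palindrome rules", {
  expect_error(check_fidelity(c("AAT"), enz), "length")
  r <- check_fidelity(c("AATT", "CCGG"), enz)      # both palindromes
  expect_equal(r$verdict, "fail")
  expect_true("AATT" %in% r$palindromes)
  r <- check_fidelity(c("ACTG", "CAGT", "TTTA"), enz)
  expect_equal(r$verdict, "fail")
  expect_length(r$rc_clashes, 1)
  r <- check_fidelity(c("AGGT", "CCAA", "GTTC", "TAAA"), enz)
  expect_equal(r$verdict, "pass")
  r <- check_fidelity(c("AGGT", "AGGT"), enz)
  expect_equal(r$verdict, "fail")
  expect_equal(r$duplicates, "AGGT")
  # near-miss only -> warn, with the external-referral message
  r <- check_fidelity(c("AAAC", "TTTG"), enz)      # Hamming(AAAC, rc(TTTG)=CAAA)=2
  r2 <- check_fidelity(c("GAAC", "GTTA"), enz)     # rc(GTTA)=TAAC vs GAAC -> 1
  expect_equal(r2$verdict, "warn")
  expect_match(r2$message, "overhang")

  # exhaustive pairwise oracle on random sets
  set.seed(602)
  for (i in 1:60) {
    os <- vapply(1:4, function(j) h_rand_dna(4), "")
    got <- check_fidelity(os, enz)
    ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    fail_oracle <- anyDuplicated(os) > 0 ||
      any(vapply(os, function(a) ham(a, rc_str(a)) == 0, TRUE)) ||
      any(utils::combn(os, 2, function(p) ham(p[1], rc_str(p[2])) == 0 && p[1] != p[2]))
    pass_oracle <- !fail_oracle && all(utils::combn(os, 2, function(p)
      ham(p[1], rc_str(p[2])) >= 2)) &&
      all(vapply(os, function(a) ham(a, rc_str(a)) >= 2, TRUE))
    if (fail_oracle) expect_equal(got$verdict, "fail")
    if (pass_oracle) expect_equal(got$verdict, "pass")
  }
})

test_that("slot combinations expand into the Cartesian product of plans", {
  set.seed(603)
  motif <- c(BsaI = enz$recognition)
  first4 <- "TGCA"
  proms <- lapply(1:3, function(i) {
    gg_part(paste0("prom", i), role = "promoter",
            seq = nuc_seq(paste0(first4, h_rand_clean_dna(18, motif)),
                          molecule = "DNA"))
  })
  seeds <- list(gg_part("seedA", role = "seed",
                        seq = nuc_seq(paste0("CATG", h_rand_clean_dna(20, motif)),
                                      molecule = "DNA")))
  scafs <- list(gg_part("scaf", role = "scaffold",
                        seq = nuc_seq(paste0("GACC", h_rand_clean_dna(20, motif)),
                                      molecule = "DNA")))
  plasmids <- lapply(1:2, function(i) {
    gg_part(paste0("pX", i), role = "plasmid",
            seq = h_make_plasmid(enz, first4, "CTTG"), production = "none")
  })
  plans <- expand_combinations(list(plasmids, proms, seeds, scafs), enz)
  expect_length(plans, 6)   # 2 x 3 x 1 x 1
  expect_length(unique(vapply(plans, function(p) p$name, "")), 6)
  single <- expand_combinations(list(plasmids[1], proms[1], seeds, scafs), enz)
  ref <- plan_assembly(list(plasmids[[1]], proms[[1]], seeds[[1]], scafs[[1]]), enz)
  expect_identical(single[[1]]$expected_construct$residues,
                   ref$expected_construct$residues)
  expect_error(expand_combinations(list(plasmids, list()), enz), "slot")
})
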