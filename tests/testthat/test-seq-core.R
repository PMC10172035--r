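test_that("reverse complement and transcription behave as Watson-Crick ops", {
  expect_equal(reverse_complement(nuc_seq("GGTCTC"))$residues, "GAGACC")
  expect_equal(reverse_complement(nuc_seq("A", molecule = "RNA"))$residues, "U")
  expect_equal(transcribe(nuc_seq("ATGC"))$residues, "AUGC")
  expect_equal(transcribe(nuc_seq("TTTT"))$residues, "UUUU")
  expect_error(transcribe(nuc_seq("AUGC", molecule = "RNA")), "DNA input")
  expect_error(nuc_seq("ACGN"), "invalid DNA residue 'N' at position 4")
  expect_error(nuc_seq("ACGU", molecule = "RNA", topology = "circular"),
               "circular")

  set.seed(101)
  for (i in 1:100) {
    mol <- sample(c("DNA", "RNA"), 1)
    s <- if (mol == "DNA") h_rand_dna(sample(1:60, 1)) else h_rand_rna(sample(1:60, 1))
    x <- nuc_seq(s, molecule = mol)
    rr <- reverse_complement(reverse_complement(x))
    expect_identical(rr$residues, x$residues)
    if (mol == "DNA") expect_equal(nchar(transcribe(x)$residues), nchar(s))
  }
})

test_that("motif scanning reports every occurrence on both strands", {
  hits <- scan_motifs(nuc_seq("AAGGTCTCAA"), c(BsaI = "GGTCTC"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 2L)
  expect_equal(hits$strand, "+")

  hits <- scan_motifs(nuc_seq("AAGAGACCAA"), c(BsaI = "GGTCTC"))
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 2L)
  expect_equal(hits$strand, "-")

  expect_equal(nrow(scan_motifs(nuc_seq("AAAAAA"), c(BsaI = "GGTCTC"))), 0)
  expect_error(scan_motifs(nuc_seq("ACGT"), c(bad = "")), "empty motif")

  # overlapping occurrences are all reported
  hits <- scan_motifs(nuc_seq("AAAA"), c(m = "AA"), both_strands = FALSE)
  expect_equal(hits$start, 0:2)

  # agreement with a naive substring scan, incl. circular wrap-around
  set.seed(102)
  for (i in 1:200) {
    n <- sample(10:50, 1)
    s <- h_rand_dna(n, probs = c(0.4, 0.1, 0.1, 0.4))
    motif <- h_rand_dna(sample(2:4, 1), probs = c(0.4, 0.1, 0.1, 0.4))
    circ <- sample(c(TRUE, FALSE), 1)
    x <- nuc_seq(s, molecule = "DNA",
                 topology = if (circ) "circular" else "linear")
    got <- scan_motifs(x, c(m = motif), both_strands = FALSE)
    expect_identical(got$start, h_naive_scan(s, motif, circ), label = paste(s, motif, circ))
  }
})

test_that("FASTA round trip preserves residues and ids", {
  seqs <- list(nuc_seq("ACGTACGTACGT", id = "a"),
               nuc_seq(h_rand_dna(200), id = "b"),
               nuc_seq("AUGGCU", id = "c", molecule = "RNA"))
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(seqs, path)
  back <- read_fasta(path)
  expect_equal(names(back), c("a", "b", "c"))
  for (i in 1:3) expect_identical(back[[i]]$residues, seqs[[i]]$residues)
  # 70-column wrapping on write
  expect_true(all(nchar(readLines(path)) <= 70))
  # malformed file names the offending line
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("ACGT", ">x", "ACGT"), bad)
  expect_error(read_fasta(bad), "line 1")
})

test_that("GenBank round trip preserves topology and feature coordinates", {
  feats <- data.frame(kind = c("gene", "CDS", "misc_feature"),
                      locus_tag = c("g1", "g1", "m1"),
                      start = c(10L, 10L, 150L), end = c(100L, 100L, 180L),
                      strand = c("-", "-", "+"), stringsAsFactors = FALSE)
  rec <- gb_record(nuc_seq(h_rand_dna(200), id = "chr",
                           topology = "circular"), feats)
  path <- withr::local_tempfile(fileext = ".gb")
  write_genbank(rec, path)
  back <- read_genbank(path)
  expect_identical(back$seq$residues, rec$seq$residues)
  expect_identical(back$seq$topology, "circular")
  expect_equal(back$features$start, feats$start)
  expect_equal(back$features$end, feats$end)
  expect_equal(back$features$strand, feats$strand)
  expect_equal(back$features$locus_tag, feats$locus_tag)
  # byte-stable on rewrite
  path2 <- withr::local_tempfile(fileext = ".gb")
  write_genbank(back, path2)
  expect_identical(readLines(path), readLines(path2))
})
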