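#' Extract the mRNA binding window around a target's start codon
#'
#' Coordinates in `window_rel` are relative to the first base of the
#' annotated start codon (position 0), negative values lying upstream in the
#' mRNA (5' direction). The returned subsequence is in mRNA orientation
#' (sense strand, transcribed), correct for minus-strand genes.
#'
#' @param record A [gb_record] holding the annotated target region/genome.
#' @param locus_tag Locus tag of the target gene. Features of kind `CDS` are
#'   preferred; a `gene` feature with the same tag is accepted when no CDS is
#'   annotated.
#' @param window_rel Integer pair `(start_rel, end_rel)`, half-open, e.g.
#'   `c(-30, 21)` for 30 nt upstream through 21 nt of coding sequence.
#' @return A list of class `target_window` with fields `locus_tag`,
#'   `window_start_rel`, `window_end_rel`, `mrna_subseq` (RNA [nuc_seq]),
#'   plus the genomic footprint `chrom`, `gen_start`, `gen_end`, `strand`.
#' @export
extract_target_window <- function(record, locus_tag, window_rel = c(-30L, 21L)) {
  stopifnot(inherits(record, "gb_record"))
  window_rel <- as.integer(window_rel)
  if (length(window_rel) != 2L || window_rel[1] >= window_rel[2])
    stop(sprintf("empty or inverted window (%d, %d)", window_rel[1], window_rel[2]))
  f <- record$features
  cand <- f[f$locus_tag == locus_tag & f$kind %in% c("CDS", "gene"), , drop = FALSE]
  if (!nrow(cand)) {
    stop(sprintf("locus '%s' not found; available tags: %s", locus_tag,
                 paste(unique(f$locus_tag[nzchar(f$locus_tag)]), collapse = ", ")))
  }
  cand <- cand[order(match(cand$kind, c("CDS", "gene"))), , drop = FALSE]
  feat <- cand[1, ]
  n <- nchar(record$seq$residues)
  if (feat$strand == "+") {
    anchor <- feat$start                       # genomic pos of start codon base 0
    lo <- anchor + window_rel[1]
    hi <- anchor + window_rel[2]
  } else {
    # start codon first base sits at genomic end-1; mRNA coord r -> genomic end-1-r
    lo <- feat$end - window_rel[2]
    hi <- feat$end - window_rel[1]
  }
  if (lo < 0 || hi > n)
    stop(sprintf("window [%d,%d) for locus '%s' exceeds record bounds [0,%d)",
                 lo, hi, locus_tag, n))
  sub <- subseq0(record$seq, lo, hi)
  if (feat$strand == "-") sub <- reverse_complement(sub)
  mrna <- transcribe(nuc_seq(sub$residues, id = paste0(locus_tag, "_window")))
  structure(list(locus_tag = locus_tag,
                 window_start_rel = window_rel[1],
                 window_end_rel = window_rel[2],
                 mrna_subseq = mrna,
                 chrom = record$seq$id,
                 gen_start = lo, gen_end = hi, strand = feat$strand),
            class = "target_window")
}

#' Enumerate antisense seed candidates over a target window
#'
#' One candidate per sliding offset: the seed is the exact reverse
#' complement (RNA) of the corresponding window subsequence. Candidates
#' whose DNA form contains an excluded motif on either strand are removed
#' from the returned list; they are retained, with a machine-readable
#' reason, in the `"dropped"` attribute so downstream reports can account
#' for every enumerated offset.
#'
#' @param window A `target_window` from [extract_target_window()].
#' @param seed_len Seed length in nt (>= 8).
#' @param excluded_motifs Named character vector of DNA motifs (e.g. type IIS
#'   recognition sites) that must not occur in a seed.
#' @return List of `seed_candidate` objects ordered 5' to 3' along the mRNA,
#'   with attribute `dropped`: data.frame(`match_start_rel`, `reason`).
#' @export
enumerate_seeds <- function(window, seed_len = 24L, excluded_motifs = character()) {
  stopifnot(inherits(window, "target_window"))
  seed_len <- as.integer(seed_len)
  wlen <- nchar(window$mrna_subseq$residues)
  if (seed_len < 8L) stop("seed_len must be >= 8")
  if (seed_len > wlen)
    stop(sprintf("seed_len %d exceeds window length %d", seed_len, wlen))
  offsets <- 0:(wlen - seed_len)
  cands <- list()
  dropped <- data.frame(match_start_rel = integer(), reason = character(),
                        stringsAsFactors = FALSE)
  for (off in offsets) {
    target_sub <- subseq0(window$mrna_subseq, off, off + seed_len)
    seed <- reverse_complement(target_sub)
    rel <- window$window_start_rel + off
    seed$id <- sprintf("%s_seed%+d", window$locus_tag, rel)
    seed_dna <- back_transcribe(seed)
    hits <- scan_motifs(seed_dna, excluded_motifs, both_strands = TRUE)
    if (nrow(hits)) {
      dropped <- rbind(dropped, data.frame(
        match_start_rel = rel,
        reason = sprintf("seed motif %s", hits$motif_name[1]),
        stringsAsFactors = FALSE))
      next
    }
    if (window$strand == "+") {
      gs <- window$gen_start + off
      ge <- gs + seed_len
    } else {
      ge <- window$gen_end - off
      gs <- ge - seed_len
    }
    cands[[length(cands) + 1L]] <- structure(
      list(locus_tag = window$locus_tag, seed_rna = seed,
           match_start_rel = rel, match_len = seed_len,
           target_sub = target_sub,
           chrom = window$chrom, gen_start = gs, gen_end = ge,
           strand = window$strand),
      class = "seed_candidate")
  }
  attr(cands, "dropped") <- dropped
  attr(cands, "n_enumerated") <- length(offsets)
  cands
}
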