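#' Genome-wide off-target scan of a seed sequence
#'
#' Ungapped seed-and-extend scan (a desk-scale BLASTn-style search): every
#' exact `word_size`-mer shared between the query and either strand of any
#' replicon is extended in both directions without gaps under an X-drop
#' rule, scored with a match/mismatch scheme, and assigned a
#' Karlin-Altschul E-value `K*m*n*exp(-lambda*S)` where `n` counts both
#' strands of all replicons. Hits overlapping the intended target site
#' (`exclude`) are omitted; remaining hits with `evalue <= evalue_cutoff`
#' are reported as maximal deduplicated segments, sorted by E-value.
#'
#' @param seed_dna DNA [nuc_seq] query (an RNA seed should be
#'   back-transcribed first).
#' @param genome A [nuc_seq], [gb_record], or list of either (replicons).
#' @param scheme A [scoring_scheme()].
#' @param word_size Exact-match word length for seeding (>= 4). The default
#'   4 makes the scan effectively exhaustive for 20-30 nt seeds: with
#'   shorter words than BLASTn's defaults, every segment that could beat
#'   the best clean match run contains a seed word, so the top hit equals
#'   the global best ungapped local alignment in practice.
#' @param xdrop Score drop-off terminating extension (default 10).
#' @param evalue_cutoff Report hits with E-value at or below this.
#' @param exclude Optional list(`chrom`, `start`, `end`): genomic interval
#'   of the intended target site (0-based half-open); overlapping hits on
#'   either strand are omitted.
#' @return data.frame with columns `chrom`, `start`, `end` (forward-strand,
#'   0-based half-open), `strand`, `score`, `evalue`.
#' @export
scan_offtargets <- function(seed_dna, genome, scheme = scoring_scheme(),
                            word_size = 4L, xdrop = 10, evalue_cutoff = 10,
                            exclude = NULL) {
  seed_dna <- as_nuc_seq(seed_dna)
  if (seed_dna$molecule != "DNA") stop("query must be DNA; back-transcribe RNA seeds")
  word_size <- as.integer(word_size)
  if (word_size < 4L) stop("word_size < 4 is pathologically sensitive; use >= 4")
  q <- seed_dna$residues
  m <- nchar(q)
  if (word_size > m) stop("word_size exceeds query length")
  reps <- normalize_replicons(genome)
  if (!length(reps)) stop("genome must contain at least one replicon")
  total_n <- 2 * sum(vapply(reps, function(s) nchar(s$residues), 0))

  qvec <- strsplit(q, "")[[1]]
  words <- substring(q, 1:(m - word_size + 1L), word_size:m)
  qpos_by_word <- split(0:(m - word_size), words)

  rows <- list()
  for (rep_seq in reps) {
    n <- nchar(rep_seq$residues)
    for (strand in c("+", "-")) {
      subj <- if (strand == "+") rep_seq$residues else rc_string(rep_seq$residues)
      if (n < word_size) next
      sub_words <- substring(subj, 1:(n - word_size + 1L), word_size:n)
      svec <- strsplit(subj, "")[[1]]
      diag_cache <- new.env(parent = emptyenv())
      for (word in names(qpos_by_word)) {
        ss <- which(sub_words == word)
        if (!length(ss)) next
        hits_qs <- expand.grid(qpos = qpos_by_word[[word]], spos = ss - 1L)
        for (hi in seq_len(nrow(hits_qs))) {
          qpos <- hits_qs$qpos[hi]
          spos <- hits_qs$spos[hi]
          d <- spos - qpos           # diagonal
          key <- as.character(d)
          dinfo <- diag_cache[[key]]
          if (is.null(dinfo)) {
            q0 <- max(0L, -d)                  # first query index on diagonal
            q1 <- min(m - 1L, n - 1L - d)      # last
            sc <- ifelse(qvec[(q0 + 1L):(q1 + 1L)] == svec[(d + q0 + 1L):(d + q1 + 1L)],
                         scheme$match, scheme$mismatch)
            dinfo <- list(q0 = q0, q1 = q1, sc = sc)
            diag_cache[[key]] <- dinfo
          }
          seg <- xdrop_extend(dinfo$sc, qpos - dinfo$q0, word_size, xdrop)
          qa <- dinfo$q0 + seg$a      # 0-based query segment [qa, qb]
          qb <- dinfo$q0 + seg$b
          sa <- d + qa
          sb <- d + qb
          if (strand == "+") {
            fs <- sa; fe <- sb + 1L
          } else {
            fs <- n - (sb + 1L); fe <- n - sa
          }
          rows[[length(rows) + 1L]] <-
            c(chrom = rep_seq$id, start = fs, end = fe, strand = strand,
              score = seg$score)
        }
      }
    }
  }
  if (!length(rows)) return(empty_offtarget_hits())
  df <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  df$score <- as.numeric(df$score)
  df <- unique(df)
  df$evalue <- karlin_evalue(df$score, m, total_n, scheme)
  df <- df[df$evalue <= evalue_cutoff, , drop = FALSE]
  if (!is.null(exclude) && nrow(df)) {
    keep <- !(df$chrom == exclude$chrom &
              df$start < exclude$end & df$end > exclude$start)
    df <- df[keep, , drop = FALSE]
  }
  df <- df[order(df$evalue, df$chrom, df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

empty_offtarget_hits <- function() {
  data.frame(chrom = character(), start = integer(), end = integer(),
             strand = character(), score = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

# Bidirectional X-drop extension of a word hit along one diagonal.
# sc: per-position scores along the diagonal; w0: 0-based index (into sc) of
# the word start; w: word length. Returns 0-based [a,b] segment indices into
# sc and the segment score.
xdrop_extend <- function(sc, w0, w, xdrop) {
  word_score <- sum(sc[(w0 + 1L):(w0 + w)])
  # rightwards from word end
  best_r <- 0; cur <- 0; b <- w0 + w - 1L
  i <- w0 + w
  while (i <= length(sc) - 1L) {
    cur <- cur + sc[i + 1L]
    if (cur > best_r) { best_r <- cur; b <- i }
    if (cur <= best_r - xdrop) break
    i <- i + 1L
  }
  # leftwards from word start
  best_l <- 0; cur <- 0; a <- w0
  i <- w0 - 1L
  while (i >= 0L) {
    cur <- cur + sc[i + 1L]
    if (cur > best_l) { best_l <- cur; a <- i }
    if (cur <= best_l - xdrop) break
    i <- i - 1L
  }
  list(a = a, b = b, score = word_score + best_r + best_l)
}

normalize_replicons <- function(genome) {
  if (is_nuc_seq(genome)) return(list(genome))
  if (inherits(genome, "gb_record")) return(list(genome$seq))
  if (is.list(genome)) {
    return(lapply(genome, function(g) {
      if (inherits(g, "gb_record")) g$seq
      else if (is_nuc_seq(g)) g
      else stop("genome list elements must be nuc_seq or gb_record")
    }))
  }
  stop("genome must be a nuc_seq, gb_record, or list of them")
}
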