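#' Built-in type IIS enzyme table
#'
#' Recognition sites, spacer lengths (bases between the recognition site and
#' the top-strand cut) and overhang lengths for the type IIS enzymes the
#' assembly designer supports. Type IIS enzymes cut at a fixed offset
#' outside their recognition motif, leaving programmable single-stranded
#' overhangs of 3 or 4 nucleotides.
#'
#' @return A data.frame with columns `name`, `recognition`, `spacer_len`,
#'   `overhang_len`.
#' @export
type_iis_enzymes <- function() {
  data.frame(
    name = c("BsaI", "BsmBI", "BbsI", "SapI", "PaqCI"),
    recognition = c("GGTCTC", "CGTCTC", "GAAGAC", "GCTCTTC", "CACCTGC"),
    spacer_len = c(1L, 1L, 2L, 1L, 4L),
    overhang_len = c(4L, 4L, 4L, 3L, 4L),
    stringsAsFactors = FALSE
  )
}

#' Look up a type IIS enzyme by name
#' @param name Enzyme name, e.g. `"BsaI"`.
#' @return A one-row list with fields `name`, `recognition`, `spacer_len`,
#'   `overhang_len`.
#' @export
get_enzyme <- function(name) {
  tab <- type_iis_enzymes()
  i <- match(name, tab$name)
  if (is.na(i)) {
    stop(sprintf("unknown enzyme '%s'; available: %s",
                 name, paste(tab$name, collapse = ", ")))
  }
  as.list(tab[i, ])
}

#' Scan a sequence for motif occurrences
#'
#' Reports every verbatim occurrence of each motif (and, optionally, of its
#' reverse complement, reported as strand `-`), including overlapping
#' occurrences. Circular records are scanned across the origin by extending
#' the sequence with its first `motif length - 1` characters.
#'
#' @param seq A [nuc_seq]. RNA inputs are scanned in their DNA form.
#' @param motifs Named character vector of DNA motifs (names label the hits;
#'   unnamed motifs are labelled by their sequence).
#' @param both_strands Scan the reverse complement of each motif too.
#' @return data.frame with columns `motif_name`, `start` (0-based, on the
#'   forward strand of `seq`), `strand`, sorted by `start`.
#' @export
scan_motifs <- function(seq, motifs, both_strands = TRUE) {
  seq <- as_nuc_seq(seq)
  res <- if (seq$molecule == "RNA") chartr("U", "T", seq$residues) else seq$residues
  if (length(motifs) == 0) return(empty_motif_hits())
  motifs <- vapply(motifs, toupper, "")
  if (is.null(names(motifs))) names(motifs) <- motifs
  names(motifs)[!nzchar(names(motifs))] <- motifs[!nzchar(names(motifs))]
  if (any(!nzchar(motifs))) stop("empty motif is not allowed")
  n <- nchar(res)
  out <- vector("list", length(motifs) * 2L)
  k <- 0L
  for (mi in seq_along(motifs)) {
    m <- motifs[[mi]]
    mlen <- nchar(m)
    subject <- res
    if (seq$topology == "circular" && mlen > 1L && n > 1L) {
      subject <- paste0(res, substr(res, 1L, min(mlen - 1L, n)))
    }
    variants <- list(c(m, "+"))
    if (both_strands) {
      mrc <- rc_string(m)
      if (mrc != m) variants <- c(variants, list(c(mrc, "-")))
    }
    for (v in variants) {
      starts <- find_all_fixed(subject, v[[1]])
      starts <- starts[starts <= n]        # 1-based start within original
      if (length(starts)) {
        k <- k + 1L
        out[[k]] <- data.frame(motif_name = names(motifs)[mi],
                               start = starts - 1L, strand = v[[2]],
                               stringsAsFactors = FALSE)
      }
      if (both_strands && v[[2]] == "+" && rc_string(m) == m) {
        # palindromic motif: each + hit is also a - hit at the same start
        if (length(starts)) {
          k <- k + 1L
          out[[k]] <- data.frame(motif_name = names(motifs)[mi],
                                 start = starts - 1L, strand = "-",
                                 stringsAsFactors = FALSE)
        }
      }
    }
  }
  hits <- if (k) do.call(rbind, out[seq_len(k)]) else empty_motif_hits()
  hits <- unique(hits)
  hits[order(hits$start, hits$motif_name, hits$strand), , drop = FALSE]
}

empty_motif_hits <- function() {
  data.frame(motif_name = character(), start = integer(),
             strand = character(), stringsAsFactors = FALSE)
}

# all (possibly overlapping) 1-based start positions of fixed pattern
find_all_fixed <- function(subject, pattern) {
  if (nchar(pattern) > nchar(subject)) return(integer())
  m <- Biostrings::matchPattern(pattern, Biostrings::DNAString(subject))
  Biostrings::start(m)
}

#' Does a sequence contain any of the given motifs (either strand)?
#' @noRd
contains_motif <- function(seq, motifs) {
  nrow(scan_motifs(seq, motifs, both_strands = TRUE)) > 0L
}

#' Resolve excluded-enzyme names to a named motif vector
#' @noRd
resolve_enzyme_motifs <- function(names_csv) {
  if (is.null(names_csv) || !length(names_csv) || !nzchar(names_csv[1]))
    return(character())
  nm <- trimws(unlist(strsplit(paste(names_csv, collapse = ","), ",")))
  nm <- nm[nzchar(nm)]
  motifs <- vapply(nm, function(x) get_enzyme(x)$recognition, "")
  names(motifs) <- nm
  motifs
}
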