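#' Nucleic-acid sequence record
#'
#' Lightweight carrier for a single DNA or RNA sequence with an identifier,
#' molecule type and topology. All coordinates used throughout the package
#' are 0-based, half-open; 1-based inclusive numbers appear only in
#' user-facing reports and GenBank output.
#'
#' @param residues Character scalar, uppercase over `ACGT` (DNA) or `ACGU`
#'   (RNA). Ambiguity codes are rejected.
#' @param id Record identifier.
#' @param molecule `"DNA"` or `"RNA"`. Guessed from the residues when `NULL`
#'   (`U` present implies RNA, otherwise DNA).
#' @param topology `"linear"` or `"circular"`. Circular records must be DNA.
#' @return An object of class `nuc_seq`.
#' @examples
#' s <- nuc_seq("ATGCATGC", id = "demo")
#' reverse_complement(s)
#' @export
nuc_seq <- function(residues, id = "seq", molecule = NULL,
                    topology = c("linear", "circular")) {
  topology <- match.arg(topology)
  if (!is.character(residues) || length(residues) != 1L || is.na(residues))
    stop("residues must be a single character string")
  residues <- toupper(residues)
  if (!nzchar(residues)) stop("residues must be non-empty")
  if (is.null(molecule)) {
    molecule <- if (grepl("U", residues, fixed = TRUE)) "RNA" else "DNA"
  }
  molecule <- match.arg(molecule, c("DNA", "RNA"))
  alph <- if (molecule == "DNA") "ACGT" else "ACGU"
  bad <- regexpr(sprintf("[^%s]", alph), residues)
  if (bad > 0L) {
    stop(sprintf("invalid %s residue '%s' at position %d (0-based %d)",
                 molecule, substr(residues, bad, bad), bad, bad - 1L))
  }
  if (topology == "circular" && molecule != "DNA")
    stop("circular topology is only allowed for DNA records")
  structure(list(id = as.character(id), residues = residues,
                 molecule = molecule, topology = topology),
            class = "nuc_seq")
}

#' @export
print.nuc_seq <- function(x, ...) {
  n <- nchar(x$residues)
  shown <- if (n > 60) paste0(substr(x$residues, 1, 57), "...") else x$residues
  cat(sprintf("<nuc_seq> %s  %d nt %s (%s)\n  %s\n",
              x$id, n, x$molecule, x$topology, shown))
  invisible(x)
}

#' @export
length.nuc_seq <- function(x) nchar(x$residues)

#' @export
as.character.nuc_seq <- function(x, ...) x$residues

is_nuc_seq <- function(x) inherits(x, "nuc_seq")

as_nuc_seq <- function(x, molecule = NULL) {
  if (is_nuc_seq(x)) x else nuc_seq(x, molecule = molecule)
}

#' Reverse complement
#'
#' Watson-Crick complement, reversed. The molecule type is preserved
#' (U pairs A for RNA).
#'
#' @param seq A [nuc_seq] (or plain string; molecule guessed).
#' @return A `nuc_seq` of the same molecule type and length.
#' @export
reverse_complement <- function(seq) {
  seq <- as_nuc_seq(seq)
  res <- if (seq$molecule == "DNA") {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq$residues)))
  } else {
    as.character(Biostrings::reverseComplement(Biostrings::RNAString(seq$residues)))
  }
  nuc_seq(res, id = seq$id, molecule = seq$molecule, topology = "linear")
}

#' Transcribe DNA to RNA
#'
#' Coding-strand convention: plain T to U substitution, no complementation.
#'
#' @param seq A DNA [nuc_seq].
#' @return An RNA `nuc_seq` of identical length.
#' @export
transcribe <- function(seq) {
  seq <- as_nuc_seq(seq)
  if (seq$molecule != "DNA") stop("transcribe() expects a DNA input")
  nuc_seq(chartr("T", "U", seq$residues), id = seq$id, molecule = "RNA")
}

#' Back-transcribe RNA to DNA (U to T)
#' @param seq An RNA [nuc_seq].
#' @return A DNA `nuc_seq`.
#' @export
back_transcribe <- function(seq) {
  seq <- as_nuc_seq(seq)
  if (seq$molecule != "RNA") stop("back_transcribe() expects an RNA input")
  nuc_seq(chartr("U", "T", seq$residues), id = seq$id, molecule = "DNA")
}

# substring in 0-based half-open coordinates
subseq0 <- function(seq, start, end) {
  seq <- as_nuc_seq(seq)
  n <- nchar(seq$residues)
  if (start < 0 || end > n || start >= end)
    stop(sprintf("subsequence [%d,%d) out of bounds for length %d", start, end, n))
  nuc_seq(substr(seq$residues, start + 1L, end), id = seq$id,
          molecule = seq$molecule)
}

# hot-path complement/reverse on plain strings (avoids S4 construction
# overhead in inner loops); user-facing reverse_complement() goes through
# Biostrings
rc_string <- function(x, molecule = "DNA") {
  y <- if (molecule == "DNA") chartr("ACGT", "TGCA", x) else chartr("ACGU", "UGCA", x)
  paste(rev(strsplit(y, "", fixed = TRUE)[[1]]), collapse = "")
}
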