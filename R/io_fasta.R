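#' Read a (multi-record) FASTA file
#'
#' @param path File path.
#' @param molecule Force `"DNA"`/`"RNA"`; by default guessed per record
#'   (`U` present implies RNA).
#' @return A named list of [nuc_seq] records.
#' @export
read_fasta <- function(path, molecule = NULL) {
  if (!file.exists(path)) stop(sprintf("FASTA file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) && !startsWith(trimws(lines[nonempty[1]]), ">")) {
    stop(sprintf("%s: malformed FASTA, line %d does not start a record",
                 path, nonempty[1]))
  }
  set <- Biostrings::readBStringSet(path)
  if (!length(set)) stop(sprintf("%s: no FASTA records", path))
  out <- lapply(seq_along(set), function(i) {
    id <- strsplit(names(set)[i], "\\s+")[[1]][1]
    nuc_seq(as.character(set[[i]]), id = id, molecule = molecule)
  })
  names(out) <- vapply(out, function(s) s$id, "")
  out
}

#' Write FASTA (wrapped at 70 columns)
#'
#' @param seqs A [nuc_seq] or list of them. Optional per-record description
#'   lines may be supplied via `desc`.
#' @param path Output path.
#' @param desc Optional character vector of descriptions appended to the
#'   header lines.
#' @export
write_fasta <- function(seqs, path, desc = NULL) {
  if (is_nuc_seq(seqs)) seqs <- list(seqs)
  con <- file(path, open = "wb")   # binary: byte-stable newlines
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    s <- seqs[[i]]
    hdr <- paste0(">", s$id)
    if (!is.null(desc) && nzchar(desc[i])) hdr <- paste(hdr, desc[i])
    writeLines(hdr, con)
    n <- nchar(s$residues)
    starts <- seq(1L, n, by = 70L)
    writeLines(substring(s$residues, starts, pmin(starts + 69L, n)), con)
  }
  invisible(path)
}
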