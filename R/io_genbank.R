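#' Annotated sequence record (GenBank-style)
#'
#' Couples a [nuc_seq] with a feature table. Features use the package's
#' internal 0-based half-open convention; GenBank files on disk use the
#' standard 1-based inclusive numbering, converted on read/write.
#'
#' @param seq A [nuc_seq].
#' @param features data.frame with columns `kind`, `locus_tag`, `start`,
#'   `end` (0-based half-open), `strand` (`"+"`/`"-"`).
#' @return An object of class `gb_record`.
#' @export
gb_record <- function(seq, features = empty_features()) {
  stopifnot(is_nuc_seq(seq))
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  needed <- c("kind", "locus_tag", "start", "end", "strand")
  if (!all(needed %in% names(features)))
    stop("features must have columns kind, locus_tag, start, end, strand")
  n <- nchar(seq$residues)
  if (nrow(features)) {
    bad <- which(features$start < 0 | features$start >= features$end |
                 (seq$topology == "linear" & features$end > n))
    if (length(bad))
      stop(sprintf("feature %s [%d,%d) out of bounds for length %d",
                   features$locus_tag[bad[1]], features$start[bad[1]],
                   features$end[bad[1]], n))
  }
  structure(list(seq = seq, features = features), class = "gb_record")
}

#' @export
print.gb_record <- function(x, ...) {
  cat(sprintf("<gb_record> %s: %d nt %s (%s), %d features\n",
              x$seq$id, nchar(x$seq$residues), x$seq$molecule,
              x$seq$topology, nrow(x$features)))
  invisible(x)
}

empty_features <- function() {
  data.frame(kind = character(), locus_tag = character(), start = integer(),
             end = integer(), strand = character(), stringsAsFactors = FALSE)
}

#' Write a GenBank flat file
#'
#' Writes LOCUS (with topology), a FEATURES table (gene/CDS/misc_feature and
#' similar simple kinds with `/locus_tag` qualifiers) and ORIGIN. The LOCUS
#' date field is a fixed constant so identical records produce byte-identical
#' files.
#'
#' @param record A [gb_record].
#' @param path Output path.
#' @export
write_genbank <- function(record, path) {
  stopifnot(inherits(record, "gb_record"))
  s <- record$seq
  n <- nchar(s$residues)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %-16s %d bp    %s     %-8s SYN 01-JAN-1980",
                     s$id, n, s$molecule, s$topology), con)
  writeLines(sprintf("DEFINITION  %s.", s$id), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  f <- record$features
  if (nrow(f)) {
    for (i in seq_len(nrow(f))) {
      loc <- sprintf("%d..%d", f$start[i] + 1L, f$end[i])
      if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
      writeLines(sprintf("     %-16s%s", f$kind[i], loc), con)
      writeLines(sprintf("                     /locus_tag=\"%s\"", f$locus_tag[i]), con)
    }
  }
  writeLines("ORIGIN", con)
  res <- tolower(s$residues)
  for (off in seq(1L, n, by = 60L)) {
    chunk <- substr(res, off, min(off + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(1L, nchar(chunk), by = 10L) + 9L, nchar(chunk)))
    writeLines(sprintf("%9d %s", off, paste(blocks, collapse = " ")), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read a GenBank flat file (single record)
#'
#' Parses LOCUS (name, length, molecule, topology), features of simple kinds
#' with a single `a..b` or `complement(a..b)` location and a `/locus_tag`
#' qualifier, and the ORIGIN sequence. Compound (`join`) locations are not
#' supported.
#'
#' @param path File path.
#' @return A [gb_record].
#' @export
read_genbank <- function(path) {
  if (!file.exists(path)) stop(sprintf("GenBank file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  iloc <- grep("^LOCUS", lines)
  if (!length(iloc)) stop(sprintf("%s: no LOCUS line", path))
  toks <- strsplit(trimws(lines[iloc[1]]), "\\s+")[[1]]
  if (length(toks) < 4 || toks[4] != "bp")
    stop(sprintf("%s: malformed LOCUS at line %d", path, iloc[1]))
  id <- toks[2]
  topology <- if (any(tolower(toks) == "circular")) "circular" else "linear"
  molecule <- if (any(toupper(toks) == "RNA")) "RNA" else "DNA"

  ifeat <- grep("^FEATURES", lines)
  iorig <- grep("^ORIGIN", lines)
  if (!length(iorig)) stop(sprintf("%s: no ORIGIN section", path))
  iend <- grep("^//", lines)
  iend <- if (length(iend)) iend[iend > iorig[1]][1] else length(lines) + 1L

  feats <- empty_features()
  if (length(ifeat)) {
    i <- ifeat[1] + 1L
    while (i < iorig[1]) {
      line <- lines[i]
      if (grepl("^     \\S", line)) {
        kind <- sub("^\\s*(\\S+).*$", "\\1", line)
        loc <- trimws(substring(line, 22))
        strand <- "+"
        if (grepl("^complement\\(", loc)) {
          strand <- "-"
          loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
        }
        if (!grepl("^[0-9]+\\.\\.[0-9]+$", loc))
          stop(sprintf("%s: unsupported feature location '%s' at line %d",
                       path, loc, i))
        ab <- as.integer(strsplit(loc, "\\.\\.")[[1]])
        tag <- ""
        j <- i + 1L
        while (j < iorig[1] && grepl("^\\s{10,}", lines[j]) &&
               !grepl("^     \\S", lines[j])) {
          q <- trimws(lines[j])
          if (startsWith(q, "/locus_tag="))
            tag <- gsub("\"", "", sub("^/locus_tag=", "", q))
          j <- j + 1L
        }
        feats <- rbind(feats, data.frame(kind = kind, locus_tag = tag,
                                         start = ab[1] - 1L, end = ab[2],
                                         strand = strand,
                                         stringsAsFactors = FALSE))
        i <- j
      } else {
        i <- i + 1L
      }
    }
  }

  seq_lines <- lines[(iorig[1] + 1L):(iend - 1L)]
  residues <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!nzchar(residues))
    stop(sprintf("%s: empty ORIGIN section at line %d", path, iorig[1]))
  gb_record(nuc_seq(residues, id = id, molecule = molecule, topology = topology),
            feats)
}
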