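#' A DNA part for Golden Gate assembly
#'
#' @param name Part name.
#' @param role One of `plasmid`, `promoter`, `seed`, `scaffold`, `other`.
#' @param seq DNA [nuc_seq] (plasmids circular, everything else linear).
#' @param production `"anneal"` (oligo annealing), `"pcr"`, or `"none"`
#'   (plasmids).
#' @param template_name For PCR parts: name of the library template (the
#'   part's own sequence is used when `NA`).
#' @return List of class `gg_part`.
#' @export
gg_part <- function(name, role = c("other", "plasmid", "promoter", "seed", "scaffold"),
                    seq, production = c("anneal", "pcr", "none"),
                    template_name = NA_character_) {
  role <- match.arg(role)
  production <- match.arg(production)
  seq <- as_nuc_seq(seq)
  if (seq$molecule != "DNA") stop("parts must be DNA")
  if (role == "plasmid" && seq$topology != "circular")
    stop("plasmid parts must be circular")
  if (role != "plasmid" && seq$topology != "linear")
    stop("non-plasmid parts must be linear")
  structure(list(name = name, role = role, seq = seq,
                 production = production, template_name = template_name),
            class = "gg_part")
}

#' Read / write a parts library (saved-data TSV)
#'
#' Human-editable tab-separated library with columns `name`, `role`,
#' `topology`, `production`, `sequence`; the design pipeline appends its
#' results in the same format so the library grows over time.
#'
#' @param path File path.
#' @return Named list of [gg_part].
#' @export
read_parts_library <- function(path) {
  if (!file.exists(path)) stop(sprintf("parts library not found: %s", path))
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  needed <- c("name", "role", "topology", "production", "sequence")
  if (!all(needed %in% names(tab)))
    stop(sprintf("%s: parts library needs columns %s", path,
                 paste(needed, collapse = ", ")))
  parts <- lapply(seq_len(nrow(tab)), function(i) {
    gg_part(tab$name[i], role = tab$role[i],
            seq = nuc_seq(tab$sequence[i], id = tab$name[i], molecule = "DNA",
                          topology = tab$topology[i]),
            production = if (tab$production[i] %in% c("anneal", "pcr")) tab$production[i] else "none")
  })
  names(parts) <- tab$name
  parts
}

#' @rdname read_parts_library
#' @param parts Named list of [gg_part].
#' @export
write_parts_library <- function(parts, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("name\trole\ttopology\tproduction\tsequence", con)
  for (p in parts) {
    writeLines(sprintf("%s\t%s\t%s\t%s\t%s", p$name, p$role, p$seq$topology,
                       p$production, p$seq$residues), con)
  }
  invisible(path)
}

#' In-silico type IIS digestion
#'
#' Cuts every recognition site (both strands) at the enzyme's fixed offset
#' and returns the resulting double-stranded fragments with their 5'
#' single-stranded overhangs. A fragment is represented by its top strand
#' `tops` (beginning with the bases of its left overhang `lovh`) plus
#' `rovh`, the top-strand bases immediately 3' of the fragment that its
#' right-end bottom-strand overhang is complementary to (i.e. the bases a
#' compatible downstream fragment must start with).
#'
#' @param seqrec [nuc_seq], circular or linear DNA.
#' @param enzyme Enzyme list from [get_enzyme()].
#' @return List of fragment lists: `tops`, `lovh`, `rovh`, `source`.
#' @export
digest <- function(seqrec, enzyme) {
  seqrec <- as_nuc_seq(seqrec)
  res <- seqrec$residues
  n <- nchar(res)
  ovh <- enzyme$overhang_len
  reclen <- nchar(enzyme$recognition)
  hits <- scan_motifs(seqrec, stats::setNames(enzyme$recognition, enzyme$name),
                      both_strands = TRUE)
  if (!nrow(hits)) {
    frag <- list(tops = res, lovh = "", rovh = "", source = seqrec$id)
    return(if (seqrec$topology == "circular") list() else list(frag))
  }
  cuts <- integer()
  for (i in seq_len(nrow(hits))) {
    s <- hits$start[i]
    tc <- if (hits$strand[i] == "+") s + reclen + enzyme$spacer_len
          else s - enzyme$spacer_len - ovh
    if (seqrec$topology == "circular") {
      tc <- ((tc %% n) + n) %% n
      cuts <- c(cuts, tc)
    } else {
      if (tc >= 0 && tc + ovh <= n) cuts <- c(cuts, tc)
    }
  }
  cuts <- sort(unique(cuts))
  at <- function(a, b) {     # 0-based half-open substring with circular wrap
    if (b <= n) substr(res, a + 1L, b)
    else paste0(substr(res, a + 1L, n), substr(res, 1L, b - n))
  }
  frags <- list()
  if (seqrec$topology == "circular") {
    if (length(cuts) < 2) {
      return(list())  # a single cut linearizes; no defined fragments to ligate
    }
    for (i in seq_along(cuts)) {
      a <- cuts[i]
      b <- if (i < length(cuts)) cuts[i + 1L] else cuts[1] + n
      frags[[i]] <- list(tops = at(a, b), lovh = at(a, a + ovh),
                         rovh = at(b %% n, (b %% n) + ovh),
                         source = seqrec$id)
    }
  } else {
    bounds <- c(0L, cuts, n)
    for (i in seq_len(length(bounds) - 1L)) {
      a <- bounds[i]; b <- bounds[i + 1L]
      lovh <- if (i == 1L) "" else at(a, a + ovh)
      rovh <- if (i == length(bounds) - 1L) "" else at(b, b + ovh)
      frags[[length(frags) + 1L]] <- list(tops = at(a, b), lovh = lovh,
                                          rovh = rovh, source = seqrec$id)
    }
  }
  frags
}

fragment_contains_site <- function(frag, enzyme) {
  contains_motif(nuc_seq(frag$tops, molecule = "DNA"),
                 stats::setNames(enzyme$recognition, enzyme$name))
}

# reverse-complement a fragment (flip the double-stranded molecule).
# The extended region tops+rovh maps to its reverse complement; overhang
# lengths swap ends (new lovh = rc(old rovh), new rovh = rc(old lovh)).
flip_fragment <- function(frag) {
  ext2 <- rc_string(paste0(frag$tops, frag$rovh))
  nl <- nchar(frag$lovh); nr <- nchar(frag$rovh); ne <- nchar(ext2)
  list(tops = substr(ext2, 1L, ne - nl),
       lovh = substr(ext2, 1L, nr),
       rovh = if (nl > 0) substr(ext2, ne - nl + 1L, ne) else "",
       source = paste0(frag$source, "_rc"))
}
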