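#' Plan a scarless Golden Gate assembly
#'
#' The first part must be the Golden Gate acceptor plasmid (circular, with
#' exactly two recognition sites cutting inward around a dropout); the
#' remaining parts are the inserts, ordered 5' to 3'. Junction overhangs are
#' drawn from the final construct's own sequence (scarless): the overhang at
#' each junction is the first `overhang_len` bases of the downstream part.
#' At the two backbone junctions the plasmid's own fixed cut sites dictate
#' the overhangs; compatibility with the flanking insert ends is checked,
#' never silently patched with adapter bases.
#'
#' @param parts List of [gg_part]; `parts[[1]]` is the plasmid.
#' @param enzyme Enzyme from [get_enzyme()].
#' @param name Optional plan name (defaults to part names joined by `_`).
#' @return List of class `assembly_plan`: `enzyme`, `ordered_parts`,
#'   `junction_overhangs` (circular, one per junction, starting with
#'   plasmid->insert1), `expected_construct` (circular DNA [nuc_seq]),
#'   `fragments` (per-part fragment specs used for oligo design and
#'   simulation), `backbone`.
#' @export
plan_assembly <- function(parts, enzyme, name = NULL) {
  if (length(parts) < 2) stop("an assembly needs the plasmid plus at least one insert")
  stopifnot(all(vapply(parts, inherits, TRUE, "gg_part")))
  plasmid <- parts[[1]]
  if (plasmid$role != "plasmid")
    stop("the first part must have role 'plasmid'")
  inserts <- parts[-1]
  ovh <- enzyme$overhang_len
  motif <- stats::setNames(enzyme$recognition, enzyme$name)
  for (p in inserts) {
    hits <- scan_motifs(p$seq, motif, both_strands = TRUE)
    if (nrow(hits))
      stop(sprintf("insert '%s' contains an internal %s site at position %d strand %s",
                   p$name, enzyme$name, hits$start[1], hits$strand[1]))
    if (nchar(p$seq$residues) <= ovh)
      stop(sprintf("insert '%s' is shorter than the overhang length", p$name))
  }
  nsites <- nrow(scan_motifs(plasmid$seq, motif, both_strands = TRUE))
  if (nsites != 2)
    stop(sprintf("plasmid '%s' must carry exactly two %s sites (found %d)",
                 plasmid$name, enzyme$name, nsites))
  frags <- digest(plasmid$seq, enzyme)
  if (length(frags) != 2)
    stop(sprintf("digestion of plasmid '%s' did not yield two fragments", plasmid$name))
  has_site <- vapply(frags, fragment_contains_site, TRUE, enzyme = enzyme)
  if (sum(has_site) != 1)
    stop(sprintf("plasmid '%s': could not identify a site-free backbone fragment",
                 plasmid$name))
  backbone <- frags[[which(!has_site)]]
  # plasmid-dictated overhangs: rovh = insert-side start, lovh = backbone start
  first4 <- function(p) substr(p$seq$residues, 1L, ovh)
  if (backbone$rovh != first4(inserts[[1]]))
    stop(sprintf("junction 1 (plasmid -> %s): plasmid expects overhang %s but insert starts with %s",
                 inserts[[1]]$name, backbone$rovh, first4(inserts[[1]])))
  n_ins <- length(inserts)
  junctions <- character(n_ins + 1L)
  junctions[1] <- backbone$rovh
  if (n_ins > 1) {
    for (k in seq_len(n_ins - 1L)) junctions[k + 1L] <- first4(inserts[[k + 1L]])
  }
  junctions[n_ins + 1L] <- backbone$lovh
  construct_seq <- paste0(backbone$tops,
                          paste(vapply(inserts, function(p) p$seq$residues, ""),
                                collapse = ""))
  construct <- nuc_seq(construct_seq,
                       id = if (is.null(name))
                         paste(vapply(parts, function(p) p$name, ""), collapse = "_")
                       else name,
                       molecule = "DNA", topology = "circular")
  resid <- scan_motifs(construct, motif, both_strands = TRUE)
  if (nrow(resid))
    stop(sprintf("assembly would re-create a %s site at position %d of the construct",
                 enzyme$name, resid$start[1]))
  # per-part fragment specs (rovh = overhang of the junction downstream)
  fragments <- vector("list", n_ins)
  for (k in seq_len(n_ins)) {
    nxt <- if (k < n_ins) first4(inserts[[k + 1L]]) else backbone$lovh
    fragments[[k]] <- list(tops = inserts[[k]]$seq$residues,
                           lovh = first4(inserts[[k]]),
                           rovh = nxt, source = inserts[[k]]$name)
  }
  plan <- structure(list(enzyme = enzyme, ordered_parts = parts,
                         junction_overhangs = junctions,
                         expected_construct = construct,
                         fragments = fragments, backbone = backbone,
                         name = construct$id),
                    class = "assembly_plan")
  stopifnot(identical(rederive_overhangs(plan), junctions))
  plan
}

# re-read the junction overhangs from the expected construct's sequence
rederive_overhangs <- function(plan) {
  construct <- plan$expected_construct$residues
  ovh <- plan$enzyme$overhang_len
  backbone_len <- nchar(plan$backbone$tops)
  lens <- vapply(plan$ordered_parts[-1], function(p) nchar(p$seq$residues), 0)
  starts <- backbone_len + cumsum(c(0, lens[-length(lens)]))  # 0-based junction coords
  at <- function(a) {
    n <- nchar(construct)
    a <- a %% n
    if (a + ovh <= n) substr(construct, a + 1L, a + ovh)
    else paste0(substr(construct, a + 1L, n), substr(construct, 1L, a + ovh - n))
  }
  c(vapply(starts, at, ""), at(0L))
}

#' Overhang fidelity check
#'
#' Flags overhang sets likely to mis-ligate in a one-pot reaction: exact
#' duplicates, reverse-complement clashes (one overhang equal to the
#' reverse complement of another), palindromic (self-complementary)
#' overhangs, and near-misses (pairs within Hamming distance 1 of a
#' reverse-complement match). Verdict is `fail` for duplicates/rc-clashes/
#' palindromes, `warn` for near-misses only, `pass` otherwise; on warn or
#' fail the report carries a referral to an external overhang-set
#' optimization service.
#'
#' @param overhangs Character vector of overhangs (all of the enzyme's
#'   overhang length).
#' @param enzyme Enzyme from [get_enzyme()].
#' @return List of class `fidelity_report`: `duplicates`, `rc_clashes`,
#'   `palindromes`, `near_misses`, `verdict`, `message`.
#' @export
check_fidelity <- function(overhangs, enzyme) {
  ovh <- enzyme$overhang_len
  if (any(nchar(overhangs) != ovh))
    stop(sprintf("all overhangs must have length %d for %s", ovh, enzyme$name))
  n <- length(overhangs)
  rc <- vapply(overhangs, rc_string, "")
  dup_tab <- table(overhangs)
  duplicates <- names(dup_tab[dup_tab > 1])
  palindromes <- unique(overhangs[overhangs == rc])
  hamming <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  rc_clashes <- list(); near_misses <- list()
  if (n >= 1) {
    for (i in seq_len(n)) {
      for (j in i:n) {
        a <- overhangs[i]; b <- overhangs[j]
        h <- hamming(a, rc_string(b))
        if (h == 0) {
          if (i < j && a != b) rc_clashes[[length(rc_clashes) + 1L]] <- c(a, b)
          # i == j handled as palindrome; duplicates handled above
        } else if (h == 1) {
          near_misses[[length(near_misses) + 1L]] <- c(a, b)
        }
      }
    }
  }
  verdict <- if (length(duplicates) || length(rc_clashes) || length(palindromes))
    "fail" else if (length(near_misses)) "warn" else "pass"
  msg <- if (verdict == "pass") "overhang set passes the local fidelity heuristic"
  else paste("low-fidelity overhang set; consider re-optimizing the overhangs",
             "with an external overhang-set design service (e.g. the ligase",
             "fidelity tools provided by enzyme vendors)")
  structure(list(duplicates = duplicates, rc_clashes = rc_clashes,
                 palindromes = palindromes, near_misses = near_misses,
                 verdict = verdict, message = msg),
            class = "fidelity_report")
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat(sprintf("<fidelity_report> verdict: %s\n", x$verdict))
  if (length(x$duplicates))
    cat("  duplicates:", paste(x$duplicates, collapse = ", "), "\n")
  if (length(x$rc_clashes))
    cat("  rc clashes:", paste(vapply(x$rc_clashes, paste, "", collapse = "/"),
                               collapse = ", "), "\n")
  if (length(x$palindromes))
    cat("  palindromes:", paste(x$palindromes, collapse = ", "), "\n")
  if (length(x$near_misses))
    cat("  near misses:", paste(vapply(x$near_misses, paste, "", collapse = "/"),
                                collapse = ", "), "\n")
  if (x$verdict != "pass") cat(" ", x$message, "\n")
  invisible(x)
}

#' Combinatorial expansion of slot choices into assembly plans
#'
#' Takes one list of candidate parts per slot (slot 1 = plasmids) and
#' produces one [plan_assembly()] result per element of the Cartesian
#' product, with deterministic naming. Oligo deduplication across plans
#' happens in [write_assembly_outputs()].
#'
#' @param slot_choices List of non-empty lists of [gg_part].
#' @param enzyme Enzyme from [get_enzyme()].
#' @return List of `assembly_plan`.
#' @export
expand_combinations <- function(slot_choices, enzyme) {
  if (!length(slot_choices) || any(!vapply(slot_choices, length, 0L)))
    stop("every slot must offer at least one part")
  idx <- expand.grid(rev(lapply(slot_choices, seq_along)))
  idx <- idx[, rev(seq_len(ncol(idx))), drop = FALSE]
  plans <- vector("list", nrow(idx))
  for (r in seq_len(nrow(idx))) {
    parts <- lapply(seq_along(slot_choices),
                    function(s) slot_choices[[s]][[idx[r, s]]])
    plans[[r]] <- plan_assembly(parts, enzyme)
  }
  plans
}
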