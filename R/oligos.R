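#' Nearest-neighbor melting temperature of a primer annealing region
#'
#' Unified DNA nearest-neighbor model:
#' `Tm = dH*1000 / (dS + R*ln(Ct/4)) - 273.15 + 16.6*log10([Na+])`,
#' with dH from the shipped stack table plus the two terminal initiation
#' terms, R = 1.987 cal/(mol K), total strand concentration `Ct` and
#' monovalent salt `[Na+]`. Strand-symmetric: `Tm(x) == Tm(rc(x))`.
#'
#' @param annealing_region DNA string (>= 8 nt).
#' @param Ct Total strand concentration in M (default 0.25e-6).
#' @param Na Monovalent cation concentration in M (default 0.05).
#' @return Melting temperature in degrees C.
#' @export
compute_tm <- function(annealing_region, Ct = 0.25e-6, Na = 0.05) {
  s <- toupper(as.character(annealing_region))
  if (is_nuc_seq(annealing_region)) s <- annealing_region$residues
  if (nchar(s) < 8) stop("annealing region must be at least 8 nt for the NN model")
  if (grepl("[^ACGT]", s)) stop("annealing region must be plain DNA (ACGT)")
  tab <- dna_nn_table()
  ch <- strsplit(s, "")[[1]]
  stacks <- paste0(ch[-length(ch)], ch[-1])
  dH <- sum(tab$dH[stacks])
  dS <- sum(tab$dS[stacks])
  for (endb in c(ch[1], ch[length(ch)])) {
    key <- if (endb %in% c("G", "C")) "init_GC" else "init_AT"
    dH <- dH + tab$dH[[key]]
    dS <- dS + tab$dS[[key]]
  }
  R <- 1.987
  unname(dH * 1000 / (dS + R * log(Ct / 4)) - 273.15 + 16.6 * log10(Na))
}

#' Design a pair of annealing oligonucleotides for a part
#'
#' For short parts the double-stranded fragment is produced by annealing
#' two synthetic oligos: `top = upstream_ovh + core` (i.e. the part's own
#' sequence, whose first bases are the upstream overhang) and
#' `bottom = rc(core + downstream_ovh)`. Annealing them yields the part
#' duplex with the intended 5' single-stranded overhangs on both ends.
#'
#' @param part A [gg_part] with `production == "anneal"`.
#' @param upstream_ovh,downstream_ovh Junction overhangs flanking the part
#'   (the upstream overhang must equal the part's leading bases).
#' @param max_len Maximum orderable oligo length (default 100).
#' @return List of two oligo records (`name`, `sequence`, `kind`,
#'   `tm_annealing = NA`).
#' @export
design_anneal_oligos <- function(part, upstream_ovh, downstream_ovh,
                                 max_len = 100L) {
  stopifnot(inherits(part, "gg_part"))
  if (part$production != "anneal") stop("part is not marked for annealing production")
  seqs <- part$seq$residues
  no <- nchar(upstream_ovh)
  if (substr(seqs, 1L, no) != upstream_ovh)
    stop(sprintf("part '%s' does not start with its upstream overhang %s",
                 part$name, upstream_ovh))
  core <- substr(seqs, no + 1L, nchar(seqs))
  if (!nzchar(core)) stop("zero-length core: part is nothing but its overhang")
  top <- paste0(upstream_ovh, core)
  bottom <- rc_string(paste0(core, downstream_ovh))
  if (nchar(top) > max_len || nchar(bottom) > max_len)
    stop(sprintf("part '%s' too long for annealing oligos (> %d nt); use pcr production",
                 part$name, max_len))
  list(list(name = paste0(part$name, "_top"), sequence = top,
            kind = "anneal_top", tm_annealing = NA_real_),
       list(name = paste0(part$name, "_bottom"), sequence = bottom,
            kind = "anneal_bottom", tm_annealing = NA_real_))
}

#' Simulate annealing of an oligo pair into a sticky-ended fragment
#'
#' Reconstructs the duplex formed by a top/bottom oligo pair and returns it
#' in the package's fragment representation (top strand + the overhang a
#' compatible downstream fragment must start with), or an error when the
#' oligos do not form a clean duplex with 5' overhangs.
#'
#' @param top,bottom Oligo sequences (5' to 3').
#' @param ovh_len Overhang length of the enzyme in use.
#' @return Fragment list (`tops`, `lovh`, `rovh`).
#' @export
simulate_annealing <- function(top, bottom, ovh_len) {
  bt <- rc_string(bottom)      # bottom strand in top-strand orientation
  # bt must equal substr(top, ovh_len+1, ...) + downstream overhang
  core_top <- substr(top, ovh_len + 1L, nchar(top))
  if (substr(bt, 1L, nchar(core_top)) != core_top)
    stop("oligos do not anneal into a clean duplex")
  rovh <- substr(bt, nchar(core_top) + 1L, nchar(bt))
  if (nchar(rovh) != ovh_len)
    stop("annealed duplex lacks the expected 3' junction overhang")
  list(tops = top, lovh = substr(top, 1L, ovh_len), rovh = rovh,
       source = "annealed_oligos")
}

#' Design PCR primers that amplify a part with flanking enzyme sites
#'
#' The forward primer is `pad + recognition + spacer + upstream_ovh +
#' annealing region`, the annealing region being the part prefix (after the
#' overhang bases) extended 3' until the nearest-neighbor Tm reaches
#' `tm_target` (length 18-35 nt). The reverse primer mirrors this on the
#' bottom strand with the downstream overhang reverse-complemented.
#' Digesting the simulated amplicon with the enzyme releases exactly the
#' intended part with the intended overhangs.
#'
#' @param part A [gg_part] with `production == "pcr"`.
#' @param upstream_ovh,downstream_ovh Junction overhangs flanking the part.
#' @param enzyme Enzyme from [get_enzyme()].
#' @param tm_target Annealing Tm target in degrees C (default 60).
#' @param pad 5' padding bases ahead of the recognition site (default "TA";
#'   type IIS enzymes need flanking bases to cut efficiently).
#' @param spacer_base Base used to fill the enzyme's spacer (default "A").
#' @return List of two oligo records with `kind` `"pcr_fwd"`/`"pcr_rev"` and
#'   `tm_annealing` set, plus attribute `amplicon` (the simulated product).
#' @export
design_pcr_primers <- function(part, upstream_ovh, downstream_ovh, enzyme,
                               tm_target = 60, pad = "TA", spacer_base = "A") {
  stopifnot(inherits(part, "gg_part"))
  if (part$production != "pcr") stop("part is not marked for pcr production")
  seqs <- part$seq$residues
  no <- nchar(upstream_ovh)
  if (substr(seqs, 1L, no) != upstream_ovh)
    stop(sprintf("part '%s' does not start with its upstream overhang %s",
                 part$name, upstream_ovh))
  spacer <- strrep(spacer_base, enzyme$spacer_len)
  motif <- stats::setNames(enzyme$recognition, enzyme$name)

  anneal_fwd <- grow_annealing_region(substr(seqs, no + 1L, nchar(seqs)),
                                      tm_target, part$name, "forward")
  anneal_rev <- grow_annealing_region(rc_string(seqs), tm_target,
                                      part$name, "reverse")
  for (reg in c(anneal_fwd, anneal_rev)) {
    if (contains_motif(nuc_seq(reg, molecule = "DNA"), motif))
      stop(sprintf("part '%s': annealing region contains a %s site",
                   part$name, enzyme$name))
  }
  fwd <- paste0(pad, enzyme$recognition, spacer, upstream_ovh, anneal_fwd)
  rev <- paste0(pad, enzyme$recognition, spacer, rc_string(downstream_ovh),
                anneal_rev)
  for (pr in c(fwd, rev)) {
    if (length(find_all_fixed(pr, enzyme$recognition)) != 1L)
      stop(sprintf("part '%s': primer does not contain exactly one %s site",
                   part$name, enzyme$name))
  }
  amplicon <- paste0(pad, enzyme$recognition, spacer, seqs, downstream_ovh,
                     rc_string(paste0(pad, enzyme$recognition, spacer)))
  out <- list(list(name = paste0(part$name, "_fwd"), sequence = fwd,
                   kind = "pcr_fwd", tm_annealing = compute_tm(anneal_fwd)),
              list(name = paste0(part$name, "_rev"), sequence = rev,
                   kind = "pcr_rev", tm_annealing = compute_tm(anneal_rev)))
  attr(out, "amplicon") <- nuc_seq(amplicon, id = paste0(part$name, "_amplicon"),
                                   molecule = "DNA")
  out
}

grow_annealing_region <- function(template, tm_target, part_name, side) {
  n <- nchar(template)
  lo <- min(18L, n)
  if (lo < 18L)
    stop(sprintf("part '%s' too short for a %s annealing region", part_name, side))
  for (len in 18:min(35L, n)) {
    reg <- substr(template, 1L, len)
    if (compute_tm(reg) >= tm_target) return(reg)
  }
  if (compute_tm(substr(template, 1L, min(35L, n))) >= tm_target)
    return(substr(template, 1L, min(35L, n)))
  stop(sprintf("part '%s': Tm target %.1f C unreachable within 35 nt on the %s primer",
               part_name, tm_target, side))
}
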