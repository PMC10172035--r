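#' Write assembly-plan output files
#'
#' Per plan: a plain-text junction diagram (`<name>_assembly.txt`) showing
#' parts, junction overhangs, enzyme geometry and the fidelity verdict; a
#' CSV order sheet (`<name>_oligos.csv`: name, sequence, kind, tm); and a
#' GenBank record of the expected construct (`<name>.gb`) with features for
#' each part and each junction overhang. A consolidated
#' `oligo_order_all.csv` across plans lists every distinct oligo once.
#' All outputs are deterministic.
#'
#' @param plans List of `assembly_plan` (or a single plan).
#' @param directory Output directory (created if needed).
#' @param tm_target PCR primer annealing Tm target, degrees C.
#' @return Invisibly, the list of written file paths.
#' @export
write_assembly_outputs <- function(plans, directory, tm_target = 60) {
  if (inherits(plans, "assembly_plan")) plans <- list(plans)
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(directory))
      stop(sprintf("cannot create output directory %s", directory))
  }
  written <- character()
  all_oligos <- list()
  for (plan in plans) {
    oligos <- plan_oligos(plan, tm_target)
    all_oligos <- c(all_oligos, oligos)
    fr <- check_fidelity(plan$junction_overhangs, plan$enzyme)

    # junction diagram
    txt <- file.path(directory, paste0(plan$name, "_assembly.txt"))
    con <- file(txt, open = "wb")
    writeLines(sprintf("assembly plan: %s", plan$name), con)
    writeLines(sprintf("enzyme: %s (%s, spacer %d, overhang %d)",
                       plan$enzyme$name, plan$enzyme$recognition,
                       plan$enzyme$spacer_len, plan$enzyme$overhang_len), con)
    writeLines(sprintf("expected construct: %d bp circular",
                       nchar(plan$expected_construct$residues)), con)
    writeLines("", con)
    pn <- vapply(plan$ordered_parts, function(p) p$name, "")
    for (k in seq_along(plan$junction_overhangs)) {
      up <- if (k == 1L) paste0(pn[1], " (backbone)") else pn[k]
      down <- if (k == length(plan$junction_overhangs)) paste0(pn[1], " (backbone)")
              else pn[k + 1L]
      writeLines(sprintf("  [%s] --%s--> [%s]", up,
                         plan$junction_overhangs[k], down), con)
    }
    writeLines("", con)
    writeLines(sprintf("fidelity verdict: %s", fr$verdict), con)
    if (fr$verdict != "pass") writeLines(paste0("  ", fr$message), con)
    close(con)
    written <- c(written, txt)

    # per-plan order sheet
    csv <- file.path(directory, paste0(plan$name, "_oligos.csv"))
    write_oligo_csv(oligos, csv)
    written <- c(written, csv)

    # GenBank of the expected construct
    gb <- file.path(directory, paste0(plan$name, ".gb"))
    write_genbank(construct_record(plan), gb)
    written <- c(written, gb)
  }
  dedup <- all_oligos[!duplicated(vapply(all_oligos, function(o)
    paste(o$sequence, o$kind), ""))]
  consolidated <- file.path(directory, "oligo_order_all.csv")
  write_oligo_csv(dedup, consolidated)
  written <- c(written, consolidated)
  invisible(written)
}

plan_oligos <- function(plan, tm_target = 60) {
  oligos <- list()
  for (k in seq_along(plan$fragments)) {
    part <- plan$ordered_parts[[k + 1L]]
    fr <- plan$fragments[[k]]
    pair <- if (part$production == "pcr") {
      design_pcr_primers(part, fr$lovh, fr$rovh, plan$enzyme,
                         tm_target = tm_target)
    } else {
      design_anneal_oligos(part, fr$lovh, fr$rovh)
    }
    oligos <- c(oligos, pair)
  }
  oligos
}

write_oligo_csv <- function(oligos, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("name,sequence,kind,tm_annealing", con)
  for (o in oligos) {
    tm <- if (is.na(o$tm_annealing)) "" else sprintf("%.2f", o$tm_annealing)
    writeLines(sprintf("%s,%s,%s,%s", o$name, o$sequence, o$kind, tm), con)
  }
  invisible(path)
}

construct_record <- function(plan) {
  parts <- plan$ordered_parts
  ovh <- plan$enzyme$overhang_len
  n_backbone <- nchar(plan$backbone$tops)
  feats <- data.frame(kind = "misc_feature",
                      locus_tag = paste0("plasmid_backbone_", parts[[1]]$name),
                      start = 0L, end = n_backbone, strand = "+",
                      stringsAsFactors = FALSE)
  pos <- n_backbone
  for (k in 2:length(parts)) {
    len <- nchar(parts[[k]]$seq$residues)
    feats <- rbind(feats, data.frame(
      kind = "misc_feature",
      locus_tag = paste0(parts[[k]]$role, "_", parts[[k]]$name),
      start = pos, end = pos + len, strand = "+", stringsAsFactors = FALSE))
    pos <- pos + len
  }
  total <- nchar(plan$expected_construct$residues)
  jstarts <- c(n_backbone,
               if (length(parts) > 2)
                 n_backbone + cumsum(vapply(parts[2:(length(parts) - 1L)],
                                            function(p) nchar(p$seq$residues), 0)),
               0L)
  for (k in seq_along(plan$junction_overhangs)) {
    a <- jstarts[k] %% total
    feats <- rbind(feats, data.frame(
      kind = "misc_feature",
      locus_tag = paste0("overhang_", plan$junction_overhangs[k]),
      start = a, end = min(a + ovh, total), strand = "+",
      stringsAsFactors = FALSE))
  }
  gb_record(plan$expected_construct, feats)
}
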