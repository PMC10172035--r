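#' Fuse a seed onto the sRNA scaffold
#'
#' Concatenates seed and scaffold (seed 5' of the scaffold by default,
#' matching the usual synthetic sRNA transcriptional-unit layout) and
#' re-checks the excluded motifs across the junction: a motif can straddle
#' the seed/scaffold boundary even when both halves are clean.
#'
#' @param seed_rna RNA [nuc_seq] seed.
#' @param scaffold_rna RNA [nuc_seq] scaffold.
#' @param excluded_motifs Named DNA motif vector.
#' @param seed_3prime Fuse seed 3' of the scaffold instead.
#' @return List with `full` (RNA `nuc_seq`, or `NULL` when dropped) and
#'   `drop_reason` (`NA` or a machine-readable reason string).
#' @export
fuse_seed_scaffold <- function(seed_rna, scaffold_rna,
                               excluded_motifs = character(),
                               seed_3prime = FALSE) {
  seed_rna <- as_nuc_seq(seed_rna); scaffold_rna <- as_nuc_seq(scaffold_rna)
  if (seed_rna$molecule != "RNA" || scaffold_rna$molecule != "RNA")
    stop("fuse_seed_scaffold() expects RNA inputs (transcribe first)")
  res <- if (seed_3prime) paste0(scaffold_rna$residues, seed_rna$residues)
         else paste0(seed_rna$residues, scaffold_rna$residues)
  full <- nuc_seq(res, id = paste0(seed_rna$id, "_", scaffold_rna$id),
                  molecule = "RNA")
  hits <- scan_motifs(back_transcribe(full), excluded_motifs, both_strands = TRUE)
  if (nrow(hits)) {
    return(list(full = NULL,
                drop_reason = sprintf("junction motif %s", hits$motif_name[1])))
  }
  list(full = full, drop_reason = NA_character_)
}

#' Score one seed candidate
#'
#' Fills the three design metrics: `dG_hybrid` (nearest-neighbor duplex
#' energy of the seed against its mRNA window subsequence), off-target
#' counts / best E-value from the genome-wide scan (the intended target
#' site excluded), and `structure_distance` (pairing-profile distance of
#' the full synthetic sRNA to the wild-type sRNA).
#'
#' @param candidate A `seed_candidate`.
#' @param config A `design_config`.
#' @param genome Reference genome ([nuc_seq]/[gb_record]/list).
#' @param wt_profile Optional precomputed wild-type [pairing_profile()]
#'   (computed on the fly when `NULL`).
#' @param scheme [scoring_scheme()] for the off-target scan.
#' @param params [nn_params()].
#' @return List of class `scored_design`.
#' @export
score_design <- function(candidate, config, genome, wt_profile = NULL,
                         scheme = scoring_scheme(), params = nn_params()) {
  stopifnot(inherits(candidate, "seed_candidate"))
  fused <- fuse_seed_scaffold(candidate$seed_rna, config$scaffold_seq,
                              config$excluded_motifs,
                              seed_3prime = config$fuse_seed_3prime)
  out <- list(candidate = candidate, full_sRNA = fused$full,
              dG_hybrid = NA_real_, n_offtargets = NA_integer_,
              best_offtarget_evalue = NA_real_,
              structure_distance = NA_real_,
              drop_reason = fused$drop_reason, rank = NA_integer_)
  class(out) <- "scored_design"
  if (!is.na(fused$drop_reason)) return(out)
  out$dG_hybrid <- duplex_energy(candidate$seed_rna, candidate$target_sub,
                                 params)$dG
  hits <- scan_offtargets(back_transcribe(candidate$seed_rna), genome,
                          scheme = scheme,
                          evalue_cutoff = config$evalue_cutoff,
                          exclude = list(chrom = candidate$chrom,
                                         start = candidate$gen_start,
                                         end = candidate$gen_end))
  out$n_offtargets <- nrow(hits)
  out$best_offtarget_evalue <- if (nrow(hits)) min(hits$evalue) else NA_real_
  if (is.null(wt_profile))
    wt_profile <- pairing_profile(partition_function(config$wildtype_srna, params))
  full_profile <- pairing_profile(partition_function(fused$full, params))
  out$structure_distance <- profile_distance(full_profile, wt_profile)
  out
}

#' Rank scored designs
#'
#' Hard filters first: designs whose structure distance exceeds the
#' configured cutoff are dropped (reason recorded); in strict mode designs
#' with any off-target at or below the E-value cutoff are dropped too. The
#' survivors are ordered lexicographically: fewer off-targets, then smaller
#' structure distance, then more negative hybridization energy, then
#' binding site closer to the start codon (|match_start_rel|), then 5'-to-3'
#' window offset as the final deterministic tie-break. The list is truncated
#' to `max_results` (overflow designs keep a drop reason) and ranks 1..k are
#' assigned.
#'
#' @param designs List of `scored_design`.
#' @param config A `design_config`.
#' @return List with `ranked` (designs with `rank` set) and `dropped`
#'   (designs with `drop_reason` set). Input order never affects the result.
#' @export
rank_designs <- function(designs, config) {
  if (!length(designs)) stop("no scored designs to rank")
  pre_dropped <- Filter(function(d) !is.na(d$drop_reason), designs)
  live <- Filter(function(d) is.na(d$drop_reason), designs)
  dropped <- pre_dropped
  keep <- list()
  for (d in live) {
    if (d$structure_distance > config$structure_cutoff) {
      d$drop_reason <- sprintf("structure distance %.4f > cutoff %.4f",
                               d$structure_distance, config$structure_cutoff)
      dropped[[length(dropped) + 1L]] <- d
    } else if (config$strict_offtargets && d$n_offtargets > 0) {
      d$drop_reason <- sprintf("off-target at E <= %g", config$evalue_cutoff)
      dropped[[length(dropped) + 1L]] <- d
    } else {
      keep[[length(keep) + 1L]] <- d
    }
  }
  if (length(keep)) {
    key <- vapply(keep, function(d) {
      c(d$n_offtargets, d$structure_distance, d$dG_hybrid,
        abs(d$candidate$match_start_rel), d$candidate$match_start_rel)
    }, numeric(5))
    ord <- do.call(order, as.data.frame(t(key)))
    keep <- keep[ord]
    if (length(keep) > config$max_results) {
      for (i in (config$max_results + 1L):length(keep)) {
        d <- keep[[i]]
        d$drop_reason <- sprintf("rank %d exceeds max_results %d",
                                 i, config$max_results)
        dropped[[length(dropped) + 1L]] <- d
      }
      keep <- keep[seq_len(config$max_results)]
    }
    for (i in seq_along(keep)) keep[[i]]$rank <- i
  }
  list(ranked = keep, dropped = dropped)
}

#' Run the full seed-design pipeline
#'
#' Window extraction, seed enumeration, motif exclusion, off-target screen,
#' hybridization scoring, structure-perturbation scoring, ranking, and
#' report writing for every requested target locus. Outputs per target: a
#' TSV report in which every enumerated offset appears exactly once (ranked
#' or with a drop reason), a FASTA of the ranked full sRNAs (headers carry
#' the MFE dot-bracket as a curation aid), and a parts-library fragment the
#' assembly designer can consume. Identical inputs produce byte-identical
#' outputs.
#'
#' @param config A `design_config` or path to a config file.
#' @param targets Path to the annotated target GenBank file, or a
#'   [gb_record].
#' @param reference Path to the reference genome (FASTA or GenBank), or
#'   [nuc_seq]/list. Defaults to the target record itself.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a named list per locus of [rank_designs()] results.
#' @export
run_seed_design <- function(config, targets, reference = NULL, out_dir = ".") {
  if (is.character(config)) config <- load_design_config(config)
  stopifnot(inherits(config, "design_config"))
  record <- if (is.character(targets)) read_genbank(targets) else targets
  stopifnot(inherits(record, "gb_record"))
  genome <- if (is.null(reference)) list(record$seq)
            else if (is.character(reference)) read_reference(reference)
            else normalize_replicons(reference)
  loci <- config$target_loci
  if (is.null(loci)) {
    loci <- unique(record$features$locus_tag[record$features$kind %in% c("CDS", "gene") &
                                             nzchar(record$features$locus_tag)])
  }
  if (!length(loci)) stop("no target loci: target file has no tagged gene/CDS features")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  params <- nn_params()
  scheme <- scoring_scheme()
  wt_profile <- pairing_profile(partition_function(config$wildtype_srna, params))
  results <- list()
  for (locus in loci) {
    window <- extract_target_window(record, locus, config$window_rel)
    cands <- enumerate_seeds(window, config$seed_len, config$excluded_motifs)
    enum_dropped <- attr(cands, "dropped")
    scored <- lapply(cands, score_design, config = config, genome = genome,
                     wt_profile = wt_profile, scheme = scheme, params = params)
    rk <- if (length(scored)) rank_designs(scored, config)
          else list(ranked = list(), dropped = list())
    rk$enum_dropped <- enum_dropped
    rk$n_enumerated <- attr(cands, "n_enumerated")
    results[[locus]] <- rk
    write_design_report(rk, locus, config, out_dir)
  }
  write_parts_fragment(results, config, out_dir)
  invisible(results)
}

read_reference <- function(path) {
  first <- readLines(path, n = 1, warn = FALSE)
  if (startsWith(first, "LOCUS")) list(read_genbank(path)$seq) else read_fasta(path)
}

num_or_dot <- function(x, fmt = "%.4f") {
  ifelse(is.na(x), ".", sprintf(fmt, x))
}

write_design_report <- function(rk, locus, config, out_dir) {
  rows <- list()
  for (d in rk$ranked) {
    rows[[length(rows) + 1L]] <- data.frame(
      rank = d$rank, locus_tag = locus,
      match_start_rel = d$candidate$match_start_rel,
      seed_rna = d$candidate$seed_rna$residues,
      full_sRNA = d$full_sRNA$residues,
      dG_hybrid = num_or_dot(d$dG_hybrid),
      n_offtargets = d$n_offtargets,
      best_evalue = num_or_dot(d$best_offtarget_evalue, "%.3e"),
      structure_distance = num_or_dot(d$structure_distance),
      drop_reason = ".", stringsAsFactors = FALSE)
  }
  for (d in rk$dropped) {
    rows[[length(rows) + 1L]] <- data.frame(
      rank = NA_integer_, locus_tag = locus,
      match_start_rel = d$candidate$match_start_rel,
      seed_rna = d$candidate$seed_rna$residues,
      full_sRNA = if (is.null(d$full_sRNA)) "." else d$full_sRNA$residues,
      dG_hybrid = num_or_dot(d$dG_hybrid),
      n_offtargets = ifelse(is.na(d$n_offtargets), NA, d$n_offtargets),
      best_evalue = num_or_dot(d$best_offtarget_evalue, "%.3e"),
      structure_distance = num_or_dot(d$structure_distance),
      drop_reason = d$drop_reason, stringsAsFactors = FALSE)
  }
  if (!is.null(rk$enum_dropped) && nrow(rk$enum_dropped)) {
    for (i in seq_len(nrow(rk$enum_dropped))) {
      rows[[length(rows) + 1L]] <- data.frame(
        rank = NA_integer_, locus_tag = locus,
        match_start_rel = rk$enum_dropped$match_start_rel[i],
        seed_rna = ".", full_sRNA = ".", dG_hybrid = ".",
        n_offtargets = NA_integer_, best_evalue = ".",
        structure_distance = ".",
        drop_reason = rk$enum_dropped$reason[i], stringsAsFactors = FALSE)
    }
  }
  df <- if (length(rows)) do.call(rbind, rows) else NULL
  path <- file.path(out_dir, sprintf("%s_designs.tsv", locus))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(
    sprintf("# seed design report for locus %s", locus),
    sprintf("# seed_len=%d window=[%d,%d) scaffold=%s evalue_cutoff=%g structure_cutoff=%g",
            config$seed_len, config$window_rel[1], config$window_rel[2],
            config$scaffold_name, config$evalue_cutoff, config$structure_cutoff),
    "# match position = seed binding-site 5' end relative to the start codon;",
    "# ranking: off-targets, structure distance, dG_hybrid, |match position|, offset",
    "# off-target screen: seed alone vs both strands of the reference (target site excluded)"),
    con)
  if (is.null(df)) {
    writeLines("# no viable design", con)
    writeLines(paste(c("rank", "locus_tag", "match_start_rel", "seed_rna",
                       "full_sRNA", "dG_hybrid", "n_offtargets", "best_evalue",
                       "structure_distance", "drop_reason"), collapse = "\t"), con)
    return(invisible(path))
  }
  ord <- order(is.na(df$rank), df$rank, df$match_start_rel)
  df <- df[ord, , drop = FALSE]
  df$rank <- ifelse(is.na(df$rank), ".", as.character(df$rank))
  df$n_offtargets <- ifelse(is.na(df$n_offtargets), ".", as.character(df$n_offtargets))
  writeLines(paste(colnames(df), collapse = "\t"), con)
  for (i in seq_len(nrow(df)))
    writeLines(paste(unlist(df[i, ]), collapse = "\t"), con)
  if (!length(rk$ranked)) writeLines("# no viable design", con)
  close(con); on.exit()
  # FASTA of ranked full sRNAs, MFE dot-bracket in the description
  if (length(rk$ranked)) {
    seqs <- lapply(rk$ranked, function(d) {
      s <- d$full_sRNA
      s$id <- sprintf("%s_rank%d", locus, d$rank)
      s
    })
    desc <- vapply(rk$ranked, function(d) {
      sprintf("dG_hybrid=%.2f mfe=%s", d$dG_hybrid,
              mfe_structure(d$full_sRNA)$structure)
    }, "")
    write_fasta(seqs, file.path(out_dir, sprintf("%s_srnas.fasta", locus)), desc)
  }
  invisible(path)
}

write_parts_fragment <- function(results, config, out_dir) {
  path <- file.path(out_dir, "parts_fragment.tsv")
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines("name\trole\ttopology\tproduction\tsequence", con)
  writeLines(sprintf("%s\tscaffold\tlinear\tanneal\t%s",
                     config$scaffold_name,
                     back_transcribe(config$scaffold_seq)$residues), con)
  for (locus in names(results)) {
    for (d in results[[locus]]$ranked) {
      writeLines(sprintf("seed_%s_r%d\tseed\tlinear\tanneal\t%s",
                         locus, d$rank,
                         back_transcribe(d$candidate$seed_rna)$residues), con)
    }
  }
  invisible(path)
}
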