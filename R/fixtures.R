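#' Generate a self-contained synthetic test fixture
#'
#' Builds, entirely from a seeded RNG, the full set of inputs the two
#' designers need: (a) an annotated toy genome (GenBank) with `n_genes`
#' non-overlapping CDSs on alternating strands; (b) a scaffold FASTA with a
#' designed stem-loop hairpin and a U-tract terminator-like 3' end; (c) a
#' circular Golden Gate acceptor plasmid (GenBank) with two inward-facing
#' recognition sites around a dropout; (d) a parts library TSV (plasmid,
#' promoter, scaffold); and (e) a default design config. All outputs are
#' reproducible from `rng_seed`.
#'
#' @param out_dir Output directory.
#' @param rng_seed Integer seed; the only source of randomness.
#' @param n_genes Number of annotated genes.
#' @param genome_len Genome length (bp).
#' @param scaffold_len Scaffold length (nt).
#' @param enzyme_name Type IIS enzyme the plasmid is designed for.
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
generate_fixture <- function(out_dir, rng_seed = 1L, n_genes = 3L,
                             genome_len = 3000L, scaffold_len = 40L,
                             enzyme_name = "BsaI") {
  enzyme <- get_enzyme(enzyme_name)
  if (genome_len < n_genes * 400L + 400L)
    stop("genome too short to host the requested genes with flanks")
  if (scaffold_len < 24L) stop("scaffold_len must be >= 24")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(rng_seed)
  motif <- stats::setNames(enzyme$recognition, enzyme$name)

  rand_dna <- function(n, probs = c(0.25, 0.25, 0.25, 0.25)) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
          collapse = "")
  }
  rand_clean <- function(n, probs = c(0.25, 0.25, 0.25, 0.25)) {
    for (i in 1:200) {
      s <- rand_dna(n, probs)
      if (!contains_motif(nuc_seq(s, molecule = "DNA"), motif)) return(s)
    }
    stop("could not generate a site-free sequence; infeasible fixture spec")
  }

  # (a) toy genome
  genome_res <- rand_dna(genome_len)
  gene_len <- 300L
  spacing <- (genome_len - 400L) %/% n_genes
  feats <- empty_features()
  for (g in seq_len(n_genes)) {
    gs <- 200L + (g - 1L) * spacing
    tag <- sprintf("gene_%04d", g)
    strand <- if (g %% 2L == 1L) "+" else "-"
    feats <- rbind(feats,
                   data.frame(kind = c("gene", "CDS"), locus_tag = tag,
                              start = gs, end = gs + gene_len, strand = strand,
                              stringsAsFactors = FALSE))
  }
  genome <- gb_record(nuc_seq(genome_res, id = "toygenome", molecule = "DNA"),
                      feats)
  genome_path <- file.path(out_dir, "genome.gb")
  write_genbank(genome, genome_path)
  ref_path <- file.path(out_dir, "reference.fasta")
  write_fasta(genome$seq, ref_path)

  # (b) scaffold: 4-nt handle + GC-rich stem + GAAA loop + U-tract end
  stem_len <- max(6L, (scaffold_len - 16L) %/% 2L)
  utract <- scaffold_len - 8L - 2L * stem_len
  scaffold_dna <- NULL
  for (i in 1:200) {
    stem <- rand_dna(stem_len, probs = c(0.1, 0.4, 0.4, 0.1))
    cand <- paste0("CGGA", stem, "GAAA", rc_string(stem), strrep("T", utract))
    if (!contains_motif(nuc_seq(cand, molecule = "DNA"), motif)) {
      scaffold_dna <- cand
      break
    }
  }
  if (is.null(scaffold_dna)) stop("could not design a site-free scaffold")
  scaffold <- nuc_seq(scaffold_dna, id = "scafFix", molecule = "DNA")
  scaffold_path <- file.path(out_dir, "scaffold.fasta")
  write_fasta(scaffold, scaffold_path)

  # wild-type sRNA: a natural-style seed grafted on the same scaffold
  wt_seed <- rand_clean(24L)
  wildtype <- paste0(wt_seed, scaffold_dna)

  # (c) acceptor plasmid: dropout carries both sites, cuts face the backbone
  promoter_dna <- "TTGACAGCTAGCTCAGTCCTAGGTATAATGCTAGC"   # sigma70-style
  ovh_first <- substr(promoter_dna, 1L, enzyme$overhang_len)  # plasmid -> insert 1
  sp <- strrep("A", enzyme$spacer_len)
  plasmid_res <- NULL
  for (i in 1:200) {
    backbone <- paste0("CTAA", rand_dna(796L))
    dropout <- paste0(ovh_first, sp, rc_string(enzyme$recognition),
                      rand_dna(16L), enzyme$recognition, sp)
    cand <- nuc_seq(paste0(dropout, backbone), id = "pGGfix",
                    molecule = "DNA", topology = "circular")
    if (nrow(scan_motifs(cand, motif, both_strands = TRUE)) == 2L) {
      plasmid_res <- cand
      break
    }
  }
  if (is.null(plasmid_res)) stop("could not design a two-site acceptor plasmid")
  dropout_len <- nchar(ovh_first) + 2L * nchar(sp) +
    2L * nchar(enzyme$recognition) + 16L
  plasmid_rec <- gb_record(plasmid_res, data.frame(
    kind = "misc_feature", locus_tag = "dropout", start = 0L,
    end = dropout_len, strand = "+", stringsAsFactors = FALSE))
  plasmid_path <- file.path(out_dir, "plasmid.gb")
  write_genbank(plasmid_rec, plasmid_path)

  # (d) parts library
  parts <- list(
    gg_part("pGGfix", role = "plasmid", seq = plasmid_res, production = "none"),
    gg_part("Pfix", role = "promoter",
            seq = nuc_seq(promoter_dna, id = "Pfix", molecule = "DNA"),
            production = "anneal"),
    gg_part("scafFix", role = "scaffold",
            seq = nuc_seq(scaffold_dna, id = "scafFix", molecule = "DNA"),
            production = "anneal"))
  names(parts) <- vapply(parts, function(p) p$name, "")
  library_path <- file.path(out_dir, "parts_library.tsv")
  write_parts_library(parts, library_path)

  # (e) default config
  config_path <- file.path(out_dir, "config.ini")
  con <- file(config_path, open = "wb")
  writeLines(c("# synthetic sRNA design configuration (generated fixture)",
               "seed_len = 24",
               "window_start = -30",
               "window_end = 21",
               "scaffold_name = scafFix",
               sprintf("scaffold_seq = %s", scaffold_dna),
               sprintf("wildtype_srna = %s", wildtype),
               "evalue_cutoff = 1.0",
               sprintf("excluded_enzymes = %s", enzyme$name),
               "max_results = 5",
               "target_loci = gene_0001"), con)
  close(con)

  invisible(list(genome = genome, scaffold = scaffold, plasmid = plasmid_res,
                 parts = parts, wildtype = wildtype,
                 paths = c(genome = genome_path, reference = ref_path,
                           scaffold = scaffold_path, plasmid = plasmid_path,
                           library = library_path, config = config_path)))
}
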