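#' Read a flat key-value (INI dialect) config file
#'
#' Lines of the form `key = value`; `#` and `;` start comments; section
#' headers `[...]` are tolerated and ignored. Returned values are strings.
#'
#' @param path File path.
#' @return Named list of strings.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  out <- list()
  for (i in seq_along(lines)) {
    line <- sub("[#;].*$", "", lines[i])
    line <- trimws(line)
    if (!nzchar(line) || grepl("^\\[.*\\]$", line)) next
    if (!grepl("=", line, fixed = TRUE))
      stop(sprintf("%s line %d: expected 'key = value', got '%s'", path, i, line))
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    key <- trimws(kv[1])
    out[[key]] <- trimws(paste(kv[-1], collapse = "="))
  }
  out
}

#' Assemble and validate a seed-design configuration
#'
#' Defaults follow common practice for translation-initiation-region
#' occlusion by sRNAs: 24-nt seeds over a window from 30 nt upstream to 21
#' nt downstream of the start codon. The window is interpreted relative to
#' the annotated translation start.
#'
#' @param scaffold_seq Scaffold sequence (DNA or RNA string / [nuc_seq]):
#'   the structural part of the sRNA (terminator etc.) the seed is fused to.
#' @param wildtype_srna The natural sRNA the scaffold derives from (used as
#'   the structure comparator). Defaults to the scaffold itself.
#' @param seed_len Seed length (>= 8).
#' @param window_rel Integer pair, window relative to the start codon.
#' @param evalue_cutoff Off-target E-value report threshold.
#' @param excluded_enzymes Comma-separated type IIS enzyme names whose
#'   recognition sites must not occur in any designed sRNA.
#' @param structure_cutoff Hard filter: designs with a pairing-profile
#'   distance to the wild type above this are dropped. Default `NULL` means
#'   `seed_len`: the seed region differs from the wild-type seed by design
#'   and may contribute up to 2 cost units per position, so a budget of
#'   half that over the seed length tolerates seed-local refolding while
#'   still flagging designs whose structural change extends into the
#'   scaffold.
#' @param max_results Maximum number of ranked designs reported per target.
#' @param scaffold_name Label used in reports and part libraries.
#' @param strict_offtargets Drop (rather than merely rank down) designs with
#'   any off-target hit at or below `evalue_cutoff`.
#' @param fuse_seed_3prime Fuse the seed 3' of the scaffold instead of the
#'   default 5' layout.
#' @param target_loci Optional character vector of locus tags to design
#'   against (default: every annotated tag in the target file).
#' @return List of class `design_config`.
#' @export
design_config <- function(scaffold_seq,
                          wildtype_srna = NULL,
                          seed_len = 24L,
                          window_rel = c(-30L, 21L),
                          evalue_cutoff = 1,
                          excluded_enzymes = "BsaI",
                          structure_cutoff = NULL,
                          max_results = 10L,
                          scaffold_name = "scaffold",
                          strict_offtargets = FALSE,
                          fuse_seed_3prime = FALSE,
                          target_loci = NULL) {
  scaffold <- as_nuc_seq(scaffold_seq)
  if (scaffold$molecule == "DNA") scaffold <- transcribe(scaffold)
  scaffold$id <- scaffold_name
  motifs <- resolve_enzyme_motifs(excluded_enzymes)
  if (length(motifs) && contains_motif(back_transcribe(scaffold), motifs))
    stop("scaffold contains an excluded recognition motif")
  wt <- if (is.null(wildtype_srna)) scaffold else {
    w <- as_nuc_seq(wildtype_srna)
    if (w$molecule == "DNA") w <- transcribe(w)
    w
  }
  seed_len <- as.integer(seed_len)
  if (seed_len < 8L) stop("seed_len must be >= 8")
  if (is.null(structure_cutoff)) structure_cutoff <- as.numeric(seed_len)
  if (evalue_cutoff <= 0 || structure_cutoff <= 0)
    stop("cutoff values must be positive")
  structure(list(seed_len = seed_len,
                 window_rel = as.integer(window_rel),
                 scaffold_name = scaffold_name,
                 scaffold_seq = scaffold,
                 wildtype_srna = wt,
                 evalue_cutoff = as.numeric(evalue_cutoff),
                 excluded_motifs = motifs,
                 structure_cutoff = as.numeric(structure_cutoff),
                 max_results = as.integer(max_results),
                 strict_offtargets = isTRUE(strict_offtargets),
                 fuse_seed_3prime = isTRUE(fuse_seed_3prime),
                 target_loci = target_loci),
            class = "design_config")
}

#' Build a [design_config()] from a key-value config file
#'
#' Recognized keys: `seed_len`, `window_start`, `window_end`,
#' `scaffold_name`, `scaffold_seq` or `scaffold_fasta`, `wildtype_srna`,
#' `evalue_cutoff`, `excluded_enzymes`, `structure_cutoff`, `max_results`,
#' `strict_offtargets`, `target_loci` (comma-separated).
#'
#' @param path Config file path.
#' @return A `design_config`.
#' @export
load_design_config <- function(path) {
  kv <- read_config(path)
  get <- function(key, default = NULL) if (!is.null(kv[[key]])) kv[[key]] else default
  scaffold <- if (!is.null(kv$scaffold_fasta)) {
    read_fasta(kv$scaffold_fasta)[[1]]
  } else if (!is.null(kv$scaffold_seq)) {
    kv$scaffold_seq
  } else stop(sprintf("%s: config must provide scaffold_seq or scaffold_fasta", path))
  loci <- get("target_loci")
  if (!is.null(loci)) loci <- trimws(strsplit(loci, ",")[[1]])
  design_config(
    scaffold_seq = scaffold,
    wildtype_srna = get("wildtype_srna"),
    seed_len = as.integer(get("seed_len", 24L)),
    window_rel = c(as.integer(get("window_start", -30L)),
                   as.integer(get("window_end", 21L))),
    evalue_cutoff = as.numeric(get("evalue_cutoff", 1)),
    excluded_enzymes = get("excluded_enzymes", "BsaI"),
    structure_cutoff = {sc <- get("structure_cutoff"); if (is.null(sc)) NULL else as.numeric(sc)},
    max_results = as.integer(get("max_results", 10L)),
    scaffold_name = get("scaffold_name", "scaffold"),
    strict_offtargets = tolower(get("strict_offtargets", "false")) %in% c("true", "1", "yes"),
    target_loci = loci)
}
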