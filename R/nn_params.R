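#' Nearest-neighbor RNA energy parameters
#'
#' Loads the versioned RNA stack table shipped with the package
#' (`extdata/rna_stack_dG37.tsv`): the 16 Watson-Crick dinucleotide stack
#' free energies at 37 degrees C, the duplex initiation term, the terminal
#' A-U (and wobble) end penalty, a generic stack value for stacks involving
#' a G-U wobble pair, and the flat loop-opening penalty used by the
#' partition function's simplified energy model.
#'
#' @param temperature Temperature in Kelvin (default 310.15, i.e. 37 C).
#'   `RT` is derived as `0.0019872 * temperature` kcal/mol (0.6163 at 37 C).
#' @return List of class `nn_params` with fields `stacks` (named numeric),
#'   `duplex_init_dG37`, `terminal_AU_penalty`, `gu_stack_dG37`,
#'   `loop_penalty_dG37`, `temperature`, `RT`.
#' @export
nn_params <- function(temperature = 310.15) {
  key <- sprintf("rna_%.6f", temperature)
  cached <- get0(key, envir = .param_cache)
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "rna_stack_dG37.tsv", package = "srnaforge")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  vals <- stats::setNames(tab$value, tab$param)
  keys <- as.vector(outer(c("A", "C", "G", "U"), c("A", "C", "G", "U"), paste0))
  stacks <- vals[keys]
  if (anyNA(stacks)) stop("RNA stack table is incomplete")
  if (any(stacks >= 0)) stop("RNA stack energies must be negative")
  out <- structure(list(stacks = stacks,
                 duplex_init_dG37 = unname(vals[["init"]]),
                 terminal_AU_penalty = unname(vals[["terminal_AU"]]),
                 gu_stack_dG37 = unname(vals[["gu_stack"]]),
                 loop_penalty_dG37 = unname(vals[["loop_penalty"]]),
                 temperature = temperature,
                 RT = 0.0019872 * temperature),
            class = "nn_params")
  assign(key, out, envir = .param_cache)
  out
}

#' Nearest-neighbor DNA dH/dS table (for primer melting temperatures)
#' @return List with `dH`/`dS` named vectors (kcal/mol, cal/mol/K) for the
#'   16 stacks plus `init_GC`/`init_AT` terminal initiation terms.
#' @export
dna_nn_table <- function() {
  cached <- get0("dna", envir = .param_cache)
  if (!is.null(cached)) return(cached)
  path <- system.file("extdata", "dna_nn_dHdS.tsv", package = "srnaforge")
  tab <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  out <- list(dH = stats::setNames(tab$dH, tab$param),
              dS = stats::setNames(tab$dS, tab$param))
  assign("dna", out, envir = .param_cache)
  out
}

.param_cache <- new.env(parent = emptyenv())
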