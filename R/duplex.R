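#' Hybridization free energy of a fully complementary RNA duplex
#'
#' Nearest-neighbor energy of the contiguous seed:target hybrid:
#' `dG = duplex_init + sum(stacks) + terminal end penalties`, where the end
#' penalty applies to each terminal A-U or G-U closing pair. The seed must
#' be the exact reverse complement of the target subsequence (the design
#' guarantees this by construction); with `allow_gu = TRUE`, G-U wobble
#' opposition is also accepted and wobble-containing stacks take the
#' generic `gu_stack_dG37` value.
#'
#' @param seed_rna RNA [nuc_seq], antisense seed.
#' @param target_rna RNA [nuc_seq], the bound mRNA subsequence (equal length).
#' @param params [nn_params()].
#' @param allow_gu Accept G-U wobble pairs (default strict Watson-Crick).
#' @return List of class `duplex_result`: `dG` (kcal/mol), `n_stacks`,
#'   `penalties_applied` (character labels).
#' @export
duplex_energy <- function(seed_rna, target_rna, params = nn_params(),
                          allow_gu = FALSE) {
  seed_rna <- as_nuc_seq(seed_rna); target_rna <- as_nuc_seq(target_rna)
  if (seed_rna$molecule != "RNA" || target_rna$molecule != "RNA")
    stop("duplex_energy() expects RNA inputs")
  s <- strsplit(seed_rna$residues, "")[[1]]
  t <- strsplit(target_rna$residues, "")[[1]]
  L <- length(s)
  if (L != length(t)) stop("seed and target must have equal lengths")
  wc <- c(A = "U", U = "A", C = "G", G = "C")
  partner <- rev(t)                     # seed position k pairs target L+1-k
  is_wc <- wc[s] == partner
  is_gu <- (s == "G" & partner == "U") | (s == "U" & partner == "G")
  ok <- if (allow_gu) is_wc | is_gu else is_wc
  if (!all(ok)) {
    k <- which(!ok)[1]
    stop(sprintf("seed is not complementary to target: mismatch %s:%s at seed position %d",
                 s[k], partner[k], k))
  }
  penalties <- "duplex_init"
  dG <- params$duplex_init_dG37
  n_stacks <- max(0L, L - 1L)
  if (L >= 2L) {
    for (k in 1:(L - 1L)) {
      if (is_gu[k] || is_gu[k + 1L]) {
        dG <- dG + params$gu_stack_dG37
      } else {
        dG <- dG + params$stacks[[paste0(s[k], s[k + 1L])]]
      }
    }
  }
  for (endk in unique(c(1L, L))) {
    pr <- sort(c(s[endk], partner[endk]))
    if (identical(pr, c("A", "U")) || identical(pr, c("G", "U"))) {
      dG <- dG + params$terminal_AU_penalty
      penalties <- c(penalties, sprintf("terminal_AU_end%d", if (endk == 1L) 5L else 3L))
    }
  }
  structure(list(dG = dG, n_stacks = n_stacks, penalties_applied = penalties),
            class = "duplex_result")
}
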