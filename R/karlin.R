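#' Solve the Karlin-Altschul characteristic equation for lambda
#'
#' For an ungapped match/mismatch scoring scheme and background base
#' frequencies `p`, lambda is the unique positive root of
#' `sum_ij p_i p_j exp(lambda * s(i,j)) = 1`, where `s(i,j)` is `match` when
#' `i == j` and `mismatch` otherwise. The root is found by bisection on a
#' bracketing interval and refined until the residual is below `tol`.
#'
#' @param match Positive integer match reward.
#' @param mismatch Negative integer mismatch penalty.
#' @param background Base frequency 4-vector summing to 1 (default uniform).
#' @param tol Residual tolerance (default 1e-12; the contract is < 1e-9).
#' @return Positive numeric lambda (nats per score unit).
#' @export
solve_lambda <- function(match = 1, mismatch = -2,
                         background = rep(0.25, 4), tol = 1e-12) {
  if (abs(sum(background) - 1) > 1e-9 || any(background < 0))
    stop("background frequencies must be non-negative and sum to 1")
  if (match <= 0) stop("match reward must be positive")
  p_match <- sum(background^2)
  e_score <- p_match * match + (1 - p_match) * mismatch
  if (e_score >= 0)
    stop(sprintf("expected per-position score %.4f is non-negative; no valid Karlin-Altschul statistics", e_score))
  f <- function(lam) p_match * exp(lam * match) + (1 - p_match) * exp(lam * mismatch) - 1
  lo <- 0
  hi <- 1
  while (f(hi) < 0) hi <- hi * 2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    fm <- f(mid)
    if (abs(fm) < tol) return(mid)
    if (fm < 0) lo <- mid else hi <- mid
  }
  mid
}

#' Ungapped scoring scheme with Karlin-Altschul statistics
#'
#' @inheritParams solve_lambda
#' @param K Karlin-Altschul K. The default 0.71 is used with the default
#'   `(+1, -2)` scheme; exact calibration of K to NCBI BLASTn is a non-goal
#'   (rankings and thresholds depend on relative E-values).
#' @return List of class `scoring_scheme` with fields `match`, `mismatch`,
#'   `lambda`, `K`, `background`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -2, K = 0.71,
                           background = rep(0.25, 4)) {
  lambda <- solve_lambda(match, mismatch, background)
  structure(list(match = match, mismatch = mismatch, lambda = lambda,
                 K = K, background = background),
            class = "scoring_scheme")
}

#' E-value of an ungapped hit
#'
#' `E = K * m * n * exp(-lambda * score)` with `m` the query length and `n`
#' the total searched length (both strands of all replicons).
#'
#' @param score Segment score(s).
#' @param m Query length.
#' @param n Total searched length.
#' @param scheme A [scoring_scheme()].
#' @return Numeric E-value(s).
#' @export
karlin_evalue <- function(score, m, n, scheme) {
  scheme$K * m * n * exp(-scheme$lambda * score)
}
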