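#' McCaskill-style partition function and base-pair probabilities
#'
#' Computes exact base-pair probabilities under the package's simplified
#' nearest-neighbor energy model by inside-outside dynamic programming over
#' all nested secondary structures with Watson-Crick and G-U pairs and a
#' minimum hairpin loop of 3 unpaired bases.
#'
#' Energy model: each base pair (i,j) contributes the dinucleotide stack
#' free energy when the enclosed pair (i+1,j-1) is also formed, and the flat
#' loop-opening penalty `loop_penalty_dG37` otherwise (hairpin, bulge,
#' interior and multibranch closings are all flat). Stacks involving a G-U
#' wobble take the generic `gu_stack_dG37` value. Boltzmann weights use
#' `RT = 0.0019872 * temperature`, so raising the temperature flattens the
#' ensemble. The identical model is used by the exhaustive-enumeration
#' oracle in the package's tests, which the recursions match to 1e-9.
#'
#' @param seq RNA [nuc_seq] (DNA inputs are transcribed), length <= 500.
#' @param params [nn_params()].
#' @param blocked Optional integer vector of 1-based positions forbidden
#'   from pairing (used for accessibility calculations).
#' @return Object of class `pair_probs`: fields `seq`, `p` (symmetric n x n
#'   matrix of pair probabilities), `Z` (partition function), `params`.
#' @export
partition_function <- function(seq, params = nn_params(), blocked = integer()) {
  seq <- as_nuc_seq(seq)
  if (seq$molecule == "DNA") seq <- transcribe(seq)
  r <- strsplit(seq$residues, "")[[1]]
  n <- length(r)
  if (n > 500) stop("partition_function() is limited to sequences <= 500 nt (O(n^3))")
  ins <- pf_inside(r, params, blocked)
  p <- matrix(0, n, n)
  if (ins$any_pairs) {
    out <- pf_outside(ins)
    p <- ins$Zb * out$bZb / ins$Ztot
    p <- p + t(p)           # store symmetric
  }
  if (!is.finite(ins$Ztot))
    stop("partition function overflow; sequence too long/stable for direct summation")
  structure(list(seq = seq, p = p, Z = ins$Ztot, params = params,
                 blocked = blocked),
            class = "pair_probs")
}

# pairing weight machinery shared by inside/outside/MFE
pf_model <- function(r, params, blocked = integer()) {
  n <- length(r)
  wc <- c(A = "U", U = "A", C = "G", G = "C")
  pairmat <- matrix(FALSE, n, n)
  gu <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j - i >= 4) {
        iswc <- wc[[r[i]]] == r[j]
        isgu <- (r[i] == "G" && r[j] == "U") || (r[i] == "U" && r[j] == "G")
        if ((iswc || isgu) && !(i %in% blocked) && !(j %in% blocked)) {
          pairmat[i, j] <- TRUE
          gu[i, j] <- isgu
        }
      }
    }
  }
  # stack energy for closing pair (i,j) over inner pair (i+1,j-1)
  stackE <- function(i, j) {
    if (gu[i, j] || gu[i + 1L, j - 1L]) params$gu_stack_dG37
    else params$stacks[[paste0(r[i], r[i + 1L])]]
  }
  list(r = r, n = n, pairmat = pairmat, gu = gu, stackE = stackE,
       RT = params$RT, gloop = params$loop_penalty_dG37)
}

pf_inside <- function(r, params, blocked = integer()) {
  md <- pf_model(r, params, blocked)
  n <- md$n
  Z <- matrix(1, max(n, 1L), max(n, 1L))   # Z[i,j] for i<=j; 1 elsewhere unused
  Zb <- matrix(0, max(n, 1L), max(n, 1L))
  wloop <- exp(-md$gloop / md$RT)
  any_pairs <- any(md$pairmat)
  if (n >= 5 && any_pairs) {
    for (d in 4:(n - 1L)) {
      for (i in 1:(n - d)) {
        j <- i + d
        if (md$pairmat[i, j]) {
          Zin <- Z[i + 1L, j - 1L]
          Zbin <- Zb[i + 1L, j - 1L]
          wst <- if (md$pairmat[i + 1L, j - 1L]) exp(-md$stackE(i, j) / md$RT) else 0
          Zb[i, j] <- wst * Zbin + wloop * (Zin - Zbin)
        }
        ks <- (i + 4L):j
        zr <- numeric(length(ks))
        inner <- ks < j
        zr[!inner] <- 1
        if (any(inner)) zr[inner] <- Z[cbind(ks[inner] + 1L, j)]
        Z[i, j] <- Z[i + 1L, j] + sum(Zb[i, ks] * zr)
      }
    }
  }
  list(model = md, Z = Z, Zb = Zb, Ztot = if (n >= 1) Z[1, n] else 1,
       any_pairs = any_pairs, wloop = wloop)
}

pf_outside <- function(ins) {
  md <- ins$model
  n <- md$n
  Z <- ins$Z; Zb <- ins$Zb; wloop <- ins$wloop
  bZ <- matrix(0, n, n); bZb <- matrix(0, n, n); bZn <- matrix(0, n, n)
  bZ[1, n] <- 1
  for (d in (n - 1L):0) {
    # outflows of bZ and bZn first (they feed same-span bZb cells)
    for (i in 1:(n - d)) {
      j <- i + d
      v <- bZ[i, j]
      if (v != 0 && i < j) {
        bZ[i + 1L, j] <- bZ[i + 1L, j] + v
        if (d >= 4) {
          ks <- (i + 4L):j
          zr <- numeric(length(ks)); innr <- ks < j
          zr[!innr] <- 1
          if (any(innr)) zr[innr] <- Z[cbind(ks[innr] + 1L, j)]
          bZb[i, ks] <- bZb[i, ks] + v * zr
          if (any(innr)) {
            kk <- ks[innr]
            bZ[cbind(kk + 1L, j)] <- bZ[cbind(kk + 1L, j)] + v * Zb[i, kk]
          }
        }
      }
      w <- bZn[i, j]
      if (w != 0 && i < j) {
        bZ[i + 1L, j] <- bZ[i + 1L, j] + w
        if (d >= 5) {
          ks <- (i + 4L):(j - 1L)
          bZb[i, ks] <- bZb[i, ks] + w * Z[cbind(ks + 1L, j)]
          bZ[cbind(ks + 1L, j)] <- bZ[cbind(ks + 1L, j)] + w * Zb[i, ks]
        }
      }
    }
    if (d >= 4) {
      for (i in 1:(n - d)) {
        j <- i + d
        u <- bZb[i, j]
        if (u != 0 && md$pairmat[i, j]) {
          if (md$pairmat[i + 1L, j - 1L]) {
            bZb[i + 1L, j - 1L] <- bZb[i + 1L, j - 1L] +
              exp(-md$stackE(i, j) / md$RT) * u
          }
          bZn[i + 1L, j - 1L] <- bZn[i + 1L, j - 1L] + wloop * u
        }
      }
    }
  }
  list(bZ = bZ, bZb = bZb, bZn = bZn)
}

#' Per-position pairing profile
#'
#' Collapses a base-pair probability matrix into, for each position, the
#' probability of pairing with an upstream partner, a downstream partner, or
#' remaining unpaired (the triple sums to 1).
#'
#' @param pp A `pair_probs` object from [partition_function()].
#' @return Matrix of class `pairing_profile` with columns `p_upstream`,
#'   `p_downstream`, `p_unpaired`.
#' @export
pairing_profile <- function(pp) {
  stopifnot(inherits(pp, "pair_probs"))
  p <- pp$p
  n <- nrow(p)
  up <- vapply(seq_len(n), function(i) if (i > 1) sum(p[1:(i - 1), i]) else 0, 0)
  down <- vapply(seq_len(n), function(i) if (i < n) sum(p[i, (i + 1):n]) else 0, 0)
  unp <- pmax(0, 1 - up - down)
  out <- cbind(p_upstream = up, p_downstream = down, p_unpaired = unp)
  class(out) <- c("pairing_profile", class(out))
  out
}

#' Alignment distance between two pairing profiles
#'
#' Global (Needleman-Wunsch) alignment of the two per-position profile
#' vectors with column cost equal to the L1 distance of the triples (range
#' 0..2) and a per-gap cost of `gap_cost`. The default gap cost 2 equals the
#' maximum column cost, so indels are never cheaper than a total mismatch.
#' The distance is non-negative, symmetric, and zero exactly for identical
#' profiles.
#'
#' @param a,b `pairing_profile` matrices.
#' @param gap_cost Cost per gapped column (default 2).
#' @return Numeric distance (total minimal alignment cost).
#' @export
profile_distance <- function(a, b, gap_cost = 2) {
  a <- unclass(a); b <- unclass(b)
  n <- nrow(a); m <- nrow(b)
  if (!n || !m) stop("profiles must be non-empty")
  cost <- abs(outer(a[, 1], b[, 1], "-")) +
          abs(outer(a[, 2], b[, 2], "-")) +
          abs(outer(a[, 3], b[, 3], "-"))
  prev <- (0:m) * gap_cost
  for (i in seq_len(n)) {
    cur <- numeric(m + 1L)
    cur[1] <- i * gap_cost
    for (j in seq_len(m)) {
      cur[j + 1L] <- min(prev[j] + cost[i, j],
                         prev[j + 1L] + gap_cost,
                         cur[j] + gap_cost)
    }
    prev <- cur
  }
  prev[m + 1L]
}

#' Accessibility penalty of a region (ED term)
#'
#' `ED = -RT * ln P(region fully unpaired)`, with the probability taken from
#' the ratio of the constrained partition function (all positions in the
#' region forbidden from pairing) to the unconstrained one. Always >= 0.
#' Off by default in the design pipeline.
#'
#' @param pp A `pair_probs` object (carries sequence and parameters).
#' @param region Integer pair, 0-based half-open `(start, end)` within the
#'   sequence.
#' @return Non-negative numeric, kcal/mol.
#' @export
accessibility_penalty <- function(pp, region) {
  stopifnot(inherits(pp, "pair_probs"))
  n <- nchar(pp$seq$residues)
  region <- as.integer(region)
  if (region[1] < 0 || region[2] > n || region[1] >= region[2])
    stop("region out of bounds")
  blocked <- (region[1] + 1L):region[2]
  r <- strsplit(pp$seq$residues, "")[[1]]
  Zc <- pf_inside(r, pp$params, blocked)$Ztot
  max(0, -pp$params$RT * (log(Zc) - log(pp$Z)))
}


#' Minimum free energy structure (dot-bracket)
#'
#' Argmax structure under the same simplified energy model as
#' [partition_function()]; emitted as a manual-curation convenience only.
#'
#' @param seq RNA [nuc_seq] (DNA inputs are transcribed).
#' @param params [nn_params()].
#' @return List with `structure` (dot-bracket string) and `dG` (kcal/mol).
#' @export
mfe_structure <- function(seq, params = nn_params()) {
  seq <- as_nuc_seq(seq)
  if (seq$molecule == "DNA") seq <- transcribe(seq)
  r <- strsplit(seq$residues, "")[[1]]
  n <- length(r)
  md <- pf_model(r, params)
  if (n < 5 || !any(md$pairmat))
    return(list(structure = strrep(".", n), dG = 0))
  E <- matrix(0, n, n)      # min energy over all structures of [i,j]
  Eb <- matrix(Inf, n, n)   # ... with (i,j) paired
  En <- matrix(0, n, n)     # ... with (i,j) NOT paired together
  cE <- matrix(0L, n, n)    # pointer: 0 = skip i, k = pair (i,k)
  cEn <- matrix(0L, n, n)
  cEb <- matrix(0L, n, n)   # 1 = stack, 2 = loop
  for (d in 4:(n - 1L)) {
    for (i in 1:(n - d)) {
      j <- i + d
      if (md$pairmat[i, j]) {
        best <- md$gloop + En[i + 1L, j - 1L]
        ch <- 2L
        if (md$pairmat[i + 1L, j - 1L] && is.finite(Eb[i + 1L, j - 1L])) {
          st <- md$stackE(i, j) + Eb[i + 1L, j - 1L]
          if (st < best) { best <- st; ch <- 1L }
        }
        Eb[i, j] <- best
        cEb[i, j] <- ch
      }
      bE <- E[i + 1L, j]; pE <- 0L
      bN <- E[i + 1L, j]; pN <- 0L
      for (k in (i + 4L):j) {
        if (is.finite(Eb[i, k])) {
          rest <- if (k < j) E[k + 1L, j] else 0
          v <- Eb[i, k] + rest
          if (v < bE - 1e-12) { bE <- v; pE <- k }
          if (k < j && v < bN - 1e-12) { bN <- v; pN <- k }
        }
      }
      E[i, j] <- bE; cE[i, j] <- pE
      En[i, j] <- bN; cEn[i, j] <- pN
    }
  }
  db <- rep(".", n)
  trace <- function(i, j, kind) {
    while (i <= j) {
      if (j - i < 4) return(invisible())
      if (kind == "Eb") {
        db[i] <<- "("; db[j] <<- ")"
        if (cEb[i, j] == 1L) {
          i <- i + 1L; j <- j - 1L
          next
        } else {
          i <- i + 1L; j <- j - 1L; kind <- "En"
          next
        }
      }
      ptr <- if (kind == "En") cEn[i, j] else cE[i, j]
      if (ptr == 0L) {
        i <- i + 1L; kind <- "E"
      } else {
        trace(i, ptr, "Eb")
        i <- ptr + 1L; kind <- "E"
      }
    }
  }
  trace(1L, n, "E")
  list(structure = paste(db, collapse = ""), dG = E[1, n])
}
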