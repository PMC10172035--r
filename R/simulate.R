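#' Simulate a one-pot Golden Gate digestion-ligation
#'
#' Digests the plasmid (and any supplied linear material still carrying
#' recognition sites, e.g. PCR amplicons) with the enzyme, pools the
#' resulting sticky-ended fragments with any pre-formed fragments (annealed
#' oligo duplexes, planned part fragments), and exhaustively closes
#' circles over complementary overhangs. Each fragment may be used at most
#' once per product and in either orientation. Returned are all distinct
#' circular products that contain no residual recognition site; products
#' are deduplicated up to rotation and strand flip. An empty list is a
#' valid, reportable outcome.
#'
#' @param material List of fragments (lists with `tops`, `lovh`, `rovh`)
#'   and/or [nuc_seq] linear DNAs to digest first.
#' @param plasmid Circular DNA [nuc_seq] (or `NULL` if the backbone is
#'   already among `material`).
#' @param enzyme Enzyme from [get_enzyme()].
#' @return List of circular DNA [nuc_seq] products.
#' @export
simulate_golden_gate <- function(material, plasmid, enzyme) {
  pool <- list()
  add_material <- function(x) {
    if (is_nuc_seq(x)) {
      for (fr in digest(x, enzyme)) pool[[length(pool) + 1L]] <<- fr
    } else if (is.list(x) && !is.null(x$tops)) {
      pool[[length(pool) + 1L]] <<- x
    } else stop("material must be fragments or nuc_seq molecules")
  }
  for (x in material) add_material(x)
  if (!is.null(plasmid)) add_material(as_nuc_seq(plasmid))
  if (!length(pool)) return(list())
  ovh <- enzyme$overhang_len
  # orientation variants; index f refers to the physical fragment
  variants <- lapply(pool, function(fr) list(fwd = fr, rev = flip_fragment(fr)))
  products <- character()
  n <- length(pool)
  # DFS over sequences of distinct fragments chained by matching overhangs
  search <- function(chain_tops, chain_lovh, chain_rovh, used, start_idx) {
    if (length(chain_tops) && chain_rovh == chain_lovh &&
        nchar(chain_lovh) == ovh) {
      products[[length(products) + 1L]] <<- paste(chain_tops, collapse = "")
    }
    for (f in seq_len(n)) {
      if (used[f]) next
      for (orient in c("fwd", "rev")) {
        fr <- variants[[f]][[orient]]
        if (nchar(fr$lovh) != ovh || nchar(fr$rovh) != ovh) next
        if (!length(chain_tops)) {
          if (f < start_idx) next  # canonical start: lowest fragment index first
          used[f] <- TRUE
          search(list(fr$tops), fr$lovh, fr$rovh, used, f)
          used[f] <- FALSE
        } else if (fr$lovh == chain_rovh) {
          used[f] <- TRUE
          search(c(chain_tops, list(fr$tops)), chain_lovh, fr$rovh, used, start_idx)
          used[f] <- FALSE
        }
      }
    }
  }
  search(list(), "", "", rep(FALSE, n), 1L)
  if (!length(products)) return(list())
  canon <- vapply(products, canonical_rotation, "")
  keep <- !duplicated(canon)
  out <- list()
  motif <- stats::setNames(enzyme$recognition, enzyme$name)
  idx <- 0L
  for (i in which(keep)) {
    prod <- nuc_seq(products[[i]], id = sprintf("product_%d", idx + 1L),
                    molecule = "DNA", topology = "circular")
    if (!contains_motif(prod, motif)) {
      idx <- idx + 1L
      prod$id <- sprintf("product_%d", idx)
      out[[idx]] <- prod
    }
  }
  out
}

# canonical form of a circular dsDNA: lexicographic minimum over all
# rotations of both strands
canonical_rotation <- function(s) {
  n <- nchar(s)
  best <- NULL
  for (variant in c(s, rc_string(s))) {
    dbl <- paste0(variant, variant)
    for (k in 0:(n - 1L)) {
      rot <- substr(dbl, k + 1L, k + n)
      if (is.null(best) || rot < best) best <- rot
    }
  }
  best
}

#' Are two circular sequences the same molecule (up to rotation/flip)?
#' @param a,b Circular DNA ([nuc_seq] or strings).
#' @return Logical.
#' @export
same_circular_seq <- function(a, b) {
  a <- if (is_nuc_seq(a)) a$residues else a
  b <- if (is_nuc_seq(b)) b$residues else b
  nchar(a) == nchar(b) && canonical_rotation(a) == canonical_rotation(b)
}
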