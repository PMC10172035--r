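# Independent oracles and random-input builders shared across the suite.
# Every oracle here deliberately uses a different algorithm than the
# implementation it checks (enumeration instead of dynamic programming,
# per-diagonal maximum-segment scan instead of seed-and-extend, naive
# substring scan instead of Biostrings matching).

h_rand_dna <- function(n, probs = rep(0.25, 4)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = probs),
        collapse = "")
}

h_rand_rna <- function(n) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE), collapse = "")
}

h_rand_clean_dna <- function(n, motifs) {
  for (i in 1:500) {
    s <- h_rand_dna(n)
    if (!nrow(scan_motifs(nuc_seq(s, molecule = "DNA"), motifs))) return(s)
  }
  stop("helper could not build a motif-free sequence")
}

# --- exhaustive secondary-structure enumeration (partition oracle) --------

# all nested pair sets with min hairpin loop 3 and WC+GU pairs
h_enum_structures <- function(r) {
  n <- length(r)
  wc <- c(A = "U", U = "A", C = "G", G = "C")
  can_pair <- function(i, j) (j - i >= 4) &&
    (wc[[r[i]]] == r[j] || (r[i] == "G" && r[j] == "U") ||
       (r[i] == "U" && r[j] == "G"))
  memo <- new.env(parent = emptyenv())
  structs <- function(i, j) {
    if (i >= j) return(list(list()))
    key <- paste(i, j)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    out <- structs(i + 1, j)
    if (j - i >= 4) {
      for (k in (i + 4):j) {
        if (can_pair(i, k)) {
          left <- structs(i + 1, k - 1)
          right <- structs(k + 1, j)
          for (a in left) for (b in right) {
            out[[length(out) + 1L]] <- c(list(c(i, k)), a, b)
          }
        }
      }
    }
    memo[[key]] <- out
    out
  }
  structs(1, n)
}

# energy under the identical per-closing-pair model: stack term when the
# enclosed pair is formed, flat loop penalty otherwise
h_struct_energy <- function(S, r, params) {
  if (!length(S)) return(0)
  pset <- vapply(S, function(p) paste(p, collapse = ","), "")
  isgu <- function(i, j) (r[i] == "G" && r[j] == "U") ||
    (r[i] == "U" && r[j] == "G")
  e <- 0
  for (p in S) {
    i <- p[1]; j <- p[2]
    if (paste(i + 1, j - 1, sep = ",") %in% pset) {
      e <- e + if (isgu(i, j) || isgu(i + 1, j - 1)) params$gu_stack_dG37
               else params$stacks[[paste0(r[i], r[i + 1])]]
    } else {
      e <- e + params$loop_penalty_dG37
    }
  }
  e
}

h_enum_pairprobs <- function(seqstr, params) {
  r <- strsplit(seqstr, "")[[1]]
  n <- length(r)
  SS <- if (n >= 5) h_enum_structures(r) else list(list())
  w <- vapply(SS, function(S) exp(-h_struct_energy(S, r, params) / params$RT), 0)
  Z <- sum(w)
  p <- matrix(0, n, n)
  for (si in seq_along(SS)) {
    for (pr in SS[[si]]) p[pr[1], pr[2]] <- p[pr[1], pr[2]] + w[si]
  }
  list(p = (p + t(p)) / Z, Z = Z,
       # P(interval fully unpaired), for the accessibility oracle
       p_region_unpaired = function(a, b) {  # 1-based inclusive
         free <- vapply(SS, function(S) {
           !length(S) || all(vapply(S, function(pr)
             pr[1] < a || pr[1] > b, TRUE) &
             vapply(S, function(pr) pr[2] < a || pr[2] > b, TRUE))
         }, TRUE)
         sum(w[free]) / Z
       })
}

# --- ungapped local alignment DP oracle (off-target oracle) ---------------

h_dp_best_ungapped <- function(q, s, match = 1, mismatch = -2) {
  qv <- strsplit(q, "")[[1]]
  best <- 0
  for (subj in c(s, as.character(reverse_complement(nuc_seq(s, molecule = "DNA"))))) {
    sv <- strsplit(subj, "")[[1]]
    m <- length(qv); n <- length(sv)
    for (d in (-(m - 1)):(n - 1)) {
      q0 <- max(1, 1 - d); q1 <- min(m, n - d)
      if (q0 > q1) next
      sc <- ifelse(qv[q0:q1] == sv[(q0:q1) + d], match, mismatch)
      cur <- 0
      for (x in sc) {
        cur <- max(0, cur) + x
        if (cur > best) best <- cur
      }
    }
  }
  best
}

# --- naive motif scan (seq-core oracle) -----------------------------------

h_naive_scan <- function(seqstr, motif, circular = FALSE) {
  subject <- if (circular && nchar(motif) > 1)
    paste0(seqstr, substr(seqstr, 1, nchar(motif) - 1)) else seqstr
  n <- nchar(seqstr); mlen <- nchar(motif)
  starts <- integer()
  if (nchar(subject) >= mlen) {
    for (i in 1:(nchar(subject) - mlen + 1)) {
      if (substr(subject, i, i + mlen - 1) == motif && i <= n)
        starts <- c(starts, i - 1L)
    }
  }
  starts
}

# --- random Golden Gate material ------------------------------------------

# acceptor plasmid whose dropout expects `first_ovh` on the insert side
h_make_plasmid <- function(enzyme, first_ovh, backbone_start, backbone_len = 120) {
  motif <- stats::setNames(enzyme$recognition, enzyme$name)
  sp <- strrep("A", enzyme$spacer_len)
  for (i in 1:300) {
    backbone <- paste0(backbone_start, h_rand_dna(backbone_len - nchar(backbone_start)))
    dropout <- paste0(first_ovh, sp, rc_str(enzyme$recognition),
                      h_rand_dna(12), enzyme$recognition, sp)
    cand <- nuc_seq(paste0(dropout, backbone), id = "plasmid",
                    molecule = "DNA", topology = "circular")
    if (nrow(scan_motifs(cand, motif)) == 2) return(cand)
  }
  stop("helper could not build an acceptor plasmid")
}

rc_str <- function(x) as.character(reverse_complement(nuc_seq(x, molecule = "DNA")))

# one random 4-part assembly (plasmid + promoter-like + seed-like +
# scaffold-like inserts); returns NULL unless the junction overhang set
# passes the fidelity check
h_random_passing_plan <- function(enzyme, lens = c(22, 24, 26)) {
  motif <- stats::setNames(enzyme$recognition, enzyme$name)
  ins <- lapply(lens, function(L) h_rand_clean_dna(L, motif))
  plasmid <- h_make_plasmid(enzyme, substr(ins[[1]], 1, enzyme$overhang_len),
                            h_rand_dna(enzyme$overhang_len))
  parts <- c(list(gg_part("pX", role = "plasmid", seq = plasmid, production = "none")),
             lapply(seq_along(ins), function(k) {
               gg_part(paste0("ins", k),
                       role = c("promoter", "seed", "scaffold")[k],
                       seq = nuc_seq(ins[[k]], molecule = "DNA"),
                       production = "anneal")
             }))
  plan <- tryCatch(plan_assembly(parts, enzyme), error = function(e) NULL)
  if (is.null(plan)) return(NULL)
  if (check_fidelity(plan$junction_overhangs, enzyme)$verdict != "pass") return(NULL)
  plan
}

# random pairing profile (rows normalized to sum 1, boundary rules applied)
h_rand_profile <- function(n) {
  m <- matrix(stats::runif(n * 3), n, 3)
  m <- m / rowSums(m)
  m[1, 1] <- 0; m[n, 2] <- 0
  m <- m / rowSums(m)
  colnames(m) <- c("p_upstream", "p_downstream", "p_unpaired")
  class(m) <- c("pairing_profile", class(m))
  m
}

h_small_fixture_config <- function(scaffold_dna, wildtype, window = c(-14L, 14L),
                                   genome_len = 600L) {
  design_config(scaffold_seq = scaffold_dna, wildtype_srna = wildtype,
                seed_len = 24L, window_rel = window, evalue_cutoff = 1,
                excluded_enzymes = "BsaI,BsmBI", max_results = 3L)
}
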