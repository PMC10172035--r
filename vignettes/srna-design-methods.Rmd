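---
title: "Designing synthetic bacterial sRNAs: models and methods"
author: "srnaforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing synthetic bacterial sRNAs: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnaforge)
```

## The design problem

Bacterial small regulatory RNAs (sRNAs) repress or activate target mRNAs by
base-pairing through a short contiguous *seed region*, while the remainder of
the molecule — the *scaffold* — supplies structural elements such as
chaperone-binding sites and a Rho-independent terminator. A synthetic sRNA is
built by grafting a new antisense seed onto a proven natural scaffold and
expressing the fusion from a promoter as one transcriptional unit. Two
computational problems stand between an annotated target gene and a clone:

1. **Which seed?** The seed must bind its intended mRNA window strongly, must
   not bind elsewhere in the genome, and must not disturb the scaffold's
   fold — and its DNA must stay free of the type IIS recognition sites used
   for cloning.
2. **How to build it?** The chosen promoter + seed + scaffold must be turned
   into a scarless Golden Gate assembly: junction overhangs drawn from the
   construct's own sequence, checked for ligation fidelity, and realized as
   orderable oligonucleotides or PCR primers.

`srnaforge` implements both halves with self-contained, desk-scale models.
This vignette records the models, their assumptions, the tunable parameters,
and the design decisions taken where more than one choice was defensible.

## Candidate enumeration

The mRNA binding window is specified relative to the first base of the
annotated start codon (negative = upstream), the natural anchor for designs
that occlude the translation-initiation region; minus-strand genes are
handled by reverse-complementing the genomic window. Defaults: seed length
24 nt, window (−30, +21). Each sliding offset yields one candidate whose
seed is the exact reverse complement of the window subsequence —
non-contiguous (bulged) pairings are out of scope by construction. A
candidate whose DNA form contains an excluded recognition motif on either
strand is dropped at enumeration; the fused seed+scaffold is re-checked
later because a motif can straddle the junction. Targets annotated only as
`gene` (without a `CDS`) are accepted; the CDS feature wins when both carry
the same locus tag.

## Off-target screen

Each seed (the seed alone, not the fusion — the scaffold is a natural
sequence with genuine genomic self-matches that would drown the signal) is
scanned against both strands of every replicon with an ungapped
seed-and-extend search: exact word matches are extended bidirectionally
under an X-drop rule (default 10) and scored with a +1/−2 match/mismatch
scheme. Significance uses Karlin–Altschul statistics,

$$E = K\,m\,n\,e^{-\lambda S},$$

with $m$ the seed length, $n$ the total searched length (both strands of
all replicons), and $\lambda$ the unique positive root of
$\sum_{ij} p_i p_j e^{\lambda s(i,j)} = 1$, found by bisection to a residual
below $10^{-9}$. $K$ defaults to 0.71 with the default scheme: only
relative E-values matter for ranking and thresholding, and calibration to
NCBI BLASTn is explicitly not attempted. The intended target site is
excluded from the hit list.

The default word size is 4. Short seeds make the classical trade-off
degenerate: with words of length 7, an optimal ungapped segment whose match
runs are all shorter than 7 (for example two 5-mers split by two
mismatches) contains no seed word and is silently missed — about 8% of
random 24-nt/2-kb searches in our measurements. At word size 4 a missed
optimum would need at least 18 matches arranged in runs of three or
shorter, which is negligible at these search sizes, so the scan's top hit
coincides with the exhaustive dynamic-programming optimum while staying a
seed-and-extend algorithm. The test suite enforces this equivalence against
an independent per-diagonal maximum-segment oracle.

## Hybridization energy

Seed:target duplexes are scored with the nearest-neighbor model over the
16 Watson–Crick dinucleotide stacks (standard ΔG°37 values shipped as a
versioned TSV), plus a duplex-initiation term (+4.09 kcal/mol) and a
+0.45 kcal/mol penalty per terminal A·U or G·U closing pair. Because every
candidate is a perfect contiguous hybrid of the same length, this
consistent simplified score preserves the ranking semantics that matter;
absolute agreement with more elaborate interaction tools is not claimed.
An optional accessibility term, $ED = -RT\ln P(\text{region unpaired})$
from the constrained partition function, is available but off by default.

## Structure comparison (partition function)

Whether a grafted seed disturbs the scaffold fold is judged by comparing
base-pairing propensities of the synthetic sRNA with those of the wild-type
sRNA supplied in the config. Pair probabilities come from McCaskill-style
inside–outside recursions over all nested secondary structures (Watson–
Crick and G·U pairs, minimum hairpin loop of 3).

The energy model is deliberately simple and fully specified: a base pair
$(i,j)$ contributes the dinucleotide stack energy when $(i{+}1, j{-}1)$ is
also paired, and otherwise one flat loop-opening penalty (+4.0 kcal/mol
default) — hairpin, bulge, interior and multibranch closings all flat.
Stacks involving a G·U wobble take one generic value (−1.3 kcal/mol).
This per-pair attribution makes the model an unambiguous stochastic
grammar: the inside phase uses the decomposition
$Z^b_{ij} = w^{stack}_{ij} Z^b_{i+1,j-1} + w^{loop}\,(Z_{i+1,j-1} -
Z^b_{i+1,j-1})$, and a matching outside phase yields exact pair
probabilities in $O(n^3)$. The identical model drives the
exhaustive-enumeration oracle in the test suite, so the recursions are
checked to $10^{-9}$, not merely approximated. Full Turner-style loop
tables would change the numbers but not the purpose of this score —
detecting drastic refolding — and would make exact testing impossible at
this scale. Boltzmann weights use $RT = 0.0019872\,T$ (0.6163 kcal/mol at
37 °C); temperature is configurable, and the suite spot-checks that heating
flattens the ensemble. Sequences are limited to 500 nt (cubic cost and
direct-scale summation).

Each probability matrix is collapsed into a per-position profile
(P(paired upstream), P(paired downstream), P(unpaired)) and two profiles
are compared by global alignment with column cost = L1 distance of the
triples and gap cost 2.0 — the maximum column cost, so length differences
are never cheaper than total mismatch. The distance is non-negative,
symmetric and zero exactly on identical profiles.

**Structure cutoff.** Designs farther than `structure_cutoff` from the
wild type are dropped. The default is `seed_len`: the seed region
(usually 24 of ~60 nt) differs from the wild-type seed *by design* and can
contribute up to 2 cost units per position, so budgeting half that maximal
divergence over the seed length tolerates seed-local refolding while still
flagging changes that spread into the scaffold. No claim of equivalence to
any external tool's threshold is made; the cutoff is an exposed parameter.

## Ranking

Scored designs are ordered lexicographically: fewer off-target hits at the
configured E-value first (the only safety-type criterion), then smaller
structure distance, then more negative hybridization energy, then binding
site closer to the start codon (|relative position|), with the 5′→3′
window offset as a final deterministic tie-break. Hard filters (structure
cutoff; optionally any off-target in strict mode) run before sorting, and
every filtered candidate keeps a machine-readable drop reason so that
ranked + dropped always equals enumerated. Reports are byte-identical
across reruns: fixed-format numbers, no timestamps (including a constant
LOCUS date in GenBank output). Minimum-free-energy dot-bracket strings
(argmax under the same simplified model) are emitted in the FASTA headers
as a curation convenience only.

## Golden Gate planning

Type IIS enzymes (built-in table: BsaI, BsmBI, BbsI, SapI, PaqCI) cut at a
fixed offset outside their recognition site, leaving 3- or 4-nt 5′
overhangs. The acceptor plasmid carries two sites inside a dropout,
oriented so digestion excises the dropout (with both sites) and leaves a
site-free backbone whose two overhangs are fixed by the plasmid sequence.
Junction overhangs are *scarless*: the overhang at each junction is simply
the first `overhang_len` bases of the downstream part, so re-ligating the
parts reproduces the intended construct with no inserted bases. At the two
backbone junctions the plasmid's own cut geometry dictates the overhangs;
compatibility with the flanking insert ends is checked and mismatches are
errors — adapter bases are never inserted silently. More than four parts
(two seeds, concatenated transcription units) flow through the same
junction logic unchanged.

Overhang sets are screened by a local fidelity heuristic: exact
duplicates, reverse-complement clashes and palindromic overhangs fail;
pairs within Hamming distance 1 of a reverse-complement match warn. On
warn/fail the report text refers the user to external overhang-set
optimizers; empirical ligase-fidelity matrices are out of scope. The
in-silico one-pot simulator digests all site-carrying material, then
exhaustively closes circles over complementary overhangs (each fragment at
most once per product, both orientations, products deduplicated up to
rotation and strand flip, site-containing circles discarded). For every
fidelity-passing plan this yields exactly one product, byte-equal to the
expected construct up to rotation — an invariant the suite fuzz-tests over
hundreds of random plans — while deliberately mis-matched sets produce
detectable extra products.

Parts are realized either as annealing oligo pairs (top = part sequence,
bottom = rc(core + downstream overhang); guarded at 100 nt) or as PCR
primers: pad ("TA") + recognition site + spacer fill ("A"×spacer) +
overhang + an annealing region grown 3′ along the template until the
nearest-neighbor Tm reaches the target (18–35 nt, default 60 °C). Tm uses
the unified DNA nearest-neighbor ΔH/ΔS table with
$T_m = \Delta H \cdot 1000 / (\Delta S + R \ln(C_T/4)) - 273.15 +
16.6\log_{10}[\mathrm{Na^+}]$ (defaults $C_T$ = 0.25 µM, [Na⁺] = 50 mM);
it is strand-symmetric and checked against independent table summation.
Digesting the simulated amplicon must release exactly the intended part
with the intended overhangs, and both oligo routes are verified in silico
for every generated plan.

## Synthetic fixtures: what they emulate and what they do not

`generate_fixture()` builds, from a single RNG seed, an annotated toy
genome (default 3 kb, three 300-bp CDSs on alternating strands), a
scaffold with a GC-rich stem-loop and a U-tract terminator-like 3′ end, a
wild-type-style sRNA, a two-site acceptor plasmid, a parts library and a
default config. The genome is i.i.d. random sequence: it exercises
coordinate arithmetic, strand handling, motif exclusion and the off-target
machinery, but it has no codon structure, no repeat families, and base
composition exactly 25/25/25/25 — so passing tests demonstrate algorithmic
correctness, not biological performance on real genomes (where repeats
produce far more low-E-value off-targets and real scaffolds have
chaperone-binding constraints this package does not model). Chaperone
(Hfq/ProQ) site scoring is explicitly outside the scope of the energy
model, which may understate the regulatory potential of chaperone-dependent
designs. The test and acceptance workloads use desk-scale sizes chosen as
the package's own defaults: 0.6–3 kb genomes, 20–40 nt scaffolds, windows
of 28–51 nt, 500-repetition fuzz loops for the motif-exclusion and
assembly round-trip invariants.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; 1-based inclusive only in
  GenBank output and user-facing reports.
* Ambiguity codes (N, R, …) are rejected on input with the offending
  position named, never silently handled.
* Circular motif scanning extends the sequence by motif length − 1 leading
  characters so plasmid sites spanning the origin are found.
* Bisection for λ runs to a residual < 10⁻¹², well inside the 10⁻⁹
  contract; schemes with non-negative expected score are rejected.
* The partition function errors on overflow (extremely long, GC-rich
  inputs) instead of returning silently wrong numbers.
* Empty windows, seeds longer than windows, unknown loci (listing the
  available tags), unknown enzymes/parts (listing the available names),
  zero-length oligo cores and unreachable Tm targets are all explicit
  errors.
* Ties in ranking are broken by window offset; permuting the input order
  never changes a ranking.

## Limitations

Single-target designs only (one sRNA per mRNA target per run); no bulged
or non-contiguous seeds; no gapped off-target alignment or complexity
masking; no pseudoknots or co-transcriptional folding; no empirical
ligase-fidelity data; no primer secondary-structure screening; no
hierarchical (MoClo-style) multi-level assembly.
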