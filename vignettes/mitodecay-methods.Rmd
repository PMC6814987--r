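---
title: "Methods: comparative mitogenome analysis with mitodecay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenome analysis with mitodecay}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the model

Plant mitochondrial genomes combine two evolutionary regimes. A core of
roughly forty ancestral protein-coding genes evolves very slowly under
purifying selection, so Kimura two-parameter (K2P) distances between
congeners are fractions of a percent. The intergenic spacers (IGS) that
make up most of the molecule are instead replaced wholesale — entire
segments vanish or are overwritten on timescales orders of magnitude
shorter than coding-sequence divergence. The observable consequence is a
steep decay curve: the fraction of DNA two mitogenomes share drops below
50% ("half-life") while their coding divergence is still well under 1%,
with a conserved floor of genes plus flanking DNA. Superimposed on this
are repeat proliferation (dispersed and tandem), insertions of plastid
DNA (MIPTs), and — in parasitic plants — massive horizontal transfer of
host mitochondrial DNA.

`mitodecay` measures all of these from plain FASTA with one consistent
alignment engine, and ships a simulator that generates families of
genomes with ground truth for every measurement, so the pipeline can be
verified end to end without any external data.

## The alignment engine

`find_hsps()` is a deliberately transparent BLASTN-style seeder/extender:

* exact word seeds (default word size 7) on both strands, indexed by
  counting sort; `N` never seeds and always scores as a mismatch;
* ungapped X-drop extension (X = 20 score units) left and right of each
  seed; seeds that fall inside an extension already emitted on the same
  diagonal are skipped, which controls the quadratic blow-up on
  repeat-rich genomes without losing distinct hits;
* significance by Karlin–Altschul statistics: λ is the positive root of
  `Σᵢⱼ pᵢpⱼ exp(λ sᵢⱼ) = 1`, found by bisection to 1e−12 (the +1/−1
  uniform scheme solves in closed form at λ = ln 3 and is used as a unit
  check); `E = K·m·n·e^{−λS}` over the raw search space `m·n` with no
  finite-size edge correction. K defaults to the fixed value 0.3 with its
  method recorded — K shifts all E-values by a constant factor and every
  cutoff here is configurable, so a high-accuracy K is not load-bearing.

The default scoring (match +1, mismatch −2, gap open 5, extend 2, uniform
base frequencies) stands in for version-dependent BLASTN defaults that
the upstream protocol never states. With word size 7 and E ≤ 1e−6 on
genomes of a few hundred kb the minimal reportable exact repeat is about
26–30 bp, which is why the hit-length floor is 30 bp. Gapped extension is
not performed: all downstream consumers measure interval-union coverage,
for which a divergent interruption merely splits a hit without changing
the covered bases materially.

Two exact dynamic-programming aligners act as references, not as backends:
`local_align()` (full affine-gap Smith–Waterman) is the oracle against
which the heuristic is validated on small inputs, and `global_align()`
(Gotoh, traceback tie order diagonal > up > left, gap cost
`open + (k−1)·extend`) serves gene-by-gene comparisons feeding K2P.

## Repeats and collapsing

Dispersed repeats come from genome self-comparison with the trivial
full-length self-hit removed and *all* other hits retained, including
reciprocal duplicates: both sides of every hit are repetitive DNA, and
both are counted (union-merged with tandem arrays) when partitioning the
genome into repetitive and single-copy fractions. Partly or wholly
overlapping repeats are treated as a single repeat unit; size-bin counts
are reported for merged units (default) and for raw hits, since the
upstream convention is ambiguous between the two.

The tandem detector proposes candidate periods from self-lag match runs
(lags 1–500), infers a column-majority consensus motif, and scores the
array against the consensus at +2/−7. The score counts only copies beyond
the first: a two-copy window always agrees with its own consensus on the
first copy, so including it would let dense chance lag-runs in random
sequence cross the threshold. Arrays need ≥ 2 full copies and score ≥ 50
(the conventional tandem-repeat-finder defaults); harmonic calls at
multiples of the true period are deduplicated by score, then smallest
period. Indel-containing (wraparound-gapped) arrays are split rather than
joined; this is a known simplification.

Repeat families > 1 kb are clustered by single linkage where the two
sides of one HSP are linked as copies and records overlapping ≥ 50%
reciprocally are linked as the same location. Within a family the
leftmost location is kept and the rest are deleted (deletions union-merged
first so no base is removed twice, applied right to left). Leftmost-copy
retention is an arbitrary but deterministic stand-in for a manual
curation step. Collapsing is idempotent by construction and tested.

## Shared DNA, K2P and decay

Shared DNA between two (collapsed) genomes is the union length of the
query-side intervals of all retained hits, at the same alignment settings
as the repeat scan. The matrix is therefore direction-dependent
(query-coverage convention), matching how donor-profiling comparisons are
reported in this field. K2P distances use pairwise deletion (gap or
ambiguous columns dropped per pair) over per-gene global alignments
concatenated in a fixed gene order; `d = −½ln(1−2P−Q) − ¼ln(1−2Q)`, with
saturation reported as an error rather than a clamped value.

`decay_analysis()` reports per-query Pearson and Spearman statistics of
shared bp against K2P and a "half-life": the distance at which shared
percentage first crosses 50, linearly interpolated between the bracketing
subjects. Linear interpolation is the simplest defensible estimator —
the decay is not assumed to follow any parametric curve. With constant
shared DNA the correlation is reported as 0 (no decay signal) rather
than NA, with the degenerate case noted in the return value's contract.

HGT profiling ranks subjects by shared bp from a parasite query (a
multipartite parasite is first concatenated with N spacers and an offset
table for mapping hits back). `profile_consistency(a, b)` is the mean of
per-subject `100·a/b` over common subjects; identical profiles give 100,
and the measure is antisymmetric under swap (`c(a,b)·c(b,a) ≈ 100²`).

## Gene classification

A reference CDS is searched on both strands; hits under 100 bp are
suppressed (sub-100 bp fragments are conventionally not presented), the
best strand is chained co-linearly, and:

* **intact**: chain covers ≥ 90% of the reference, reconstructed CDS
  starts with ATG, every non-intron indel is a multiple of 3, no internal
  stop codon;
* **pseudogene**: coverage ≥ 30% with a frame-disrupting indel, internal
  stop, missing start — or clean truncation below 90% (truncated genes
  are flagged the same way as pseudogenes, mirroring the ψ convention);
* **fragment**: retained hits but coverage < 30%;
* **absent**: no retained hit.

Subject-side gaps ≥ 50 bp with a query-side gap ≤ 10 bp are treated as
introns: spliced out, no frame penalty, and reported by
`intron_lengths()` as the genome gaps between consecutive exons. The
numeric thresholds (90/30%, 100 bp, 50 bp) are package decisions —
upstream practice draws these distinctions pictorially — and all are
arguments with the defaults above.

## The simulator: what it emulates, and what it does not

`evolve()` draws a uniform-random ancestor containing a gene core
(default 30 CDS of 501 bp = 15 kb in a 60 kb genome — the desk-scale
shrink of a ~100 kb core in a ~400 kb mitogenome, so the full pipeline
runs in seconds; raise `genome_len` for paper-scale stress tests). Genes
are proper CDS (ATG … stop, no internal stops). Along each branch:

* K2P substitutions at the branch length with transition/transversion
  ratio κ (default 2.0), applied everywhere; substitutions that would
  create an internal stop (or break the start/stop) in a gene are
  rejected — purifying selection, and the reason planted intact genes
  classify as intact. This rejection biases coding divergence downward by
  a few percent, which the recovery tests account for.
* Segmental IGS replacement: segments with exponential lengths (default
  mean 2 kb) are overwritten with fresh random sequence until the
  expected replaced fraction `1 − exp(−turnover·branch)` is met. The
  default turnover of 100 per unit branch length reproduces the
  empirically short shared-DNA half-life (well under 1% coding
  divergence at desk scale). Replacement is in-place (equal length), so
  ancestral coordinates remain stable and truth masks are exact.
* Repeat, MIPT and HGT events are applied at the leaves as insertions
  into spacer positions, with every inserted interval recorded.

Truth tables: pairwise tree distance; and true shared DNA, computed from
the union of replacement masks **on the path between two leaves** — a
segment replaced before their common ancestor is identical in both
descendants and genuinely shared. The diagonal is 1 by convention.

The default family tree is a six-leaf ladder with *generic,
non-ultrametric* branch lengths. Under an exactly ultrametric ladder
several subjects sit at identical distances from distal queries; tied
distances make rank correlations of −1 unattainable by construction, an
artifact no real distance matrix exhibits.

What a green test does **not** establish: the simulator has no
recombination-driven multipartite structure or stoichiometric variation,
no RNA editing, no selection beyond the stop-codon filter, replacement
preserves length (real spacer turnover changes genome size), and inserted
repeat copies duplicate ancestral sequence while being marked novel in
the truth masks — so configurations with repeat/MIPT events measure
slightly more shared DNA than the truth tables state. Recovery tests that
compare against truth therefore use event-free configurations.

### Desk-scale noise and the decay test

One scaling subtlety is deliberate. At desk scale the spacer compartment
is ~45 kb; with 2 kb replacement segments each branch draws only ~20
segments, so the *realized* shared DNA of a single family carries
sampling noise about seven times larger (relative) than at paper scale
(~390 kb of IGS). The end-to-end decay test therefore scales the segment
mean with the genome (2 kb × 60/400 ≈ 300 bp), preserving the noise
regime of the system being emulated; with that, per-query Spearman
ρ ≤ −0.9 holds robustly across seeds. The generator *default* stays at
2 kb: it is the stated world, and users running paper-scale genomes
should keep it.

## Numerical and formatting conventions

Coordinates are 0-based half-open internally; emitted BED is 0-based
half-open, and tabular reports are labelled explicitly. Analyses treat
circular master chromosomes as linear, as deposited; no origin-spanning
seed rule is applied (none is established for these analyses). `N` bases
never seed and score as mismatches. Quartiles in `boxplot_stats()` are
type-7 (linear interpolation), outliers exactly outside 1.5·IQR fences,
whiskers at the most extreme non-outliers. All randomness flows from one
integer seed; per-branch and per-event streams are derived by stable
label hashing, so adding a leaf does not perturb other lineages, and
identical configurations are byte-identical.

## Known limitations

* Exact reproduction of NCBI BLASTN bit-scores/E-values is a non-goal;
  the scoring scheme is explicit precisely because the upstream one is
  not.
* The tandem detector does not model wraparound indels or the full
  statistical machinery of Tandem Repeats Finder.
* Gene classification assumes the reference CDS is close enough to seed
  7-mer hits; at coding divergence far beyond ~10% the absent/fragment
  boundary becomes conservative.
* Shared-DNA values depend on the collapse step; comparing uncollapsed
  genomes inflates estimates and is allowed only explicitly.
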