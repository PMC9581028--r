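---
title: "Conservation-based prediction of prokaryotic gene starts: model, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conservation-based prediction of prokaryotic gene starts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The inference problem

The 3' end of a prokaryotic protein-coding gene is fixed by its stop codon
and is predicted nearly perfectly by ab initio tools; the 5' end — the
translation initiation site — is not. `startfinder` treats start selection as
an inference over the *longest open reading frame* (LORF): the in-frame
extension of the ORF upstream to the nearest stop codon, which by
construction contains the true start and every in-frame decoy. The evidence
is a multiple alignment of homologous LORFs: real starts sit at the boundary
where cross-species conservation switches from intergenic drift to
protein-coding constraint, and start-capable codons (ATG/GTG/TTG) at or near
the true start tend to be preserved while upstream decoys decay.

Two modeling commitments follow from this framing and are worth stating as
assumptions:

* **Homologs carry the signal.** A gene with too few usable homologs gets no
  prediction. Declines are first-class outputs (they quantify *coverage*,
  as distinct from accuracy on emitted predictions).
* **No regulatory-signal models.** Ribosome-binding-site or promoter motifs
  are deliberately unused; conservation is the only evidence source, which
  keeps the method applicable across leadered and leaderless transcription.

## Target selection

Raw homologs (from any search adapter, or from fixtures) pass through four
filters, in order:

1. **Coverage.** The pairwise protein alignment must cover more than 80% of
   *both* the query and the target (`coverage_min = 0.8`, strict). Poorly
   covered alignments say nothing about the region near the start.
2. **Distance window.** The Kimura two-parameter distance computed from the
   codon-backmapped nucleotide alignment must fall in
   `[kimura_min, kimura_max] = [0.1, 0.5]` substitutions/site. Closer
   targets are uninformative (no divergence contrast); more distant ones
   degrade the alignment with gaps. The estimator
   `d = -1/2 ln[(1-2P-Q)√(1-2Q)]` is undefined when the log argument is
   non-positive; such pairs are flagged `undefined_distance`, never coerced
   to 0 or infinity.
3. **Redundancy.** Targets are scanned in ascending distance-to-query order
   and dropped when within `kimura_min` of an already-kept target.
   The ascending-distance greedy order is a determinism choice: of any
   redundant pair the one closer to the query survives. Target–target
   distances are composed through query coordinates rather than realigned.
4. **Sampling cap.** At most `max_targets = 50` targets are kept (uniform
   subsample under `rng_seed`); fewer than `min_targets = 10` declines the
   gene. Filtering precedes sampling by default (`sample_first = FALSE`)
   so that the cap never displaces informative targets; the opposite order
   is available for sensitivity analysis.

Every input target exits with exactly one disposition — kept or a single
rejection reason — so audits conserve counts.

## The dual-layer alignment

The protein alignment (external aligner, gold fixture rows, or the colinear
aligner for indel-free families) is back-mapped so each amino-acid column
expands to its source codon or three gaps. All scores below are defined on
this structure; column↔offset maps are exact, and ungapping any layer
reproduces the source sequence byte for byte. Alignment columns upstream of
a target LORF's 5' end are gaps, and such rows simply contribute nothing at
those columns.

Translation uses NCBI table 11 (the bacterial/archaeal code; no
alternative table is modeled), with initiators *not* forced to
methionine: a GTG start reads V, a TTG start reads L, and the display layer
distinguishes start-capable codons (uppercase M/V/L) from synonymous
non-start codons (lowercase v/l). Codons containing ambiguity letters are
never start candidates and never match in any score.

## Scores and the three-step selection

**Block identity (step A and the C-2 guard).** For a block of `r = 10`
query-ungapped columns starting at column `i`,
`S_blk(i, r) = 1/(r (N-1)²) Σ_{m≠n} Σ_{j∈J(i,r)} H(m,n,j)`, summing over
ordered row pairs; a block is conserved when `S_blk > t_blk = 0.5`. The
normalization is implemented exactly as printed, which makes the maximum
`N/(N-1)` rather than 1; whether `(N-1)²` is a typographical variant of
`N(N-1)` is left open deliberately, and `blk_norm = "pair_count"` switches to
the alternative for sensitivity analysis without changing the default. At
the default threshold the two normalizations rarely disagree (they differ by
the factor `N/(N-1)` ≤ 1.1 at `N ≥ 10`).

Two boundary rules matter when blocks are used to separate candidates:

* A *possible N-terminal* — any query start-candidate column — is never one
  of a block's `r` scored positions.
* The reported block boundary is the first member column that is conserved
  on its own (per-column identity above the threshold; a qualifying window
  always contains one). Without this rule the 10-column average lets the
  boundary overshoot one or two unconserved columns upstream of the
  conserved run, and step A then miscounts candidates "upstream of the
  block". On benchmark families this overshoot was the dominant error mode
  of step A (a lone decoy upstream of an overshot boundary gets predicted);
  with the rule, step-A errors essentially disappear while `S_blk` itself
  stays exactly as printed.

**Candidate conservation (steps B and C).** For a candidate at column `i`,
`S5'(i, x) = 1/N Σ_j [G(i,j,x) − P(i,j)]` over the `N` *target* rows (the
query does not vote for its own candidate): `G = 1` when the target carries
ATG/GTG/TTG among its codons within `x = neigh_codons = 2` codon columns of
`i`; `P = 1` when the target's codon at `i` encodes valine or leucine via a
non-start codon (GTA/GTC/GTT, CTA/CTC/CTG/CTT/TTA) — near-certain evidence
that the column is ordinary coding sequence rather than a start. Rows gapped
across the window contribute zero either way but stay in the denominator.
Thresholds: `t_5prime = 0.5`.

**Dispatch.** With upstream-gene context indicating overlap or
near-abutment (3' end at or downstream of 10 nt upstream of the LORF start,
`overlap_trigger_nt`), step B runs before C; otherwise A runs before C:

* **A** predicts the single candidate strictly upstream of the left-most
  conserved block; zero or ≥ 2 candidates fall through. The candidate itself
  need not be conserved.
* **B** scores candidates within `overlap_window_nt = 9` nt of the upstream
  gene's 3' end and predicts the best one above threshold; ties resolve to
  the most upstream candidate (as do all score ties in the package).
* **C** screens candidates 5'→3' (C-1) for the first above threshold, `u`,
  then searches `downstream_recheck_nt = 30` nt downstream of `u` for the
  best-scoring candidate `d` (C-2). `d` is predicted when it is above
  threshold and no conserved block of any length 1..`r` lies strictly
  between the two candidates; otherwise `u` is predicted. The "otherwise"
  branch is read as attaching to the block condition: when no downstream
  candidate qualifies at all, `u` stands. This reading is pinned by a trace
  test.

**Intergenic-distance conservation.** For per-sequence signed distances
`D(n)` from the upstream gene 3' end to the start (negative = overlap),
`DC(x, f) = 1/N Σ I{x−f ≤ D(n) ≤ x+f}` with `x` the modal distance. Mode
ties resolve to the smallest absolute value, then the most negative
(overlaps are the biologically favored configuration at operon junctions).
The margin `f` has no published value; the default is 3 nt — one codon of
annotation jitter — and is exposed in the configuration.

## The synthetic benchmark generator

`simulate_family()` emulates exactly the regime the selection pipeline
assumes: a star topology of homologous LORFs around an ancestral query,
`[upstream | true start | gene body | stop]`, with

* **K80 substitution**, per-site independent, using the exact
  transition-probability forms for the requested expected distance, so the
  Kimura estimator is consistent for the simulated rate (verified by test);
  transition:transversion rate ratio 2 by default; no indels, so the gold
  alignment is colinear and score logic is tested in isolation from aligner
  behavior (an indel mode is future work).
* **Conservation contrast**: mean coding rate 0.24 subs/site with per-target
  factors Uniform(0.5, 1.5) — realized query–target distances 0.12–0.36,
  inside the [0.1, 0.5] selection window and bracketing the clade-average
  distances (≈ 0.23–0.38) reported for real homolog databases — and an
  upstream rate of 3× coding (capped at 0.745, the estimator's domain), the
  minimum contrast at which recovery is claimed.
* **Truth preservation**: per-codon rejection sampling keeps the true start
  start-capable (ATG↔GTG↔TTG drift is allowed — real start codons vary),
  forbids in-frame stops before the terminal codon, and keeps the terminal
  stop a stop.
* **Controlled candidates**: ancestral upstream codons exclude stop *and*
  start codons, so the query's candidate set is exactly the true start plus
  `decoy_upstream_starts` planted decoys; the first ten gene-body codons
  also exclude start codons, so the benchmark probes upstream-candidate
  discrimination rather than genuinely ambiguous tandem-start genes (where
  no annotation-free method can define a unique truth).
* **Overlap modes**: −4 (`…ATGA…`, the upstream stop sharing 4 nt with the
  start) and −1 (`…TGATG…`), the configurations enriched at operon
  junctions, with per-target frame-preserving (multiple-of-3) annotation
  jitter of the upstream 3' end; `D(n)` statistics and step-B context read
  the recorded annotation, as they would from a real GFF3.

What the generator does **not** emulate — and what passing benchmarks
therefore cannot show — includes: realistic phylogenies (star topology
only), codon-usage and GC bias, indels and alignment error, horizontal
transfer, rate variation along the gene, and search-stage artifacts
(paralogs, partial hits). Results on synthetic families measure the
selection logic under its own model assumptions, not genome-scale accuracy.

## Numerical and scale choices

* Coordinates are 0-based half-open internally; GFF3 I/O converts to
  1-based inclusive. All 3'-anchored keys are strand-aware.
* Percentages are carried at full precision and rendered only at output.
* Degenerate inputs: empty candidate sets, all-gap windows, zero comparable
  alignment columns, and sub-minimum target counts all produce defined,
  flagged results (empty tibbles, zero scores, `undefined_distance`,
  declined predictions) rather than errors.
* Benchmark sizes used by the tests and the acceptance script — 200 families
  of 20 targets, 100-codon genes, 60-nt upstream regions, 1–2 decoys; 500
  random small alignments (≤ 8 rows, ≤ 30 columns) for oracle equivalence;
  2,000 genes for the combiner — were chosen so the full suite completes in
  a few minutes on a single core while keeping binomial noise on the
  recovery rate near one percentage point.

## Known limitations

* Step A depends on a detectable conserved block; at the distance window's
  far edge, amino-acid identity between targets can hover near the 0.5
  threshold, so block detection (and hence step A) is conservative and most
  benchmark predictions arrive via step C. This mirrors the method's design:
  C is the general case.
* Step C-1 accepts the first candidate above threshold scanning 5'→3'; a
  chance-conserved decoy more than 30 nt upstream of the true start
  therefore wins, and the C-2 re-check cannot rescue it. On benchmark
  families this is the dominant residual error (a few percent at 3×
  contrast) and is inherent to the published procedure.
* The agreement combiner suppresses error toward the product of the two
  streams' error rates only insofar as their errors are independent;
  correlated errors (e.g. both tools misled by the same conserved decoy)
  break the bound, and the benchmark injects independent errors by
  construction.
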