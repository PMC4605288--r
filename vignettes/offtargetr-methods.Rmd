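---
title: "Methods: segmented off-target scoring with chromatin accessibility"
author: "offtargetr authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmented off-target scoring with chromatin accessibility}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(offtargetr)
```

## The problem

A CRISPR/Cas9 ribonucleoprotein is targeted by a 20-nt spacer to a genomic
protospacer flanked by a 3' PAM (canonically NGG for *S. pyogenes* Cas9).
Targeting is imperfect: catalytically dead Cas9 binds loci carrying as many
as 9-10 mismatches against the spacer, and active Cas9 cleaves loci with up
to 6-7. Enumerating and ranking these off-target loci is a prerequisite for
both genome-editing experiments (cleavage) and dCas9 applications such as
imaging and CRISPRi (binding). offtargetr implements a complete prediction
pipeline: candidate enumeration under a mismatch budget, PAM classification,
a three-segment position-weighted score, an additive chromatin-accessibility
bonus, grid-search weight training, a benchmarking harness, and sgRNA design
for short regions.

## Candidate enumeration

`enumerate_candidates()` slides a 20-nt window over both strands of the
genome and keeps windows within Hamming distance of the guide no greater
than the mode's budget — 9 for binding, 6 for cleavage — whose adjacent 3'
trinucleotide belongs to an admitted PAM class. PAM classes are ordered by
observed Cas9 preference, GGG > NGG > NNG; the default policy searches
GGG/NGG only, and NNG is an explicit opt-in (`pam_policy(admit_nng =
TRUE)`). Substitution-only (Hamming) semantics are used throughout: bulges
and indels are out of scope. Minus-strand windows are reverse-complemented
before comparison, so reported site sequences always read 5'→3' facing the
guide with position 20 adjacent to the PAM. Coordinates are 0-based
half-open (BED convention) and cover the 20-nt protospacer only; the PAM
occupies `[end, end+3)` on + and `[start-3, start)` on −.

Two conservative conventions handle degenerate input: a non-ACGT genome base
(assembly gaps, ambiguity codes) always counts as a mismatch and never
satisfies a G required by a PAM pattern; windows whose PAM would run off the
chromosome end are skipped. The scan is validated against a naive
window-by-window oracle in the test suite for every budget 0-12 and both
PAM policies.

## The segmented score

The protospacer is split into three segments — by default 5, 5 and 10 nt
with segment 1 at the PAM-distal end and segment 3 (score `s3`)
PAM-proximal. Position `i`'s contribution depends on its segment score
`s_i` and its mismatch context:

* match: `+s_i`
* isolated mismatch (no mismatched neighbour): `−s_i / 2`
* mismatch inside a run of ≥ 2 adjacent mismatches: `−s_i`, except that
  every position of a run crossing a segment boundary contributes the
  negative *mean* of the scores of all segments the run spans.

Summed over the 20 positions this yields the base score

$$S = \sum_{i=1}^{3}\left[(n \times s_i) + (m \times (-s_i)) + (k \times
(-s_i/2))\right]$$

with `n` matches, `m` consecutive-mismatch positions and `k` single
mismatches (`n + m + k = 20`). Runs of length > 2 are treated as
consecutive mismatches position by position (the run count `m` counts
positions, not runs), and a run spanning all three segments would take the
mean of all three scores — the natural extension of the two-segment mean
rule. Scores are kept as exact doubles until output (where they print with
2 decimals) and may go negative; no floor is applied.

The trained defaults are `s1 = 5, s2 = 70, s3 = 50` for binding and
`s1 = 20, s2 = 60, s3 = 50` for cleavage (`weight_set()`), so a perfect
match scores 875 and 900 respectively. Two points deserve flagging:

* **Segment orientation.** The segment order is stated in the 5'→3'
  direction (lengths "5, 5, 10"), which puts the strongly weighted 10-nt
  segment at the PAM-proximal end — consistent with the seed-region
  biology. Descriptions of the same split sometimes label the 10-bp block
  "PAM distal"; because the two readings are mirror images, the package
  exposes `segment_scheme(orientation = "pam_proximal_first")` to flip the
  assignment, and the default follows the 5'→3' reading.
* **A non-monotonicity.** The cross-segment mean rule makes the score
  non-monotone in the mismatch mask: extending a run from a strong segment
  (`s2 = 70`) across the boundary into a weak one (`s1 = 5`) re-prices the
  whole run at the mean `(5+70)/2`, which can *raise* the score (e.g.
  mismatches {6,7} → {5,6,7} under binding defaults). This is an inherent
  property of the mean rule, not an implementation artifact; the test
  suite asserts strict decrease only for flips whose run stays within one
  segment, and documents the counterexample.

Because every position's contribution is `±s_i` or a fixed mean of the
`s_i`, the score is linear in `(s1, s2, s3)`. `score_coefficients()`
exposes this decomposition, and the optimizer exploits it to rescore a
fixed candidate set at thousands of grid points as one matrix product.

## Chromatin accessibility

Open chromatin strongly favours Cas9 occupancy. `build_bin_track()` tiles
the genome into fixed-width bins (default 200 bp, on the order of a DNase I
hypersensitive site; the bin width is a resolution choice, not part of the
model) and counts, per bin, the number of cell types whose DNase peak set
overlaps the bin by ≥ 1 bp — each cell type counting at most once per bin.
A candidate site inherits the count `X` of the most accessible bin it
overlaps (a `mean` aggregation is available as an option), and receives

$$S_d = 0.0113 \times X \times d, \qquad S_f = S + S_d$$

with chromatin weight `d = 20` (binding) or `d = 10` (cleavage). The
0.0113 coefficient is the slope of a linear trend of Cas9-site overlap
fraction against cell-type frequency fitted on aggregate 125-cell-type
human DNase data; it is stored as a configurable constant
(`dnase_coefficient`) rather than re-derived, since the package does not
ship those data. `fit_accessibility_trend()` offers a least-squares refit
on per-class overlap fractions for users with their own tracks. With no
track supplied (e.g. non-human genomes), `S_f = S` and the ranking is by
sequence alone.

`finalize_scores()` sorts by `S_f` descending with a fully deterministic
tie-break — PAM class priority (GGG > NGG > NNG), then chromosome, start,
strand — so identical inputs always produce byte-identical outputs.

## Weight training

`grid_search()` trains `(s1, s2, s3)` against a gold-standard interval set.
The objective is the number of the top-N ranked predictions (default
N = 1000) fully contained in a gold interval; the counting unit is the
prediction, so two predictions inside one gold interval count twice.
Candidates are enumerated once (the search step is weight-independent) and
rescored per grid point via the linear decomposition. The grid is the full
Cartesian product of the three value lists (the historical starting range
is 0-20). Exhaustive enumeration is used rather than random sampling:
with `t` values per axis the space is `t^3`, which is tractable, and
determinism matters more than sampling economy. When a maximizer sits on a
parameter's upper boundary the range is extended by one step of uniform
spacing and re-evaluated; a parameter stops extending once the best
objective on its frontier has dropped at least `stop_drop` (default 10
correctly predicted sites) below the best seen anywhere. A zero objective
is not chased: if the whole grid scores zero the lexicographically
smallest point is returned with a warning flag. Ties always break toward
the smallest `(s1, s2, s3)`. `train_chromatin_weight()` runs the same
objective over a 1-D grid of `d` values with the segment weights held
fixed, preferring the smallest `d` on ties.

## Evaluation harness

`top_n_overlap()` reproduces the standard benchmark: count the top-N
predicted intervals 100% contained within a gold interval (`bedtools
intersect -f 1` semantics, with the fraction applied to the prediction); a
prediction inside two overlapping gold intervals counts once, and N beyond
the list length saturates. `overlap_curve()` tabulates this over a range
of N, yielding the monotone overlap-vs-list-length curves used to compare
predictors.

`random_region_enrichment()` asks whether a site set is concentrated in
frequently open chromatin: each site takes the `X` of its most accessible
bin, and the observed per-frequency-class fractions are compared with
`n_simulations` (default 1000) sets of length-matched regions placed
uniformly at random, chromosomes sampled proportional to length. The
summary statistic is the mean per-site `X`; the empirical one-sided
p-value uses the add-one correction `(1 + #{sim ≥ obs}) / (n_sims + 1)`,
so its floor at 1000 simulations is 1/1001. Any parametric p-value printed
elsewhere for such an enrichment would rest on distributional assumptions
this simulation does not make, so the two need not agree numerically.

## Guide design

`find_protospacers()` scans a user region (23-250 nt) for every 20-mer
flanked by an NGG-class PAM on either strand. `rank_guides()` then runs
the full prediction pipeline per guide and ranks guides ascending by
*off-target burden*, defined here as the sum of final scores `S_f` over
all candidate sites excluding the single best-scoring perfect hit (the
on-target locus). The burden metric is a design choice of this package —
the ranking currency is the score the pipeline already produces; counting
sites above a threshold or taking the maximum off-target score are obvious
alternatives and can be computed from the per-guide site tables in the
report. A guide with several perfect hits is non-unique and the extra
perfect hits count toward its burden; a guide with no perfect hit is
flagged and ranked by the burden over all its hits. Design defaults to
cleavage weights, the genome-editing use case.

## Synthetic worlds

All tests run on synthetic data generated in code; nothing is downloaded.
`synthetic_spec()` + `generate_fixture()` realize a seeded world: a random
background genome (default GC 0.41, human-like), a guide, planted sites
with exact mismatch structure (explicit positions control run/single
layout), per-cell-type DNase peak tracks with controllable coverage of
planted sites, and a padded gold BED. The generator verifies itself: after
planting, the genome is scanned and the background redrawn (guide and
layout included) until the candidate set equals the manifest exactly, so a
fixture's ground truth is exact, not probabilistic. Identical specs yield
identical bytes, and the caller's RNG stream is left untouched.

What the fixtures do *not* emulate: real genomes are repetitive and
GC-heterogeneous, so real candidate sets are vastly larger and
rank-correlated with repeat families; real DNase peaks have width and
signal structure that a uniform-peak simulation lacks; and gold-standard
assays (ChIP-seq, GUIDE-seq) carry detection thresholds and biases absent
here. Passing tests therefore demonstrate algorithmic correctness — exact
budgets, exact score arithmetic, exact containment counting, calibrated
simulation p-values — not predictive performance on biological data.

## Problem sizes and numerical choices

The test suite uses genomes of 1.5-4 kb, 20 oracle genomes of 2.5 kb for
the search equivalence check, 10^5 random masks for the scoring oracle,
200-simulation enrichment runs repeated 20 times, and a 125-point
recovery grid — sizes chosen so the whole suite completes in minutes while
still exercising every code path at meaningful density. Scores are exact
double arithmetic (the only fractions are halves and thirds from the
single-mismatch and mean rules); no rounding occurs before output.
Ranking ties, grid-search ties and PAM preference are all broken by fixed
deterministic rules stated above, so every pipeline stage is reproducible
bit for bit at a fixed seed.

## Known limitations

* Substitution-only alignment; DNA/RNA bulges are not modelled.
* Only NGG/NNG-family PAMs; NAG-only or NGA policies are not offered.
* The mismatch-identity of a base change (e.g. rG:dT wobble) is ignored;
  only position and adjacency matter.
* The naive scan is linear in genome size per guide and is intended for
  targeted regions and test genomes, not whole-human-genome throughput.
* The chromatin model is a single linear term in cell-type frequency;
  histone marks and methylation are not integrated.
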