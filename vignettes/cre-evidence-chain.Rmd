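---
title: "Localising cis-regulatory elements from converging genomic evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Localising cis-regulatory elements from converging genomic evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cretrace)
library(tibble)
```

`cretrace` implements the computational evidence chain used to localise a
cis-regulatory element (CRE) controlling a discrete phenotype — the
motivating case being the switch loci that toggle wing-pattern elements
such as the *Heliconius* hindwing yellow bar. No single genomic signal
suffices: the package combines phenotype-association evidence from
population haplotypes, chromatin accessibility, carrier-specific read-depth
anomalies, and three-dimensional promoter contact, and only intervals
supported across tiers are nominated. A synthetic-data generator with
recorded ground truth makes every stage testable offline.

## Topology weighting of phenotype hypotheses

For predefined sample groups (populations/morphs), a window tree relates
all haplotypes; the weight of a group topology is the fraction of
one-tip-per-group subtrees inducing it. A genomic block where the
*phenotype* grouping (e.g. yellow-barred populations monophyletic) carries
weight near 1, against a genome-wide background concordant with species
relationships, is the association signature of a shared functional variant.

Sliding windows hold a fixed number of SNPs — 50 SNPs with a 20-SNP step by
default — and a window enters the profile only when at least 10 of its
sites have every group at least 50% genotyped. Window trees are built by
neighbor joining on normalized Hamming distances (mismatch fraction over
sites genotyped in both haplotypes; a pair with no shared genotyped site is
an error rather than a zero distance). Only the topology of the window tree
is consumed, and NJ is deterministic and provably exact whenever the
distance matrix is additive, which our tests verify on random additive
matrices; a likelihood tree-builder would add dependencies without changing
the weighting.

Weighting is exact (full enumeration of the one-per-group combinations, a
count ratio summing to exactly 1) up to a configurable cap of $10^6$
combinations, with a seeded Monte-Carlo estimator (default 1000 iterations)
beyond it. Unrooted group topologies are enumerated exhaustively —
$(2G-5)!!$ of them for $G$ groups (1, 3, 15, 105 for $G = 3 \dots 6$) — and
identified canonically by their split sets (`"A,C|B,D"`), so identical
shapes always share an id. For four groups the induced topology of each
subtree is resolved by the four-point condition on edge-count path
distances, which on a binary tree is never ambiguous; the generic path
restricts the tree's split matrix and both routes are cross-checked in the
tests.

Association intervals are maximal runs of at least `min_windows = 2`
consecutive windows whose hypothesis weight reaches `threshold = 0.75`,
merged in bp space. The threshold is a free parameter: published analyses
identify the high-weight block visually, so no printed value exists to
match; 0.75 demands a three-to-one majority of subtrees and, at the default
simulation depth, cleanly separates planted blocks (weights near 1) from
species-tree background (weights near 0).

## Coverage-drop scanning

An insertion absent from the reference (or a deletion) leaves a localized
deficit of mapped read depth in carriers. Depth tracks arrive pre-filtered
(the upstream convention is mapping quality ≥ 30, recorded as provenance);
each individual's per-base depth is tiled into non-overlapping 50 bp
windows (a trailing window is kept only if it covers at least half a
window), summarised by the median (midpoint mean for even counts),
normalized by that individual's scaffold-wide mean depth — removing
library-size scale, so rescaling any individual's depths leaves all calls
unchanged — and averaged per group.

A window is a candidate drop when the groups separate cleanly: a non-empty
carrier set at or below `carrier_max = 0.75` of expected depth, everyone
else at or above `control_min = 0.90`, and nobody in between. Runs of at
least `min_windows = 3` candidate windows with a constant carrier set
become calls, and a call is *phenotype-concordant* only when its carrier
set is exactly the groups of one phenotype — the "explained by phenotype,
rather than geography" criterion that separates a shared variant from
population-specific artefacts. The three thresholds are invented plumbing
(the source analyses judge the drop visually): they are exposed, and
validated purely against simulations, where the default settings recover
planted 300 bp, 60%-depth drops and stay silent on nulls.

## Virtual 4C and contact enrichment

From a binned symmetric Hi-C matrix (5 kb bins by default), the virtual-4C
profile at an anchor is simply the anchor's matrix row. Enrichment of a
CRE–promoter pair is judged against the empirical distance-decay
expectation: for each bin distance $d$, the mean and median count over all
$n_{\text{bins}} - d$ pairs (self-distance excluded). Features given in bp
map to the bin containing their midpoint. With $o$ the observed pair count,
$T$ the total count at that distance and $e$ the rounded per-distance mean,
the two-sided Fisher's exact test evaluates $[[o, T-o], [e, T-e]]$; the
reported odds ratio is the sample ratio with a Haldane 0.5 correction when
a cell is zero. The per-distance (not pooled-across-distances) expectation
is used; the median is reported alongside the mean as a robustness
diagnostic.

This table is the most literal encoding of "observed contacts relative to
those expected from the background", but it is intrinsically conservative:
conditioning on the margins makes the null standard score
$\approx (o-e)/\sqrt{o+e}$, so only about $1/\sqrt{2}$ of a Poisson
deviation registers and rejection at $\alpha = 0.05$ effectively requires a
2.8$\sigma$ deviation. Under pure distance-decay simulation the empirical
type-I error is therefore well below nominal (the acceptance script
measures it, around 0.004 rather than 0.05), while a planted 10× loop at
count scales comparable to the data is still detected essentially always.
The practical reading: significance calls are trustworthy (false-positive
rate below nominal); marginal loops near the detection threshold may be
missed. Calibration is measured over pairs at distances where the expected
count is at least 1, because pairs with $e = 0$ yield the degenerate table
$[[o, T], [0, T]]$ and can never reject.

## Accessibility peaks and CRE nomination

The peak caller is deliberately transparent: smooth with a centred moving
average (75 bp), threshold at the global mean plus `k_sigma = 3` times
$\max(\text{SD}, 1.0)$ (the floor prevents wall-to-wall calls on
near-constant tracks), take maximal super-threshold runs, merge runs closer
than 50 bp and drop runs under 100 bp. It is translation-equivariant and
recovers planted boxcars to within the smoothing bandwidth. Replicate-aware
or local-background callers are out of scope because no replicate structure
is modelled. All intervals are BED-convention 0-based half-open;
nomination returns accessibility peaks with ≥ 1 bp overlap with any
high-association interval, annotated with the best overlapping association
score, and the pipeline composer then requires a concordant coverage drop
and a significant promoter contact on top.

## Consensus alignment and indel calling

Reference/carrier consensus pairs (Sanger-amplicon scale, ~1–2 kb) are
aligned by a global affine-gap Gotoh dynamic program written for exact
reproducibility: match +1, mismatch −1, gap open −5 charged once per run,
extend −1 per base (a length-$L$ gap costs $-5 - L$; both cost conventions
exist, so this is stated explicitly), `N` neutral at 0. Traceback ties
resolve match > deletion > insertion, and every gap run is then
left-normalized — shifted to the smallest coordinate on the first sequence
among equal-scoring placements — so indel positions are reproducible; a
planted insertion can therefore legitimately report a coordinate a base or
two left of where it was planted when the flank extends the inserted
sequence. Scores are verified against exhaustive enumeration of all
alignments at short lengths and against an independent aligner at 12 bp;
TE-scale planted insertions (690 bp and 163 bp, the sizes of the BovB-like
and Helitron-like elements at the yellow-bar locus) are recovered at exact
length. Windowed identity (fraction of identical columns per window of
first-sequence coordinates, gaps counting against) provides the
cross-species identity track with its conventional 75% display threshold.

## Ridge-spacing morphometrics

Scale ultrastructure is summarised by the dominant spatial period of
intensity traces drawn across ridges: linear detrend, Hann taper, FFT, peak
within a spacing band of 0.1–5 µm (bracketing the ~0.2 µm microrib and
~0.6 µm crossrib structures), refined by quadratic interpolation over the
three bins around the maximum. The estimator is pixel-equivariant,
amplitude-invariant, and recovers planted periods within 2% at
signal-to-noise ratio 3 with ≥ 10 periods per trace. Batch summaries
(typically 10–20 traces per scale type) report per-type mean, SD and the
count of excluded (e.g. flat) traces. Trace acquisition from micrographs is
out of scope; traces arrive as CSV.

## The synthetic-data generator

Every stage has a paired generator whose recorded truth is sufficient for
recovery testing, and the defaults are the study conditions used
throughout the tests:

* `sim_haplotypes()` — 4 groups × 4 haplotypes, 2000 sites; sites evolve
  down *fixed* group trees (a species tree pairing consecutive groups, a
  phenotype tree pairing alternating groups inside the planted block
  [800, 1200)), with groups as shallow clades (tip branches 0.05, internal
  branches 0.5 in substitution-scale units, scale `theta_bg = 0.3`). Fixed
  trees rather than a coalescent make the planted truth exact — the
  deliberate trade of realism for testability; there is no recombination,
  no mutation-rate variation, and within-group diversity is uniformly low.
  At these settings a 50-SNP window typically segregates at well over 10
  sites, so window trees are well resolved.
* `sim_depth()` — 20 individuals, 10 kb, mean depth 30, negative-binomial
  counts with dispersion (size) 10; carriers multiply the mean by
  `drop_frac = 0.4` over a 300 bp footprint. No breakpoint soft-clipping or
  mappability structure is modelled.
* `sim_contacts()` — Poisson counts at $\text{scale} \cdot d^{-\alpha}$
  (scale 100, $\alpha = 1$), symmetric, zero diagonal, planted loops as
  multiplicative enrichment (> 1).
* `sim_track()` — boxcar peaks on negative-binomial background noise.
* `sim_insertion_pair()` / `sim_trace()` — random backbone with planted
  insertions; sinusoid plus Gaussian noise.

All generators are bit-reproducible given `seed`. Because the generators
implement exactly the statistical structure each detector assumes, passing
tests demonstrate correctness of the implementations and internal
consistency of the chain — not robustness to the messier features of real
data (repeat-induced mappability artefacts, unequal within-group sampling,
matrix-balancing biases, acquisition noise in traces).

## Problem sizes and reproducibility

The recovery-rate checks in the test suite and in `scripts/acceptance.R`
use 100 seeded replicates per condition (1000 pairs for the contact-test
calibration), at the default generator sizes above — small enough to run on
a laptop in minutes, large enough that a ≥ 95/100 recovery criterion is
meaningful. The end-to-end composer `run_synthetic_cre_pipeline()` builds a
20 kb locus (SNPs at 10 bp spacing, 500 bp contact bins, a decoy
accessibility peak outside the association block) and nominates the unique
peak passing association, coverage-drop and contact tiers.

```{r example, eval = FALSE}
run <- run_synthetic_cre_pipeline(seed = 1)
run$candidates
```

## Known limitations

* The association stage consumes phased haplotypes; unphased data must be
  phased (or pseudo-haplotyped) upstream.
* Drop calls are window-resolution: breakpoints are not refined, and depth
  alone cannot distinguish insertion from deletion — that requires the
  alignment stage on amplicon consensi.
* The contact-enrichment test is conservative by construction (see above);
  it reports no multiple-testing correction because the intended use is a
  single anchored CRE–promoter hypothesis.
* Matrix balancing/ICE normalisation, TAD calling, peak replication
  structure and TE family classification are out of scope.
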