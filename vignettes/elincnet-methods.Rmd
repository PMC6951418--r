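---
title: "elincnet: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{elincnet: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette explains what `elincnet` computes, the assumptions behind each
stage, the parameters that matter, and the design choices taken where the
procedure was genuinely open. It is the package's account of its own
methods; all numbers quoted elsewhere (README, tests) are produced by the
code itself.

## The classification problem

Intergenic lncRNAs fall into two regulatory archetypes distinguishable by
TSS chromatin: enhancer-associated transcripts (elincRNAs; high H3K4me1,
low H3K4me3, and — as the fitted model indicates — high DNA methylation and
body H3K122ac) and canonical, promoter-like transcripts (high H3K4me3 and
H3K9ac at the TSS, high H3K36me3 over the body). `elincnet` derives
training labels from the H3K4me1/H3K4me3 ratio alone, then learns a sparse
linear model over a broader multi-omic feature set so the two classes can
be separated genome-wide, including at loci where the two H3K4 marks are
equivocal.

## Regions

All coordinates are 0-based half-open (BED convention); GTF input is
converted on read. For a transcript with strand-aware start site TSS:

* **TSS interval** — `[TSS − flank, TSS + flank)`, default `flank = 500` bp.
  Windows are clipped at chromosome boundaries rather than discarded, so
  the transcript universe does not depend on assembly edge effects.
* **Gene body** — from `TSS + flank` (transcript-forward) to the TTS. A
  transcript no longer than `flank` has an empty body and is an error at
  region construction; the feature builder drops such rows (body features
  are half the columns, so zero-filling would fabricate signal).

The TSS of a minus-strand transcript is its maximal genomic coordinate —
standard strand semantics.

## High-confidence labeling

For expressed transcripts (`fpkm >= 0.5`) with at least one of the two mark
counts ≥ `min_signal = 10` in the TSS interval, the observed statistic is
the pseudocounted ratio `(me1 + 1) / (me3 + 1)`. The pseudocount keeps
zero-denominator ratios finite without changing the ordering among
transcripts that pass the signal filter.

The null is built by **independently shuffling each mark's count vector
across transcripts** and pooling the recomputed per-transcript ratios over
`n_perm = 10000` rounds. Independent shuffles break the within-transcript
pairing of the two marks, which is exactly the association the test
interrogates; the alternative (swapping marks within a transcript) yields a
degenerate two-point null and was rejected. Ratios are pooled across
transcripts rather than kept per transcript: a per-transcript null under
this scheme would differ only in which shuffled values it retains, while
pooling gives a stable, well-resolved distribution. The count vectors are
sorted internally before shuffling so the realized null depends only on the
multiset of counts, making labels exactly invariant to input row order.

Thresholds use the **nearest-rank** percentile (the value at rank
`ceiling(p/100·N)`), which is reproducible across platforms, and the label
rules are **strict**: elinc above the 95th percentile, canonical below the
5th. Under an exchangeable null (both marks identically distributed) each
confident class is assigned at close to its nominal 5% rate; discreteness
of Poisson-valued ratios plus the strict inequalities bias the realized
rate slightly below nominal, well within binomial noise at n = 2000.

One behaviour worth understanding: when the input universe consists of two
large, strongly separated classes, the independent-shuffle null *re-creates*
the extreme ratios by cross-pairing (an elinc-like me1 with a canonical-like
me3), so the labeled fraction saturates near the tail mass regardless of
effect size. The permutation test is informative in the realistic regime —
a mostly exchangeable background with a minority of genuinely
enhancer-marked transcripts — and the test suite exercises it there (1000
background transcripts + 50 planted; recovery of the planted subset is
essentially complete). This is a property of the test itself, not an
implementation artifact.

## Features

One column per (region, assay):

* **Coverage ratio** (histone marks, TFs, CpG islands, repeat classes):
  the fraction of region bases overlapped by ≥ 1 track interval. Depth is
  deliberately ignored — the statistic is a base fraction, invariant to how
  a track is segmented, bounded in [0, 1], and directly comparable across
  assays with different library sizes. bedGraph segments with value ≥ 1 are
  treated as covered. TF features use read-interval coverage (peak calls
  work identically if supplied as intervals).
* **Mean β** (DNA methylation): arithmetic mean of per-position β values in
  the region; a region with no measured position is imputed to 0 and
  counted in a message. Imputing 0 (rather than dropping rows) keeps the
  matrix complete; methylation-free regions are genuinely unmethylated or
  unassayed, and at ESC-like probe densities the imputation rate is low.

Read counting uses a ≥ 1 bp overlap rule — the simplest deterministic
choice. Exon structure is carried on transcripts but unused: every feature
is interval-based over the TSS window or the full body span.

## The regularized model

Labels are coded y = +1 (elinc) / −1 (canonical) — inferred from the
sign-based classification rule — and the solver minimizes

$$\frac{1}{2n}\sum_i (y_i - \beta_0 - x_i^\top\beta)^2 +
  \lambda\sum_j\left[\tfrac{1-\alpha}{2}\beta_j^2 + \alpha|\beta_j|\right]$$

by cyclical coordinate descent. The `1/(2n)` scaling is the common
coordinate-descent convention and makes λ comparable across sample sizes;
consequently λ values are on that conventional scale. Numerical details:

* Columns are standardized to zero mean and unit 1/n-variance during
  fitting; the intercept is unpenalized; coefficients are reported on the
  original feature scale. A zero-variance column is an error (a constant
  feature carries no class information and breaks standardization).
* The coordinate update is the soft-threshold step
  `β_j ← S(z_j, λα) / (1 + λ(1−α))`, implemented in compiled code with
  Gram-matrix (covariance) updates: iterates are identical to residual-based
  updates at O(p) per coordinate instead of O(n).
* Convergence: largest standardized-coefficient update below `tol = 1e-7`
  per full sweep; non-convergence at `max_iter` raises a condition carrying
  the last iterate. The objective is non-increasing across sweeps (asserted
  in tests via the `trace` option).
* λ path: 100 points log-spaced from λ_max (the smallest λ zeroing all
  coefficients at the given α; for α < 0.001 the grid uses the α = 0.001
  convention) down by a factor of 1e-4, fit with warm starts.
* Cross-validation: folds are stratified by class (with a two-to-one class
  imbalance at realistic scale, unstratified folds risk single-class
  validation sets); the fold seed is a mandatory argument; the chosen λ
  minimizes mean CV MSE, ties broken toward the larger (sparser) λ. α is
  selected by comparing the best CV MSE across a grid under identical fold
  assignments, ties broken toward the larger (sparser) α.
* A score of exactly 0 classifies as `indeterminate`: the decision rule is
  defined by strict inequalities, and forcing a class at the boundary would
  be arbitrary.

The published seven-feature model (intercept 2.0860; +5.79 TSS_DNAme,
+3.16 TSS_H3K4me1, +0.53 Body_DNAme, +0.46 Body_H3K122ac, −5.17
Body_H3K36me3, −4.13 TSS_H3K9ac, −0.87 TSS_H3K4me3) is provided as a fixed
`regnet` object; a unit step in any feature changes the score by exactly
its coefficient, which is how the per-feature contribution rates are
reported. The λ and CV-MSE values attached to the original fit depend on
the mouse ESC datasets it was trained on and on a different software λ
scale, and are not reproduced here.

## Evaluation

ROC and PR curves sweep thresholds over distinct scores. Ties in scores
receive half credit (midranks), so the trapezoid ROC AUC equals the
Mann–Whitney statistic `P(s⁺ > s⁻) + ½P(tie)` — this is also the oracle the
tests check against by brute-force pair counting. PR AUC uses step-wise
interpolation. Cross-validated metrics are computed on out-of-fold scores
pooled across folds; accuracy uses the sign rule (score > 0 ⇒ elinc, with
0 counted as a negative prediction so confusion counts always sum to n).

## External validation

* **Overlap labels:** a transcript covering strictly more than half of an
  enhancer (promoter) element is labeled elinc (canonical); a transcript
  qualifying for both is a `conflict` and excluded from test sets — the
  neutral choice when the annotation evidence is contradictory. The
  fraction is of the *annotation element's* length.
* **Chromatin-state randomization:** the observed count of transcripts
  covered over 0.3 of their length (transcript-fraction reading of the
  threshold, strict inequality) is compared to a null where each transcript
  is replaced by a same-length interval placed uniformly on its own
  chromosome; placements are constrained to fit, matching the
  "length-matched random regions" design. The p-value is the add-one
  empirical `(1 + #{null ≥ obs}) / (1 + n_perm)`, never exactly 0 and
  super-uniform under the null.

## Synthetic data

The generator emulates the statistical structure the classifier assumes:

* Non-overlapping transcripts (2–6 kb) slotted along toy chromosomes,
  random strand, log-normal FPKM.
* For each (region, assay), a per-transcript coverage fraction drawn from a
  Beta distribution — mean 0.8 in the enriched class vs 0.2 in the other
  for the seven informative (region, assay) pairs (directions follow the
  published coefficient signs), 0.5 for the paired uninformative regions
  and for noise assays; concentration 20 throughout. The fraction is
  realized as a single contiguous covered interval, which makes the
  realized coverage ratio exact up to 1 bp rounding.
* DNA methylation as probes every 100 bp carrying the region's drawn β.
* H3K4me1/H3K4me3 read intervals in the TSS window with Poisson depths
  100/25 for elincRNAs and 25/100 for canonical — planted count ratios of
  about 4 and ¼, comparable to the ratio ≥ 2 / ≤ 0.5 regimes seen in
  confident real sets without being degenerate.

What it does **not** emulate: fragmented/multi-modal coverage within a
region, read-level noise (GC bias, mappability), correlated assays,
isoform structure, or a realistic mixture of ambiguous transcripts.
Passing tests therefore demonstrate that the machinery recovers planted
structure under its own assumptions, not performance on real chromatin
data.

Default study conditions for the end-to-end recovery check: 200 transcripts
per class, 7 informative features, 5 noise assays (10 noise columns),
α grid {0, 0.5, 1}, 10-fold CV. Calibration checks use 2000 transcripts
with Poisson(50) counts and 10,000 permutation rounds; randomization checks
use tens of transcripts and 2000 rounds — sizes at which every property is
measurable in seconds on a single core.

## Known limitations

* The coverage-ratio reading of "signal in a region" discards depth; very
  broad, shallow domains and sharp, tall peaks of equal footprint are
  indistinguishable.
* The permutation labeler's pooled null assumes transcripts are
  exchangeable after the signal filter; strong library-size or
  TSS-accessibility covariates would violate this.
* The linear sign rule yields no calibrated class probability.
* Leave-one-out requests (`k = n`) reuse the stratified cycling assignment,
  giving ≤ 2-sample folds rather than exact LOO; pooled scores are
  unaffected.
* Real-data scale results (transcript inventories, accuracies near 0.99)
  depend on the underlying mouse ESC datasets and are outside what the
  synthetic conditions can or should reproduce.
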