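---
title: "Consensus gene selection for two-group expression matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus gene selection for two-group expression matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triselect)
```

## Overview

`triselect` addresses a standard design in expression profiling: a
probe-by-sample matrix of log-scale intensities (thousands of probes,
a few dozen samples) and a binary phenotype. Its output is a small
*consensus panel* of probes nominated simultaneously by three feature
selection algorithms of very different character, plus a cross-validated
benchmark of how well that panel classifies the samples. The guiding idea
is that an agreement between a margin-based wrapper (SVM-RFE), a
rank-statistic filter (ROC/pAUC) and an all-relevant embedded method
(shadow-attribute selection over random forests) is much harder for a
noise probe to achieve than a high score in any single method.

This vignette documents the model and procedure, the parameters that
matter, the numerical conventions, and what the synthetic benchmark does
and does not demonstrate.

## The selection procedure

Given an aligned pair `(M, Y)` — `M` a probes × samples matrix, `Y` a 0/1
vector (1 = case) — `select_features()` runs:

1. **SVM-RFE.** A linear soft-margin SVM is trained on all surviving
   (standardized) features; each feature's ranking criterion is the
   squared component of the primal weight vector, `c_i = w_i²`; the
   lowest-criterion features are eliminated and the loop repeats. The
   final ranking is the reverse elimination order. The linear kernel is a
   requirement of the criterion, not a tuning choice: only a linear
   machine has a primal weight per feature. The cost parameter defaults
   to 1 and is deliberately not tuned — RFE rankings are insensitive to
   cost on standardized expression data, and nested tuning would multiply
   runtime by an order of magnitude.
2. **ROC ranking.** Each probe is scored as a univariate classifier by
   the area under its empirical ROC curve (equivalently the normalized
   Mann–Whitney statistic, ties counting one half), or by the partial
   area below a false-positive-rate bound `t0`. Ranking is two-sided by
   default — a probe with AUC 0.1 separates the groups exactly as well as
   one with AUC 0.9 — via `max(AUC, 1 − AUC)` (for pAUC, the larger of
   the two class orientations). `t0` defaults to 0.1, a conventional
   "small false positive rate"; `--one-sided` restores the raw
   orientation.
3. **Shadow-attribute selection.** Each iteration permutes every
   still-undecided feature across samples to form shadow attributes,
   trains a random forest on real + shadow features, and credits a "hit"
   to a real feature whose importance Z-score beats the best shadow.
   Accumulated hits are tested against Binomial(n, ½), two-sided, with
   Bonferroni correction across the still-undecided features; clear
   winners are *confirmed*, clear losers *rejected*, the rest remain
   *tentative* (they are reported as such, never forced). We use the
   forest's scaled permutation importance as the Z-score; it differs from
   mean/SD-over-trees by the constant factor √n_trees, which cancels in
   every real-versus-shadow comparison. Defaults: 500 trees, at most 100
   iterations, α = 0.05.
4. **Moderated-t gate.** The SVM-RFE and ROC rankings are cut to their
   top `k` probes (default `k = ceiling(0.0366 × p)`, the ratio of a
   top-1,000 cut on a 27,336-probe array); each top-k set is then gated
   by requiring `|logFC| > 2` and adjusted `p < 0.01` under the moderated
   t-test (below). The gate removes top-ranked probes whose ranking is
   not backed by a significant mean shift. `--no-gate` disables it.
5. **Intersection.** The consensus panel is the intersection of the gated
   SVM-RFE set, the gated ROC set and the confirmed set of the shadow
   selector, ordered by matrix probe order. An empty intersection is a
   valid, prominently logged result.

### The moderated t-test

For probe *g* with pooled two-sample residual variance `s²_g` on
`d = n − 2` degrees of freedom, the empirical-Bayes model treats the
true variances as drawn from a scaled inverse-χ² prior with parameters
`(d₀, s₀²)`, estimated by the method of moments on `log s²_g`: the excess
of `var(log s²)` over `trigamma(d/2)` identifies `d₀` through trigamma
inversion (Newton iteration), and `mean(log s²)` then identifies `s₀²`
through the digamma correction. The posterior variance
`s̃²_g = (d₀s₀² + d s²_g)/(d₀ + d)` replaces `s²_g` in the t statistic,
which gains `d₀` degrees of freedom (`d₀ + d`, capped at 10⁶ when the
moment equations put `d₀ = ∞`, i.e. when the observed log-variance spread
is no larger than the χ² sampling spread). Setting `prior_df = 0`
recovers the classical pooled t exactly; the unit tests verify both that
identity and agreement of `(d₀, s₀², t, p)` with an independent reference
implementation of the same estimator.

**Multiplicity family.** The gate tests only the `k` candidates each
ranker nominated, so the adjustment (Bonferroni by default, BH
selectable) is computed *within each gated set*; the variance prior, by
contrast, is estimated from all probes, where the moment equations are
well conditioned. Adjusting over the whole array instead would test a
family of hypotheses nobody nominated and makes the gate's α
interpretation inconsistent with its candidate set.

### Cross-validated evaluation

`evaluate_all()` benchmarks six standard classifiers — linear-kernel SVM
(cost 1), 500-tree random forest, Gaussian naive Bayes, a single-hidden-
layer neural network (8 units, one replicate), 5-nearest-neighbours on
standardized Euclidean distance, and unpenalized logistic regression —
on the selected panel under stratified k-fold cross-validation (default
k = 10). Folds are dealt round-robin within class, with the dealing
pointer carried across classes, so fold sizes differ by at most one and
per-class counts by at most one; with 26 cases and 18 controls the folds
have 4–5 samples, 2–3 cases and 1–2 controls each. Plain random
partitioning would regularly produce control-free folds at these sizes.
Standardization parameters are learned on the training folds only.

Predictions are pooled across folds into one confusion matrix before
computing Sensitivity, Specificity, Accuracy and F1. Averaging per-fold
metrics instead (available via `pool = FALSE`) is unstable when a fold
holds one or two controls — a single misclassified control then
contributes a specificity of 0 or 1 to the average. A metric whose
denominator is zero is reported as `NA`, never as 0. All models share the
same folds, so table differences reflect the learners alone.

## The synthetic generator

`simulate_dataset()` emulates the data the pipeline is designed for: a
log-intensity matrix for `n_case + n_control` samples where probe *g* is
Normal(`baseline_mean`, σ_g²) with σ_g ~ Uniform(`baseline_sd_range`),
and a planted subset of `n_informative` probes whose case-group mean is
shifted by `effect · σ_g`, with alternating sign so both over- and
under-expression occur. The effect is expressed in per-probe SD units, so
it is scale-free: the theoretical two-sided AUC of a planted probe is
Φ(effect/√2) regardless of σ_g. Optional equicorrelated blocks among
noise probes and a heavier-tailed t-noise toggle support robustness
checks.

Defaults define the study conditions used throughout the tests:
26 cases / 18 controls; 2,000 probes at "study-shaped" scale (a
desk-scale stand-in for a ~27k-probe array; full scale is reachable
through `n_probes`); 8 planted probes at effect 2 SD; baseline mean 7
log-units; `baseline_sd_range = (1.5, 3)`. The SD range was chosen so
that a 2-SD shift produces |logFC| between 3 and 6 — the magnitude regime
reported for top hits in the kind of study this emulates — and therefore
clears the logFC > 2 gate with margin; smaller per-probe SDs would make
the gate, not the rankers, the binding constraint at this effect size.

What passing on synthetic data does **not** show: real arrays have
probe-level correlation structure, batch effects, non-Gaussian tails and
intensity-dependent variance that the generator (by default) omits.
Recovery of all planted probes here demonstrates correctness of the
machinery and calibration of the nulls, not expected sensitivity on any
particular real dataset.

## Numerical conventions and degenerate inputs

* **Variance filter**: threshold is the type-7 empirical quantile of the
  per-probe variances; probes exactly at the threshold are retained.
  The fraction removed defaults to 0.5. Filtering ignores labels.
* **Tie-breaking** is everywhere stable by input probe order: ROC score
  ties keep matrix order, RFE criterion ties eliminate the lower column
  index first, constant matrices rank in input order.
* **AUC with ties** uses midranks (ties count ½), which equals the
  trapezoidal area through the tied, sloped ROC segments; `pAUC(t0)`
  linearly interpolates the ROC polygon at `t0` and equals the full AUC
  at `t0 = 1`.
* **Constant features**: the shadow selector excludes zero-variance
  features from the forest (they can never beat a shadow; their Z is 0),
  which also avoids a degenerate all-constant forest; RFE standardizes
  them to 0 so they are eliminated first.
* **Missing values** are a hard load error; the rankers assume complete
  matrices. Non-finite values are rejected by RFE with a data error.
* **Determinism**: every stochastic operation takes an explicit seed and
  restores the caller's RNG state (`withr::with_seed`); reruns are
  byte-identical, which the pipeline tests assert on the written
  artifacts.

## Problem sizes used in the test suite

The suite exercises the full study-shaped design (2,000 × 44, 8 planted,
effect 2 SD) once for ranker-recovery and CV checks, and uses smaller
matrices elsewhere so each property is tested at the size that isolates
it: AUC/pAUC against exhaustive oracles at ≤ 20 samples per class
(500 random instances); moderated-t calibration at 200 null probes with
10 samples per group; shadow-selector null behaviour at 60 probes × 44
samples over 20 label permutations; consensus null behaviour at 250
probes × 44 samples over 20 seeds (median panel size 0). These sizes are
the package's choices for sharp, repeatable checks; the null results are
insensitive to matrix width.

## Known limitations

* Two groups only; no paired designs, covariates or multi-class
  extension. The gate's design matrix is the two-group contrast.
* SVM-RFE with chunked elimination (10% per pass above 500 surviving
  features) can permute ranks far from the top relative to strict
  one-at-a-time elimination; top ranks are produced one-at-a-time.
* The shadow selector's decisions depend on forest variability; two
  seeds can disagree on borderline (tentative) probes. Confirmed and
  rejected tiers are stable in practice and identical under a fixed
  seed.
* The moderated-t moment estimator assumes a common residual df across
  probes (true for complete two-group matrices) and no zero-variance
  probes among the majority (zero-variance probes are excluded from the
  moment fit and fully shrunk).
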