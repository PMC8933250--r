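---
title: "Connectome-based predictive modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Connectome-based predictive modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cpmr)
```

## The model

Connectome-based predictive modeling (CPM) predicts a behavioral severity
score — here motivated by motor-impairment ratings in Parkinson's disease,
which live on a bounded, right-skewed scale — from resting-state functional
connectivity. Each subject contributes a square symmetric matrix of
Fisher-z-transformed Pearson correlations between the mean time series of
atlas nodes (268 nodes, hence 35,778 candidate connections, in the canonical
parcellation this package's defaults assume). The pipeline has three stages:

1. **Candidate selection.** For every edge, the strength across training
   subjects is correlated with the score by *partial Spearman correlation*,
   controlling nuisance covariates (age, disease duration, gender, and
   optionally mean head motion). Rank correlation is used throughout because
   severity scores of this kind are not normally distributed; the package
   treats this as a fixed design decision rather than re-testing normality.
   Edges with `p < p_threshold` join the positive (strength indexes higher
   severity) or negative candidate set by the sign of the correlation.
2. **Consensus.** Selection runs once per leave-one-out fold; only edges
   selected in *every* fold — the consensus connections — survive. This is
   an intersection, so the consensus is a subset of each fold's candidates.
3. **The linear model.** Each subject's positive and negative summed
   strengths `x1`, `x2` feed an ordinary least-squares fit
   `predicted = a1 * x1 + a2 * x2 + b`. Performance is summarized by the
   Spearman correlation `r_true` between predicted and observed scores and
   by the mean squared error.

An important caveat the package documents prominently: the headline model's
evaluation is **in-sample**. The consensus masks come from cross-validation,
but the final coefficients are fit on all training subjects and evaluated on
those same subjects. The honest out-of-sample counterpart is the per-fold
variant (`cpm_variant(..., variant = "per_fold")`), in which each held-out
subject is predicted by a model fit without it; its `r_true` is
systematically lower, and the package's simulations confirm that ordering.

## Tunable parameters

* `p_threshold` — the selection cutoff, in `(0, 0.05]`; default `0.009`.
  `cpm_optimize_threshold()` scans the conventional grid `.001–.050` in
  steps of `.001` (50 values) and returns the cutoff maximizing in-sample
  `r_true`; ties resolve to the *smaller* (more stringent) threshold.
  Because the criterion is in-sample, looser thresholds admit more edges
  and can inflate apparent performance — another reason to read the
  per-fold variant alongside.
* `fd_threshold` (`scrub()`) — framewise-displacement censoring, default
  0.2 mm, with volumes *at or above* the threshold removed.
* `min_volumes` — minimum surviving volumes before a subject is flagged for
  exclusion; default 120 (four minutes of data at a 2 s repetition time).
  Mean FD is reported over all input volumes, pre-scrub.
* `n_perm` — permutation count, default 1000.

## Permutation inference

`cpm_permutation()` shuffles the score vector across subjects and re-runs
the *entire* consensus-selection-and-fit pipeline per shuffle; covariate and
matrix rows stay aligned with their subjects. The p value is the strict
fraction of permuted runs whose r meets or exceeds the observed `r_true` —
a plain `count / n_perm` with no +1 smoothing, so 0 is attainable.
Permutation iterations with an empty consensus score r = −1 so the
denominator stays fixed.

Two statistical properties deserve emphasis:

* **Calibration requires an exchangeable score.** Shuffling only the scores
  is exact when the score is independent of the covariates. When covariates
  correlate with the score (as age and duration do here by design), the
  permuted datasets are not distributionally equivalent to the observed one
  and the test becomes *conservative*: selection on permuted scores is not
  handicapped by the covariate-aligned variance, so permuted r values run
  high. The package's calibration suite therefore uses null cohorts whose
  covariates are uncoupled from the score (while still flowing through the
  partial-correlation machinery); there the rejection rate at α = .05 sits
  inside the binomial confidence band.
* **Power collapses at full dimensionality with small n.** With 35,778
  candidate edges, 47 subjects and `p < .009`, a *permuted* run still
  selects on the order of a hundred spurious consensus edges, and the
  in-sample fit of their sums is itself highly correlated with the shuffled
  scores (selection bias). The null distribution of in-sample r then sits
  near the ceiling and the test cannot distinguish a genuinely predictive
  model from it. At smaller dimensionality (hundreds of edges), permuted
  consensus sets are typically empty and the test has power. The package's
  permutation demonstrations are therefore run at the 40-node scale; the
  full-scale pipeline is exercised for fitting, recovery, validation and
  anatomy, where the planted ground truth provides the verification signal.

## Model comparison

`steiger_z()` implements the dependent-correlation Z test for two
correlations sharing one variable (the observed score), using the
Fisher-transformed difference scaled by an asymptotic standard error whose
covariance term evaluates at the mean of the two compared correlations. The
three input correlations must form a positive semi-definite correlation
matrix — any triple computed from real data does. `cpm_compare()` wires this
to two models' prediction vectors with all correlations computed as
Spearman, matching the evaluation metric; identical predictions short-circuit
to z = 0. Lesion comparisons apply a Bonferroni family of 14 (seven
networks, two cohorts).

## Network anatomy

Nodes map to seven canonical functional networks (frontoparietal 63,
default mode 20, motor 50, visual 45, limbic 30, basal ganglia 29,
cerebellum 31 — summing to 268). `seven_network_partition()` ships a
*synthetic block assignment* carrying only these sizes; real analyses should
supply their own partition file.

Conventions, chosen where the procedure admits more than one reading:

* A network's *contribution* counts model edges **incident** to it, so a
  between-network edge credits both endpoints' networks. Normalization
  divides by the possible edges incident to the network,
  `n_k (n_k − 1)/2 + n_k (N − n_k)`.
* Aggregate within- and between-network per-mille proportions **pool**
  counts over pooled possibles before dividing; an averaging mode over
  per-pair ratios is exposed as an option since either reading is
  defensible.
* Lesioned models reuse the full model's fixed threshold; no
  re-optimization after node removal.

## The synthetic cohort generator

Every downstream stage is verified against cohorts with planted structure,
generated as follows:

* **Score.** A latent standard Gaussian `z` per subject maps through a
  Gaussian copula onto a scaled Beta(2, 5) — right-skewed — on the clinical
  range 4–68.
* **Planted edges.** A planted edge's strength is
  `mu_e + beta * z + noise`, with the sign of `beta` set by the planted
  polarity. Because rank correlation is invariant to the monotone map from
  `z` to the score, the edge–score Spearman correlation has the closed form
  `(6/pi) * asin(r/2)` with `r = beta / sqrt(beta^2 + noise_sd^2)`;
  inverting gives `beta = noise_sd * r / sqrt(1 - r^2)` with
  `r = 2 * sin(pi * rho_s / 6)`, so the configured `effect_size` is the
  exact expected rank correlation — no numerical calibration loop is
  needed. All other edges are independent Gaussian noise around per-edge
  baselines.
* **Covariates.** Age and duration couple to the same latent through a
  Gaussian copula at configured rank correlations (defaults .404 and .527),
  then map onto realistic units (years; duration log-normal). Gender is an
  independent Bernoulli(½); clinical stage is an ordinal cut of a noisy
  copy of the latent; mean FD is log-normal and independent of the score.
* **Time series.** `generate_timeseries_cohort()` draws node signals from a
  latent-factor model (coupled node pairs share a factor, so a loading of 1
  yields correlation 1) and attaches an FD trace whose motion spikes reach
  the 0.2 mm censoring threshold at a configured per-volume rate.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: spatial dependence among edges (real
connectomes are strongly structured; here non-planted edges are
independent), temporal autocorrelation and physiological noise in the BOLD
signal, integer-valued clinical scores (scores are continuous, which keeps
ranks tie-free), scanner/site effects, and any medication-induced
reorganization of the validation cohort — validation cohorts share the
training population's structure, so transfer performance is optimistic
relative to the attenuation seen in clinically distinct samples.

## Numerical choices

* Correlations of magnitude 1 are clamped to `±(1 − 1e−7)` before `atanh`,
  with a warning.
* Selection thresholds are applied as equivalent critical values on the
  partial correlation (`|rho| > t_crit / sqrt(df + t_crit²)` with
  `df = n − 2 − k`), which is algebraically identical to `p < threshold`
  and avoids p-value evaluation in permutation loops.
* Leave-one-out ranks are derived from full-sample ranks by the exact
  shift identity when no ties are present (the general re-ranking path
  handles ties, e.g. binary gender among covariates, with average ranks).
* Degenerate cases: a constant summed-strength feature is dropped from the
  fit with a warning and reported with a zero coefficient; an all-empty
  consensus is an error in `cpm()` and the r = −1 convention inside
  permutations; partial correlations with no residual rank variance return
  0 with a warning; `cpm_evaluate()` returns `NA` correlation (with the MSE
  still computed) when a vector is constant.
* Selection decisions are exactly invariant to strictly increasing
  transforms of the score (everything is rank-based). The in-sample
  `r_true` of the *two-feature* model is not exactly invariant, because the
  refit can change the ratio `a1 / a2` and hence the rank order of
  predictions; single-feature variants are exactly invariant. The test
  suite asserts precisely these two statements.

## Problem sizes used in the verification suites

Simulation scales were chosen to make each property measurable at desk
scale: oracle equivalence on cohorts of ≤ 10 subjects and 6 nodes against a
brute-force reimplementation; permutation calibration on 200 null cohorts
of 47 subjects × 40 nodes with 200 permutations each; parameter recovery at
100 subjects × 30 nodes with rank-correlation effect .6 (consensus recall
and precision ≥ .8, held-out validation r ≥ .5, and the in-sample model
dominating the per-fold variant across 100 seeds); the full 268-node
pipeline is exercised end-to-end in the acceptance script.

## Limitations

The package starts from parcellated node time series or precomputed
matrices; voxel-level preprocessing, nuisance regression, filtering and
atlas construction are upstream and out of scope. Only leave-one-out
cross-validation is implemented (no k-fold variants), the predictive model
is the linear two-feature form (no regularization or nonlinear learners),
and feature selection is the correlation filter described above.
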