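---
title: "Methods: probabilistic sweet-spot mapping and its stability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic sweet-spot mapping and its stability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pssmapr)
library(dplyr)
```

## The problem

In deep brain stimulation (DBS) research, each tested stimulation setting
activates a volume of brain tissue (the VTA, a binary mask on a common
voxel grid) and is labeled with a clinician-rated symptom-improvement
score in percent. Aggregating many labeled VTAs and testing, voxel by
voxel, whether stimulation of that location is associated with improvement
above a clinically meaningful threshold yields a probabilistic stimulation
map; the voxels that survive testing and plausibility filters form the
*probabilistic sweet spot* (PSS).

Sweet spots are data-hungry: their location and extent move as patients
are added or as fewer stimulations per patient are available. `pssmapr`
quantifies that movement and estimates how many patients (`nPat`) and
stimulations per patient (`nStim`) are needed before the sweet spot's
geometry stops changing — a *stability boundary* over the
(`nPat`, `nStim`) plane.

## Voxel-wise statistics

At every tested voxel the sample is the set of improvement scores of the
stimulations whose VTA covers that voxel. The hypotheses are directional:
H0: improvement < θ versus H1: improvement ≥ θ, with θ = 50 a typical
rigidity threshold and θ = 75 a typical tremor threshold (both
config-exposed in `test_config()`). Three engines are provided:

* **WFDR** — one-sample, one-sided Wilcoxon signed-rank test with
  Benjamini–Hochberg FDR correction across the tested voxels; a voxel is
  significant when the corrected p < α (default 0.05). The signed-rank
  null is computed exactly (shift algorithm on doubled midranks, which
  handles the heavy ties of quantized scores exactly) for n ≤ 25 and by a
  tie-corrected normal approximation above.
* **WPERM** — the same voxel statistic, corrected by a permutation
  family-wise scheme: improvement scores are shuffled across all
  stimulations of the dataset (masks fixed), the standardized signed-rank
  statistic is recomputed everywhere, and the corrected p of a voxel is
  the proportion of permutations (the observed arrangement included)
  whose family-maximum statistic reaches the voxel's observed statistic.
  Default 200 permutations.
* **BAYES** — a directional Bayesian one-sample test: scores at a voxel
  are modeled as Normal(μ, σ²) with μ ~ Normal(θ, 25²) and
  σ ~ Half-Normal(25); the evidence is the directional Bayes factor
  (posterior odds of μ ≥ θ over prior odds), thresholded at BF ≥ 10.
  Because the prior on μ is centered at θ, the prior odds are 1 and the
  BF reduces to the posterior odds.

Significant voxels then pass two occurrence filters — at least 25% of the
patients must stimulate the voxel, and its stimulation count must reach
10% of the maximum of the stimulation occurrence map — and connected
components smaller than 1 mm³ are removed (6-connectivity by default;
18/26 selectable).

### Choices the literature leaves open

* *Permutation unit and correction family.* We permute scores across all
  stimulations of the dataset (not within patient) and use the
  max-statistic family-wise construction, the standard nonparametric FWE
  correction. The standardized statistic makes voxels with different
  per-voxel sample sizes comparable within a permutation.
* *Bayes-factor estimator.* With posterior draws available, the
  directional (posterior-odds over prior-odds) estimator is used rather
  than a Savage–Dickey density ratio: it is the natural estimator for a
  one-sided hypothesis pair and needs no density estimation at a point.
  When no draw falls below θ the BF is reported at the finite cap
  `2 × num_samples + 1`, which is seed-stable and above any practical
  evidence threshold.
* *Tested family.* Only voxels with at least `min_observations` (default
  5) usable observations are tested — for the Wilcoxon engines that
  counts non-zero differences from θ, since zero differences are
  discarded before ranking. Correcting over never-tested voxels would
  inflate the family size for no benefit, and 1–2-sample tests are
  meaningless.
* *Posterior sampler.* The per-voxel model is a two-parameter normal;
  its posterior is sampled by a conjugate Gibbs step for μ alternated
  with a Metropolis step on log σ, driven by per-voxel sufficient
  statistics and vectorised across voxels, so a whole map costs seconds.
  μ mixes perfectly (it is drawn from its exact conditional each
  iteration); a fixed-σ mode exists in which the draws are exact iid
  conjugate samples, used by the test suite to check the sampler against
  the closed form.

## Resampling scheme

`sampling_plan()` implements an additive, without-replacement design that
mimics a center accumulating patients: each chain starts from 4 random
patients and adds 2 at a time from the remaining pool, so subgroups are
nested within a chain; 10 chains by default, with the full cohort
appended once as the shared terminal point. Each patient subgroup is then
reduced to 4, 6, 8, 10, 12 stimulations per patient, three times. On a
36-patient cohort this yields 160 subgroup datasets plus the full cohort
(161) and 2415 datasets in total. Every dataset is regenerable in
isolation from the master seed and its key (a stable hash derives
per-key sub-seeds), so nothing needs to be stored. Stimulation subsets
are re-drawn independently at each chain level; whether the original
design nested them across sizes is not documented, and independence is
the weaker assumption.

## Geometric variability and stability

Sweet spots from successive sizes within a chain (4 vs 6 patients, 6 vs
8, …, largest subgroup vs full cohort) are compared with three percent
metrics: volume difference normalized by the larger volume, Dice overlap,
and centroid distance normalized by the larger equivalent-sphere diameter
`(6V/π)^{1/3}` (a rotation-invariant reading of "largest diameter" that
is stable for ragged voxel sets; a Feret-diameter option exists). All
stimulation-sampling cross pairs (3 × 3) are averaged within a chain,
then across chains, giving a curve per (method, metric, nStim) indexed at
the larger size of each pair. Conventions for empty sweet spots keep the
curves computable where a method returns very small volumes: two empty
volumes have volume difference 0 but undefined Dice; one empty volume
gives volume difference 100, Dice 0, and undefined centroid distance.
Undefined values are `NA`, never a substitute number, and are dropped
from averages.

The *stability point* of a curve is the earliest point after which every
later value stays within 5 percentage points (absolute, on the metric's
own percent scale) of the final full-cohort value. All trailing points
must qualify — the wording "after which the differences remained below
5%" is read as a persistence requirement, not a one-point test — and an
undefined trailing value vetoes stability, since an empty-sweet-spot tail
is evidence of instability. A point qualifying only at the last support
point does not count. Tightening the tolerance can only move the
stability point later, which the property tests verify.

## The stability boundary

Each curve point becomes a binary record: label 1 where `nPat` is at or
past the curve's stability point, 0 otherwise (all 0 when no stability
point exists). The total stimulation count `nPat × nStim` is the single
feature of a Bayesian logistic regression `P(stable) =
logistic(β₀ + β₁ · total)`, fitted per method for each metric and for all
metrics pooled. The feature is standardized internally; both
standardized-scale coefficients carry Normal(0, 10²) priors (weakly
informative — the source literature states none) and the posterior is
sampled by adaptive random-walk Metropolis initialised from the
maximum-likelihood fit.

For a draw with β₁ > 0 the 50% threshold is T = −β₀/β₁ and the minimum
stimulations per patient at `nPat` patients is `max(1, ceil(T/nPat))`
(ceiling because stimulations are integers, and conservative with respect
to stability). Draws with β₁ ≤ 0 admit no finite threshold; they are
censored at a configurable cap (default 100, beyond the probed range) and
their fraction is reported. The boundary curve reports the per-`nPat`
mean and 2.5/97.5 posterior percentiles of the per-draw minima over the
probe range 4–100 patients, plus `mean_cont`, the mean of the continuous
(pre-ceiling) minima, whose convex non-increasing shape is free of
ceiling granularity. With a censored tail capped at a large value the
mean can exceed the 97.5 percentile; the percentiles, not the mean,
carry the uncertainty statement. Model quality is assessed by a
stratified 70/30 train–test split with accuracy and F1 (positive class =
stable); stratification keeps small minority classes represented.

## What the synthetic cohorts emulate — and what they do not

No clinical VTA dataset is shipped or downloadable, so
`generate_cohort()` creates cohorts with the statistical structure the
analysis assumes:

* a ground-truth sweet-spot ellipsoid (default 3 × 3 × 4 mm semi-axes at
  the grid center) on a 32³ grid at 1 mm isotropic — desk-scale, yet
  large enough for the 14 mm trajectory span;
* VTAs as axis-aligned ellipsoids with radii `r = r0 + k√amplitude`
  (defaults r0 = 0.8 mm, k = 1.4), a monotone stand-in for
  electric-field-thresholded volumes without finite-element simulation;
* per-patient electrode trajectories jittered laterally around the
  target (sd 1.5 mm): the PD-like mode explores two parallel tracks
  2 mm apart spanning 14 mm in 1 mm steps with 12–22 stimulations per
  patient and amplitudes 0.2–3 in 0.2 steps; the ET-like mode places
  exactly 4 contact stimulations on one track;
* scores as a saturating monotone response of the overlap fraction ω of
  a VTA with the ground truth, `100 · min(1, ω/ω_sat)^γ`, plus Gaussian
  rating noise, clipped to [0, 100] and quantized to 12.5 (half-steps of
  the clinical 0/25/50/75/100 scale; continuous mode available).

The response parameters are mode-specific and were calibrated once, by
Monte-Carlo over the generator itself, so the marginal score
distributions land where the two clinical cohorts are described: PD-like
ω_sat = 0.30, γ = 0.80, noise sd 14 gives a wide distribution with mean
near 50; ET-like ω_sat = 0.80, γ = 1.10, noise sd 10 gives a
high-skewed distribution with mean near 70. A design alternative —
drawing scores directly from a target Beta distribution — was rejected
because it breaks the generative link between score and overlap (a VTA
with no overlap must be able to score 0 and tests rely on the spatial
signal being monotone).

What the generator does *not* emulate: patient-specific conductivity,
electric-field physics, electrode localisation error, atlas registration
error, per-patient score offsets (rater effects), or spatially
correlated noise. Passing tests therefore show that the pipeline's
statistics, geometry and boundary model behave correctly under a known
ground truth — not that any particular clinical cohort will reproduce
specific published stability points.

## Numerical choices and degenerate inputs

* Exact Wilcoxon null for n ≤ 25 (`exact_n` exposed), tie-corrected
  normal approximation with continuity correction above; all-zero
  differences return p = 1.
* The Bayes sampler works on centered sufficient statistics (the
  residual sum is computed as `ss0 + n(μ − x̄)²` with `ss0 ≥ 0`), keeps
  log σ floored at 10⁻³, and treats any non-finite acceptance ratio as a
  rejection; non-finite per-voxel results are flagged not-significant.
* Empty significance maps, empty sweet spots, and single-class stability
  records are legal inputs everywhere downstream; they propagate as
  empty volumes, `NA` metrics, and degenerate (not-existing) boundaries
  rather than errors.
* The pipeline recomputes rather than caches: every stage is
  deterministic given (config, seed), datasets regenerate from per-key
  hashed sub-seeds in milliseconds at these problem sizes, and
  recomputation keeps the run free of stale-state hazards.

## Problem sizes used by the shipped checks

The test suite and `scripts/acceptance.R` run the full sampling-plan
*counting* at study scale (36 patients, 2415 dataset keys — keys only,
no mapping), ground-truth recovery at full mapping scale (36 patients ×
12 stimulations on the 32³ grid with default test settings), the
boundary recovery on 255 records with 2000 posterior draws, and a
complete end-to-end pipeline scaled to 12 patients on a 16³ grid with
stimulation counts 4 and 6, two chains, three stimulation replicates,
50 permutations and 500/250 MCMC — sizes chosen so each stage still
exercises every code path at meaningful sample sizes.

## Known limitations

* The Wilcoxon permutation scheme and the Bayes-factor construction are
  reasonable standard readings of under-specified methods; other
  readings (within-patient permutation, Savage–Dickey) would change
  WPERM's severity and BAYES's evidence scale.
* The logistic boundary uses the total stimulation count as its only
  feature; cohorts where `nPat` and `nStim` act asymmetrically are not
  representable.
* Synthetic trajectories use a simple per-patient jitter model; the
  per-patient spatial covariance of real VTAs is unknown and the
  emulation makes no fidelity claim about it.
* Voxel-wise tests ignore covariates (age, disease duration) and
  laterality; hemispheres are assumed pooled upstream.

## A short tour

```{r tour, eval = FALSE}
cohort <- generate_cohort(pd_cohort_config(n_patients = 12, seed = 1))
pss <- extract_pss(cohort, test_config("BAYES", seed = 1))
pss

res <- run_pipeline(pipeline_config(
  cohort = pd_cohort_config(n_patients = 12, seed = 1),
  plan = sampling_plan(n_patient_reps = 2, stim_counts = c(4, 6),
                       n_stim_reps = 3, seed = 1),
  methods = "BAYES", seed = 1
))
autoplot(res$curves)
autoplot(res$boundaries)
tidy(res$fits$BAYES$all)
```
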