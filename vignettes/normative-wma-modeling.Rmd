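---
title: "Normative connectome-based modelling of working memory ability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative connectome-based modelling of working memory ability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmaconn)
```

## The modelling problem

Working memory deficits appear across many psychiatric diagnoses with
diagnosis-dependent severity. `wmaconn` implements a two-stage normative
strategy for studying this: first, learn the mapping from resting-state
functional connectivity (FC) to working memory ability (WMA) in healthy
individuals; second, apply that fixed normative map to independent cohorts —
healthy or diagnosed — and ask whether the *predicted* WMA reproduces
individual differences and group-level impairment, and which connections
carry the predicted impairment.

The package contains the whole chain as testable units: FC feature
extraction from voxel-level time series, behavioural plateau estimation,
sparse Bayesian regression, confound-controlled generalization statistics,
and per-connection decomposition of predicted group differences. A
synthetic-cohort generator with planted ground truth stands in for the
restricted clinical datasets, so every stage can be validated end to end.

## FC features

Nodes are the 18 networks of a whole-brain intrinsic-connectivity
parcellation, grouped into seven functional clusters. Two feature types are
used, in a fixed canonical order (18 within-network features, then the 153
between-network pairs (i, j), i < j, lexicographic; 171 in total):

* **between-network FC** — Pearson correlation between network-mean time
  courses;
* **within-network FC** — the mean of all pairwise voxel correlations inside
  a network.

Raw correlations are used as features; no Fisher z-transform is applied
anywhere, and the within-network average is taken over raw r (an explicit
choice — averaging z-transformed r would differ in the third decimal at
typical values and is easy to bolt on for sensitivity analysis). Note an
aggregation property: within-network features are invariant to any per-voxel
affine rescaling, but between-network features are not invariant to
rescaling a *single* voxel, because the network mean reweights; they are
invariant to per-voxel offsets and to a shared positive gain per network.

Preprocessing before correlation follows the order: nuisance regression of
the six realignment parameters plus mean gray-matter, white-matter and CSF
signals (with intercept) on the full series, then motion scrubbing, then FC.
Framewise displacement uses the Power-style sum of absolute backward
differences, rotations converted to arc length at a 50 mm head radius;
frames with FD > 0.5 mm are removed (neighbours retained), and subjects
losing more than 40% of frames are flagged for exclusion. An ideal
(FFT-mask) band-pass of 0.009–0.08 Hz is available for
high-temporal-resolution acquisitions, where it suppresses cardiac-band
power near 0.3 Hz; it is off in the default profile because the standard
2 s-TR pipeline does not include it.

Test–retest reliability of each feature is summarized by the one-way
random-effects ICC, `(MS_b - MS_w) / (MS_b + (k - 1) MS_w)` with k the
number of sessions; negative values are reported as zero, which is why
ICC summaries of weakly reliable features pile up at 0.

## Behavioural target

WMA is the plateau of a letter 3-back learning curve: per-session d-prime
(`qnorm(hit rate) - qnorm(false-alarm rate)`, extreme rates clipped to the
1/(2N) rule), smoothed with a five-session centred moving average whose
window shrinks symmetrically at the edges (this preserves linear trends
everywhere), then fitted with the inverse curve `y = a - b/x`. Because the
model is linear in 1/x, the fit is exact least squares by linear
regression — deterministic, no iterative optimizer. The plateau `a` is the
WMA estimate.

Fitting the *smoothed* trace is a declared choice. Smoothing leaves the
plateau nearly untouched but biases the speed parameter `b` slightly (the
window average of `1/x` exceeds `1/x` at early sessions); the unbiasedness
checks in the test suite therefore fit raw noisy curves, while the
`wma_from_sessions()` wrapper reproduces the smoothed pipeline.

## Sparse Bayesian regression (ARD)

The normative map is `y = intercept + X w + e` with an automatic relevance
determination prior: each weight has its own Gaussian precision, optimised
together with the noise precision by EM/variational updates of the log
marginal likelihood. Features and target are z-scored internally; returned
weights are on the original scale, and the standardization round-trips to
1e-10. Irrelevant features see their precision diverge and are pruned at
1e8; convergence is declared at a relative evidence change below 1e-8
(cap 5000 iterations). With the default flat hyperpriors the updates are
exact EM steps, so the stored free-energy trace is non-decreasing — a
property the tests assert. The noise-precision update is damped (at most
doubling per iteration); this is a generalized-EM partial step, preserving
monotonicity while preventing an early jump to an interpolating solution on
near-noiseless data.

Two practical regimes matter:

* **Recoverable regime.** With k planted connections among p = 171 features,
  exact support recovery needs roughly n ≳ k·log(p/k) subjects. Inside it
  (e.g. k = 16 at n = 100, or k = 8 at n = 50) the fit recovers the exact
  support with weight errors below 1e-3 on noiseless data and leave-one-out
  R² of 1.0.
* **Phase boundary.** Right at the threshold (k = 16 near n ≈ 50), ARD — like
  any sparse recovery method — converges to interpolating local optima on a
  minority of datasets. This is a property of the estimation problem, not of
  the implementation; users with small cohorts should expect selected
  supports to vary under resampling.

The number of selected connections is data-dependent and is reported as
whatever emerges; nothing forces a particular support size. Per-connection
contribution ratios are defined as the training mean of `w_i x_i` divided by
the summed means over the support, ×100; they are signed and sum to 100 up
to rounding. This normalization is declared, not claimed identical to every
published variant.

## Generalization statistics

Applied to an independent cohort, predictions are compared with measured
scores by partial correlation (Pearson, or Spearman as rank-then-residualize)
controlling the stated confounds. Significance uses label-permutation nulls
that *preserve the confound links*: only the prediction vector is shuffled,
the confounds stay attached to their subjects. P-values are two-sided with
the add-one estimator; when the sample is small enough the null is
enumerated exhaustively and the sampled and exhaustive procedures coincide
by construction. Group impairment uses pooled-variance t-tests per diagnosis
against matched controls (matching the conventional degrees of freedom,
e.g. t with 116 df for 58 + 60 subjects), Bonferroni-adjusted; effect sizes
are Hedges' g with the small-sample correction `J = 1 - 3/(4(n1+n2)-9)` and
a large-sample CI `g ± 1.96·sqrt((n1+n2)/(n1·n2) + g²/(2(n1+n2-2)))`.
Diagnosis-wise Z-scores of predicted WMA (deviation from same-site controls,
divided by the control SD) feed a one-way ANOVA with a non-gating Bartlett
report and Holm step-down post-hoc tests. Comparing two dependent partial
correlations (two outcome measures sharing the prediction) has no canonical
test; the package uses a subject-level bootstrap of the difference, a
declared substitute rather than a reconstruction of any particular method.

## Impairment decomposition

To attribute predicted group impairment to connections, control FC
distributions are first aligned per connection onto the training cohort's
distribution by the linear map `x' = (x - mu_src)/sd_src · sd_ref + mu_ref`,
with source moments estimated from the *controls* and the identical map
applied to patients. Then, for each patient p and selected connection i:

* **D-score**: `D_ip = w_i x_ip - mean_c(w_i x_ic)` — the weighted-FC
  deviation from the control mean. Because the model is a linear weighted
  summation, `sum_i D_ip` equals the patient's predicted-WMA deviation from
  the control mean exactly (intercepts cancel); the tests assert this to
  1e-10 and the acceptance script recomputes it.
* **Z-score**: `Z_ip = D_ip / SD_c(w_i x_ic)`; the controls' own Z-scores are
  exactly standardized per connection.

Because Z variances are heterogeneous across diagnoses and connections,
diagnosis and diagnosis × connection effects are tested by permutation on a
mixed two-way decomposition (diagnosis between subjects, connection within).
The main-effect null permutes whole subjects' diagnosis labels (rows intact;
this statistic depends only on subject means, which keeps 10,000 shuffles
cheap). The interaction null additionally shuffles connection labels; the
published description is ambiguous about whether that shuffle is per subject
or global, so the default permutes independently within each subject and a
flag (`interaction_scheme = "global"`) exposes the other reading. Defaults
are 10,000 shuffles for main/pairwise effects and 100,000 for the
interaction; both are parameters, and the examples here use reduced counts.
Per-connection screening uses tie-corrected Kruskal–Wallis chi-squares with
Benjamini–Hochberg FDR at Q < 0.05; the chi-square distributions of model
vs non-model connections are compared by a two-sample Kolmogorov–Smirnov
test. Cluster summaries keep only connections bridging two different
clusters and add each bridging connection's diagnosis-mean D-score to both
endpoint clusters; clusters touching no selected bridging connection are
absent from the output (with the canonical atlas this can legitimately leave
e.g. the default-mode cluster out entirely).

## The synthetic-data generator

The generator emulates exactly the statistical structure the analysis
assumes, with planted ground truth:

* **FC**: per-subject vectors `fc = fc_mean + delta[diagnosis] + N(0,
  fc_sd² I)`, features independent, default `fc_sd = 0.1`, within-network
  means near 0.5 and between-network means in (-0.1, 0.3). Healthy controls
  have `delta = 0` and site-invariant population means; optional additive
  per-site offsets default to zero.
* **WMA**: `wma_true = intercept + w_true·fc + N(0, noise_sd²)` with 16
  nonzero weights by default; measured scores add Gaussian measurement
  noise. Confounds (fluid intelligence, composite cognition, age, head
  motion) are correlated with true WMA at configurable couplings (defaults
  0.5, 0.5, -0.2, -0.3) — enough structure for the partial-correlation and
  permutation machinery to have something to remove.
* **Effect sizes**: `delta_for_effect(gt, g)` shifts FC along
  `w/|w|²` so the true-WMA shift is exactly `g` control SDs, planting a
  population Hedges' g. The reference conditions use g = -0.68, -0.29,
  -0.16, 0.09 for SCZ/MDD/OCD/ASD at group sizes 58/60, 77/63, 46/47, 69/71.
* **Time series**: latent network factors with the covariance implied by the
  target between-network correlations (eigenvalue clipping at 1e-10 repairs
  non-PSD targets, with renormalized diagonal and a warning); within-network
  FC is set by the voxel noise-to-signal ratio via the closed form
  `r = var_signal/(var_signal + var_noise)`, which makes it analytically
  checkable. Motion traces are slow random walks with sustained displacement
  steps at chosen frames, so FD exceeds threshold at exactly those frames.
* **Learning curves**: `y = a - b/x` plus session noise; optional trial-level
  realization draws binomial hit/false-alarm counts at the equal-bias rates
  `pnorm(±y/2)` over 20 target / 40 non-target trials per session.

What the generator does *not* emulate — haemodynamics, spatial structure,
scanner artifacts beyond motion steps, non-Gaussian behavioural
distributions, and FC correlations *between* features — bounds what passing
tests show: they validate the estimation machinery under the model's own
assumptions, not robustness to real-data violations of them. Distributions
of behavioural scores and confounds are stand-ins, as no generative model
for them is published.

## Numerical choices and degenerate inputs

* Constant target `y`: empty support, intercept = mean(y). Zero-variance
  features: dropped with a warning, weight 0. Zero-variance network mean
  series: an error naming the network.
* Noise precision capped at 1e12 so noiseless problems stay well
  conditioned; posterior computed in the dual (n × n) form when more
  features than subjects are active.
* Permutation p-values: add-one `(1 + hits)/(1 + n_perm)` two-sided;
  exhaustive enumeration (exact tail fraction, no add-one) switches on
  automatically when n! does not exceed the shuffle budget.
* ICC is clamped at zero after the formula, never before.
* All generators and resampling functions take explicit integer seeds and
  are byte-reproducible; fitting itself is deterministic (equal-precision
  initialization).

## Problem sizes used in validation

The shipped tests and the acceptance script run entirely on synthetic data
at sizes chosen to make the checks sharp but quick: n = 100 cohorts for
support recovery (20 and 10 seed replicates), n = 50 for leave-one-out
closure, 100–200 seed replicates for effect-size recovery at the reference
group sizes, and 500 null replicates at 199 shuffles for type-I calibration
of the permutation tests. One caveat surfaced by this calibration work: at
the reference group sizes the sample Hedges' g has a standard error of
roughly 0.17–0.21, so the *full* ordering of four planted effect sizes
separated by as little as 0.13 reproduces in only about half of simulated
cohorts — recovering the ordering reliably is a property of the means across
replicates, not of a single study-sized sample.

## Worked example

```{r example, eval = FALSE}
atlas <- make_atlas()
gt <- ground_truth(atlas, n_nonzero = 16, noise_sd = 0.1, seed = 1)
train <- simulate_cohort(c(HC = 100), gt, atlas, seed = 2)

model <- fit_vbsr(train$fc, train$cohort$score)
print(model)
contribution_ratios(model, train$fc)

gt$delta$SCZ <- delta_for_effect(gt, -0.68)
clin <- simulate_cohort(c(HC = 60, SCZ = 58), gt, atlas, seed = 3)
pat <- clin$cohort$diagnosis == "SCZ"
al <- align_to_reference(clin$fc[!pat, ], clin$fc[pat, ], train$fc)
D <- d_scores(model, al$patients, al$controls)
Z <- z_scores(D, al$controls, model)
cluster_summed_dscores(D, atlas, rep("SCZ", sum(pat)))
```

## Known limitations

* FC features are generated independently per connection; real FC vectors
  have strong inter-feature correlation, which typically *helps* prediction
  but hurts support identifiability — synthetic support-recovery rates are
  optimistic in that specific sense.
* The ARD optimum is a local one near the sparse-recovery phase boundary
  (see above).
* The alignment transform matches first and second moments only; site
  effects that change FC shape are out of scope.
* The bootstrap comparison of dependent correlations and the two
  interaction-shuffle schemes are declared conventions where the field has
  no single standard.
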