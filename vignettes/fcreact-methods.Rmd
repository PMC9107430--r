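---
title: "Methods: connectivity reactivity to a levodopa challenge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: connectivity reactivity to a levodopa challenge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The scientific problem

Parkinsonian tremor responds to levodopa in some patients and barely at all
in others, and the dopaminergic system alone does not explain the split:
tremor is also under strong cholinergic influence. A pharmacological-challenge
resting-state fMRI design probes this directly: each patient is scanned
OFF medication (overnight withdrawal) and ON medication (about an hour after
a standard carbidopa/levodopa dose), motor symptoms are scored with UPDRS-III
in both states, and the question becomes *which subcortico-cortical
connections change differently under levodopa in dopamine-responsive versus
dopamine-resistant tremor patients*.

`fcreact` implements that analysis end to end on extracted ROI time series:

1. **Connectivity.** Pearson correlation between each subcortical seed time
   course and each cortical parcel time course, Fisher r-to-z transformed.
   Dopaminergic seeds are the bilateral thalamus, caudate, putamen and
   pallidum (8 ROIs); cholinergic seeds are the bilateral basal-forebrain
   BF123 and BF4 subdivisions (4 ROIs); the cortex is parcellated into 96
   labeled regions. This yields a 96 x 8 dopaminergic and a 96 x 4
   cholinergic matrix per subject-session — 768 + 384 = 1152 edges.
2. **Reactivity.** Each edge's functional reactivity is its connectivity
   change rate, `(z_ON - z_OFF) / |z_OFF|`; each patient's tremor
   responsiveness is the relative drop of the tremor sub-score
   (UPDRS-III items 20 + 21), `(tremor_OFF - tremor_ON) / tremor_OFF`.
3. **Phenotyping.** Patients at or above the cohort median of tremor
   responsiveness form the dopamine-responsive group; the rest are
   dopamine-resistant.
4. **Feature selection.** Stability selection: 500 resamples (80% per-class
   stratified subsampling without replacement) of an L1-penalized logistic
   regression of group on edge reactivities, each with an inner ten-fold
   cross-validation choosing the penalty; edges with a nonzero coefficient
   in at least 60% of resamples are declared discriminating.
5. **Inference.** Covariate-adjusted group comparisons of the selected
   edges' reactivity and session-wise connectivity, paired OFF–ON tests,
   a mixed-model group-by-status interaction, partial correlation of
   reactivity with tremor responsiveness, and network-level summaries
   against normal controls.

Because cohort data of this kind are not publicly deposited, the package
ships a synthetic cohort generator that reproduces the statistical structure
the analysis assumes, so that every stage is testable and the whole pipeline
can be exercised and audited without patient data.

## The synthetic cohort

`sim_params()` / `simulate_cohort()` emulate the study design: 24
dopamine-resistant and 28 dopamine-responsive tremor patients (optionally
93 controls), two sessions each, with ROI signals drawn from a zero-mean
multivariate Gaussian.

**Covariance structure.** All ROI pairs share a background correlation
(default `rho_background = 0.2`, an equicorrelation structure), and exactly
one planted edge is overridden: OFF-session correlation 0.16 in both groups,
ON-session correlation 0.17 for resistant and 0.01 for responsive patients
(the calibration targets for the headline basal-forebrain-to-parietal-
operculum edge in this study design). Equicorrelation is used rather than correlating
only the subcortico-cortical pairs because the latter cross-block structure
is severely indefinite at realistic correlation levels, while
equicorrelation is positive definite by construction for any
`rho > -1/(p-1)`; the extra cortico-cortical correlations it implies are
never consumed downstream. If a planted override ever leaves the matrix
non-positive-definite, the background is shrunk by 10% steps and the
offending pair reported if that fails.

**Scan length.** The acquisition protocol in this design fixes TR = 2 s but
scan duration is a free parameter. The default is `n_timepoints = 480`
volumes (16 min), a long-protocol choice made deliberately: the reactivity
statistic divides by `|z_OFF|`, so Fisher-z sampling noise
(SE = 1/sqrt(T-3)) in a baseline near 0.16 propagates multiplicatively.
At 480 volumes the planted edge's between-group reactivity separation is a
standardized d of about 1.5 — the design effect the selection stage is built
to detect — whereas at 200 volumes denominator noise drags it below d = 1
and recovery of the planted edge is no longer reliable. Short-scan regimes
can still be studied by setting `n_timepoints` explicitly.

**Clinical scores.** Baseline tremor sub-scores are rounded positive normal
(mean 4, sd 3, floor 1); per-group tremor change rates come from Beta
distributions moment-matched to means/SDs of 0.27/0.24 (resistant) and
0.92/0.13 (responsive), and `tremor_ON = round(tremor_OFF * (1 - change))`.
Rigidity, bradykinesia and residual items improve with group-independent
Beta change rates, so the group signal lives only in tremor, as observed.
Covariates are drawn from one shared distribution (age ~ N(60, 9),
education ~ N(9, 4.4) rounded at 0, 60% male), i.e. the groups are matched
by construction. Planted exclusions (lacunar infarction, ON status at
baseline, no baseline tremor, refused MRI, high head motion) add recruits
that carry flags and no imaging, which lets the subject-flow filters be
tested against the recruitment arithmetic (78 recruited, 5+2+10+4+5
excluded, 52 analyzed).

**What the generator does not emulate** — and hence what passing tests do
not establish about real data: hemodynamics and band-limited spectra
(time points are i.i.d. by default; an optional stationary AR(1) coefficient
adds temporal autocorrelation without moving the cross-sectional
covariance), head-motion and physiological artifacts, between-subject
variability in the *true* connectivity (all subjects in a group share one
population covariance), spatial structure among cortical parcels beyond
equicorrelation, and any missing-data mechanism.

## Numerical and procedural choices

- **Correlation clipping.** `edge_fc()` clips |r| at `1 - 1e-12` before
  `atanh`, so perfectly correlated (degenerate) pairs stay finite; the
  downstream change rates and model fits require finite values.
- **Reactivity denominator floor.** `|z_OFF|` is floored at `1e-6` and the
  affected entries are flagged rather than dropped: the selection design
  matrix must be complete across all 1152 edges, and extreme change rates
  are a documented feature of this statistic, not an error state.
- **Median convention.** For an even patient count the median is the
  midpoint of the two central order statistics; ties at the median go to
  the responsive group ("at or above the median").
- **Penalty grid.** 100 log-spaced values from `lambda_max` (the smallest
  penalty with an all-zero slope solution, computed in closed form from the
  standardized score at the null model) down to `0.001 * lambda_max`; the
  inner CV picks the grid value minimizing mean held-out binomial deviance
  (the `lambda.min` convention). Features are standardized within each
  training subsample, never globally, to avoid leakage. Coefficients below
  `1e-8` in magnitude are treated as exact zeros so that coordinate-descent
  dust never counts as a selection.
- **Subsample arithmetic.** Per class, `floor(0.8 * class_size)` subjects
  without replacement — 19 + 22 = 41 at the 24/28 group sizes.
- **Seed discipline.** Every stochastic component takes a seed; resampling
  iterations derive their seeds from the master seed in one documented draw
  (`sample.int(.Machine$integer.max, n_iter)`), so runs are bitwise
  reproducible and single iterations can be re-run in isolation. The
  pipeline derives per-stage streams from one master seed the same way.
- **Covariate adjustment.** Group comparisons include age, gender and
  education as linear-model covariates and test the group coefficient;
  the mixed model and the partial correlation instead residualize first and
  then fit — the two styles follow how each analysis is conventionally
  described, and they are not interchangeable in general; both are exposed
  and documented.
- **Normality gates.** Paired OFF–ON tests use a paired t-test when the
  paired differences pass a Lilliefors-style Kolmogorov–Smirnov test at
  alpha = 0.05 and a Wilcoxon signed-rank test otherwise; two-group
  continuous demographics gate the pooled t-test against the Mann–Whitney U
  the same way; samples too small or degenerate for the gate take the
  nonparametric branch. All-zero paired differences are reported as
  degenerate with p = 1.
- **Interaction test.** The group-by-status interaction comes from a linear
  mixed model with a per-subject random intercept, fit by REML, with a
  Satterthwaite-df t-test of the interaction coefficient. A Wald normal
  approximation was considered and rejected: at ~50 subjects it inflates
  the type-I error to about 0.059 (measured over 3000 null simulations),
  grazing the upper edge of the tolerance the test suite enforces, whereas
  the Satterthwaite reference restores ~0.05. Singular random-effects fits
  fall back to the exactly equivalent two-sample t-test on per-subject
  ON–OFF differences and say so in the output.
- **Replicate seeding.** Simulation loops (power and type-I estimates) run
  inside one continuous seeded RNG stream rather than re-seeding every
  replicate from drawn integers; integer-seeded replicate streams showed
  measurable overdispersion of rejection rates across seed batches.
- **Multiplicity.** Bonferroni exactly where the design applies it: the
  selected-edge comparisons (alpha/2 when two edges are selected) and the
  network-mean comparisons; everything else at raw alpha = 0.05.

## Calibration of the interaction power check

The test suite checks the interaction test's power on a calibrated
group-specific ON shift of -0.15 z with n = 24/28. Session-wise connectivity SDs reported in cohorts of this kind
(~0.17–0.28) are *total* cross-subject SDs;
the simulation decomposes them into a between-subject SD of 0.17 and an
occasion-level residual SD of 0.10. The per-subject ON–OFF difference then
has SD ~0.14, giving a noncentrality around 3.8 and power well above the
80% the suite requires. Treating the whole 0.2 as occasion-level residual
would instead give ~47% power — incompatible with the design's own
detection requirement — which is why the decomposition matters and is
stated here explicitly.

## Heavy tails make recovery cohort-dependent

The change-rate denominator is the magnitude of the OFF-session Fisher z.
With a planted baseline near 0.16 and sampling SD `1/sqrt(T-3)`, some
cohorts contain a subject whose planted-edge baseline lands near zero; that
subject's reactivity becomes an extreme outlier, inflates the feature's
standard deviation, and can suppress the edge's standardized group effect
enough that the selection stage misses it. Real cohorts show exactly these tails (reported reactivity SDs an
order of magnitude above the means), so this
is a property of the statistic, not an artifact of the generator. In
practice, recovery of the planted edge at the default calibration holds for
roughly half of simulated cohorts at 480 volumes and degrades at shorter
scans; the test suite exercises recovery on the package's canonical fixture
cohort, and the acceptance script reports the measured frequency and rank
for whatever seed it is given.

## Stability selection is not calibrated error control

The 60% frequency threshold is a fixed convention, not a family-wise error
rate. The suite's planted-recovery check passes with a wide margin, but its
companion null-safety check (no edge above 60% under permuted labels in at
least 90% of 20 replicate runs at 100 iterations) is *not* reliably
attainable with the minimum-deviance CV rule: a fixed permuted labeling
that by chance aligns with some feature at |t| around 3 gets that feature
selected consistently across 80% subsamples, because resamples of one
cohort are highly overlapping and the frequency statistic inherits any
within-cohort chance association. Replacing the CV rule with the
one-standard-error convention removes these false alarms but also drives
the planted edge's selection frequency to zero — it is no resolution. The
suite therefore reports the null-safety property honestly as measured;
users should read selection frequencies as a stability ranking within a
cohort, to be confirmed by the downstream covariate-adjusted tests, not as
calibrated significance.

## Problem sizes used by the test suite

Structural and property tests run on reduced cohorts (8–16 patients, 8–12
ROIs, 20–120 volumes); the recovery, null-safety and determinism checks run
on the full-size default cohort (52 patients, 108 ROIs, 480 volumes) with
100 resampling iterations, and the power/type-I simulations use 200/500
replicates. These sizes are the package's chosen verification conditions.

## Known limitations

- ROIs are abstract labeled columns; atlas handling, voxel extraction, and
  all MRI preprocessing are upstream and out of scope.
- The change-rate statistic is scale-free but heavy-tailed near zero
  baselines; analyses of edges with weak OFF connectivity should expect
  extreme values (the flags in `reactivity_table()` mark floored cases).
- Selection frequencies are cohort-conditional stability measures (see
  above), and the 60% cutoff is a convention.
- The generator's group covariances are homogeneous across subjects;
  real cohorts add between-subject connectivity variance that the
  synthetic power characteristics do not reflect.
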