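---
title: "Multiscale entropy mapping of BOLD signals: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiscale entropy mapping of BOLD signals: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Resting-state BOLD fluctuations are not noise: healthy neural signals
carry structure across a wide range of temporal scales, and
neurodegeneration is hypothesized to erode that structure. Sample
entropy quantifies the irregularity of a single series at one scale;
multiscale entropy (MSE) extends it by coarse-graining the series and
re-estimating entropy at each scale. The diagnostic signature is the
*shape* of the entropy-versus-scale curve: uncorrelated noise loses
entropy rapidly as it is averaged down, whereas signals with long-range
(1/f-like) correlations hold their entropy roughly constant. `boldmse`
implements this analysis voxelwise for 4-D fMRI volumes, the group
inference that sits on top of it, and a synthetic cohort generator that
makes the whole chain testable without access to any imaging archive.

## The estimator

**Coarse-graining.** At scale $l$, consecutive non-overlapping windows
of $l$ samples are averaged: $y_j^{(l)} = \frac{1}{l}
\sum_{i=(j-1)l+1}^{jl} x_i$, giving $\lfloor N/l \rfloor$ samples;
trailing remainder samples are discarded. Scale 1 is the original
series.

**Sample entropy.** For template length $m$ and tolerance $r$, matches
are counted over ordered pairs of templates $(i, j)$, $i \ne j$, with
both template start indices running over $1 \ldots N - m$ so that the
$(m+1)$-length extension always exists and the two counts are over the
same pair set. Distance is Chebyshev (max-norm); a componentwise
difference exactly equal to the tolerance counts as a match (inclusive
boundary — a deterministic tie-break that is immaterial for continuous
data). Self-matches are excluded. The estimate is
$SE = -\ln(A/B)$ with $A$ the $(m+1)$-length and $B$ the $m$-length
match count. When either count is zero the entropy is undefined and
propagates as a missing value — never substituted by 0 or a cap — and
such voxels are tallied per scale in the run log.

**Tolerance convention.** $r$ is expressed as a fraction of the
standard deviation of the *original, scale-1* series and is **not**
recomputed from coarse-grained series; because the preprocessing
standardizes every voxel to unit SD, the absolute tolerance inside the
pipeline equals $r$ itself. We use the population SD (divide by $N$)
both here and in the standardization step, so the two conventions can
never disagree. The literature is split on population-vs-sample SD and
on the boundary rule; both choices here are conventions, documented and
applied consistently, and neither measurably affects continuous data.

**Parameters.** The estimator grid is the six pairs
$(m, r) \in \{(2, .15), (2, .25), (2, .30), (2, .35), (1, .25),
(1, .35)\}$ over scales 1–6, with $(m = 2, r = 0.35)$ the default pair
used by every driver. With 130 retained time points, scale 6 leaves
$\lfloor 130/6 \rfloor = 21$ samples — above the validity floor
$\lfloor N/l \rfloor > m + 1$ that the package enforces; scales failing
it yield missing values rather than numbers.

**Analytic reference.** For i.i.d. Gaussian noise the per-coordinate
match probability at tolerance $r$ is $\mathrm{erf}(r/2)$ (the
difference of two independent unit-variance Gaussians has variance 2),
so the large-$N$ sample entropy is $-\ln \mathrm{erf}(r/2)$ for every
$m$. This closed form, exposed as `analytic_white_noise_se()`, anchors
the estimator tests: at $N = 10^5$ the estimate sits within 0.02 of the
limit for all four $r$ values and both $m$ values.

## Temporal preprocessing

Per subject, in the order the processing narrative prescribes: drop the
first 10 volumes (the generator marks them with a large additive offset
so a failure to drop them is caught immediately); per-voxel linear
detrend; OLS regression of nuisance series (global, motion, CSF, WM —
supplied as a table, one row per retained volume); zero-phase band-pass;
standardization to mean 0, SD 1. Standardization is last, so every
analyzable voxel enters entropy mapping with SD exactly 1.

The filter is an order-2 Butterworth applied forward and backward
(zero phase, to avoid lag distortion of entropy), with odd-symmetric
edge extension and steady-state initial conditions. The nominal band is
0.01–0.2 Hz, but at TR = 3 s the Nyquist frequency is 0.167 Hz, so the
upper edge is clipped to 0.99 x Nyquist and the clipping is recorded in
the run log — the band is effectively a 0.01 Hz high-pass at this TR.
How the original toolchain handled this inconsistency is not
documented anywhere we could find; clipping is our decision.

Zero-variance or non-finite voxels are flagged non-analyzable, set to
missing, counted, and excluded from every downstream map. All spatial
preprocessing (slice timing, realignment, MNI normalization, smoothing)
is assumed done upstream and is out of scope.

## Group inference

**Voxelwise ANOVA.** The group effect is the general-linear-model
partial F comparing [intercept, age, sex, education, group dummies]
against [intercept, age, sex, education], with $(g-1, n-g-c)$ degrees
of freedom. Sex enters as a single binary covariate; age and education
enter linearly.

**Cluster correction.** The reference analysis used Gaussian-random-
field theory; this package deliberately substitutes label-permutation
max-cluster-size correction, which keeps the same two-threshold
structure (voxel $p < 0.001$, cluster $p < 0.05$) while providing
exact-level control at desk scale without smoothness estimation.
Covariates are held fixed via Freedman–Lane residual permutation
(permute the reduced-model residuals). Clusters are maximal
face-connected (6-connectivity — the conservative choice) components of
supra-threshold voxels; a cluster survives when
$(1 + \#\{\text{null max size} \ge \text{size}\})/(n_{perm}+1) \le 0.05$.

**ROI analyses.** Surviving-cluster peaks (mm coordinates through the
image affine; no storage-order assumption) define 8-mm spheres with
inclusive voxel-center membership. Fivefold cross-validation splits
subjects into group-stratified folds by a round-robin pointer that
continues across groups, so a 124-subject design yields folds of 24/25
with every group in every fold; each fold's ROIs are selected on the
other four folds and evaluated on the held-out fold, and both per-fold
and pooled tables are reported (the original description is ambiguous
on pooling, so we emit both, labeled). Post-hoc pairwise tests are
two-sample pooled-variance t tests on covariate-adjusted residuals,
Bonferroni-multiplied by the six pairs and capped at 1. Spearman
correlations (average ranks, asymptotic two-sided p) relate ROI entropy
to MMSE, FAQ, CDR and GMV; the multiple-comparison method for these
families is unnamed in the reference analysis, so we default to
Benjamini–Hochberg within each (score, scale) family across ROIs, with
Bonferroni available — a logged interpretation, not a reproduced fact.

## The synthetic cohort

The generator emulates the study design — four groups of 30/33/32/29
subjects (124 total), 140 volumes at TR = 3 s, isotropic 3-mm voxels —
on a 20x24x20 grid whose "brain" is an ellipsoid of ~3,200 voxels
(semi-axes 0.9 of the grid half-extent; brains do not fill their
bounding boxes, and the mask keeps runtimes desk-scale). Complexity is
manipulated by mixing unit-variance spectral-synthesis 1/f noise with
white noise: the pink weight directly controls the flatness of the MSE
curve, which is exactly the property the theory section of the analysis
turns on (an AR(1) mode exists for robustness checks). Background
voxels share weight 0.40 in all groups; inside a planted 9-mm sphere at
(0, -9, 0) mm the groups receive monotone weights 0.90/0.75/0.60/0.45
(NC/EMCI/LMCI/AD) plus per-subject jitter (SD 0.06). No effect-size
information transferable from any real clinical cohort exists — group-
difference F statistics are a property of the data they were computed
on — so these defaults were chosen once to give a clearly detectable
but not trivial contrast at 20–30 subjects per group, and are not
revisited.

Clinical scores couple to each subject's *realized* planted weight
$w$: MMSE $= 14 + 18w + \varepsilon(1.8)$ clamped to [0, 30]
(group means then fall from ~29 for NC to ~22 for AD, matching the
demographic pattern of the emulated cohort), FAQ
$= 28 - 33w + \varepsilon(2.5)$, CDR $= 2.0 - 2.35w + \varepsilon(0.25)$
clamped to [0, 3], and per-ROI GMV $= 0.5 + 0.3w + \varepsilon(0.05)$.
Covariates are group-independent by construction (age ~ N(73, 7), sex ~
Bernoulli(0.5), education ~ N(16, 2.3)), so covariate adjustment is a
no-op on average; a `confounded_age` mode shifts AD ages +5 years to
test that adjustment actually works. Nuisance series (a slow global
drift, three pseudo-motion random walks, CSF/WM-like smooth noise) are
mixed into every in-brain voxel with random loadings (SD 0.25) and
returned for regression. The first 10 volumes carry a +1000 offset.

A property worth noting: the planted effect is nearly invisible at
scale 1 (the slight reversal there reflects pink noise's lower
single-scale entropy) and grows with scale, so the group contrast at
scale 6 dwarfs the scale-1 contrast — the curve-shape signature the
method is designed to detect.

**What the generator does not emulate:** hemodynamic response,
spatial autocorrelation of real fMRI, scanner noise physics, or tissue
anatomy (the GM/WM/CSF "masks" are concentric shells). Passing tests
therefore demonstrate that the estimator and inference chain behave
correctly on signals with known complexity structure — not that any
particular clinical effect size is reproduced.

## Numerical choices and degenerate inputs

- Tolerance boundary: inclusive (`<=`); SD: population (divide by N);
  both applied identically everywhere.
- Undefined entropy (zero matches) is `NA`, counted per voxel and
  scale, and excluded from sphere and mask means.
- Scales with $\lfloor N/l \rfloor \le m + 1$ are rejected per series.
- Rank-deficient nuisance or ANOVA designs fail loudly, naming the
  offending columns.
- Requested band edges above Nyquist are an error at the single-series
  level; the subject-level pipeline clips to 0.99 x Nyquist and logs it.
- Empty masks and empty sphere intersections return missing values with
  a warning or error naming the ROI.
- All randomness flows from explicit seeds; per-subject seeds derive
  deterministically from a cohort master seed, so any subject can be
  regenerated in isolation and identical seeds give byte-identical
  outputs.

## Problem sizes used by the test suite

The simulation studies run at the emulated acquisition geometry (140
volumes, TR 3 s, 3-mm 20x24x20 grid). Type-I-error runs use null
cohorts (no planted effect) of 24 subjects per group with 500
permutations, repeated 20 times, analyzed at scale 1 (a null cohort has
no scale-specific structure, so one scale suffices to audit the error
rate). Effect-recovery runs use 20 planted cohorts of 24 subjects per
group at the generator's default effect, mapped at scales {1, 6} and
analyzed at scale 6, where the planted contrast is largest. The
estimator-versus-analytic checks use $N = 10^5$ series; curve-shape
checks use $N = 10^4$ over 20 seeds. These sizes are the package's
desk-scale study conditions and are stated here so they can be scaled
up by anyone with more patience.

## Known limitations

- The permutation substitute for random-field cluster correction is
  statistically defensible but will not numerically match GRF-corrected
  cluster tables computed by other toolboxes.
- Entropy estimates at 130 time points are biased and noisy at high
  scales (21 samples at scale 6); the package reports them faithfully
  rather than attempting bias correction, matching standard practice.
- The synthetic cohort's effect sizes are constructions; nothing here
  calibrates them to any real clinical population.
- GMV enters only as a supplied per-ROI number; no morphometry is
  performed.
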