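---
title: "Microstructure models, synthetic cohorts, and the multiparametric classifier"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Microstructure models, synthetic cohorts, and the multiparametric classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`gliomicro` re-implements, as one tested pipeline, a preoperative
diffusion-MRI analysis of lower-grade-glioma recurrence: voxel-wise
microstructure reconstruction from a two-shell acquisition, ROI feature
extraction, univariate statistics and ROC analysis, and an OPLS-DA
multiparametric classifier. This vignette is the package's account of the
science: the models and their assumptions, the tunable parameters and their
defaults, what the synthetic data emulate (and do not), the numerical
choices, and the known limitations.

## Acquisition model and units

Every stage assumes the two-shell protocol: b = 0, 1250 and 2500 s/mm² with
25 near-uniform directions per nonzero shell (51 measurements), linear
tensor encoding (b-tensor shape β = 1 throughout). Internally b-values are
ms/µm² and diffusivities µm²/ms, so all exponents are O(1); the s/mm² → ms/µm²
conversion (division by 1000) happens in exactly one function,
`b_si_to_internal()`. Gradient tables use the FSL image-space dialect with no
reorientation: phantoms are generated in the same frame they are fit in, so
there is no sign/flip ambiguity. Voxel indices are 1-based, matching how R
(and `RNifti`) index arrays.

ROIs are in-plane disks of a physical diameter (default 6 mm): a voxel
belongs to a disk when its center lies within the radius. The physical
diameter is authoritative; no pixel-count range is enforced, because a fixed
diameter and a fixed pixel count cannot both hold across voxel sizes.

## The phantom: three-compartment tissue with orientation dispersion

A voxel is simulated as

* an intra-neurite *stick* (parallel diffusivity `Da`, zero perpendicular),
* an extra-neurite axially symmetric Gaussian (*zeppelin*, independent
  `De_par` ≥ `De_perp`), and
* an isotropic free-water *ball* (`d_iso`, default 3.0 µm²/ms),

with the stick and zeppelin dispersed by a shared orientation distribution:
a delta (parallel fibers), a Watson density ∝ exp(κ(n·µ)²), or a Bingham
density ∝ exp(−κ₁(n·e₂)² − κ₂(n·e₃)²) with κ₁ ≥ κ₂ ≥ 0 (κ₁ = κ₂ recovers
Watson; κ₁ = κ₂ = 0 is uniform). Signal fractions are absolute
(`f_intra + f_extra + f_iso = 1`), and S(b = 0) = S0 exactly for every
parameter setting.

The kernel–ODF convolution and all ODF normalization constants use a
product Gauss–Legendre quadrature on the sphere (64 polar × 128 azimuthal
nodes for simulation; 32 × 64 inside the NODDI optimizer). Against a
128 × 256 reference this is exact to well below 1e-6 for concentrations up
to κ ≈ 300, which bounds everything the package fits. The Bingham
normalization constant (a confluent hypergeometric function of matrix
argument) is computed by the same quadrature rather than a saddle-point
series: at these problem sizes quadrature is both simpler and more accurate,
and an independent finer quadrature cross-checks it in the tests.

The extra-neurite compartment is simulated with free `De_par`, `De_perp`
(the standard-model parameterization). The Watson-NODDI fit assumes
tortuosity coupling, so its round-trip tests use `noddi_truth()`, which
builds ground truth satisfying the coupled model — otherwise one would be
testing a model against data it cannot represent.

Rician noise is the magnitude of complex Gaussian noise with σ = S0/SNR. The
study this package emulates reports no SNR; the cohort default (SNR = 30 at
b0) is a typical clinical DKI value and is a configuration choice, not a
measured one.

## Synthetic cohorts: what the effect table encodes

`make_cohort()` produces a two-group cohort (default n = 25 non-recurrence /
23 recurrence, the study's sizes) at two levels. The *feature level* draws
each of the 21 ROI metrics from per-group normal distributions — the input
the statistics and classifier stages consume. The *signal level* simulates
small 4-D volumes with tumor and contralateral ROIs from microstructure
ground truth, to exercise the full fitting chain.

Under the `study-like` preset the recurrence-group shift of each metric is
set so the standardized effect d = √2·Φ⁻¹(AUC) reproduces that metric's
reported single-feature AUC (e.g. d ≈ 1.70 for De⊥ at AUC 0.885), with the
reported direction: recurrence shows higher AFD/AWF/FA/kurtosis/ICVF/De∥/f
and lower AD/MD/RD/De⊥/fw; ODI, Bin-ODI, DAI and Da carry zero effect.
Baseline means and SDs are plausible tumor-parenchyma values (e.g. MD
1.4 ± 0.2 µm²/ms, FA 0.25 ± 0.08, ICVF 0.35 ± 0.10), chosen once and not
revisited. Metrics are drawn independently; real metrics are strongly
correlated across reconstruction models (AWF with f, MD with De⊥, ...), so
the synthetic multiparametric classifier is *optimistic* relative to real
data — independent features carry more joint information than correlated
ones. Passing calibration tests therefore shows the machinery is correct and
well-calibrated, not that real-data AUCs of this size are guaranteed. The
`null` preset sets every effect to zero and is used for type-I-error and
null-Q²Y calibration.

## Model fitting

**DTI / DKI.** Both use two-step weighted linear least squares on
log-signals (weights = squared predicted signals from an OLS pre-pass,
the standard bias correction for log-domain fitting). DTI uses b ≤ 1250
only, the convention for tensor fits from DKI acquisitions; DKI uses both
shells and fits ln S = ln S0 − b·gᵀDg + ⅙·b²·Σ gᵢgⱼgₖgₗ W̃ᵢⱼₖₗ with
W = W̃/MD². AK/MK/RK come from directional K_app (250-direction Fibonacci
average for MK, agreeing with a 10 000-direction average to ~0.05%;
64 in-plane directions for RK) rather than closed-form contractions, because
the directional definition is the one the signal equation states and is
directly oracle-testable. K_app is softly clipped to [−3/7, 10] with a count
of clipped directions, not solved under constraints — flags preserve
auditability. AWF = K_max/(K_max+3) with K_max over the dense direction set;
a negative K_max (possible under noise) clamps to zero and is flagged.

**NODDI (Watson and Bingham).** Fixed d∥ = 1.7, d_iso = 3.0 µm²/ms and
tortuosity coupling De⊥ = d∥(1−V_ic), the convention the parameter names
come from. The objective is Gaussian (sum of squared magnitude residuals)
with S0 profiled out analytically. Initialization is a deterministic coarse
grid over V_ic (8) × ODI (8) × orientation (30) × V_iso (4) whose predicted
signals are precomputed once per scheme, followed by Nelder–Mead refinement
(restart budget 3; non-convergence returns the best candidate, flagged).
There is no randomness anywhere, so fits are exactly reproducible. The
Bingham variant refines over the full orientation frame with κ₁ = κ₂ + Δ,
Δ ≥ 0 enforcing the order; it initializes from the Watson fit. Derived
indices: ODI = (2/π)·arctan(1/κ), Bin-ODI uses √(κ₁κ₂), and
DAI = (2/π)·arctan((κ₁−κ₂)/κ₂) (1 when κ₂ = 0 < κ₁, 0 when κ₁ = κ₂) — a
documented convention; published definitions of dispersion anisotropy vary
and no printed value constrains the choice (the study found DAI
non-significant). When V_iso ≥ 0.95 the ICVF is unidentifiable and the fit
is flagged. Noise-free round trips recover fractions to < 0.001.

**SMI.** Per-shell least-squares spherical-harmonic fits (lmax = 4, 15
coefficients from 25 directions) are collapsed into rotational invariants
S_l(b) = ‖c_l‖/√(4π(2l+1)), so that the convolution model factorizes as
S_l = p_l·F_l(b) with p_l ∈ [0, 1] the ODF alignment factors and F_l the
Legendre projections of the stick+zeppelin+ball kernel (free water fixed at
3.0 µm²/ms, reported separately as fw). All three band invariants (S₀, S₂,
S₄) on both shells are used. The inverse problem at a two-shell
linear-encoding protocol is famously degenerate: distinct parameter sets
reproduce the same invariants to machine precision, and a global cubic
polynomial regression from invariants to parameters — an obvious first
choice — is measurably biased toward the prior mean (f error ≈ 0.14 on the
canonical test point). The estimator therefore approximates the posterior
mean under documented priors (f, fw uniform with f+fw ≤ 1; Da, De∥ ~ U(0,3);
De⊥ ~ U(0, De∥); p2 ~ U(0,1) with p4 coupled through the Watson family) by a
k-nearest-neighbour average (k = 100 of 200 000 prior draws, standardized
invariant space), then projects it onto the forward-model manifold by
penalized Nelder–Mead (anchor weight 1e-3), so the estimate reproduces the
observed invariants while staying on the posterior's support. Everything is
deterministic given the training seed. Identifiability is surfaced, not
hidden: each fit carries the per-parameter global-regression R² for the
protocol (≈ 0.65 for f, ≈ 0.45 for Da — weak, as expected at 2-shell LTE),
and recovery degrades for low-f, highly dispersed voxels; the tests assert
the documented tolerances (0.05 fractions / 0.2 µm²/ms on the canonical
round trip), not universal accuracy.

**CSD / AFD.** The single-fiber response is the zonal (m = 0, lmax 8) SH
profile of high-FA voxels aligned to their principal eigenvectors; a
dispersion diagnostic (relative spread of per-voxel coefficients) flags
contamination by non-single-fiber voxels. Deconvolution of the b = 2500
shell (the high-b fODF convention) solves a Tikhonov-reweighted least-squares
problem at lmax = 4 with a soft nonnegativity constraint on a 1000-point
hemisphere grid: grid points below 0.1 × the initial mean amplitude are
penalized, iterating until the active set stabilizes (cap 50, flagged
otherwise). The zero signal maps to the zero fODF exactly. AFD-total is the
fODF's spherical integral (√4π times the l = 0 coefficient, exactly rotation
invariant); lobes are segmented by steepest-ascent watershed on the same
projective mesh with antipodal lobes merged, AFD-max is the largest lobe
integral and AFD-sum the sum over lobes whose peak exceeds 0.1 × the global
peak (the threshold is exposed). Because the constraint is soft, a small
positive floor can remain between lobes; lobe sums of band-limited
nonnegative fODFs agree with brute-force mesh integration to ~1–2%.

## Statistics

Group comparisons mirror the published analysis: Shapiro–Wilk (α = 0.05) on
each group routes to a two-sample t-test (pooled when Levene accepts
homogeneity, Welch otherwise) or to the Mann–Whitney U test with normal
approximation and tie correction. Categorical tables use Pearson chi-square
*without* continuity correction — the convention validated against the
published 2×2 tables, which it reproduces at printed precision (margin
0.010, grading 0.020 at N = 47 after dropping the unknown-grade record,
midline 0.882, location 0.571, size 0.154). The printed gender p-value
(0.971) is not reproducible from the printed counts under Pearson, Yates or
Fisher conventions (all give 0.39–0.56); it is recorded as unexplained and
not asserted. No multiple-testing correction is applied across the 21
metrics, mirroring the source analysis; a Benjamini–Hochberg column is
emitted alongside for transparency.

ROC analysis computes the AUC by the Mann–Whitney identity (verified against
exhaustive pair counting with half-credit ties), DeLong confidence
intervals, auto-flips orientation so AUC ≥ 0.5 (flag recorded), and picks
the operating point maximizing Youden's J with ties broken by the lowest
threshold. Paired AUC comparison uses the DeLong Z test. ROI aggregation
averages per-ROI means with equal weights (not pooled voxels — ROIs are
equal-sized disks by construction); contralateral-normalized duplicates are
available since the study standardized against contralateral white matter
without stating whether ROC inputs were normalized.

## OPLS-DA

Predictors are autoscaled to unit variance (the default of the software
family this analysis follows); y is dummy-coded ±1. Orthogonal components
are deflated sequentially, then one predictive PLS component is fit; with
zero orthogonal components the model *is* PLS1, which the tests verify
against an independent NIPALS implementation. VIP is the
predictive-component variant VIP_j = √p·|w_j| (mean VIP² = 1 by
construction). Q²Y = 1 − PRESS/SS uses stratified 7-fold cross-validation
with seed-reproducible folds. The number of orthogonal components is chosen
by forward addition while Q²Y improves by ≥ 0.01 (cap 3). The permutation
test refits the model on permuted labels (default 200), records R²Y/Q²Y
against |corr(y_perm, y)|, and reports the OLS intercepts including the
unpermuted point — the familiar validation-plot convention, where R²Y
intercept < 0.3 and Q²Y intercept < 0.05 indicate the original fit is not an
overfitting artifact.

## Problem sizes and calibration

The test suite and acceptance script run at desk scale, chosen so the whole
suite completes in minutes on one CPU: noise-free recovery suites use single
voxels per parameter setting (the fits are deterministic, so replication
adds nothing), calibration uses 200 null cohorts and 100 study-condition
cohorts at n = 25/23, and the permutation test uses the full 200
permutations. Under the null preset the pooled per-comparison type-I rate
across the 21-metric family lands near 0.05 (0.030–0.070 is the accepted
band; with 200 replicates the per-metric binomial spread is too wide for
per-metric bands to be meaningful) and the mean null Q²Y is negative. Under
the study-condition preset the cross-validated multiparametric AUC exceeds
the best single-feature AUC in every replicate — expected, since the
features are independent by construction (see above).

## Known limitations

* The headline patient results (single-feature AUCs, model AUC 0.96,
  R²Y 0.581, Q²Y 0.422) depend on the unavailable 48-patient dataset and are
  *not* reproduced; the package reproduces the recomputable clinical-table
  statistics and replaces the rest with property-based validation on
  synthetic cohorts whose effect sizes are derived from the reported AUCs.
* Feature correlations across metrics are not modelled, which inflates
  synthetic multivariate performance relative to real cohorts.
* No preprocessing (motion/eddy/bias correction, brain extraction) and no
  DICOM handling: inputs are assumed preprocessed NIfTI + bval/bvec.
* SMI parameters other than fractions are weakly identifiable at this
  protocol; treat Da and De∥ maps quantitatively only with the reported R²
  in view.
* The signal-level phantom uses small idealized volumes (uniform tissue per
  ROI, no partial volume beyond the three compartments, no T2/TE effects,
  no gradient nonlinearity).
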