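# gliomicro

Preoperative diffusion-MRI microstructure analysis for predicting
lower-grade-glioma (LrGG, WHO grade II–III) recurrence after resection.
Roughly half of resected LrGG patients recur within two years; `gliomicro`
implements the full analysis chain that asks whether preoperative two-shell
diffusion MRI can tell the two groups apart: seven voxel-wise microstructure
reconstructions, ROI feature extraction, univariate group statistics with ROC
analysis, and an OPLS-DA multiparametric classifier with VIP scores and
permutation validation. A multi-compartment phantom simulator with known
ground truth makes every stage testable without patient data.

## Models

All models consume a two-shell acquisition (b = 0, 1250, 2500 s/mm², 25
directions per nonzero shell; internally b is in ms/µm² and diffusivities in
µm²/ms).

- **DTI** (b ≤ 1250): weighted linear least squares;
  FA = √[((λ₁−λ₂)² + (λ₁−λ₃)² + (λ₂−λ₃)²) / (2(λ₁²+λ₂²+λ₃²))],
  MD = (λ₁+λ₂+λ₃)/3, AD = λ₁, RD = (λ₂+λ₃)/2.
- **DKI** (both shells): the 22-parameter log-linear model
  S(b)/S(0) = exp(−b·D_app + ⅙·b²·D_app²·K_app); AK/MK/RK from directional
  K_app, and the WMTI axonal water fraction AWF = K_max/(K_max + 3).
- **Watson/Bingham NODDI**:
  S = (1−V_iso)(V_ic·S_ic + (1−V_ic)·S_ec) + V_iso·S_iso with fixed intrinsic
  diffusivities and tortuosity coupling; emits ICVF,
  ODI = (2/π)·arctan(1/κ), Bin-ICVF, Bin-ODI and the dispersion anisotropy
  index DAI.
- **SMI** (standard model): stick + zeppelin + ball kernel convolved with an
  ODF, S(B) = s₀ ∫ dn̂ 𝒫(n̂) 𝒦(b, β, n̂·û), estimated from per-shell
  rotational invariants (S₀, S₂, S₄ at lmax = 4) by a prior-sampled
  posterior-mean estimator with manifold-projection refinement; emits f, Da,
  De∥, De⊥, fw with a per-parameter identifiability diagnostic.
- **CSD / AFD**: constrained spherical deconvolution of the b = 2500 shell to
  a fiber ODF; AFD-total (fODF integral), AFD-max and AFD-sum (lobe
  integrals by spherical watershed).
- **OPLS-DA**: y-orthogonal variation is filtered from the autoscaled
  feature matrix, then a single predictive PLS component is fit; VIP_j =
  √p·|w_j| (mean VIP² = 1), Q²Y by stratified 7-fold cross-validation, and a
  200-permutation overfitting test with R²Y/Q²Y intercepts.

## Worked example

```r
library(gliomicro)

## the acquisition protocol
study_scheme()
#> Diffusion gradient scheme: 51 measurements
#>   shell 1: b = 0 ms/um^2 (1 dirs)
#>   shell 2: b = 1.25 ms/um^2 (25 dirs)
#>   shell 3: b = 2.5 ms/um^2 (25 dirs)

## simulate one voxel with known ground truth and fit Watson-NODDI
tr <- noddi_truth(Vic = 0.6, Viso = 0.1, odi = 0.3)
fit_noddi_watson(simulate_signal(tr, study_scheme()), study_scheme())
#> Watson-NODDI fit: ICVF 0.600, ODI 0.300, Viso 0.100

## full pipeline on a synthetic 25/23 cohort with study-like effect sizes
res <- run_pipeline(default_config(seed = 1, n_perm = 200))
res$validation
#> OPLS-DA validation: R2Y 0.800, Q2Y 0.733, score AUC 1.000
#>   200 permutations: max permuted Q2Y 0.204; intercepts R2Y 0.268, Q2Y -0.392

head(res$roc_table[order(-res$roc_table$auc), ])
#>   metric   auc ci_lo ci_hi sensitivity specificity
#>  De_perp 0.908 0.821 0.995       0.826        0.92
#>  AFD_max 0.873 0.776 0.970       0.913        0.72
#>       FA 0.783 0.649 0.916       0.609        0.88
#>       MK 0.779 0.647 0.911       0.783        0.72
#>     ICVF 0.770 0.635 0.906       0.696        0.80
#>       fw 0.758 0.620 0.896       0.783        0.68
```

The noise-free NODDI fit returns the simulated truth to three decimals. On
the synthetic cohort, extra-axonal perpendicular diffusivity (De⊥) is the
strongest single discriminator, the multiparametric OPLS-DA model separates
the groups better than any single metric, its cross-validated Q²Y stays close
to R²Y, and every label permutation scores worse than the real labels — the
overfitting-test pattern expected of a genuine group difference.

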