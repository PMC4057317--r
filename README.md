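# mpmriseg

Multiparametric quantitative MRI analysis for segmenting thermally ablated
(non-viable) tumor tissue, for researchers evaluating focal ablation therapy
(e.g. high-intensity focused ultrasound) in preclinical tumor models without
contrast agents.

The method, end to end:

1. **Quantitative mapping.** Voxelwise fits of T1 (inversion-recovery
   Look-Locker, `S(t) = A − B·exp(−t/T1*)`, `T1 = T1*(B/A − 1)`), T2 and the
   apparent diffusion coefficient (mono-exponential decays `S = S0·exp(−TE/T2)`
   and `S = S0·exp(−b·ADC)` per diffusion direction, averaged), and the
   magnetization transfer ratio `MTR = (1 − S/S0)·100%`. Tumor voxels at noise
   level in the T2-weighted reference (hemorrhage) are excluded.
2. **ISODATA clustering** of the pooled, z-scored voxel feature vectors of all
   animals and time points simultaneously — a k-means-like algorithm that
   adjusts the cluster count by splitting heterogeneous and merging close
   clusters. Eleven parameter subsets ("feature vectors", {T2} … {T1,T2,ADC,MTR})
   are clustered independently.
3. **Viability classification**: a cluster is non-viable when the fraction of
   pixels assigned to it increased significantly after treatment (paired
   t-test, two-sided p < 0.05, positive mean change, pre vs 1 h or pre vs
   72 h); per tumor the non-viable volume fraction is the share of included
   voxels in non-viable clusters.
4. **Agreement with histology**: coefficient of determination to the line of
   identity `R² = 1 − Σ(yᵢ−xᵢ)²/Σ(yᵢ−ȳ)²` (can be negative), Pearson
   correlations per sacrifice group, Wolfe's test for dependent correlations,
   and the pre-treatment rim misassignment fraction; feature vectors are
   retained at R² > 0.7 and ranked by rim misassignment.

A seeded synthetic cohort generator (`generate_cohort()`) emulates the
longitudinal study design — treated animals scanned pre/1 h/72 h, controls at
matching days, matched synthetic histology sections, Rician noise, hemorrhage
voids, peritumoral edema — with exact ground truth, so the whole pipeline is
testable without animal data. See the vignette
`vignettes/multiparametric-segmentation.Rmd` for the model, parameter choices
and limitations.

## Worked example

```r
library(mpmriseg)

res <- run_pipeline(run_config(seed = 1))   # demo cohort: 6 treated, 3 controls
print(res$evaluation)
```

```
Feature-vector evaluation (agreement with histology)
  T2+ADC               R2 to identity =   0.99  [retained]
  T1+ADC               R2 to identity =   0.98  [retained]
  T1+T2+ADC            R2 to identity =   0.98  [retained]
  T1+T2                R2 to identity =   0.93  [retained]
  T2                   R2 to identity =   0.84  [retained]
  T1+ADC+MTR           R2 to identity =   0.47
  ADC                  R2 to identity =   0.44
  T1+T2+MTR            R2 to identity =  -4.39
  T1+T2+ADC+MTR        R2 to identity =  -4.96
  T2+ADC+MTR           R2 to identity = -10.42
  ADC+MTR              R2 to identity = -13.80
Selected feature vector: T1+T2+ADC
```

Retained vectors (R² > 0.7) are ranked by pre-treatment rim misassignment;
here {T1,T2,ADC} wins, and every MTR-containing vector scores markedly lower
— the generator deliberately models MTR as an unreliable feature (see the
vignette). `res$true_pairs` compares MRI-derived against ground-truth
non-viable fractions per tumor; with these settings the treated tumors' true
fractions 0–0.5 are recovered with Pearson r = 0.995 and R² to identity
= 0.983, while control tumors average a fraction of 0.004. `res$summary`
holds the per-class parameter means (this run: viable R1 0.452 s⁻¹, R2
21.6 s⁻¹, ADC 0.85·10⁻³ mm²/s; non-viable at 1 h: R1 0.578, ADC 1.15·10⁻³;
at 72 h: ADC 1.25·10⁻³), recovering the tissue values the generator draws
from. Passing `out_dir =` writes NIfTI viability maps plus CSV fraction,
correlation and classification tables; `inst/cli/mpmriseg.R` exposes the
stages (`simulate`, `fit`, `cluster`, `classify`, `evaluate`, `run-all`) as a
command line.

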