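# litterlab

Statistical pipelines for reciprocal litter-transplant decomposition
experiments and the untargeted LC-MS metabolomics that accompanies them.

Ecologists testing the **home-field advantage (HFA)** hypothesis —
litter decomposing faster in its habitat of origin than elsewhere —
transplant litterbags of several species among their home forests, here
the three dominant Mediterranean forest types (*Quercus ilex*,
*Q. pubescens*, *Pinus halepensis*), crossed with a rain-exclusion
treatment (natural vs amplified drought, ND/AD). litterlab provides,
for that design:

* the **ADH statistic** (additional decomposition at home) with its
  replicate-resampling scheme and one-sample Student test:

  HDDᵢ = (D_iI − D_jI) + (D_iI − D_kI),
  ADDᵢ = (D_iJ − D_jJ) + (D_iK − D_kK),
  H = Σ HDD / (N − 1),
  **ADHᵢ = HDDᵢ − ADDᵢ − H**,

  where D_sF is mass loss (%) of species *s* litter in forest *F* and
  I/J/K are the home forests. ADH > 0 is a home-field advantage,
  ADH < 0 a disadvantage;
* **calibration of decomposition cell means** to published marginal
  summaries by equality-constrained least squares, and a seeded
  litterbag generator around them;
* **factorial models of litter mass remaining** with AIC stepwise
  selection (`MASS::stepAIC` under the hood) and sequential (Type I)
  %SS ANOVA tables, plus two-way trait ANOVAs;
* the **LC-MS feature-matrix filter chain** (blank S/N ≥ 10, pooled-QC
  CV ≤ 0.3, co-elution autocorrelation dedup), log/auto-scaling, PCA,
  permutation **PERMANOVA**, and **PLS-DA VIP** ranking;
* **CHO formula enumeration** and adduct mass arithmetic
  ([M−H]⁻, [M+HCOO]⁻, [M−2H]²⁻, [M+H]⁺, [M+Na]⁺) for dereplication of
  top-VIP features;
* seeded **synthetic-data generators** with known ground truth for every
  stage.

## Worked example

```r
library(litterlab)

## calibrated cell-mean table (mass loss %, 36 cells) and the ADH it implies
tab <- calibrate_cell_means()
attr(tab, "residual_norm")        # 0 (constraint set is feasible)
compute_adh_table(cell_mean_slice(tab, "ND", 24))
#>       species       HDD       ADD    H    ADH
#> 1       Qilex  2.393333 -5.386667 8.08  -0.30
#> 2  Qpubescens -7.406667 -5.386667 8.08 -10.10
#> 3 Phalepensis 21.173333 -5.386667 8.08  18.48

## a full synthetic experiment: 504 bags, ADH inference per slice
bags <- generate_litterbags(litter_sim_config(seed = 42))
res <- hfa_analysis(bags, seed = 42)
subset(res, time_months == 24 & treatment == "ND")
#>   treatment time_months     species       HDD       ADD        H        ADH
#> 7        ND          24       Qilex  2.694732 -5.098390 6.380647   1.412475
#> 8        ND          24  Qpubescens -8.781054 -3.859121 6.380647 -11.302580
#> 9        ND          24 Phalepensis 18.847616 -3.803783 6.380647  16.270752
#>      t_value      p_value n_draws
#> 7  0.8113093 4.343921e-01      12
#> 8 -7.6880733 9.514788e-06      12
#> 9 10.5275697 4.412535e-07      12
```

At two years under natural drought the pine litter shows a strong,
significant home-field advantage (ADH ≈ +16, p < 1e-6) and the downy
oak a home-field **dis**advantage (ADH ≈ −11), while the holm oak shows
no effect — the pattern the calibrated cell means encode, recovered
from noisy bags.

```r
## metabolomics: filter, ordinate, test, rank, annotate
sim <- generate_feature_matrix(metabo_sim_config(seed = 42))
filtered <- apply_filter_chain(sim$matrix)
filter_report(filtered)
#>       step                           params before removed after
#> 1 blank_sn                  sn_threshold=10    900      44   856
#> 2    qc_cv                 cv_threshold=0.3    856      43   813
#> 3 autocorr r_threshold=0.9, rt_tol_min=0.05    813      40   773

X <- log_autoscale(filtered)
permanova(t(X), attr(X, "groups"), n_perm = 999, seed = 42)[c("pseudo_F", "p_value")]
#> $pseudo_F
#> [1] 1.765379
#> $p_value
#> [1] 0.009

vip <- plsda_vip(X, attr(X, "groups"))
head(top_vips(vip, 15), 3)
#>   feature_id      vip rank
#> 1      F0201 2.301807    1
#> 2      F0124 2.292224    2
#> 3      F0037 2.283119    3

annotate_features(data.frame(feature_id = "M615T468", mz = 615.0987))[1, ]
#>   feature_id       mz adduct   formula theoretical_mz  ppm_error rdbe
#> 1   M615T468 615.0987 [M-H]- C28H24O16       615.0992 -0.7450298   17
```

The three filters remove the planted blank contaminants, QC-unstable
features and redundant co-eluting cluster members (counts telescope:
900 → 856 → 813 → 773); the ND/AD metabolomes separate significantly
(PERMANOVA p = 0.009, the attainable floor for a 5+5 design); and the
top ion annotates as the deprotonated galloyl-flavonol glycoside
C28H24O16 at −0.7 ppm.

See `vignettes/litter-decomposition-hfa.Rmd` for the model definitions,
calibration constraints, generator assumptions and design decisions.

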