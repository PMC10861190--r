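# ProteoBoneAge

Proteome-wide analysis of bone aging in longitudinal cohorts. The package
implements, as one tested R pipeline, the analysis chain used in prospective
serum-proteomics studies of osteoporosis: protein preprocessing, machine-
learning marker selection, mixed-model association with bone mineral density
(BMD), random-effects meta-analysis across cohort batches, protein risk
scores, latent-class BMD trajectories, Cox survival models with restricted
cubic splines, a Klemera–Doubal proteomic biological age, and two-sample
Mendelian randomization. It is aimed at biostatisticians and epidemiologists
who want to prototype, validate or teach this design without access to a
real cohort: a synthetic-data module generates three-visit cohorts with a
known latent bone-aging process so every stage can be checked against ground
truth.

## The models at the core

* **Association.** For each protein *j*, the standardized follow-up BMD of
  participant *i* at visit *t* is modelled with a random intercept:
  `BMD_it = β_j z_ij + γ'c_i + u_i + ε_it`, fitted by REML per cohort batch.
  Batch estimates are pooled by DerSimonian–Laird random-effects
  meta-analysis (`τ² = max(0, (Q − (k−1))/(Σw − Σw²/Σw))`), with Cochran's
  Q and I²; a protein is flagged when the pooled `p < 0.05` and `I² < 30%`.
* **Protein risk score.** `PRS_i = Σ_j w_j z_ij` over flagged proteins, with
  `w_j = −β̂_j` so that higher scores mean lower BMD; analysed per SD with
  Cox proportional hazards (Efron ties), quartile hazard ratios and a
  4-knot restricted cubic spline dose–response.
* **Trajectories.** A K-class mixture of linear growth curves
  `y_it = a_k + b_k t + ε` fitted by EM; K chosen by BIC among fits with
  adequate posterior assignment probabilities (APPA ≥ 0.7).
* **Biological age.** Klemera–Doubal: per-protein age regressions
  `x_j = q_j + k_j CA + e` are aggregated into
  `BA_E = Σ(x_j−q_j)k_j/s_j² / Σk_j²/s_j²`, then blended with chronological
  age through `s_BA` to give the corrected biological age; age acceleration
  is the residual of the corrected age on CA.
* **Mendelian randomization.** Wald ratio, IVW, MR-Egger, weighted median
  and mode-based estimators on harmonized GWAS summary statistics with a
  `p ≤ 5×10⁻⁸` instrument filter.

## Worked example

```r
library(ProteoBoneAge)

cfg <- defaultPipelineConfig(n_participants = 800, n_proteins = 60, seed = 1)
res <- runPipeline(cfg)

# pooled protein-BMD associations at the lumbar spine
head(res$meta$ls[res$meta$ls$flagged, c("protein", "beta_pooled", "p", "I2")])
#>   protein beta_pooled            p I2
#> 1    P001  -0.3126291 4.955417e-23  0
#> 3    P003   0.2736631 1.398936e-17  0
#> 4    P004  -0.2862194 2.657455e-19  0
#> 5    P005  -0.2722501 8.492171e-18  0
#> 6    P006  -0.2415115 1.259985e-13  0
#> 7    P007   0.2729220 1.486764e-17  0

res$surv$ls$cox_prs
#> CoxResult: HR 5.312 (3.710-7.605), p = 7.67e-20, 63 events/755

res$bioage$cox$ls$accel$model1
#> CoxResult: HR 2.024 (1.567-2.614), p = 6.56e-08, 63 events/755
```

Here 14 of 60 proteins are flagged at the lumbar spine (including 7 of the
8 proteins the generator actually ties to BMD); one SD of the protein risk
score multiplies the osteoporosis hazard by ≈5, and one SD of proteomic age
acceleration by ≈2 — the synthetic cohort plants a strong bone-aging
signal precisely so that every downstream stage has something detectable
to recover.

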