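# cmrtox

Quantitative cardiac MR relaxometry and histopathology analysis for
anthracycline-cardiotoxicity studies in small animals.

Anthracyclines such as doxorubicin damage the myocardium long before the
ejection fraction drops: myocytes vacuolate, the interstitium accumulates
collagen, and inflammation and edema expand the extracellular space.
Quantitative CMR — native T1, T2, and the extracellular volume fraction
(ECV) — can detect these diffuse changes non-invasively, but validating the
imaging numbers requires running a full measurement chain from raw image
series to cohort statistics. `cmrtox` implements that chain as a tested R
package:

* **Relaxometry** — pixel-wise T1 from saturation-recovery series,
  `M(TD) = A − B·exp(−TD/T1)`, by separable nonlinear least squares; T2
  from multi-echo series, `S(TE) = S0·exp(−TE/T2)`, by weighted log-linear
  fit with a nonlinear fallback; parametric maps with failure sentinels and
  ROI statistics.
* **LV geometry and function** — wall rasterization from endo/epicardial
  contours, the 15% partial-volume offset toward mid-wall, four-segment
  division (anterior/inferior/septal/lateral), blood-pool ROI validation
  (< 5 mm², in-cavity), summation-of-discs volumes, and
  SV = EDV − ESV, EF = 100·SV/EDV, CO = SV·HR/1000, mass = 1.05 g/ml ×
  wall volume.
* **ECV** — λ = ΔR1_myo/ΔR1_blood with R1 = 1/T1, ECV = (1 − Hct)·λ,
  segment-wise then averaged.
* **Histology quantification** — RGB → CIE L\*a\*b\* conversion, 3-class
  k-means (collagen / muscle / background, ≤ 100 iterations, seeded
  restarts), rule-based class labeling, collagen fraction of tissue
  pixels, and aggregation of per-HPF vacuolar counts (40 fields/subject)
  and ordinal 0–4 inflammation/edema scores.
* **Cohort statistics** — Shapiro–Wilk-gated t/ANOVA/Kruskal–Wallis with
  Bonferroni post-hoc, univariable regression, multiple regression with
  VIF and adjusted R², reduction by weakest univariable |R|, and
  power-based two-sample-t sample sizing.
* **Synthetic data** — generators for every input with known ground truth:
  T1/T2 phantoms, contour stacks that hit requested volumes exactly,
  three-class stained images with exact collagen fractions, and cohort
  tables with calibrated linear T1/ECV-vs-histology structure.

## Worked example

```r
library(cmrtox)

# a two-region T1 phantom at plateau SNR 50, fitted pixel by pixel
truth <- matrix(1148, 32, 32); truth[, 17:32] <- 1320
ph  <- make_t1_phantom(truth, noise_sd = 20, seed = 1)
map <- fit_t1_map(ph$series)
map_roi_stats(map, truth == 1148)$mean   # 1149.8  (truth 1148 ms)
map_roi_stats(map, truth == 1320)$mean   # 1324.4  (truth 1320 ms)

# LV function from a contour stack built to control-like volumes
stk <- make_contour_stack(edv = 0.69, esv = 0.18)
fn  <- lv_function(lv_volumes(stk$ED), lv_volumes(stk$ES), hr = 281,
                   wall_volume = stk$truth$wall_volume)
fn$LVSV   # 0.51 ml
fn$LVEF   # 73.9 %

# ECV from paired T1 values and hematocrit
compute_ecv(t1_myo_pre = 1148, t1_myo_post = 700,
            t1_blood_pre = 1800, t1_blood_post = 500, hct = 0.588)$ecv_pct
# 15.9 %

# collagen fraction of a stained image with known truth
him <- make_histology_image(size = 96, collagen_pct = 11.0, seed = 11)
quantify_fibrosis(him$img, seed = 12)$fibrosis_pct   # 11.00 %

# cohort statistics on a synthetic 41-subject study
tab <- make_cohort(seed = 1)$table
fit <- multiple_regression(tab, "ecv",
                           c("vacuolar_pct", "fibrosis_pct",
                             "inflammation_score", "edema_score"))
round(c(r2 = fit$r2, adj_r2 = fit$adj_r2, max_vif = max(fit$vif)), 2)
#     r2 adj_r2 max_vif
#   0.72   0.69    1.40
```

The fitted region means sit within 0.4% of the phantom truth; the stroke
volume and ejection fraction follow exactly from the constructed volumes;
the collagen fraction is recovered to count-rounding precision; and the
synthetic cohort's ECV model explains ~three quarters of the variance with
all VIFs well below 8, mirroring the calibrated generating structure.

The numbered scripts under `analysis/` run the same chain as a narrative
workflow (simulate → relaxometry → function/ECV → histology → statistics),
writing tables under `results/`:

```sh
Rscript analysis/01_simulate.R 1 && Rscript analysis/02_relaxometry.R 1 \
  && Rscript analysis/03_lv_function_ecv.R && Rscript analysis/04_histology.R 1 \
  && Rscript analysis/05_cohort_stats.R
```

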