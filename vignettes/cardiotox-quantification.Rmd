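---
title: "Quantitative CMR relaxometry and histopathology: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative CMR relaxometry and histopathology: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmrtox)
```

cmrtox implements the quantitative measurement chain used in small-animal
cardiotoxicity imaging studies: pixel-wise T1 and T2 relaxometry, left
ventricular (LV) segment modelling, extracellular volume fraction (ECV)
computation, collagen quantification of stained histology, and the
cohort-level statistics that link the imaging values to tissue findings.
Every input the chain needs can be generated synthetically with known
ground truth, so the whole pipeline is testable end to end without animal
data. This vignette explains the models, the tunable parameters and their
defaults, what the generators do and do not emulate, and the numerical
decisions taken where the methodology left the choice open.

## Relaxometry

### Saturation-recovery T1

After a saturation pulse resets longitudinal magnetization, the signal at
saturation delay TD recovers as

$$M(\mathrm{TD}) = A - B\,e^{-\mathrm{TD}/T_1},$$

with scale factors $A$ and $B$ (equal for ideal saturation; both are
reported and their agreement is a quality check, not an enforced
constraint). `fit_t1_pixel()` estimates $(A, B, T_1)$ by *separable*
nonlinear least squares: for any fixed $T_1$ the model is linear in
$(A, B)$, so those are profiled out in closed form and the search is a
one-dimensional minimisation of the profiled residual sum of squares over
$T_1$, bracketed by a 60-point log-spaced grid on the admissible range
(1–10000 ms) and refined by bounded minimisation plus a tight second pass.
Compared with a conventional 3-parameter solver started from analytic
guesses, this has no initialisation sensitivity, cannot diverge, and is
cheap enough to run per pixel; it is the same estimator class (nonlinear
least squares) with the linear subproblem solved exactly.

A fit is flagged `converged = FALSE` — and its pixel carries the `NA`
sentinel in maps — when the signal is flat, the recovery amplitude
estimate is non-positive (a decaying series is not saturation recovery),
or the optimum pins at a range bound. Sentinel pixels are excluded from
ROI statistics and never interpolated.

Magnitude data need no polarity restoration here: saturation recovery
starts at zero magnetization and increases, so the signed and magnitude
signals coincide. The cine dimension (heartbeats, cardiac phases) is
treated as acquisition metadata; the fit consumes (signal, TD) pairs
regardless of phase, because no per-phase combination rule is part of the
model.

### Multi-echo T2

Echo signals decay as $S(\mathrm{TE}) = S_0 e^{-\mathrm{TE}/T_2}$. The
default estimator is weighted log-linear least squares with weights
$\propto S^2$, which undoes the variance distortion introduced by the log
transform; with only three echoes (16, 26, 36 ms by default) this is the
standard practical choice. Any non-positive signal switches the pixel to a
separable nonlinear fallback ($S_0$ profiled, 1-D search over $T_2$), and
an all-zero signal is a failed fit. At a first-echo signal-to-noise ratio
of 30 the region-mean bias of the log-linear path is below 2% (established
by seeded Monte-Carlo in the test suite, averaged over seeds).

### Noise model

The synthetic phantoms add Gaussian noise by default, with a Rician option
(`noise_model = "rician"`). At the SNRs exercised (50 for the T1 plateau,
30 at the first echo for T2) the Gaussian approximation to magnitude noise
is standard; the Rician path exists to probe low-SNR behaviour.

## LV geometry and function

Contours are ordered closed polygons in millimetres. The wall is the
region inside the epicardial and outside the endocardial border,
rasterized by point-in-polygon testing at a configurable pixel spacing
(0.1 mm in the analyses; at that spacing the annulus-area error is below
2%).

The partial-volume offset (`apply_offset()`, default 15%) moves each
border toward mid-wall by a fraction of the *local* wall thickness,
measured along radial rays from the wall centroid. Ray-based offsetting
was chosen over normal-vector offsetting because it is closed-form
testable on circles and ellipses and cannot self-intersect on star-shaped
contours; LV short-axis borders are star-shaped in practice. Offsetting is
deliberately not idempotent-composable: applying 15% twice is not the same
as 30% once on non-circular walls (each application re-measures the
thickness), and a test asserts the inequality so the behaviour is a
documented contract.

Segments follow the four-quadrant convention: septal, anterior, lateral,
inferior occupy contiguous 90° sectors about the wall centroid,
counter-clockwise from a user-supplied septal direction. The orientation
is a per-slice input (from an RV-insertion landmark or configuration)
because no universal convention exists for rodent short-axis images.

Cavity volumes use summation of discs — endocardial area times effective
slice thickness (thickness + gap), summed over the stack — the standard
short-axis practice. Whether an inter-slice gap contributes is explicit in
the slice geometry (`gap`, default 0). Derived indices are exact
identities: SV = EDV − ESV, EF = 100·SV/EDV, CO = SV·HR/1000, and mass =
wall volume × 1.05 g/ml (the conventional myocardial density). When phases
are unlabeled, ED is the phase of maximal summed endocardial area and ES
the minimal. The blood-pool ROI contract (round, area < 5 mm², entirely
inside the endocardial border, avoiding an optional papillary-muscle
polygon) is validated, not assumed.

## ECV

With contrast shortening T1 in proportion to local agent concentration,
the partition coefficient is the ratio of relaxation-rate changes,

$$\lambda = \frac{\Delta R_{1,\mathrm{myo}}}{\Delta R_{1,\mathrm{blood}}},
\qquad R_1 = 1/T_1,$$

and $\mathrm{ECV} = (1 - \mathrm{Hct})\,\lambda$. The identity
ECV = λ(1 − Hct) is asserted on every call. Hematocrit is accepted as a
fraction or a percentage (values in (1, 100] are divided by 100 with a
message), since cohort tables conventionally print percent.

Aggregation order matters: the implementation averages T1 over each
segment first, computes one ECV per segment, and reports the global value
as the mean of segment ECVs. This mirrors the segment-wise workflow of the
measurement protocol; pooling pixels first gives a different number on
heterogeneous walls, and a fixture test asserts that difference so the
choice is visible. The 15-minute post-contrast delay is metadata only — no
contrast kinetics are modelled.

## Histology quantification

Stained images (8-bit RGB, picrosirius-red-like) are converted to CIE
L\*a\*b\* with the sRGB/D65 transform (`grDevices::convertColor`; a
hand-coded sRGB→XYZ→Lab pipeline serves as the independent oracle in the
tests) and clustered into three classes by k-means. The iteration cap is
100 — we read "internally iterated 100 times" as the per-run iteration
limit of Lloyd's algorithm — with 10 seeded restarts, keeping the restart
with the lowest within-cluster sum of squares; the alternative reading
(100 restarts) is available by setting `restarts = 100`. Given a seed the
result is byte-identical across runs.

Clusters are mapped to classes by a rule rather than by hand: background
is the centroid with the highest L\* (near-white lumen), and of the
remaining two, collagen is the centroid with the higher a\* (picrosirius
red stains collagen red). Across 60 randomized plausible palettes the rule
matches generation truth in ≥ 99% of trials.

The fibrosis fraction defaults to collagen / (collagen + muscle) — a
*tissue* proportion, excluding background, which is what "interstitial
fibrosis" denotes; `denominator = "total"` reproduces the all-pixels
reading for comparison. Pixel counts are conserved exactly and asserted.

Vacuolar injury and ordinal scores are ingested, not detected: vacuole
identification is a manual microscopy task, so the module aggregates
per-HPF counts (10 high-power fields per LV segment × 4 segments = 40,
with a completeness warning otherwise) and per-segment grades (integers
0–4; subject scores are 4-segment means, which is why quarter-step values
such as 0.25 or 1.75 arise). Subject-level aggregation uses means; cohort
summaries may additionally report medians, and both are available.

## Cohort statistics

Group comparisons are gated by per-group Shapiro–Wilk tests at α = 0.05:
any rejection (or a degenerate constant group) routes the variable to the
nonparametric path. Two groups get a Welch t-test (pooled-variance
optional) or Wilcoxon rank-sum; more get one-way ANOVA or Kruskal–Wallis
followed by all pairwise comparisons with the Bonferroni multiplier equal
to the number of pairs actually tested. Raw and adjusted p-values are both
kept; the reporting helper renders values below 0.001 as "<0.001".

Univariable regressions report the Pearson R (signed), slope, intercept
and the two-sided t-based p-value. Multiple regression is ordinary least
squares on complete cases with an explicit rank check — exact collinearity
is an error, never a silent pseudo-inverse — and per-predictor variance
inflation factors from auxiliary regressions, $\mathrm{VIF}_j =
1/(1-R_j^2)$. The adjusted-$R^2$ identity
$1-(1-R^2)(n-1)/(n-p-1)$ is asserted on every fit. Model reduction drops
the predictor with the smallest univariable |R| and refits; ties drop the
later-listed predictor, deterministically and with a message.

Sample sizing uses the classical pooled-variance noncentral-t power
computation (`power.t.test`) and returns the smallest integer n per group
reaching the target power, plus a dropout-inflated enrollment (e.g. 7 per
group at 10% dropout → 8 enrolled). Welch is the default for *analysis*
while the pooled computation is used for *planning*, matching how those
tools are conventionally paired.

## The synthetic cohort generator

`make_cohort()` draws one row per subject for six groups — a control arm
and five treatment durations (2, 4, 6, 8, 12 weeks; cumulative doses 4–24
mg/kg at 1 mg/kg twice weekly) — with included-subject counts
(5, 6, 8, 8, 7, 7), 36 treated in total. Histology covariates come first:
vacuolar and fibrosis percentages are truncated-normal draws at the
group-level reference means (truncation at physical bounds, because plain
normal draws at realistic SDs would produce negative percentages), and
ordinal scores are means of four integer segment grades, reproducing the
quarter-step granularity of real reads. The CMR values then follow
generating linear models:

$$T_1 = \beta_0 + 4.7\,\mathrm{vac} + 21.0\,\mathrm{infl} - 1.7\,\mathrm{edema} + \varepsilon,$$
$$\mathrm{ECV} = \gamma_0 + 0.17\,\mathrm{vac} + 0.44\,\mathrm{fib} + 0.60\,\mathrm{infl} - 0.39\,\mathrm{edema} + \varepsilon.$$

The residual SDs are not free knobs: they are calibrated analytically so
the models carry the reference explained-variance structure. The variance
of each linear predictor over the group mixture is computed exactly
(truncated-normal moments for the continuous covariates, the discrete
rounded-grade distribution for scores, between-group covariance from the
group-mean structure), and $\sigma_\varepsilon^2 =
\mathrm{var}(\eta)(1-\rho^2)/\rho^2$ for target population $\rho^2$. The
targets are the reference *adjusted* $R^2$ values (0.34 and 0.74): adjusted
$R^2$ is the near-unbiased estimator of the population value, so fits at
the study size reproduce both the raw and adjusted summaries in
expectation. With that calibration, the default cohort yields (Monte-Carlo
means over replicate studies) univariable R ≈ 0.57 for vacuolar→T1 and
≈ 0.74 for fibrosis→ECV, and recovers the generating slopes.

What the generators deliberately do **not** emulate: realistic cardiac
anatomy or MR artifacts (B1, motion, banding) in the phantoms; stain
variability beyond Gaussian color spread, uneven illumination, or
whole-slide formats in the histology images; and the full covariance of
real histology variables — within a group the covariates are independent,
so collinearity arises only through the shared group structure (the
generated VIFs, ≈ 1.3–2.4, are therefore milder than a real cohort's).
Passing tests consequently demonstrate correctness of the measurement
chain and its statistics under the stated models, not robustness to
acquisition artifacts.

## Numerical choices and degenerate inputs

* T1 search range (1, 10000) ms, T2 range (0.1, 1000) ms; optima at a
  bound are failures, not estimates.
* Rasterization spacing 0.1 mm for walls; contours resampled on 360 rays
  for offsetting (720 for the elliptical tests).
* Blood ROI containment is checked on 90 boundary points.
* k-means requires at least k distinct colors; fewer is a degenerate-input
  error, as is an empty fitting mask or an ROI with no valid pixels.
* All generators are pure functions of (spec, seed); the pipeline driver
  threads one master seed through every stage.

## Problem sizes

The shipped analyses and tests use 16–32 px phantoms (3–20 seeds), 96 px
histology images, 41-subject cohorts (with 120–200-per-group variants for
recovery checks), 2000-replicate null simulations for the type-I error of
the comparison layer, and 150-replicate coverage checks at ~500 subjects.
These sizes were chosen so the full chain demonstrates its statistical
properties while remaining comfortable to run interactively.

## Known limitations

* No k-space reconstruction, motion correction, B1 correction, or
  MOLLI-family variants; the relaxometry starts from magnitude images.
* Contours are inputs — there is no automatic cine segmentation.
* No stain normalization or deconvolution; scanner ICC profiles are out of
  scope for the color conversion.
* Vacuole and inflammatory-cell detection are manual upstream tasks; the
  package aggregates their counts.
* The T2 availability pattern of a real study (only a subset of subjects)
  is not emulated; the generator emits T2 for everyone and the statistics
  layer is complete-case per analysis regardless.
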