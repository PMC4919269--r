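# metkin

Quantitative analysis of dynamic small-animal PET for renally excreted
tracers such as ^11^C-metformin, aimed at studies of renal organic cation
transport (OCT2/MATE1) in health and chronic kidney disease.

Metformin is taken up from blood into the renal proximal tubule by OCT1/2
and exported into urine by MATE1. Dynamic PET with ^11^C-metformin probes
this pathway in vivo; the quantities of interest are the renal-cortex
influx rate constant and the whole-body clearance of the tracer. `metkin`
implements the full quantification chain and, because studies of this
kind rarely deposit raw image data, couples it to a synthetic cohort and
phantom generator with known ground truth so every stage is testable.

## What it computes

* **One-tissue compartment model.** The tissue curve is the plasma input
  convolved with an exponential,
  `C_T(t) = K1 ∫ C_p(τ) e^(−k2 (t−τ)) dτ`, frame-averaged on the
  acquisition schedule. `fit_1tcm()` estimates `(K1, k2)` by
  Levenberg–Marquardt least squares and returns a classed model object
  with the usual `coef()`, `summary()`, `predict()`, `residuals()`,
  `plot()` and `simulate()` methods, plus a physiological-plausibility
  gate that flags non-physiological fits for exclusion.
* **Logan graphical analysis.** `logan_vt()` regresses the Logan
  transform over frames from `t* = 20` min onward; the slope is the total
  distribution volume `V_T = K1/k2`.
* **Total body clearance.** `tbc()` computes
  `TBC = ID / AUC(0–90 min)` in mL/min/kg from the injected dose per kg
  and the image-derived input function, with frame-rectangle AUC
  integration (`auc()`).
* **Image-derived input function.** `build_idif()` reproduces the
  heart-region procedure: average the frames inside the first 20 s, take
  the six most intense axial slices, place a 15-pixel circle on each
  slice's intensity-weighted centroid, and extract the TAC of the circle
  union. `render_phantom()`/`extract_tac()` provide the 4D phantom and
  VOI machinery (NIfTI-1 I/O included); `to_suv()` converts
  concentrations to standard uptake values.
* **Group statistics.** `compare_groups()` gates on a Monte-Carlo
  Lilliefors normality test, then applies Student's pooled-variance t
  test or the exact Mann–Whitney rank-sum test; `pearson_r()` adds the
  correlation layer.
* **Synthetic cohorts.** `simulate_cohort()` draws subjects, plasma input
  functions, image-derived input functions and bilateral renal-cortex
  TACs with duration-scaled noise. `default_presets()` encodes six study
  groups (control, WT, TGF-β1-transgenic CKD, OCT1/2 knock-out,
  cimetidine, pyrimethamine) whose ground truth carries the published
  effect sizes: K1 2.2-fold lower and clearance 1.8-fold lower in CKD,
  clearance 3.0-/2.5-fold lower under OCT1/2 ablation/inhibition,
  1.1-fold higher under MATE1 inhibition.
* **Pipeline.** `run_study()` chains simulate → (optional phantom
  imaging) → fit → clearance → statistics into one seeded, byte-for-byte
  reproducible report; `report_table1()` produces the clearance
  fold-change summary. `exec/metkin` is a thin CLI over these functions.

## Worked example

```r
library(metkin)
presets <- default_presets()
wt <- simulate_cohort(presets$WT, seed = 1)   # 5 wild-type mice
s <- wt$subjects[[1]]

summary(fit_1tcm(s$cortex_left, s$idif))
#>    Estimate Std. Error
#> K1  0.77070     0.0321
#> k2  0.14407     0.0106
#> RSS 194378 over 33 frames, residual sigma 79.19 kBq/mL
#> Distribution volume K1/k2 = 5.349 mL/mL
```

The fitted `K1 = 0.77 min⁻¹` recovers this subject's ground truth
(0.80 min⁻¹) to within the noise; `K1/k2 ≈ 5.3 mL/mL` is the equilibrium
tissue-to-plasma ratio, and the Logan slope agrees with it independently:

```r
logan_vt(s$cortex_left, s$idif)
#> Logan analysis (kidney_cortex_l), t* = 20 min, 8 points
#>   V_T (slope) = 5.209 mL/mL, intercept = -5.225 min, R^2 = 0.9999

tbc(s$subject, s$idif)
#> TBC = 50.13 mL/min/kg (ID 3.237e+05 kBq/kg / AUC 6456 kBq*min/mL)
```

At the study level, the clearance fold-change table relative to control
(arrows mark the direction, `v` = lower clearance than control):

```r
report_table1(study_config(groups = c(control = 5L),
                           control = "control", seed = 1))
#> Fold-change in TBC relative to control
#>   Tg             (n=8)  1.8 v  P=7.69e-15
#>   oct12_ko       (n=4)  2.99 v  P=1.22e-11
#>   cimetidine     (n=5)  2.48 v  P=1.21e-12
#>   pyrimethamine  (n=4)  1.08 ^  P=9.06e-05
```

The CKD group clears the tracer 1.8-fold slower than control, OCT1/2 loss
or blockade 3.0-/2.5-fold slower, and MATE1 blockade slightly faster —
the effect sizes the presets encode, recovered through the full
image-quantification chain under realistic noise.

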