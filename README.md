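# sctDose

Dose-derived rectal toxicity prediction under synthetic-CT (sCT)
substitution for MR-only prostate radiotherapy.

## The problem

In an MR-only radiotherapy pathway the planning CT is replaced by a
synthetic CT derived from MR, and dose — and every toxicity prediction
downstream of dose — is computed on surrogate electron densities. For
toxicity-guided adaptive treatment the question is not only whether target
coverage survives the substitution, but whether the *risk models* do:

* **LKB NTCP** from the rectal dose-volume histogram: with the
  fractionation-corrected generalized equivalent uniform dose
  `gEUD = (Σ v_i · D_i^{1/n})^n` (EQD2, α/β = 3 Gy), the complication
  probability is `NTCP = Φ((gEUD − TD50) / (m · TD50))`, with
  (TD50, m, n) = (97.7 Gy, 0.27, 0.085) for grade-2 rectal bleeding and
  (105.0 Gy, 0.43, 1.0) for late faecal incontinence.
* **Dose-surface-map (DSM) parameters**: the rectal surface dose unwrapped
  from the posterior-most contour point clockwise, interpolated to a
  42 × 42 map, EQD2-converted, binarized at 51 and 61 Gy; the relative
  51 Gy area (risk cut-off 0.374) and the relative lateral extent of the
  largest 61 Gy cluster's moment ellipse (cut-off 0.591).

`sctDose` implements the full comparison pipeline: a seeded synthetic
pelvic phantom generator (co-registered CT + T2-like MR + contours + a
60 Gy / 20 fraction plan), three sCT strategies — bulk density (water or
population HU), tissue stratification with nominal HUs (−75 fat, 0
muscle, 204 spongy, 1067 cortical, −500 inside air) including the
CT-stratified control, and a from-scratch CPU 2D U-Net trained on
normalized MR→CT slice pairs — a simplified ray-tracing dose engine with
fixed-monitor-unit recalculation, 3D local gamma analysis (2%/2 mm,
>20% of maximum), and the paired statistics layer (Bland-Altman limits
of agreement, paired t, Shapiro-Wilk).

## Worked example

```r
library(sctDose)

ph  <- generatePhantom(PhantomConfig(seed = 1))
ptv <- structureMask(ph@structures, "PTV60")

planned <- planDose(ph@ct, ph@plan, ptv)   # fixes muScale: PTV60 median = 60
ph@plan <- planned$plan
truth <- toxicityPredictors(planned$dose, ph)

sct  <- makeSCT(ph, "bdw")                 # water bulk density
dose <- recalcFixedMU(sct, ph@plan, ptv)   # identical engine, fixed MU
pred <- toxicityPredictors(dose, ph)

round(unlist(truth), 3)
#    ptv60_median        ptv60_d95        ptv48_d95   rectum_v60_pct
#          60.000           58.921           54.308            0.000
#   g2rb_risk_pct     lfi_risk_pct        g2rb_geud       rel_area51
#           1.699            3.038           41.767            0.075
# rel_lat_extent61
#           0.055
round(pred$g2rb_risk_pct - truth$g2rb_risk_pct, 3)
# [1] 0.102
gammaAnalysis(planned$dose, dose)
# GammaResult: 99.99% of 274983 voxels pass (gamma <= 1)
```

The phantom's plan meets its clinical constraints (PTV60 median 60 Gy,
D95 58.9 ≥ 57 Gy, PTV48 D95 54.3 ≥ 45.6 Gy, rectal V60 = 0); the
ground-truth bleeding risk (1.7%) and DSM parameters sit inside the
ranges the risk models were built for. Replacing the CT by a
water-equivalent bulk-density sCT shifts the predicted bleeding risk by
+0.10 percentage points here even though 99.99% of voxels pass 2%/2 mm
gamma — the motivating observation: global dose agreement does not
guarantee toxicity-prediction agreement.

`runSCTStudy(seeds, methods = c("bdw", "ts", "ai"))` repeats this over a
seeded phantom cohort (training the U-Net on the phantoms' own slices)
and returns per-method `PairedErrors` for every predictor, ready for
`buildReport()`.

## Layout

* `R/` — S4 classes (`ImageGrid`, `StructureSet`, `Phantom`,
  `PlanConfig`, `DVHCurve`, `DoseSurfaceMap`, `LKBParams`, …) and the
  module functions; `src/` — Rcpp/RcppArmadillo kernels.
* `vignettes/sctDose-methods.Rmd` — models, assumptions, parameter
  choices, numerical conventions and limitations.
* `tests/testthat/` — unit, property and oracle tests per module plus the
  end-to-end acceptance suite.
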