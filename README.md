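# castrr

Voxel-wise mapping of the **brain–blood partition coefficient of water
(BBPC)** from multi-TR gradient-echo MRI, and its application to correcting
arterial-spin-labeling (ASL) cerebral blood flow (CBF) maps.

## The problem

ASL quantifies CBF using magnetically labeled arterial water as an
endogenous tracer. The quantification needs the partition coefficient λ of
water between brain tissue and blood, conventionally *assumed* to be a
constant 0.9 mL/g everywhere — even though λ varies by tissue, age,
species, and pathology. Calibrated short-TR recovery (CaSTRR) measures λ
per voxel in a few minutes: a phase-spoiled gradient-echo stack is acquired
at several repetition times (TR = 125, 250, 500, 1000, 2000 ms), each
voxel's signal recovery is fit to the saturation-recovery model

    S(TR) = M0 · (1 − exp(−TR / T1)),

and the proton-density map `M0` (arbitrary units) is converted to absolute
water content `WC` by one of two calibrations:

* **phantom route** — five D2O/H2O vials (40/30/20/10/0 % D2O, doped with
  0.18 mM gadobutrol so T1 ≈ 1.2 s) scanned with the subject span a known
  60–100 % water scale; ordinary least squares of known water fraction on
  mean vial M0 gives the mapping. A cohort-level regression of the
  tissue/phantom signal ratio on phantom intensity quantifies a quadratic
  scanner nonlinearity (error term Δᵢ = β·Pᵢ², subtracted from tissue and
  blood values before normalization);
* **hematocrit route** — the blood sample's water content follows
  `WC_blood = −0.271·Hct + 0.912`, and the map is rescaled so the blood-ROI
  mean matches it (no vials needed).

BBPC and the corrected CBF map then follow voxel-wise:

    BBPC = WC_brain / (WC_blood · 1.04 g/mL)
    cCBF = CBF / 0.9 · BBPC

Between the fit and the calibration, receive-coil inhomogeneity is removed
by an EM bias-field algorithm (4th-order log-polynomial field plus a
six-component Gaussian mixture), with the bright vials excluded from the
estimation and the correction applied to the whole volume.

Because no real image data are deposited for this method, the package
includes a first-class synthetic-cohort simulator with known ground truth
(tissue geometry, bias field, per-subject gain, phantom nonlinearity,
Rician noise, CBF), so every stage is verifiable by parameter recovery.

## Worked example

```r
library(castrr)

cfg <- sim_config(n_subjects = 15, snr = 50, seed = 42)   # 96x88x30 voxels
cohort <- make_cohort(cfg)
res <- process_cohort(cohort)        # fit -> bias-correct -> calibrate -> BBPC -> cCBF
sm <- cohort_summary(res$report)

round(c(gm_phantom = sm$bbpc_gm_phantom_mean, wm_phantom = sm$bbpc_wm_phantom_mean,
        gm_hct = sm$bbpc_gm_hct_mean, wm_hct = sm$bbpc_wm_hct_mean), 3)
#> gm_phantom wm_phantom     gm_hct     wm_hct
#>      0.804      0.755      0.811      0.757
round(c(r2_gm = sm$agreement_gm$r_squared, cnr_before = sm$cnr_uncorrected_mean,
        cnr_after = sm$cnr_corrected_mean), 3)
#> r2_gm cnr_before  cnr_after
#> 0.844      1.257      1.514
```

The cohort's generative truth for this seed has mean GM BBPC 0.819 and WM
0.769 mL/g (per-subject truths are drawn around 0.83 ± 0.05 and
0.78 ± 0.04), so both calibration routes recover the realized tissue means
to within ±0.02 mL/g; the two routes correlate across subjects (R² = 0.84, mirroring
the strong gray-matter agreement the method reports on real cohorts), and
voxel-wise BBPC correction raises the gray–white CNR of the CBF maps.

`attr(cohort, "truth")` holds the per-subject ground truth;
`res$report` has one row per subject (BBPC by route and tissue, CBF and
CNR before/after correction, the quadratic error term Δᵢ).

## Command line

```sh
castrr simulate --n 15 --snr 50 --seed 7 --out-dir sim
castrr fit --config sim/cohort.yaml --subject sub01 --out-dir work
castrr bias-correct --config sim/cohort.yaml --subject sub01 --out-dir work --k 6 --order 4
castrr bbpc --config sim/cohort.yaml --subject sub01 --out-dir work --method phantom
castrr correct-cbf --config sim/cohort.yaml --subject sub01 --out-dir work
castrr report --config sim/cohort.yaml --out-dir work
```

The launcher script is installed at `inst/cli/castrr`; equivalently call
`castrr_cli(c("simulate", "--n", "15"))` from R.

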