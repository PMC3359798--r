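# dcekin

Physiological compartment modelling of brain DCE-MRI concentration data.

## What this is for

Dynamic contrast-enhanced MRI (DCE-MRI) with a slow infusion of an
extracellular gadolinium agent yields concentration–time curves, in mM
over minutes, for every voxel or region of the brain. `dcekin` is for
researchers who want to turn such curves into quantitative physiology:
blood-pool kinetics, blood–brain-barrier permeability of tissue voxels,
and input/output flow rates of cerebrospinal-fluid (CSF) spaces — and, at
the cohort level, a sensitive indicator of CSF flow disturbance across
disease stages (e.g. communicating hydrocephalus). Because real
slow-infusion brain DCE-MRI datasets are scarce, the package ships a
synthetic cohort and 4D phantom generator so every stage of the pipeline
is testable end to end without any scanner data.

## The models

**Blood pool** — spins enter the circulating pool at a concentration rate
C_IN (mM/min) and are eliminated at k_OUT (1/min):

    AIF(t)     = C_IN · t · exp(−k_OUT t)
    C_BLOOD(t) = (1 − Hct) · AIF(t)

**Tissue voxel** — four compartments (blood, EES, IES, and a
water-inaccessible space NOW) with fractional volumes summing to 1;
Kety–Schmidt exchange across the blood–EES barrier and first-order
exchange across the EES–IES barrier:

    dC_EES/dt + k_EP · C_EES = k_TRANS · C_BLOOD(t)
    dC_IES/dt + k_IP · C_IES = k_PI    · C_EES(t)
    C_TISSUE = v_BLOOD·C_BLOOD + v_EES·C_EES + v_IES·C_IES

k_TRANS = 0 means an intact blood–brain barrier: the voxel enhances
through its blood compartment only.

**CSF voxel** — two compartments (blood, CSF); filtration fills the CSF
space at k_IN′ (mM/min) and evacuation empties it at k_OUT′ (1/min):

    CSFIF(t) = k_IN′ · t · exp(−k_OUT′ t)
    C_CSF_VOXEL = v_BLOOD·C_BLOOD + v_CSF·CSFIF

**IOF statistic** — per CSF region, stage-mean rates are normalized by the
control-stage means and compared:

    IOF = mean(k_IN′)|normalized / mean(k_OUT′)|normalized

Control IOF is exactly 1; IOF > 1 flags a predominant input-mechanism
disturbance, IOF < 1 a predominant output one (its reciprocal 1/IOF is
reported alongside).

Fitting is two-stage bounded Levenberg–Marquardt least squares: blood
parameters from a blood ROI first (hematocrit supplied), then tissue or
CSF parameters conditional on them, with volume closure enforced
structurally. See the vignette
(`vignettes/compartment-modelling.Rmd`) for closed forms, numerical
safeguards and identifiability notes.

## Worked example

Fit a noisy synthetic blood curve, then run a full simulate → fit → IOF
recovery experiment in which the mild stage's CSF input rate is doubled:

```r
library(dcekin)

b  <- blood_params(c_in = 0.05, k_out = 0.03, hct = 0.45)
tt <- seq(0, 60, by = 1)
curve <- generate_curve("blood", list(blood = b), tt, noise_sd = 0.005, seed = 42)
fit_blood(curve, hct = 0.45)
#> <dcekin_fit: blood model, rss = 0.00193713 mM^2, converged in 8 iterations>
#> <blood_params: c_in=0.0500183 mM/min, k_out=0.0300654 1/min, hct=0.45>

sp  <- scale_stage(cohort_spec(n_per_stage = 25), "mild", "k_in_prime", 2)
recover_cohort(sp, seed = 42)
#> <dcekin_recovery>
#>
#> Parameter recovery (median relative error):
#>    parameter median_rel_error
#>         c_in      0.004636922
#>        k_out      0.003523684
#>   k_in_prime      0.048728110
#>  k_out_prime      0.016258158
#>
#> IOF from estimated rates:
#>             region   stage       iof predominance
#>  lateral_ventricle control 1.0000000     balanced
#>  lateral_ventricle    mild 2.0179059        input
#>  lateral_ventricle  severe 0.9837492       output
```

The blood fit recovers the generating rates to a fraction of a percent at
0.005 mM noise. In the cohort run, the control stage self-normalizes to
IOF = 1 exactly; the doubled mild-stage input rate is read back as
IOF ≈ 2 (input-predominant disturbance), while the unmodified severe
stage stays near 1.

A command-line wrapper over the same functions lives in
`inst/cli/dcekin.R`:

```sh
Rscript inst/cli/dcekin.R simulate --config cohort.yaml --seed 7 --out out/
Rscript inst/cli/dcekin.R recover  --config cohort.yaml --seed 7 --out out/
Rscript inst/cli/dcekin.R iof --rates rates.tsv --control control --out iof.tsv
```

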