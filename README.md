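# tkvtools

Semi-automated measurement of **total kidney volume (TKV)** from coronal
T2-weighted abdominal MRI in autosomal dominant polycystic kidney disease
(ADPKD), for imaging scientists and renal researchers who need TKV as a
prognostic biomarker without the cost of fully manual contouring.

From one user-drawn seed contour per kidney (mid-coronal slice), two sagittal
landmark points and a crop rectangle, the pipeline selects the kidney-bearing
slices, corrects inter-slice motion (rigid registration), intra-slice bias
fields (histogram-entropy minimisation over a smooth multiplicative
polynomial field) and inter-slice gain drift (bright-tissue normalisation),
then propagates a **hybrid level-set** contour through the stack. With `phi`
negative inside, `H` a smoothed step and `g = 1/(1 + c|∇I|²)` the edge map,
the contour descends

    E(phi) = -alpha ∫ (I - mu) (1 - H(phi)) dΩ  +  beta ∫ g |∇H(phi)| dΩ

— a region force (enclose voxels brighter than `mu = 50` on a 0–255 working
scale, expel darker ones) regularised by edge-weighted curvature flow that
pins the contour to boundaries. Defaults `alpha = 0.01`, `beta = 100`,
100 iterations. Kidney volume is the area × slice-thickness sum in ml; TKV is
right + left.

The package also provides the comparison estimators and evaluation machinery
used in method-agreement studies:

- **ellipsoid** (`pi/6·L·W·D`, refusing atypical morphology) and
  **mid-slice** (`0.624 · area · n_slices · thickness`) estimates;
- **Mayo imaging classification** 1A–1E from HtTKV and age via the implied
  growth rate `(HtTKV/150)^(1/age) - 1`, with borderline flagging;
- **agreement statistics**: Dice, Bland–Altman bias and limits of agreement
  (raw/percent), test–retest CoV, limits-of-agreement **sample-size
  planning**, and per-method volume-error tables with plots;
- a **synthetic phantom generator** (ellipsoidal cystic kidneys inside an
  abdominal cross-section, with injected gain/bias/motion/noise and exact
  analytic ground truth) that backs the whole validation suite;
- batch **commands** (`cmd_segment`, `cmd_estimate`, `cmd_classify`,
  `cmd_agreement`, `cmd_simulate`) plus a thin shell wrapper at
  `inst/cli/tkv.R`.

## Worked example

Segment a synthetic patient with a known 1167 ml TKV (12 cysts per kidney,
noise, inter-slice gain drift), then classify the result:

```r
library(tkvtools)

spec <- phantom_two_kidney_spec(tkv_ml = 1167, seed = 42, n_cysts = 12,
                                noise_sd = 3,
                                interslice_gain_range = c(0.9, 1.1))
ph  <- phantom_generate(spec)          # 231 x 35 x 147 voxel volume
res <- run_phantom_case(ph)            # landmarks/seeds derived from truth

res$report
#> <volume_report> [levelset] right 587.0 ml, left 586.8 ml, TKV 1173.8 ml

round(res$tkv_error_pct, 2)            # vs the analytic 1167 ml
#> [1] 0.58
round(res$dsc, 3)                      # Dice overlap vs ground-truth masks
#> right  left
#> 0.998 0.998

mayo_classify(height_adjust(res$report$tkv_ml, 1.72), age_years = 51)
#> $value            "1C"
#> $growth_rate_pct  3.02
#> $borderline       TRUE
#> $boundary         "1B/1C"
```

The measured TKV lands within 0.6% of the analytic truth; at height 1.72 m
and age 51 the implied growth rate of 3.02 %/yr sits on the 1B/1C boundary,
so the case is flagged borderline for manual reanalysis.

Planning an agreement study against a manual reference (expected bias 2%,
SD 5%, maximum acceptable difference 15%, alpha 0.05, power 0.80):

```r
ba_sample_size(expected_mean = 2, expected_sd = 5, max_allowed_diff = 15,
               alpha = 0.05, power = 0.80)
#> [1] 60
```

On real data, use `read_dicom_series()` / `read_nifti()` and either the R
functions (`tkv_pipeline()`) or the batch command with a JSON config:

```sh
Rscript inst/cli/tkv.R segment --config my_patient.json
```

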