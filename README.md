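# cartMorph

Fully automated knee cartilage morphometry and longitudinal biomarker
qualification, in R.

Quantitative cartilage thickness from 3D knee MRI is a structural endpoint
in osteoarthritis trials: over 24 months, knees with radiographic
progression (joint space narrowing) lose medial femorotibial cartilage,
non-progressors barely change, and the ability of an automated measurement
chain to *separate* those two groups is what qualifies it as a progression
biomarker. cartMorph implements that chain end to end for people who build
and validate such pipelines: segmentation post-processing (bone-area atlas,
rigid ICP registration, reconstruction of incomplete bone areas,
cartilage-to-bone linking, automated error correction), femoral
region-of-interest definition from detected landmarks, per-plate thickness
and denuded-area morphometry, and the group-level change statistics — all
exercised against a synthetic knee generator with analytic ground truth, so
every stage is testable without any clinical data.

The core quantities, in standard notation:

* **Cartilage thickness** over the total subchondral bone area (tAB) of a
  plate: per bone-surface point, the cartilage chord along the outward
  surface normal; denuded points (dAB, full-thickness loss) count as 0.
  Compartments add plates: MFTC = MT + cMF, LFTC = LT + cLF.
* **Sensitivity to change**: SRM = x̄ / SD(x), the standardized response
  mean of the per-knee 24-month change x, with a 95 % BCa bootstrap
  confidence interval (1000 iterations).
* **Group differentiation**: Cohen's D = (x̄₁ − x̄₂) / s_pooled with a
  noncentral-t 95 % interval, plus t-tests, threshold-based individual
  progressor proportions, and a chi-square test on those proportions.

A compact 2D U-Net (weighted cross-entropy with background at half the
foreground weight; Adam, learning rate 0.01, β₁/β₂ = 0.9/0.999) provides
an optional segmentation stage; a ground-truth oracle model makes the rest
of the pipeline independent of training.

## Worked example

Generate a phantom knee, measure it, and check against the analytic truth:

```r
library(cartMorph)

ph <- makePhantom(phantomSpec(seed = 1))
ph$mask
#> LabelMask 84 x 48 x 105 | spacing 0.36 x 0.7 x 0.36 mm | protocol sagittal-DESS
#>   labels present: background, MT, cMF, LT, cLF, tAB_MT, tAB_cMF, tAB_LT,
#>   tAB_cLF, femur, tibia

ph$summary            # analytic ground truth (quadrature of the field)
#>  region mean_thickness_mm dab_pct
#>      MT          1.592836       0
#>     cMF          1.758080       0
#>      LT          1.994846       0
#>     cLF          1.985541       0

measureMask(ph$mask, roiFraction = 0.75)[, c("region", "mean_thickness_mm")]
#>  region mean_thickness_mm
#>      MT              1.59
#>     cMF              1.74
#>      LT              1.99
#>     cLF              1.96
#>    MFTC              3.32
#>    LFTC              3.95
```

The measured plate means track the analytic field to ~1 % (the MFTC sum,
3.32 mm, sits in the published baseline range for radiographically
osteoarthritic knees). Simulating the published two-stratum cohort in
exact-moment mode and qualifying the change biomarker:

```r
tbl <- simulateCohort(cohortSpec(seed = 7), exact = TRUE)
rep <- cohortReport(changeScores(tbl), nBoot = 1000, seed = 1)
formatReport(rep)[, c("region", "mean_prog_um", "mean_ref_um",
                      "cohens_d", "srm_prog", "srm_ref")]
#>  region mean_prog_um mean_ref_um cohens_d srm_prog srm_ref
#>    MFTC         -160          -8    -0.87    -0.72   -0.07
```

That is: progressors lose 160 µm (SRM −0.72), non-progressors 8 µm
(SRM −0.07), and the two groups separate with Cohen's D = −0.87 — the
qualification pattern a useful structural biomarker must show. The
end-to-end image-based driver (`runPipeline()`, or
`inst/scripts/run_pipeline.R` from a shell) runs the same analysis from
simulated volumes through segmentation, repair and morphometry to this
report, deterministically under a fixed seed.

## Documentation

The methods vignette (`vignettes/cartMorph-methods.Rmd`) documents the
phantom model and its assumptions, the thickness metric and its numerical
choices, the post-processing rules, the statistical conventions, and known
limitations.
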