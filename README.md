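# teatherm

Delta thermal radiomics for infrared thermograms of dairy cow teats.

Handheld thermal cameras export **colorized** images: a 3-channel palette
rendering of the skin temperature field plus a displayed min/max range.
`teatherm` turns those images back into calibrated temperature maps and
quantifies how the teat's thermal signature changes after machine milking
("delta radiomics"). It is aimed at veterinary and precision-livestock
researchers who want quantitative, reproducible image biomarkers from
thermography instead of a single bulk temperature reading.

The toolkit covers the full workflow:

* **Conversion** — a color lookup table anchored at the displayed range
  inverts the palette by nearest-color matching; temperatures are quantized
  to 0.1 °C and stored as unsigned integers at 10 units per °C, written and
  read as single-frame 16-bit DICOM (rescale slope 0.1, so viewers display
  °C).
* **Segmentation handling** — polygon teat traces (closed with a chord at
  the udder attachment), even-odd rasterization, and Dice agreement
  `2|A∩B|/(|A|+|B|)` with percentile-bootstrap confidence intervals.
* **Feature extraction** — a fully named 851-biomarker panel per ROI:
  14 shape + 93 intensity/texture features (18 first-order, 24 GLCM,
  16 GLRLM, 16 GLSZM, 14 GLDM, 5 NGTDM) on the original image and the same
  93 on each of 8 undecimated-Haar wavelet sub-bands, under fixed settings
  (no interpolation, bin width 0.1 °C, symmetric GLCM).
* **Expression screening** — per feature, a paired Student's t-test and
  Cohen's d (pooled SD); a biomarker is *expressed* when `p < 0.01` and
  `|d| > 1.2` jointly.
* **Feature maps** — sliding-window (default 10×10 px) maps of local mean,
  skewness, gradient magnitude and entropy, with pre/post difference maps.
* **Phantoms** — synthetic teat thermograms (superellipse teats with an
  apex temperature ramp, known ground truth, Gaussian + salt-and-pepper
  noise, paired pre/post cohorts with injected effects) so the entire
  pipeline is testable without animal data.

## Worked example

```r
library(teatherm)

# a full-frame synthetic thermogram with two teats and known ground truth
ph <- generate_phantom(phantom_spec(), seed = 42)

# invert the colorized image back to temperatures and extract all biomarkers
tmap <- convert_to_temperature(ph$image, ph$lut)
fv <- extract_all(tmap, ph$masks[["left hind teat"]])
length(fv)
#> [1] 851
round(fv[c("original_firstorder_Mean", "original_shape_Sphericity",
           "original_glcm_SumAverage", "original_ngtdm_Strength")], 4)
#>  original_firstorder_Mean original_shape_Sphericity
#>                   33.1602                    0.8821
#>  original_glcm_SumAverage   original_ngtdm_Strength
#>                   35.3431                    1.6174

# a 36-teat pre/post cohort with a +2 degC mean shift and 31% elongation
spec <- single_teat_spec(96, 120); spec$noise_sigma <- 0.3
cohort <- generate_cohort(36, effect_spec(d_mean = 2, elongation = 1.31,
                                          area_factor = 1.5),
                          spec = spec, seed = 7, render = FALSE)
tabs <- cohort_feature_tables(cohort, extraction_settings(
  wavelet = FALSE, classes = c("shape", "firstorder")))
res <- expression_screen(tabs$pre, tabs$post)
expression_counts(res)
#> $significant   [1] 23
#> $effect_size   [1] 21
#> $expressed     [1] 21
```

The mean temperature comes out expressed (`p = 8.3e-84`, `d = 4.3`, +6.0 %
of the pre-milking mean) and the major axis length recovers the injected
+31 % elongation (`percent_diff = 31.0`), while mean-independent features
such as skewness stay unexpressed on this effect — the screen separates
what changed from what did not.

Dice agreement between two observers' masks is summarized the same way:

```r
dice_summary(c(0.97, 0.93, 0.95, 0.96, 0.92, 0.94, 0.98, 0.95), seed = 1)
#>  mean lower upper
#> 0.950 0.938 0.964
```

A thin command-line wrapper over these functions lives at
`inst/cli/teatherm.R` with subcommands `convert`, `dice`, `extract`,
`delta`, `maps`, `simulate` and `run`:

```sh
Rscript inst/cli/teatherm.R simulate --n 36 --dmean 2 --seed 7 --outdir sim/
Rscript inst/cli/teatherm.R convert --image sim/teat01_pre.png \
    --tmin 5 --tmax 40 --colormap iron --out teat01.dcm
```

See `vignettes/delta-thermal-radiomics.Rmd` for the models, conventions and
design decisions (wavelet sub-band convention, perimeter estimator, GLDM
indexing, screen defaults) and for what phantom-based validation does and
does not establish about real cow images.

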