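# ihcscore

Automated four-tier scoring of DAB-stained immunohistochemistry (IHC)
images, for pathologists and image-analysis developers who need an
unbiased, reproducible alternative to visual grading of antibody
staining intensity.

IHC slides carry a brown DAB (3,3′-diaminobenzidine) chromogen where
the marker protein is expressed and a blue hematoxylin counterstain.
`ihcscore`:

1. **Unmixes** the RGB photomicrograph into pure-stain channels by
   Beer–Lambert color deconvolution. Per channel,
   `OD_c = −log10(I_c / I0_c)`, and co-localized stains add linearly in
   OD space, `od = A_H·s_H + A_D·s_D`, so inverting the matrix of unit
   stain vectors `(s_H, s_D, s_C)` recovers the per-pixel stain
   amounts. The third, *complementary* channel should come out empty
   and serves as a calibration diagnostic.
2. **Profiles** the reconstructed 8-bit DAB channel pixel by pixel
   into four calibrated intensity zones — high positive [0, 60],
   positive [61, 120], low positive [121, 180], negative [181, 235];
   intensities 236–255 (fatty tissue, blank areas) are excluded.
3. **Scores** the image: a zone holding ≥ 66 % of scored pixels wins
   directly (majority rule); otherwise the weighted formula
   `score = Σ pct_z · w_z / 100` with weights 4/3/2/1 applies, mapped
   to the nearest tier. Nuclear markers are scored over a
   threshold-derived mask of the DAB-positive nuclei.
4. **Validates** automated against manual scores with percent
   agreement, Cohen's kappa (with large-sample confidence interval)
   and the chi-square test over 4×4 score tables.

A synthetic-image generator (`renderSynthetic()`, `makeZoneMixture()`,
`makeNuclearBlobs()`) forward-composes known stain-density fields
through the same Beer–Lambert model, so the full pipeline is testable
against exact ground truth.

## Worked example

Score a synthetic image with a known zone composition, then reproduce
the validation statistics from the shipped automated-vs-manual score
table:

```r
library(ihcscore)

sp <- makeZoneMixture(c(high_positive = 0.15, positive = 0.55,
                        low_positive = 0.20, negative = 0.10),
                      size = 128, seed = 42)
img <- renderSynthetic(sp)$image      # 128x128x3 RGB array
res <- scoreImage(img)                # cytoplasmic-marker pipeline
res$report
#> IHC score log
#>   high_positive:  15.00 %
#>   positive:       55.00 %
#>   low_positive:   20.00 %
#>   negative:       10.00 %
#>   excluded:        0.00 %
#> Score: 2.750  ->  positive  (weighted formula)
```

No zone reaches 66 %, so the weighted formula fires:
`(15·4 + 55·3 + 20·2 + 10·1)/100 = 2.75`, which rounds to the
"positive" tier. The requested zone fractions are recovered exactly —
the deconvolution round trip is lossless up to 8-bit quantization.

```r
tab <- readContingencyTable(
  system.file("extdata", "agreement_manual_vs_automated.csv",
              package = "ihcscore"),
  raters = c("automated", "manual"))
percentAgreement(tab)   # 88.6
cohenKappa(tab)         # 0.843 (95% CI 0.819-0.867 via kappaCI)
```

On the 1320-case automated-vs-manual validation table, the automated
scorer matches the pathologists' consensus on 88.6 % of cases with
kappa 0.843 — "very good" agreement, and far above the kappa observed
*between* pathologists on discordant cases (−0.669 to 0.715; see the
other `agreement_*` tables in `inst/extdata/`).

Real images are read with `readRGBImage()` (JPEG/PNG/TIFF/BMP);
nuclear markers go through `scoreNuclear(img, threshold = 180)` (or
`threshold = "auto"` for Otsu). A command-line wrapper with `score`,
`agree` and `synth` subcommands is installed at
`system.file("scripts", "ihc-score.R", package = "ihcscore")`.

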