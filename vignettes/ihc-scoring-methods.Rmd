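---
title: "Methods: stain unmixing and four-tier scoring of DAB images"
author: "ihcscore"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stain unmixing and four-tier scoring of DAB images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ihcscore)
```

## The measurement problem

Immunohistochemistry (IHC) visualizes a marker protein with a brown DAB
(3,3'-diaminobenzidine) chromogen over a blue hematoxylin counterstain,
and a pathologist grades the stain intensity on a four-tier scale: high
positive (3+), positive (2+), low positive (1+), negative (0). Manual
grading is slow and subject to inter-observer perception bias — on
discordant cases, two experienced observers can agree *worse than
chance* (the shipped `agreement_observer1_vs_observer2` table has
kappa = -0.669). `ihcscore` automates the grade: it separates the DAB
signal from the counterstain by optical-density color deconvolution,
profiles every pixel of the reconstructed DAB channel into four
calibrated intensity zones, and assigns the tier by an explicit,
reproducible rule.

## Beer–Lambert unmixing

A brightfield camera measures transmitted light. Under the Beer–Lambert
law the per-channel optical density

$$OD_c = -\log_{10}\!\left(\frac{I_c}{I_{0,c}}\right) = A \cdot s_c$$

is proportional to the amount of stain $A$, with $s_c$ the stain's
absorbance fraction in channel $c \in \{R,G,B\}$. Stains co-localized
in one pixel add *linearly in OD space*, so a two-stain pixel is

$$\mathbf{od} = A_H \mathbf{s}_H + A_D \mathbf{s}_D,$$

and the stain amounts are recovered by inverting the matrix of unit
stain vectors. `ihcscore` completes the hematoxylin/DAB pair with a
third *complementary* vector (the cross product, negative components
zeroed, renormalized — flipped first if entirely non-positive, since
the cross product's orientation is arbitrary) and inverts the
row-stacked $3\times3$ matrix once per system:

```{r}
defaultStainSystem()
```

Design choices worth making explicit:

* **Default vectors.** The Ruifrok & Johnston H-DAB calibration,
  hematoxylin $(0.650, 0.704, 0.286)$ and DAB $(0.269, 0.568, 0.778)$,
  is a reproducible, widely used default. The method itself is
  vector-agnostic: any laboratory can substitute its own calibration
  via `estimateStainVector()` on a single-stain control slide, or a
  JSON config (`readStainConfig()`).
* **Background intensity** $I_0$ defaults to 255 per channel and is
  overridable; properly exposed acquisitions normalize the blank field
  near the top of the 8-bit range.
* **Dark-pixel floor.** Transmitted intensity is floored at 1 count
  before the logarithm, capping OD at $-\log_{10}(1/255) \approx
  2.4065$. This avoids infinities while matching the real dynamic
  range of an 8-bit camera.
* **No regularization.** `deconvolve()` is exact linear algebra. Small
  negative densities produced by noise are preserved in the density
  matrices and clamped to zero only at the 8-bit display boundary
  (`densityToIntensity()`, $I = \mathrm{round}(255 \cdot
  10^{-\max(d,0)})$, monotone non-increasing in $d$). Keeping the
  linear contract exact makes the round-trip properties testable to
  machine precision.

### The complementary channel as a quality diagnostic

A genuine two-stain image has no energy along the complementary
direction, so after a correct unmixing the complementary channel
renders almost entirely blank (intensity 255).
`complementaryResidual()` counts the pixels at 255; miscalibrated
vectors leak true stain into the complementary image and depress that
count by orders of magnitude. One subtlety the test suite encodes:
rotating a stain vector *within* the hematoxylin–DAB plane does not
change the plane and leaves the complementary coordinate untouched,
and rotating it towards the complementary axis pushes the residual
negative, which the display clamp renders blank. The physically
meaningful miscalibration — the one that mimics contaminated
separations — rotates a vector *away* from the complementary axis, and
that is the perturbation the paired comparisons use.

## Zone profiling and the score

The reconstructed DAB channel uses the standard 8-bit convention: 0 is
the darkest (strongest stain), 255 the lightest. The intensity axis is
partitioned into four calibrated zones with integer weights:

```{r}
defaultZones()
```

Intensities 236–255 predominantly represent fatty tissue and blank
areas; they are excluded from scoring entirely — they appear in the
profile as `excludedCount` but never enter the percentage denominator.
The zone table is configurable for other chromogens; the negative zone
is taken inclusive of 235, the exclusion band as [236, 255].

`computeScore()` applies two rules, in order:

1. **Majority rule.** If one zone holds $\geq 66\%$ of the *scored*
   pixels (inclusive comparison), its tier is assigned directly and
   the numeric score is that zone's weight.
2. **Weighted formula.** Otherwise the numeric score is
   $\sum_z \mathrm{pct}_z w_z / 100 \in [1, 4]$.

The weighted formula yields a real number, and the mapping from score
to tier is a genuinely open design point; `ihcscore` rounds to the
nearest zone weight, with exact midpoints (e.g. 2.5) rounding *up*
towards the stronger tier — the natural inverse of the weight scale,
and easy to re-derive from a report since both the score and the
percentages are returned.

```{r}
profile <- zoneProfile(matrix(c(rep(30L, 40), rep(90L, 30),
                                rep(150L, 20), rep(208L, 10)), 10))
computeScore(profile)
```

## Nuclear markers

Nuclear proteins stain only the nuclei, so scoring the whole frame
dilutes the signal with unstained area. The nuclear mode selects
DAB-positive pixels with an intensity threshold (dark-object
convention: `intensity <= threshold` is selected) and profiles only
the selection. The threshold is deliberately user-defined — choosing
it is an interactive judgement on real slides — with Otsu's method
(`autoThreshold()`, exhaustive between-class variance maximization on
the 256-bin histogram, ties broken to the lowest cut) available as an
explicit `"auto"` opt-in for unattended runs. No morphological cleanup
is applied by default; none is part of the method.

## Agreement statistics

Validation against manual scores uses 4×4 contingency tables in the
fixed tier order. `percentAgreement()` is the diagonal proportion;
`cohenKappa()` is the chance-corrected
$(p_o - p_e)/(1 - p_e)$; `chiSquareTest()` is the two-tailed Pearson
test (empty tiers dropped with a warning, reducing the degrees of
freedom from 9). For the kappa confidence interval the literature
offers several standard errors; `kappaCI()` uses the
Fleiss–Cohen–Everitt large-sample SE, which reproduces the published
intervals of all four shipped validation tables to three decimals —
strong evidence it is the estimator the original analysis used.

## The synthetic-image generator

Every pipeline stage is validated against images with *known* ground
truth, generated by running the Beer–Lambert model forwards
(`renderSynthetic()`): per pixel and channel,
$I_c = \mathrm{round}(I_{0,c} 10^{-(A_H s_{H,c} + A_D s_{D,c})} +
\varepsilon_c)$, $\varepsilon \sim N(0, \sigma)$, clamped to [0, 255].
All randomness flows from the spec's single seed through a local RNG
stream, so rendering is bit-reproducible and never disturbs the
session RNG.

The generator emulates: additive OD composition of two stains, 8-bit
quantization, additive Gaussian camera noise (in intensity space;
$\sigma = 2$ counts for nuclear fixtures, a typical read noise; 0 for
the noise-free fixtures), uniform background illumination, and
round nuclei (uniform disks by default; Gaussian-profile blobs with
soft edges as an option). It deliberately does **not** model tissue
texture, stromal morphology, uneven illumination, scanner color
management or stain-protocol variability — so passing tests certify
the *algorithmic* contract (unmixing, zoning, thresholds, scores), not
robustness to histology-grade variation, which only real slides can
probe.

Two fixture families drive the tests:

* `makeZoneMixture()` places requested pixel fractions at the zone
  *midpoint* intensities (30, 90, 150, 208; 248 for the excluded
  band) through the inverse intensity transform, apportioned by
  largest remainder so realized fractions match requests to within one
  pixel. Midpoints keep fixtures away from zone boundaries, so the
  8-bit round trip cannot flip a pixel's zone.
* `makeNuclearBlobs()` scatters disks of a chosen tier's midpoint
  intensity on a background at DAB intensity 240 (inside the excluded
  band, as blank/fatty regions are) over a constant hematoxylin
  counterstain (density 0.35), and records the exact mask and a
  workable threshold (nucleus intensity + 20).

## Numerical tolerances and problem sizes

With the H-DAB system (condition number $\approx 3.7$) the error of
the full quantized round trip — compose, round to 8 bits, OD
transform, unmix — is dominated by intensity quantization:
$\delta OD \approx 0.5/(I \ln 10)$ per channel, amplified by the
inverse matrix. The round-trip fixtures therefore draw per-stain
densities from $U(0, 0.5)$ (peak channel OD $\approx 0.53$,
transmitted light $\geq$ ~75 counts, i.e. moderately stained,
well-exposed material), where the worst-case recovery error stays
below $10^{-2}$ density units; the same path without quantization is
exact to $10^{-6}$ and better. Denser staining degrades recovery as
$1/I$ — an intrinsic property of 8-bit acquisition, not of the
algorithm.

Test and acceptance problem sizes were chosen as the smallest that
exercise every code path with comfortable statistical margins: ten
64×64 random-field images for round trips, fifty 32×32 mixtures for
the majority-rule property, one hundred 96×96 blob fixtures (cycling
all four tiers) for nuclear recovery and Otsu oracle equivalence, and
twenty paired 48×48 images for the complementary diagnostic. The whole
suite runs in seconds.

## Known limitations

* Membrane-bound markers are not supported; the zones are calibrated
  for cytoplasmic/nuclear DAB patterns.
* Two chromogens only (H + DAB); no trichrome or dual-chromogen IHC.
* No flat-field/illumination correction or white-balance estimation;
  inputs are assumed background-normalized.
* Stroma-rich fields dilute the automated score, because stromal
  pixels are counted where a pathologist would ignore them; the remedy
  is a user-supplied crop, mask, or higher-magnification field — tumor
  versus stroma classification is out of scope.
* The score characterizes stain *intensity* over area; it is not a
  percent-positive-cells score (no cell segmentation or counting).
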