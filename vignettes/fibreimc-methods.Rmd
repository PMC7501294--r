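---
title: "Single-fibre IMC analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-fibre IMC analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibreimc)
```

## The measurement problem

Imaging mass cytometry (IMC) of transverse skeletal-muscle sections yields
one 16-bit pseudo-image per metal-conjugated antibody at a fixed resolution
of 1 pixel per square micrometre. In mitochondrial myopathies the quantity
of interest is per-fibre: which muscle fibres express an
oxidative-phosphorylation (OXPHOS) subunit at a level that is abnormal
*given their mitochondrial content*? Mitochondrial mass varies strongly and
benignly between fibres (and pathologically in ragged-red fibres), so raw
subunit intensity is uninterpretable without a mass reference. `fibreimc`
uses VDAC1 (porin), an outer-membrane protein, as that per-fibre surrogate.

The pipeline has four stages, each usable on its own:

1. **Segmentation** of fibre cross-sections from the dystrophin membrane
   channel (or a gradient map of the mean of all channels).
2. **Quantification**: per-fibre mean intensity per channel plus morphology.
3. **Deficiency classification** relative to VDAC1, by two complementary
   methods (regression predictive interval; theta/KDE likelihood).
4. **Spatial analysis**: a hypergeometric test for clustering of deficient
   fibres.

## Segmentation and morphology filtering

Membrane signal is smoothed with a Gaussian kernel (`sigma = 2` px — about
half the membrane thickness, enough to bridge small gaps without merging
fibres), thresholded at Otsu's level, and fibres are taken as the
4-connected components of the complement. Regions touching the image frame
are discarded by default (`drop_border = TRUE`): fibres cut by the field
edge are incomplete cross-sections with biased area and morphology. A
one-pixel erosion of each region is available (`erode = TRUE`) for noisy
data where membrane signal bleeds into interiors; it is off by default
because it biases areas low.

Candidate regions are then filtered so that what survives plausibly is a
single transverse fibre section. Default bounds (`morphology_filter()`):
area 500–17,500 px (µm²), circularity 0–100, ellipse aspect ratio 0–10,
convexity 0.75–1. Definitions matter here:

* **circularity** is `perimeter^2 / (4 * pi * area)`, which is 1 for a disc
  and unbounded above — consistent with an upper bound of 100; the
  reciprocal definition (bounded by 1) would make that bound vacuous.
* **perimeter** uses the Crofton four-direction estimator, which converges
  to the true Euclidean boundary length for smooth digital shapes (a raw
  boundary-pixel count would overestimate a disc's perimeter by ~27% and
  poison circularity). This choice is part of the circularity definition
  and is documented accordingly.
* **aspect ratio** is the axis ratio of the best-fit ellipse from second
  central moments (with the 1/12 finite-pixel term, so a discrete
  `10 x 40` rectangle scores exactly 4).
* **convexity** is pixel area over the area of the convex hull of the
  pixel *corner* points (hulls of pixel centres undercount by a
  half-pixel rim; with corners a convex digital shape scores ~1).

Where membrane signal is too weak for automatic segmentation, a
user-supplied label map can be passed directly to `extract_features()` —
manual or external segmentations override nothing silently; they simply
replace the label matrix.

## The control regression band

For each target channel, ordinary least squares of channel intensity on
VDAC1 over *all control fibres*, with the textbook predictive interval at
level `1 - alpha` for a new control observation at reference value `x0`:

$$\hat y(x_0) \pm t_{1-\alpha/2,\,n-2}\; s \sqrt{1 + \tfrac1n +
\tfrac{(x_0-\bar x)^2}{S_{xx}}}$$

A patient fibre strictly below the lower bound is called `below`
(deficient relative to mass), strictly above the upper bound `above`
(relative upregulation), otherwise `within`; boundary ties count as
within. Bands are fitted per channel independently and no multiple-testing
correction is applied — the calls are descriptive per-fibre
classifications, not hypothesis tests over channels.

**Scale.** Regression, band and theta are computed on natural-log
intensities by default (`scale = "log"`), with non-positive values
replaced by half the smallest positive value. On the log scale the control
cloud is homoscedastic and control theta sits in the 45–70 degree range,
matching how these plots are conventionally read; `scale = "linear"` is
available.

## Theta and the KDE likelihood classifier

Theta is the angle a fibre's point (reference, target) makes with the
origin and the x-axis: `atan2(y, x) * 180 / pi`, in [0, 90] degrees on the
working scale. It compresses "expression relative to mass" into one
number: deficiency pushes theta towards 0, upregulation towards 90. Theta
is undefined at the origin (flagged `NA`, excluded from densities) and
invariant to joint positive rescaling of both coordinates.

Because a single straight band is often a poor description of patient
data (deficient fibres form a second population), fibres are also
classified by comparing Gaussian-kernel density estimates of theta for
the patient and the control populations (`stats::density`, Silverman
`nrd0` bandwidth, 512-point grid spanning the data ± 3 bandwidths, linear
interpolation between grid points and zero density outside). A patient
fibre is **affected** when its theta is more likely under the patient
density than the control density *and* lies outside the central 95%
percentile range (2.5th–97.5th empirical percentiles) of control thetas.
The percentile gate bounds the false-positive rate near 5% when patient
fibres are control-like. Two points were genuinely open and are decided
here:

* "95th percentile range" is read as the central 95% interval; the level
  is a parameter (`level`).
* The patient density includes the fibre being classified (no
  leave-one-out); with hundreds of fibres the effect of removing one is
  far below the bandwidth scale.

Pairwise structure across channels is summarised by
`theta_correlation_matrix()`: Pearson correlation of per-fibre thetas,
pairwise-complete, with constant channels flagged `NA`.

## Spatial neighbourhood enrichment

Each fibre's effective radius is that of the equal-area circle,
`sqrt(area / pi)`; two fibres are neighbours when their centroids lie
within 5 times the sample-average effective radius (both the multiplier
and Euclidean centroid distance are explicit choices; the graph is
symmetric, self-loop-free). The test asks whether deficient fibres are
over-represented in the union of the neighbourhoods of deficient fibres,
with the upper-tail hypergeometric probability
`P(X >= k), X ~ Hyp(N, K, n)` where `N` = fibres, `K` = deficient, `n` =
neighbour-set size, `k` = deficient fibres in the set.

Whether a deficient "seed" fibre may itself be counted in the neighbour
set is under-determined in the field. The default (`include_seeds =
TRUE`) counts a deficient fibre that is a neighbour of *another* deficient
fibre — a co-occurrence test. The strict exclusion convention
(`include_seeds = FALSE`) removes all deficient fibres from the set; with
binary labels nothing deficient remains to be found and the result is
degenerate at p = 1. Both are implemented so the convention is explicit
and auditable; only the co-occurrence form is informative with binary
labels.

**A structural caveat, quantified by the acceptance simulations.** The
neighbour threshold is ~2.5 fibre diameters in a packed mosaic, giving
each fibre roughly 17–25 neighbours. When the deficient fraction is
large (e.g. 30% of a 200-fibre section), the union of the seeds'
neighbourhoods covers nearly the whole section, so `n -> N`, `k -> K`,
and the test saturates: under uniform labels it rejects far *less* often
than 5% (conservative), and under seeded clusters — whose neighbourhoods
also blanket a small section — its power stays well below 90%. Clustered
labels do shift p-values systematically downward (the property the unit
tests assert), but at these problem sizes the hypergeometric
neighbourhood test is a blunt instrument; it discriminates best when
deficient fibres are rare or the section is large relative to the
neighbourhood radius. This is a property of the published test
definition, not of this implementation.

## The synthetic generator

`generate_mosaic()` emulates exactly the structure the analysis assumes,
so every stage is testable without patient images:

* **Geometry**: Lloyd-relaxed (3 iterations) Voronoi tessellation of
  uniform seeds on the pixel grid; cells touching the border are
  discarded; the membrane band is the set of pixels whose two nearest
  seed distances differ by less than `membrane_width` (default 3 px).
  Cells are convex and roughly isotropic, matching the convexity filter.
* **Intensities**: log-VDAC1 ~ Normal(5.0, 0.35) (≈150 ion counts,
  comfortably inside 16 bits); each target channel follows
  `log I_c = alpha_c + beta_c log V + N(0, sigma_c)` with defaults giving
  control theta ≈ 50 degrees and residual sd 0.12–0.15, a tight control
  band like real control sections. Deficient fibres have affected
  channels multiplied by `deficiency_factor` on the linear scale;
  ragged-red-like fibres get `rrf_vdac_factor` times the VDAC1 (target
  channels follow the control relation at the elevated mass).
* **Noise**: with `count_noise = TRUE` pixels are Poisson draws around
  the fibre mean (IMC measures ion counts); otherwise pixels carry the
  rounded mean exactly, which makes ground-truth equalities exact and is
  the default for oracle tests.
* **Nuclei**: small bright blobs at the fibre periphery in the DNA
  channel, as with an iridium intercalator.
* **Determinism**: the spec (including its seed) fully determines the
  output, bit for bit; the JSON form written by `write_mosaic_dataset()`
  regenerates the identical dataset.

What the generator does *not* emulate: isotope spillover between
channels, ablation artefacts, background staining gradients,
longitudinal-section geometry, and genuinely weak or broken membrane
signal. Passing tests on these mosaics therefore demonstrate correctness
of the algorithms under the model's assumptions, not robustness to every
failure mode of real sections — which is why the membrane-override path
for manual segmentation exists.

Fibre densities sometimes quoted for IMC acquisitions (~15 fibres per
mm²) are inconsistent with typical fibre cross-section areas at
1 px/µm² (a packed mosaic of 5,000 µm² fibres has ~200 per mm²); the
generator uses packed mosaics and does not attempt to match such
figures.

## Simulation sizes and numerical choices

Coverage simulations use 2,000 fibres per replicate (1,000 fit / 1,000
held out) over 50 replicates for the band, and 10,000 + 10,000 thetas
over 20 replicates for the percentile gate — enough that the Monte-Carlo
error on a 95% coverage is ~0.1–0.3 percentage points. Fraction-recovery
runs use 2,000 patient fibres; segmentation recovery uses 600×600 px
mosaics with 50 seeds (~25–30 surviving fibres each); spatial power/size
use 200-fibre point patterns over 100 replicates. Degenerate inputs are
handled explicitly: constant membrane images (no evidence — one
full-frame region if dark, none if saturated), zero-variance KDE samples
(minimal positive bandwidth with a warning), empty patient tables
(zero counts), and fibres at the origin of a 2Dmito plot (`NA` theta,
excluded from densities).

## Known limitations

* Segmented areas are biased ~5–8% low relative to geometric truth
  because the Otsu mask is slightly wider than the painted membrane;
  centroids are unaffected (sub-pixel accurate on noiseless mosaics).
* The KDE classifier inherits boundary bias near 0 and 90 degrees from
  the unbounded Gaussian kernel.
* The enrichment test saturates at high deficient fractions in small
  sections (see above).
* Batch effects between antibody-conjugation runs and channel spillover
  are out of scope; inputs are assumed pre-corrected.
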