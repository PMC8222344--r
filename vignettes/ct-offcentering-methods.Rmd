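---
title: "Quantifying vertical off-centering in CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vertical off-centering in CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctqc)
```

## The problem

Modern CT scanners plan the tube current slice by slice from a scout
(topogram) projection: the wider the patient appears, the more mAs the
tube-current-modulation (TCM) system delivers at that z position. The
bowtie filter and the TCM calibration both assume the patient sits at the
gantry isocentre. When a patient lies on an additional transfer mattress —
routine for emergency patients who cannot be moved — automated centering
systems that estimate body height from a ceiling camera misjudge the
stack under the patient's back and leave the body *above* the isocentre.
On an anteroposterior scout the X-ray source is above the patient, so a
raised body is laterally magnified, the TCM system sees a wider patient,
and the delivered mAs and CTDIvol rise accordingly; bowtie mismatch
additionally degrades noise uniformity.

`ctqc` implements the complete measurement chain for this problem —
body contouring, off-centering metrics, tissue-wise local noise maps,
per-slice mAs/dose extraction and paired acquisition comparison — plus a
ground-truthed synthetic torso generator so that every stage can be
validated quantitatively without scanner access.

## The synthetic phantom

`phantom_config()` / `generate_phantom_volume()` render an elliptical
soft-tissue torso whose semi-axes vary over four longitudinal zones
(shoulder, chest, abdomen, pelvis), with two lung ellipses and a
vertebral disc in the chest, spine and iliac bone lower down, and a
support stack below the back: optional additional mattress (foam), air
gap, a 25 mm fixed table pad and a table slab that always reaches the
bottom image edge. Defaults emulate a slim adult (BMI near 18 kg/m²,
chest width about 300 mm) scanned over 600 mm. At desk scale we default
to 120 slices of 128 × 128 px at 3.9 mm/px and 5 mm increment; all sizes
are parameters, and the I/O layer is exercised up to the clinical
857-slice / 0.7 mm regime in the test-suite.

Coordinates: `x` grows with column index, `y` with row index
(downwards). `vertical_offset` is the body-centre height **above** the
isocentre, so the generated barycentre sits at image-centre *y* minus the
offset and a raised body reports a **negative** `dy` in the centering
output.

The scout model is phenomenological: an AP ray at isocentre-plane lateral
position $u/m$ crossing $L$ mm of body renders as intensity
$1-\exp(-L/\tau)$ with $\tau = 10$ mm (a saturating display response that
keeps the body edge sharp, as on processed scout images), and the lateral
axis is stretched by the magnification

$$m = \frac{1}{1 - h/\mathrm{SID}},$$

where $h$ is the height above isocentre and SID = 595 mm the
source-to-isocentre distance (typical third-generation geometry). TCM is
modelled as

$$\mathrm{mAs}(z) = \mathrm{mAs}_{\mathrm{ref}} \left(
\frac{W(z)}{W_{\mathrm{ref}}}\right)^{\alpha},$$

with the apparent scout width $W(z)$, a calibration width
$W_\mathrm{ref} = 300$ mm and strength $\alpha = 1$ by default (mAs
proportional to apparent width; larger $\alpha$ emulates stronger
modulation). CTDIvol is proportional to the mean delivered mAs
(0.0579 mGy/mAs by default, a plausible 120 kVp scale factor). Noise is
additive, Gaussian, independent per pixel, with a per-material standard
deviation scaled by $\sqrt{\mathrm{mAs}_\mathrm{ref}/\mathrm{mAs}(z)}$ —
the Poisson-statistics dependence of reconstructed noise on exposure.

What the generator deliberately does **not** model: sinogram-domain
physics, bowtie-filter nonuniformity, reconstruction-kernel noise
correlation and nonstationarity, scatter, or streaks. Consequently the
generator reproduces the *dose* mechanism of off-centering (magnified
scout → more mAs) but not the measured-noise *increase* of a real
off-centred acquisition, which is driven by bowtie mismatch: in the
synthetic world extra mAs simply lowers noise. Tests passing on this
phantom therefore validate the estimators (contour, barycentre,
segmentation, noise map, comparison statistics), not scanner physics.

The mattress model exposes three knobs: thickness (0 / 35 / 100 /
135 mm, the study configurations), a compression fraction (default 0.5 —
the camera literature reports the support compressing to roughly half
thickness under load) and an air gap between mattress and pad.
`study_config()` maps each study condition to a configuration: automatic
centering lowers the table by half the mattress thickness (the camera
sees the patient top but not the stack below), leaving the body
`thickness/2 + gap` above isocentre; manual centering restores the body
to the isocentre and lowers the table by the full stack. The air gaps
(5 mm orange, 30 mm double) were fixed once to land the back-to-pad
distances near the reported clinical values; nothing downstream is tuned
to them.

## Body contour

`otsu_threshold()` maximises between-class variance on a 256-bin
histogram over the clipped range [−1024, 1500] HU; the fixed binning
makes thresholds reproducible across slices. When the two classes are
separated by an empty HU gap the criterion is constant across the gap;
the lowest optimal boundary is returned (deterministic tie-break).
`body_mask()` thresholds, labels connected components, **discards every
component whose bounding box touches the bottom image edge** (the
table), keeps the largest survivor, then applies a disc closing (radius
3 px) and fills holes so lungs belong to the body. Component selection
runs *before* the closing on purpose: closing first can bridge the body
to the table across a thin pad, after which the merged component touches
the bottom edge and everything would be rejected. The table rule is
configurable off for images without a table.

## Tissue segmentation

Body pixels are assigned by closed-open HU intervals — lung
[−950, −300), soft tissue [−100, 200), bone [200, 3000) — chosen to
leave ≥ 150 HU guard bands around the generator materials; reference
cut-offs vary across sites, so they are configurable. Pixels in no
interval stay `unassigned` and are excluded from noise maps: they are
almost always boundary pixels whose value straddles two materials.

## Local noise maps and the global noise level

For region $k$ the local noise at pixel $(i,j)$ is the sample standard
deviation (denominator $n-1$) of same-region pixels inside the window
$i\pm5,\ j\pm5$ (11 × 11, truncated at image borders — padding would
fabricate HU values). Restricting the window to the region is the point:
a window straddling, say, lung and soft tissue otherwise reads the
~800 HU material step as "noise". Pixels with fewer than 10 same-region
neighbours in the window are left undefined rather than estimated from
too few samples. The global map is the disjoint union of region maps and
the global noise level $\nu$ is its mean over defined pixels.

Implementation: padded summed-area tables give every windowed count, sum
and sum of squares in $O(nm)$; the image is centred on the region mean
first (the SD is shift-invariant), which keeps the
$\sum x^2 - (\sum x)^2/n$ cancellation benign — the result matches a
brute-force double loop to better than $10^{-9}$ HU in the tests.
Per-slice reporting follows the zone of the slice: lung noise on chest
slices (a slice is "chest" when lungs are ≥ 1% of its body pixels),
soft-tissue noise on abdomen–pelvis slices; a missing tissue yields an
absent value, never zero.

## Centering metrics

The per-slice body centre is the unweighted barycentre of mask pixels
(HU weighting is available but off by default), compared against the
image centre at the $(n-1)/2$ pixel-centre convention. Series summaries
report mean ± SD of the per-slice deviation magnitude, plus the
table-height delta against a reference acquisition (only differences are
meaningful — readout conventions vary). Scout width is measured by Otsu
on the topogram intensity; the back-to-pad gap is the distance from the
lowest mask row to a known support-top row.

## Comparison statistics

Profiles from two acquisitions are paired by nearest z within half a
slice increment (one-to-one, unmatched slices dropped and counted, never
interpolated). Differences are summarised as mean ± SD of per-slice
percent differences $100\,(x_t - x_r)/x_r$, with a two-sided paired
Student's t-test ($t = \bar d / (s_d/\sqrt n)$, $n-1$ df). Zero-variance
difference series are resolved by convention — all-zero gives $p = 1$,
identical non-zero gives $p = 0$ — and flagged as degenerate. Percent
columns intended for reports are additionally rounded to integer
percent, the precision at which such results are printed; full precision
is retained internally. No multiplicity correction is applied.

The bundled summary tables
(`system.file("extdata", "mattress_study_table1.csv", package = "ctqc")`
and `..._table2.csv`) carry per-acquisition measurements from a mattress
phantom experiment; `compare_to_reference()` turns them into the
table-height, scout-width and CTDIvol deltas quoted in the README.

## Numerical and design choices

* 11 × 11 window: the neighbourhood definition $i \pm 5$, $j \pm 5$ is
  authoritative; min-support 10 keeps single-digit-sample SDs out.
* Sample SD uses $n-1$ throughout (windows, profile SDs, percent-difference
  SDs).
* Sub-seeds for the simulator are drawn from one seeded generator per
  series; pixels are consumed in column-major order slice by slice, so a
  series is bit-reproducible for a given config and seed.
* HU values are stored as integers in the portable archive (the storage
  precision of CT pixel data); all metadata round-trips exactly.
* Degenerate inputs: constant images are rejected by Otsu; body-free
  slices raise an empty-mask error and become `NA` rows in series
  analyses; absent exposure metadata stays `NA`.
* Desk-scale problem sizes (120–150 slices at 128 px, 857 thin slices at
  32 px for the I/O regime) were chosen as the package's own test
  conditions; every size is a parameter.

## Known limitations

* The noise model cannot reproduce the bowtie-driven noise increase of
  real off-centred scans (see above); the end-to-end demonstrations
  therefore assert the dose/mAs mechanism, not the noise direction.
* The Otsu contour assumes a single body; arms, implants and multi-body
  fields of view are out of scope.
* Absolute noise values from real scanners depend on reconstruction
  kernel and iterative strength, which are not modelled; only relative
  comparisons between matched acquisitions are meaningful.
* Scout width is measured on the package's synthetic topogram object;
  vendor scout DICOMs are not parsed.
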