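# ctqc — slice-by-slice CT off-centering, noise and dose QC

CT scanners modulate the tube current along the patient (TCM) from a
scout/topogram projection and shape the beam with a bowtie filter; both
assume the patient lies at the gantry isocentre. When a patient is
scanned on an additional transfer mattress — common in emergency
imaging — automated camera-based centering can leave the body *above*
the isocentre. On an anteroposterior scout the raised body appears
laterally magnified by

    m = 1 / (1 − h / SID),

where `h` is the height above isocentre and SID the source-to-isocentre
distance; TCM then sees a wider patient and delivers more mAs, raising
CTDIvol. `ctqc` is a toolbox for medical physicists to quantify this
chain per slice along the z-axis:

* **Synthetic phantom** (`phantom_config()`, `simulate_acquisition()`,
  `study_config()`): ground-truthed anthropomorphic torso with
  mattresses, vertical offsets, magnified scout and phenomenological TCM,
  plus region-wise Gaussian noise obeying `σ ∝ sqrt(ref_mAs / mAs)`.
* **Portable series I/O** (`write_series()`, `read_series()`,
  `extract_mas_profile()`): plain-text per-slice HU matrices + JSON
  metadata sidecar; absent metadata stays absent, never zero.
* **Body contour** (`otsu_threshold()`, `body_mask()`): Otsu threshold on
  a fixed 256-bin HU histogram, table rejection, hole filling.
* **Tissue segmentation** (`hu_ranges()`, `segment_tissues()`): lung /
  soft tissue / bone by closed-open HU intervals.
* **Local noise maps** (`region_noise_map()`, `global_noise_map()`,
  `global_noise_level()`): for region k, `N^k_{i,j}` is the sample SD of
  same-region pixels in the 11×11 window `i±5, j±5`; the global map is
  the disjoint union `N = ∪_k N^k` and the global noise level
  `ν(I) = E(N_{i,j})`. Restricting windows to their region prevents
  boundary over-estimation when a window straddles two tissues.
* **Centering metrics** (`barycentre_deviation()`,
  `series_centering_summary()`, `topogram_width()`,
  `back_to_table_gap()`): per-slice body barycentre vs image centre,
  table-height deltas, scout width, back-to-support gap.
* **Acquisition comparison** (`compare_acquisitions()`,
  `paired_t_test()`, `percent_difference()`,
  `compare_to_reference()`): nearest-z pairing, mean ± SD percent
  differences, two-sided paired Student's t-tests, CTDIvol deltas.

## Worked example

Simulate a reference acquisition and one on a 10 cm mattress with
automatic (mis-)centering, then compare them:

```r
library(ctqc)
ref  <- simulate_acquisition(study_config("none",
                             n_slices = 60, slice_spacing = 10, seed = 1))
auto <- simulate_acquisition(study_config("orange", "automatic",
                             n_slices = 60, slice_spacing = 10, seed = 2))
compare_acquisitions(ref$series, auto$series)
#> <comparison_report> test vs reference
#>   mAs:  +11% +/- 1% over 60 pairs (t = 51.10, p = 1.51e-50, significant)
#>   lung noise: -5% +/- 3% over 21 pairs (p = 7.97e-07, significant)
#>   soft noise: -5% +/- 2% over 39 pairs (p = 2.47e-22, significant)
#>   CTDIvol: 15.61 vs 14.00 mGy (+11%)
#>   table height delta: +50.0 mm
```

The mattress leaves the body 55 mm above isocentre; the magnified scout
drives mAs and CTDIvol up by 11% (paired t-test significant). Noise
*falls* slightly here because the synthetic model captures only the
exposure dependence of noise, not the bowtie mismatch of a real scanner
(see the methods vignette). The per-slice detail:

```r
an <- analyze_series(auto$series)
head(an$per_slice[, c("z_mm", "mas", "zone", "dy_mm", "soft_noise_hu")])
#>   z_mm    mas           zone     dy_mm soft_noise_hu
#> 1    0 343.75 abdomen-pelvis -54.97555      8.459761
#> 2   10 343.75 abdomen-pelvis -54.97555      8.301831
#> ...
```

`dy_mm` is negative for a body above the isocentre. A command-line
interface wrapping the same pipeline lives at
`system.file("cli", "ctqc.R", package = "ctqc")` with `simulate`,
`analyze` and `compare` subcommands.

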