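# tipr

Quantitative analysis of intestinal motility from transillumination video
of freely moving mice. Light transmitted through the abdomen casts a shadow
of the contrast-agent-filled intestine onto the camera; `tipr` turns those
shadows into motor-pattern statistics:

* **Rigid frame registration** from the body silhouette: iterative
  thresholding extracts the mouse as the second-largest dark component, the
  convex hull's second-order central moments give the covariance matrix
  whose principal eigenvector is the body's major axis (angle θ), and each
  frame is rotated by 90 − θ and translated so the body centroid sits on
  the first frame's anchor centroid.
* **Spatial-temporal (kymograph) maps** along a drawn intestine
  centerline: CLAHE enhancement, cross-section profiles along equal-length
  normals, per-position Otsu thresholding of the absorbance
  (1 − intensity), offset averaging, and 2×2 median smoothing. Rows are
  intestine positions, columns time points; contractions are low values.
* **Motility metrics**: Hann-windowed spectral peak frequency of a
  cross-section series in a 0.1–2.0 Hz band; exact-enumeration two-sided
  Wilcoxon rank-sum comparison of frequency groups; phantom contrast
  `(A_b − A_t) / A_t`; FWHM and FWHM-based diameter-change estimation;
  autocorrelation-drift discrimination of peristalsis (sloped bands) vs
  segmentation (stationary alternating spots).
* **Long recordings**: Pearson-similarity behavior segmentation with
  per-epoch kymographs stitched into one long map.
* **Dual-color imaging**: demultiplexing of alternating-wavelength stacks
  into per-agent channels and color overlays.
* **Light-field 3D**: lenslet decoding, shift-and-add refocusing to a
  focal stack, per-pixel depth-index maps, axial kymographs.
* **Synthetic scenes with ground truth**: an imaging-physics generator
  (Beer–Lambert tube absorption, programmed peristalsis/segmentation,
  scripted rigid motion, scattering blur, sensor noise) so every stage is
  testable without animal data.

## Worked example

Simulate an awake-mouse segmentation recording, register it, build the
kymograph, and recover the contraction rate:

```r
library(tipr)

scene <- scene_config(duration = 60, rng_seed = 42)        # 15 Hz, 256x256
motility <- motility_config(pattern = "segmentation",
                            contraction_frequency = 0.772) # awake-mouse rate
motion <- motion_config(data.frame(
  time = c(0, 20, 40, 60), angle = c(0, 18, -12, 0),
  cx = c(128.5, 136, 123, 128.5), cy = c(128.5, 123, 133, 128.5)))

sim <- render_motility_video(scene, motility, motion)
reg <- register_video(sim$video)

# map the generator's centerline into registered coordinates
ctr <- c(128.5, 128.5)
curve <- apply_transform(
  reg$transforms[[1]],
  apply_pose(sim$truth$centerline_px, sim$truth$pose$angle[1],
             c(sim$truth$pose$cx[1], sim$truth$pose$cy[1]), ctr))

S <- st_map_from_video(reg$video, curve, normal_length = 40)
rows <- round(sim$truth$sites_mm[2] / attr(S, "pixel_pitch")) + (-3:3)
fit <- peak_frequency(cross_section_series(S, rows))
fit$peak_frequency
#> [1] 0.7666667
fit$bin_width
#> [1] 0.01666667
```

The recovered 0.767 Hz sits one spectral bin (1/60 Hz) from the generator's
0.772 Hz — the frequency resolution limit of a 60 s window. The same
recording with identity motion and a 0.380 Hz generator recovers 0.383 Hz,
and the awake/anesthetized ratio is 2.0, the expected two-fold difference.
`classify_motor_pattern(S)` reports `"segmentation"` with ~0 px of
autocorrelation-peak drift per period; a peristaltic scene at 2 mm/s
reports `"peristalsis"` with ~13 px drift.

Phantom metrics work the same way from rendered tube cross-sections:

```r
dc <- benchmark_diameter_ratio()   # 4 mm resting vs 1 mm contracted tube
c(dc$ratio, dc$change)
#> [1] 0.2355714 0.7644286
```

## Layout

* `R/` — implementation: synthetic scenes (`synthetic-scene.R`),
  registration (`registration.R`), kymographs (`stmap.R`), metrics
  (`metrics.R`), long recordings (`longrec.R`), dual-color
  (`multicolor.R`), light fields (`lightfield.R`), I/O and staged runs
  (`video.R`, `pipeline.R`), benchmark scenarios (`benchmarks.R`).
* `vignettes/tip-motility-pipeline.Rmd` — the methods vignette: model
  assumptions, parameter choices, numerical conventions, limitations.
* `tests/testthat/` — unit, property, and validation suites with
  independent oracles (exhaustive Otsu scan, sort-based median,
  enumeration rank-sum, coordinate-covariance moments).
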