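# qpitrack

Quantitative phase imaging (QPI) analysis of living cancer cells:
dry-mass growth, motility, protrusion dynamics, chemotaxis statistics and
monolayer-invasion quantification.

## The problem

Label-free interference microscopy measures the optical path delay light
accumulates crossing a cell. Because the specific refractive increment α
is nearly constant across biomolecules, that delay converts linearly to
dry-mass surface density (pg µm⁻²), so a calibrated phase image is a
densitometric map of the cell. From a time-lapse of such maps one can
read off quantities that distinguish metastatic from non-metastatic
phenotypes: dry-mass doubling time, centroid speed, the mass and area
flux of protrusions and retractions, the *dynamic polarity* (distance
between protrusion and retraction centroids — the asymmetry that drives
translocation), chemotactic directionality, and the fraction of cells
that breach a labelled monolayer in an invasion assay.

`qpitrack` implements this chain for microscopists and quantitative cell
biologists:

1. **Phase reconstruction** — four interferograms with quarter-wave
   reference steps solve the object phase per pixel:
   `φ = atan2(I₄ − I₂, I₁ − I₃)`, `OPD = φλ/2π`, `σ = OPD/α`
   (default α = 0.18 µm³/pg). Quality-guided 2-D unwrapping and an
   off-axis Fourier (hologram) mode are included.
2. **Background model** — frame-to-frame fluctuation removal, cell-free
   background reconstruction from each pixel's temporal mode,
   periphery/centre inpainting of always-covered areas, subtraction.
3. **Segmentation & tracking** — a low (1% of maximum) threshold that
   preserves the thin cell periphery (negative values retained in the
   statistics), 8-connected labelling, and nearest-neighbour linking
   gated on mass similarity.
4. **Metrics** — exponential growth fits (Td = ln 2 / slope), step
   speeds (a 5-min displacement × 12 gives µm/h), per-minute
   protrusion/retraction mass and area, dynamic polarity.
5. **Chemotaxis statistics** — directions at a 70 µm horizon, Rayleigh
   test with mean-direction CI, hierarchical unbalanced ANOVA on
   gradient displacement components, 2×2 incidence chi-square.
6. **Invasion assay** — hole detection in the red monolayer channel
   (< 50% of baseline), green-cell tracking, coincidence scoring,
   movie-level treatment comparison.
7. **Synthetic scenes** — a seeded generator (cells as Gaussian
   dry-mass blobs on persistent random walks, sinusoidal interferogram
   formation, scripted invasion movies) so the entire pipeline is
   testable without any raw data.

## Worked example

```r
library(qpitrack)

cells <- list(
  cell_spec(initial_mass_pg = 600, doubling_time_h = 36,
            initial_position_um = c(150, 120), speed_um_per_h = 20,
            shape_sigma_um = c(10, 10)),
  cell_spec(initial_mass_pg = 900, doubling_time_h = 24,
            initial_position_um = c(450, 300), speed_um_per_h = 33,
            shape_sigma_um = c(12, 9)))
sp <- scene_spec(n_frames = 20, cells = cells, rng_seed = 1)

run <- run_qpi_pipeline(sp)   # simulate, render, reconstruct, analyse
run
#> qpi_run: 20 frames, 2 tracks
#>               quantity       mean        sem  n   unit
#>         mean_cell_mass  778.40223 162.285325  2     pg
#>  mean_speed_over_steps   26.49350   1.068878 38   um/h
#>  mean_speed_over_cells   26.49350   6.501318  2   um/h
#>     mean_doubling_time   29.84200   5.713891  2      h
#>   mean_protrusion_mass   15.79519   1.960951 38 pg/min
#>  mean_dynamic_polarity   45.75970   4.400198 38     um
#>    mean_max_pixel_mass 4197.35367 318.924237 38     fg
```

The two cells are recovered with their scheduled masses (mean 778 pg vs
the true time-averaged 781 pg), and the growth fit of the first track
returns its doubling time:

```r
run$growth_fits[[1]]
#> growth_fit (track 1 ): growing
#>   doubling time: 35.56 h  (slope 0.01949 +/- 0.000233 per h, r^2 = 0.9974 )
#>   points: 20
```

(true value 36 h; the 20-frame movie spans 3.2 h, so the slope carries
real uncertainty). Directional statistics work on any tracks; the 2×2
incidence test reproduces its closed form:

```r
incidence_chi_square(0, 20, 9, 15)
#>  Pearson chi-square test for a 2x2 table
#> data:  (0, 20; 9, 15)
#> X-squared = 9.4286, df = 1, p-value = 0.002136
```

Invasion movies run the same way:

```r
mv <- invasion_scene_spec(n_green_cells = 10, invading_indices = c(2, 5, 8),
                          rng_seed = 7)
run_invasion_pipeline(mv)$result
#> invasion_result : 3 of 10 cells invading (fraction 0.300)
```

## Documentation

The methods vignette (`vignettes/qpitrack-methods.Rmd`) describes the
imaging model, the background reconstruction, every tunable parameter
with its unit and default, what the synthetic scenes do and do not
emulate, and the package's numerical choices and limitations.
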