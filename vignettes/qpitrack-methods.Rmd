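---
title: "Quantitative phase imaging of cell growth, motility and invasion: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative phase imaging of cell growth, motility and invasion: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpitrack)
```

`qpitrack` implements a complete analysis chain for incoherent-source
quantitative phase imaging (QPI) of living cells — from raw phase-shifted
interferograms to dry-mass growth curves, centroid speeds,
protrusion/retraction dynamics and chemotaxis statistics — together with a
two-channel fluorescence invasion assay quantification. Because raw
microscope movies of this kind are rarely shareable, the package also ships
a seeded synthetic-scene generator that produces inputs with the
statistical structure every downstream stage assumes; all of the package's
tests run against it.

## The imaging model

A phase-shifting interference microscope records, at every time point,
four frames of the interference between an object beam that has passed
through the cells and a reference beam, with the reference phase advanced
by a quarter wave between frames:

$$ I_k(x,y) = A + B\cos\!\big(\varphi(x,y) + k\pi/2\big) + \varepsilon,
\qquad k = 0,\dots,3 . $$

The object phase is recovered per pixel in closed form as the
four-quadrant arctangent of a ratio of two image differences,
$\varphi = \operatorname{atan2}(I_3 - I_1,\, I_0 - I_2)$, which is exact
for quarter-wave steps and machine-precision exact on noise-free data (a
property the test suite asserts over random phase, amplitude and
modulation). We deliberately use `atan2` rather than the arctangent of the
plain ratio: the two-argument form resolves the quadrant ambiguity. Only
the quarter-wave schedule is supported; a Carré-type solution for general
steps is a documented non-goal, and the step schedule is an explicit
argument rather than an assumption.

The optical path difference follows as $\mathrm{OPD} = \varphi
\lambda/2\pi$ (micrometres). Because the specific refractive increment
$\alpha$ is nearly the same for all major biomolecules, OPD converts
linearly to dry-mass surface density $\sigma = \mathrm{OPD}/\alpha$
(pg\,µm^-2^). The default $\alpha = 0.18$ µm³/pg is the literature-standard
average; it is a parameter everywhere it is used.

Where the accumulated phase exceeds one period, maps are unwrapped by a
quality-guided flood fill: pixels join the solution in order of a local
smoothness quality (negative wrapped-gradient energy), each shifted by the
integer multiple of $\lambda$ that best matches an already-solved
neighbour. Disconnected valid regions are unwrapped independently and the
count reported. Pixels with no fringe modulation are flagged invalid,
filled by nearest-neighbour averaging and counted.

An off-axis (Fourier) reconstruction mode is also provided for
single-shot holograms: one object sideband is isolated around the fringe
carrier with a Gaussian filter of width 0.2 of the carrier magnitude
(keeping the DC term and the conjugate sideband several filter widths
away), demodulated, and inverse-transformed.

## Background reconstruction

Three effects separate the raw OPD from the cell signal: a static smooth
aberration surface, frame-to-frame global level fluctuations, and sensor
noise.

*Fluctuations.* Frames are aligned to the first frame by the modal value
of their pixelwise difference image. Differencing cancels the static
surface exactly, so over cell-free pixels the difference is a point mass
at the offset difference; the mode estimator (modal histogram bin refined
by a local median) is exact for a point mass and unbiased for symmetric
noise. The aligned stack is then shifted so the modal value of its
provisional background pixels — the lowest half of each frame's values,
since cells only add positive OPD — is zero.

*Surface.* Per pixel, the most frequent OPD value over time estimates the
cell-free background: cells pass transiently, the background persists. The
temporal histogram uses a bin width of 4× the robust noise SD (median
absolute deviation of temporal differences, with each difference frame's
global level removed first). A pixel's mode is trusted only when its modal
bin holds at least `f_min = 0.25` of the frames; areas covered by cells
during the entire time-lapse have no dominant value and are flagged.

A refinement pass then repeats the temporal mode with cell-covered frames
excluded per pixel: cells are provisionally segmented on the first-pass
corrected stack and their masks dilated by 5 px, because the faint cell
periphery extends well beyond any threshold and a slowly moving cell can
otherwise leave its tail inside a pixel's modal bin and bias the
background under the cell. After the refined surface is known, the
per-frame offsets are re-estimated as the median of (frame − surface)
over that frame's cell-free pixels, which locates each offset to the
noise level rather than to the histogram bin width. If the refinement
pass degenerates (more than half of the field flagged, as happens in a
fully static scene where provisional masks swallow the field), the first
pass is kept.

*Inpainting.* Flagged areas are filled with a blend of local and global
structure, $w L + (1-w) G$: $L$ is the harmonic (Laplace) interpolation
from the gap boundary, solved sparsely; $G$ is a global degree-2
polynomial least-squares fit to all unflagged pixels; and
$w = e^{-d/d_0}$ decays with the distance to the gap boundary
($d_0 = 20$ px). The periphery of a gap thus follows local values and its
centre the global surface, continuously. Any background that is itself a
plane is reproduced exactly (a plane is both harmonic and degree-2); a
quadratic background is recovered within 2% of its range on a central
gap. A gap component touching all four image borders has no usable
periphery and falls back to $G$ alone. The blend form and the global
model are this package's explicit choice — the underlying idea (local
periphery values, more global values in gap centres) admits many
realisations.

## Segmentation and tracking

Cells are segmented on the background-subtracted dry-mass map with a
threshold of 1% of the maximum cell signal after mild Gaussian smoothing
(SD 1 px). The mask is expanded by a 2 px margin and all per-label
statistics are computed on the *raw* values inside it: the thinnest parts
of a cell carry small, sometimes negative, phase values, and clipping them
at a hard threshold would systematically under-measure mass. Total label
mass is therefore a signed sum; centroids are mass-weighted using the
positive part. Components are 8-connected; those below 50 µm² are
discarded. Touching cells are treated as clusters and tracked as single
objects — no splitting is attempted.

Tracking links each object to the nearest object with a similar mass in
the next frame: candidate pairs are taken greedily in ascending distance
order and accepted only if the distance is ≤ 30 µm per lapse and the
relative mass difference is ≤ 0.35. The mass gate is what preserves
identities when two cells of different size cross paths; the test suite
checks this against a brute-force optimal assignment. "Similar mass" is
not quantified in the source methodology; 0.35 absorbs growth plus
segmentation noise between frames and is configurable.

## Growth, speed, protrusion and polarity

*Growth.* Dry-mass growth is exponential to good approximation, so
ordinary least squares of $\ln m$ on time gives the doubling time
$T_d = \ln 2 / \hat\beta$. Negative slopes are reported as shrinking;
slopes within $10^{-12}$ of zero as non-growing ($T_d = \infty$).

*Speed.* Step speed is the centroid displacement between consecutive
frames scaled to µm/h — a 5-min displacement is multiplied by 12. The
centroid is the mass-weighted centroid of the dry-mass distribution, not
the mask centroid. Means and SEMs are reported both over steps and over
cells, because the two weightings genuinely differ and the convention is
often left unstated in the field.

*Protrusion/retraction.* For a track's consecutive masks, the protrusion
is the newly occupied area and the retraction the vacated area; their
masses are measured on the later and earlier map respectively and
normalised per minute (division by the lapse in minutes). The pixel-count
identity $\mathrm{area}(t) + P\,\Delta t - R\,\Delta t =
\mathrm{area}(t+1)$ holds exactly by construction and is asserted on
every synthetic frame pair. Dynamic polarity — the distance between the
protrusion and retraction centroids — measures the spatial asymmetry of
shape change that drives translocation; centroids are unweighted area
centroids by default (mass-weighted behind a flag, since the convention
is not fixed by the source). Polarity is undefined, and recorded missing,
when either set is empty.

## Chemotaxis statistics

Trajectories become circular data through the horizon rule: each cell's
direction is taken at the moment its path first reaches 70 µm from its
start, with the crossing interpolated linearly within the crossing step
onto the horizon circle. Cells that never reach the horizon are excluded
— chemotaxis is undefined for non-motile cells. The Rayleigh test of
uniformity uses $Z = n\bar R^2$ with the standard series approximation
for the p-value (accurate in the n = 10–200 range used here; exceedances
are clipped into $(0,1]$), and the mean direction carries a 95% CI from
the von Mises large-sample circular standard error. The Monte-Carlo
calibration in the acceptance suite (10 000 uniform samples of n = 60)
checks the realised type-I error at 0.05 ± 0.006.

Population comparisons use a two-level nested ANOVA on per-cell mean
displacement components along the gradient direction: population is fixed,
movies are random within population, and the population effect is tested
against the movie-within-population mean square with sequential sums of
squares, which handles unbalanced data. Cells (not steps) are the sampling
units — steps within a cell are strongly autocorrelated, and movies, not
cells, are the independent replicates. A population represented by a
single movie is refused, since its error stratum cannot be estimated.

The 2×2 incidence comparison is the closed-form Pearson chi-square with
df = 1 (Yates correction behind a flag, off by default), cross-checked in
the tests against both `chisq.test` and a numerically integrated
chi-square tail.

## Invasion assay

The observable is coincidence: a cancer cell invading a labelled
confluent monolayer opens a hole under itself, visible as a local loss of
red fluorescence. Holes are pixels whose median-smoothed intensity falls
below 50% of the median-smoothed first-frame baseline (the intact
reference), assembled into components of at least 50 µm²; regions already
dark in the baseline are excluded from scoring, and an optional per-frame
renormalisation to the baseline median absorbs global photobleaching.
Green cells are Otsu-segmented and tracked with the same mass-gated
linker, integrated intensity standing in for mass. A cell is invading
when its footprint ever overlaps a hole by at least 30% — a cell sitting
on the hole it opened needs only partial overlap, and mere holes (or mere
cells) never count. The 50% reduction factor and the 30% overlap are
explicit parameters: the source methodology says "significant reduction"
and "coincidence" without numbers, and validated manually.

Treatment comparisons take movies as experimental units: per-treatment
mean ± SEM of movie-level invading fractions, with a one-way ANOVA
against the reference group. The acceptance suite includes a power check
of this design at the published scale (17 movies per arm, ~90 cells per
movie, true fractions 0.21 vs 0.03): rejection in at least 95% of 200
replicates.

## The synthetic-scene generator

The generator is first-class, tested code, and its defaults are the study
conditions: a 634 × 483 µm field at 530 nm and a 10-min lapse for QPI
(pixel size 2 µm, so the field fits a 242 × 317 px frame), a
1308 × 1308 µm field at a 15-min lapse for invasion (rendered here at
218 × 218 px, 6 µm pixels, to keep test runtimes reasonable), cell masses
of several hundred pg, doubling times of 24–36 h and speeds of 10–33 µm/h
— the ranges the imaging literature reports for these sarcoma and
carcinoma lines.

Cells are anisotropic Gaussian dry-mass blobs truncated at 4σ and
renormalised so the integrated mass matches the schedule exactly (that
renormalisation is what makes the conservation tests exact rather than
approximate). Motion is a persistent random walk of constant step speed:
the heading gains a wrapped-normal increment with
SD $= \sqrt{2\Delta t/P}$ per lapse, giving directional correlation
$e^{-\Delta t/P}$ with persistence time $P$; chemotactic bias is a
mixture — a fraction of steps is taken exactly along the drift direction,
so a drift fraction $f$ at speed $v$ produces a mean gradient-component of
$f\,v$. Growth is exactly exponential. The optical background is a
degree-2 polynomial in OPD with per-frame Gaussian offsets, and the
sensor adds white Gaussian intensity noise. One integer seed drives every
draw; identical specs and seeds give bit-identical outputs, and the RNG
state of the calling session is left untouched.

What the generator does *not* emulate is worth stating: no optical
diffraction or PSF, no shot noise or camera gain, no halo/shade-off, no
mitosis or cell–cell occlusion beyond simple blob overlap, no
out-of-focus structure in the monolayer. Passing tests therefore show
that the algorithms are correct for data obeying the stated forward
models, not that they are robust to every artefact of real microscopy.

Coordinates follow one convention everywhere: images are (row, col)
matrices; physical x runs along columns and y along rows (y grows
downward), both in micrometres from the first pixel centre; angles are
measured from +x by `atan2(dy, dx)` in that frame.

## Numerical choices and degenerate inputs

- Zero-modulation pixels are filled by iterative neighbour averaging and
  counted, never silently dropped.
- The temporal-mode bin width floor is 1 nm OPD, so noise-free synthetic
  stacks do not degenerate to zero-width bins.
- The `hist_mode_refined` estimator (modal bin, then median within ±1.5
  bins) is exact for point masses — which is what makes the
  constant-shift fluctuation tests exact.
- Empty frames segment to zero labels, not errors; zero tracked cells
  yield an invasion fraction flagged undefined, not 0.
- Ties in greedy linking are broken by candidate order after a stable
  sort on distance; merges close the losing track and are logged.
- Growth fits exclude non-positive masses (logged) and refuse to fit
  fewer than 3 points.

## Problem sizes used in the checks

The shipped acceptance checks run the full pipeline on a 242 × 317 px,
30-frame, 3-cell scene (~15 s), a 120 × 160 px speed-recovery scene, a
180 × 180 px, 12-frame invasion movie, 10 000 Rayleigh replicates and a
200-replicate power simulation — sizes chosen so the whole suite
completes in well under a minute while every statistical criterion
retains its stated resolution.

## Known limitations

- A cell that never moves is indistinguishable from background structure
  by the temporal-mode principle; the refinement pass detects the
  degeneracy and falls back rather than fixing it. Long movies of motile
  cells — the intended regime — do not suffer from this.
- The greedy linker matches the stated nearest-similar-mass rule; it is
  not a globally optimal assignment and will not recover from extended
  occlusions (`max_gap` defaults to 0).
- The Rayleigh series p-value is slightly anticonservative in the far
  tail; it is clipped, not recomputed exactly.
- Fourier-mode reconstruction assumes the carrier is supplied, not
  auto-detected, and uses a fixed Gaussian sideband filter.
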