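---
title: "Methods: the NIR-HSI seed-viability pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the NIR-HSI seed-viability pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hsisort)
library(dplyr)
```

## The problem

Seed lots lose viability during multi-year cold storage ("natural aging"),
and conventional germination tests take two weeks per lot. Near-infrared
hyperspectral imaging (NIR-HSI) offers a nondestructive alternative: a
line-scan camera over a conveyor belt records a reflectance spectrum
(900--1700 nm) for every pixel of every seed, and the spectra carry
signatures of the carbohydrate, protein and moisture differences between
viable and nonviable seeds. `hsisort` implements the full chemometric
pipeline from raw line-scan cubes to per-seed sort decisions, together with
a synthetic scene generator that provides ground truth for every stage.

## Radiometric calibration and scene preparation

Raw counts are converted to relative reflectance with the two-point
correction

$$X_\mathrm{cal} = \frac{X_\mathrm{raw} - X_\mathrm{dark}}
                        {X_\mathrm{ref} - X_\mathrm{dark}},$$

where the white reference is a >99%-reflectance Teflon frame and the dark
reference is acquired with the lens covered. The result is clipped to
$[0, 1.2]$: a little headroom above the white reference tolerates specular
pixels without letting sensor glitches through. Spatial impulse noise is
suppressed with a 3×3 per-band median filter (reflect padding at frame
edges; the implementation and the streaming runtime use the identical edge
rule so batch and online processing agree exactly).

Seeds are segmented by thresholding the band-mean reflectance image against
the dark belt background (default threshold 0.2), labelling 4-connected
components, and removing components below `min_area` (default 20 px).
Manual region-of-interest drawing is not reproducible, so this automatic
rule is the documented stand-in; on synthetic scenes it recovers the true
footprints exactly in the noise-free limit. Per-seed spectra are plain
arithmetic means over the footprint pixels.

## Preprocessing suite

Row-wise transforms available before model fitting: mean/max/range
normalisation, multiplicative scatter correction (MSC, least-squares
regression of each spectrum on a reference; the reference is frozen to the
mean calibration spectrum at training time), standard normal variate (SNV,
using the sample $n-1$ standard deviation), and Savitzky--Golay first and
second derivatives (default window 11, polynomial order 2, derivative per
band step, full-length output with polynomial edge fitting).

The package default for training is **mean normalisation**. On synthetic
scenes every method classifies essentially perfectly, but the whitening
transforms (SNV/MSC) relocate regression-coefficient weight toward spectrum
edges and shared (non-discriminative) bands, while the simple
normalisations preserve band geometry so the coefficient curve peaks at the
absorption bands and stays chemically interpretable.

## The classifier

PLS-DA: class membership is coded 0 (nonviable) / 1 (viable) and regressed
on the preprocessed spectra by NIPALS partial least squares,
$Y = Xb + E$ with latent structure $X = TP^\top + E_X$,
$Y = UQ^\top + E_Y$. The regression vector is composed as
$b = W(P^\top W)^{-1}q$; at full rank it equals the ordinary least-squares
solution, and predictions match an independent PLS implementation to
$10^{-6}$ (both checked in the test suite). Numerical settings: at most 500
NIPALS iterations per component at tolerance $10^{-10}$ (single-response
fits converge in one pass); a component with no remaining $X$/$y$
covariance is an error, not a silent stop.

The latent-variable count is selected by venetian-blind $k$-fold
cross-validation ($k = 10$, seeded random fold offset), minimising
misclassification error at the 0.5 cut with ties resolved toward fewer
components.

Before fitting, an outlier screen projects the spectra onto their first two
principal components and flags rows whose Hotelling $T^2$ exceeds the
F-ellipse bound at 98.9% confidence; on well-behaved data about 1.1% of
rows fall outside, which the tests verify by simulation.

**Threshold shifting.** A score above the decision threshold $t$ calls the
seed viable; a score exactly at $t$ is nonviable (borderline seeds travel
with the reject stream). $t$ starts at 0.5 and is raised on a 0.01 grid
until the predicted-viable group of the calibration scores (scores
$\geq t$, so the returned cut clears every offending score) reaches the
requested purity; the default target is 0.95. If even $t = 0.99$ cannot
reach the target the maximum is returned with a flag rather than silently.
Raising $t$ can only shrink the predicted-viable group, so the false-viable
count is monotone non-increasing in $t$ and the returned $t$ is monotone
non-decreasing in the purity target.

Calibration/validation splitting is stratified by class within variety at
the *seed* level (both sides of a seed always share a split), with
`round(fraction * n)` seeds per stratum. The default fraction is 2/3, which
with double-sided spectra reproduces the canonical 612 = 408 + 204 layout;
the companion "70%" phrasing in common use corresponds to the same 2:1
counts, so the fraction is exposed as configuration rather than hard-coded.

## Chemical imaging and per-seed decisions

The chemical image scores every masked pixel through the model. The
regression vector was fitted on preprocessed spectra, so each pixel
spectrum receives the model's preprocessing before projection; projecting
raw pixels would mix incompatible spaces. Pixels that are degenerate for
the transform (e.g. constant under SNV) are assigned the nonviable score
floor 0 and tallied, never propagated as errors. The prediction map is
binarised at the model threshold (same tie rule), cleaned by morphological
area opening (4-connectivity, same `min_area` as segmentation -- one knob,
so specks are treated consistently), and reduced to a per-seed call: viable
iff the viable-pixel fraction of the footprint is at least `f` (default
0.5, with $\geq$ at the boundary). Both reduction routes -- pixel-fraction
and mean-spectrum classification -- are implemented; on noise-free scenes
they agree exactly (tested).

## Streaming online loop

The online runtime consumes the cube as frames of `frame_height` lines.
Each line is calibrated, median-filtered against its true neighbours
(a one-line lookahead buffer reproduces the batch filter bit-exactly,
including the edge rule), thresholded, and stitched onto open seed blobs by
pixel-column overlap with the blob's previous line (4-connectivity; blobs
joined by a later line are merged). A 4-connected component cannot skip a
scan line, so a blob with no pixels on the current line has fully exited
the field of view and is decided immediately with exactly the batch
operations. Streaming decisions are therefore identical to batch decisions
for every frame height -- the suite checks heights 1, 8, 64 and full-cube.
Timing is simulated, never wall-clock: one line per exposure period
(17 ms), belt at 49 mm/s, actuation delay = nozzle distance / belt speed.

## The synthetic scene generator

No public seed data accompanies this problem, so the generator is the
package's test bed, and its defaults *are* the study conditions for every
property the suite asserts. It emulates:

* two class mean spectra built from a smooth seed-coat baseline minus
  Gaussian absorption features at 1415 nm (C--H, carbohydrates), 1475 nm
  (N--H, proteins) and 1605 nm (O--H, moisture), with the nonviable class
  both absorbing more deeply at those bands and sitting slightly lower
  broadband, so its mean reflectance is lower across 1425--1670 nm.
  Feature widths (sigma 20/18/26 nm) are narrow enough that the three
  class-difference excursions stay distinct and localised within 30 nm of
  their centres; a shared 1190 nm band carries no class contrast;
* per-seed scatter: multiplicative $a \sim \mathrm{lognormal}(0, 0.08)$,
  additive $b \sim N(0, 0.01)$, a small linear baseline tilt, and i.i.d.
  pixel noise (sd 0.01 reflectance) -- precisely the distortions MSC, SNV,
  normalisation and derivatives are designed to remove;
* a physical sensor model: dark current (120 counts) with fixed-pattern
  noise, a smooth lamp profile peaking near 1300 nm, and integer count
  quantisation, so two-point calibration is a genuine inversion;
* elliptical seed footprints (aspect 1.5--2 along track) placed on a
  jittered grid over a dark belt; both-sides scanning as a second pass with
  independent scatter and a small side offset;
* linked per-seed ground truth: class, a latent chemistry triple (class
  means 0.70 vs 0.45 on a 0--1 scale, per-seed jitter clamped to ±0.10 so
  the classes stay disjoint), a germination outcome drawn from a logistic
  probability monotone in mean chemistry (viable seeds germinate at
  roughly 80%, nonviable below 30%), and assay tables -- gravimetric
  wet/dry weights whose wet-basis moisture content is proportional to the
  latent moisture level, and chromatographic peak areas linear in the
  latent levels with magnitudes around 15--35 area %, matching the scale
  reported for watermelon seed endosperm.

The class spectral contrast is a free parameter (`contrast`), documented as
such: no public measurement fixes it. What passing tests show is that the
*method* is implemented correctly and recovers known structure under a
realistic noise model; they do not certify accuracy on real seed lots,
whose scatter, dormancy states and optical variability the generator does
not attempt to reproduce.

## Problem sizes and numerical choices

The test suite and the acceptance script use 600-seed training sets
(four 150-seed scenes), 200-seed sets per contrast level, 20-seed scenes
for streaming equivalence, and 200 replicate 40-seed assay tables for the
ANOVA power property -- sizes chosen so the full pipeline exercises every
stage while a complete run stays in the minutes range on one core.
Degenerate inputs follow explicit rules rather than NaN propagation:
identical ANOVA groups give $F = 0, p = 1$; zero-variance rows are errors
in table preprocessing but floor-scored in pixel maps; empty segmentation
masks yield empty region lists, not errors; an empty predicted group
reports a germination rate of `NA`, never 0.

## Known limitations

* The generator uses a single endmember per class; real seeds show embryo
  versus coat structure within one footprint.
* No optical point-spread function or radiative-transfer model; scatter is
  the standard multiplicative/additive abstraction.
* The per-seed decision rule (viable-pixel fraction, $f = 0.5$) is a
  simple monotone reduction; published figures show the binary maps but do
  not state the reduction rule, so both it and the mean-spectrum route are
  provided.
* One-way ANOVA is run per variety with no multiple-testing correction,
  matching the verification convention it mirrors; with three analytes a
  user comparing many varieties should correct accordingly.
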