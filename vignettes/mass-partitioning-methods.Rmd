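---
title: "Measuring dry-mass partitioning during cytokinesis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring dry-mass partitioning during cytokinesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(massdivide)
```

## The measurement model

Quantitative phase imaging (QPI) reports, per pixel, the optical path
difference (OPD) that light accumulates through a cell relative to the
surrounding medium. Because the refractive index of cytoplasm rises
linearly with the concentration of dissolved biomass, the integrated OPD
over a cell footprint is proportional to its dry mass through the
specific refractive increment $\alpha$:

$$ m \;=\; \frac{1}{\alpha} \int_A \mathrm{OPD}\, dA, $$

with $\alpha = 1.8\times10^{-4}\,\mathrm{m^3/kg}$ as a whole-cell
average. The package carries OPD in nanometers and pixel areas in
$\mu m^2$, so a footprint of 100 $\mu m^2$ at 100 nm holds
$100 \times 100 \times 10^{-6} / \alpha = 55.6$ pg. This conversion
(`opdSumToMassPg()`) is the only physics in the mass measurement; it is
independent of cell shape, which is what makes mass a robust observable
through the drastic shape changes of mitosis.

Two derived observables drive the division analysis:

* **mean phase shift** — mean OPD over the segmented footprint,
  proportional to mass per area. When an adherent cell rounds up for
  mitosis its footprint shrinks at nearly constant mass, so the mean
  phase shift rises sharply, and falls again as daughters respread.
* **shape factor** — $4\pi A/P^2$, equal to 1 for a circle; rounded
  mitotic cells approach 1.

The pair-normalized daughter mass difference

$$ \Delta m \;=\; \frac{2\,|m_{d1}-m_{d2}|}{m_{d1}+m_{d2}} \in [0, 2] $$

quantifies partitioning error; the signed form (daughter 1 defined as
the heavier daughter at the furrow, so $\Delta m_0 \ge 0$) supports rate
fits and direction-preserving heatmaps.

## The synthetic movie generator

No public instrument data accompany this problem, so every stage is
validated against a seeded generator (`simulateMovie()`) whose analytic
core (`.scenarioState()`) produces both the rendered frames and the
ground-truth ledger from the same state — the two cannot disagree.

Cells are rendered as order-4 super-Gaussian OPD domes whose discrete
integral is normalized exactly to the scenario's true mass at each
frame. Geometry defaults (240 x 320 px at 1 um/px; flat radius 13 um,
rounded radius 6 um; 3-min frame interval; ~350 pg cells growing at
0.3 pg/min; additive Gaussian OPD noise of 3 nm sd) describe a typical
adherent fibroblast time-lapse at 20x. Rounding is parameterized on
$1/R^2$ rather than $R$: interpolating $1/R^2$ logistically in time
makes the *observable* mean-phase trace a logistic whose midpoint is
exactly the programmed `tEntryMid`/`tExitMid`, so timing recovery can
be tested against the ledger without a shape-model correction. With
these defaults a rounded 350 pg cell peaks near 630 nm OPD — beyond
the 530 nm illumination wavelength — so wrapped movies genuinely
exercise the unwrapping stage while staying below two wavelengths
(the single-correction regime; the generator errors beyond it).

From the furrow time onward a dividing scenario renders two touching
daughter lobes, radii scaled by the square root of their mass share,
centers separated by 1.15 times the summed radii (a clear OPD saddle
for the watershed) plus a slow 0.05 um/min drift apart. The programmed
split fraction $f$ assigns daughter masses $fM$ and $(1-f)M$; a signed
redistribution rate moves a fixed fraction of the furrow-time mass per
minute between the connected daughters for a stated duration, linearly,
conserving the pair total exactly. The intensity channel — used only as
a classifier feature — is a constant minus the local OPD gradient
magnitude plus noise.

What the generator does **not** emulate: optical diffraction and
interference fringes, 3-D refractive-index structure, migration beyond
constant drift, cells crossing or occluding one another, debris, and
uneven illumination. Passing tests therefore demonstrate algorithmic
correctness against a faithful geometric phantom, not robustness to
every artifact of real interferometry.

## Phase unwrapping

Reconstruction reports phase modulo one wavelength, so pixels whose
true OPD exceeds $\lambda$ appear wrapped ($\mathrm{OPD} - \lambda$).
Following the two-region classification formulation, a linear
discriminant over a 16-channel pixel-statistic bank (raw OPD,
intensity, a phase-quality map built from windowed gradient variance,
Sobel x/y/magnitude, Laplacian, Gaussian-smoothed OPD at 2 and 5 px,
local sd at 3 and 7 px, local range, median residual, morphological
gradient, intensity edge magnitude, and wrap proximity
$\max(\lambda - \mathrm{OPD}, 0)$) scores each pixel's membership in a
wrapped region. Training labels come from the generator's wrap-mask
ledger instead of manual annotation; the decision threshold maximizes
balanced accuracy on a deterministic held-out fifth of the training
pixels (systematic every-5th-pixel split per class, so retraining with
swapped labels yields the mirrored model).

The thresholded score map is then refined by random-walker
segmentation. Seeds are threshold-relative rather than fixed
percentiles of the score map: foreground seeds are the morphological
core of the above-threshold candidates restricted to the upper part of
the candidate score range, background seeds are everything beyond a
2-px dilation, and the walker adjudicates the uncertain shell.
Percentile seeding (e.g. the 99th percentile) silently assumes wrapped
pixels occupy a fixed fraction of the frame and seeds false positives
whenever they do not. The walker's edge weights combine the score image
with the raw OPD: a wrap boundary is a one-pixel cliff of nearly
$\lambda$ in raw OPD, and including it lets the cut snap to the exact
boundary (pixel-perfect masks on held-out synthetic frames). Detected
regions receive exactly one positive wavelength correction; negative or
multiple corrections are excluded by construction. Correction is not
idempotent — re-running requires recomputing the mask.

## Segmentation and mass measurement

Frames are smoothed with a 2-px Gaussian (the paper states no value; 2
px suppresses 3 nm noise without moving 6-um-scale saddles), foreground
is selected by Otsu's threshold, and touching cells are split along the
smoothed-OPD ridge by the watershed transform (tolerance 15 nm; shallow
maxima closer than that merge). Two numerical choices matter:

* **Otsu on log-compressed OPD.** On a frame holding one bright rounded
  cell and one dim flattened cell, Otsu on the raw histogram places the
  threshold between the two cell classes (~200 nm) and deletes the dim
  cell. Applying Otsu to $\log(1+\mathrm{OPD})$ keeps the split at the
  background/cell boundary regardless of how bright the brightest cell
  is.
* **Hysteresis support.** Masses are summed over the raw (unsmoothed)
  OPD, and cell support extends from the Otsu level down to an absolute
  floor of 10 nm on the smoothed image (about 17 times the smoothed
  noise level at default settings) — components that never reach the
  Otsu level are dropped as noise. Without this extension the
  threshold clips the dim super-Gaussian skirt and biases flat-cell
  masses several percent low; with it, total frame mass matches the
  ledger within 2% and empty/noise-only frames segment to nothing.
  Regions under 50 $\mu m^2$ are discarded.

Perimeter is measured as the 8-connected boundary chain length with
diagonal steps weighted $\sqrt 2$ (the regionprops-style count of
pixels around the boundary). Plain boundary-pixel counting makes a
digital circle's shape factor 1.26 — above the circle's theoretical
maximum of 1 — while the chain length gives ~0.91 for circles and
$\pi/4$ for squares, as the definition intends.

## Tracking and division detection

Frame-to-frame linking is a global one-to-one assignment minimizing
total squared centroid displacement (Jonker–Volgenant solver, verified
against exhaustive enumeration), with links beyond 20 um/frame
forbidden and a fixed cost of $maxDisp^2$ for leaving a region
unmatched. The cost is purely positional, as in colloid tracking; there
is no gap closing. One veto sits on top of the assignment: a link is
cut when the successor's mass falls below 0.85x the current mass — a
cell cannot lose 15% of its dry mass in 3 minutes, but a dividing
parent "becomes" its nearer ~50% daughter under any positional cost.
The veto makes parent tracks end at the furrow and both daughters start
fresh tracks, and places out-of-window splits (e.g. 0.8/0.2) in the
candidate log rather than silently continuing the parent track.

Division detection applies three criteria: (1) a parent track ends and
two new tracks begin in the next frame within 30 um, each holding
0.35–0.65 of the parent's last mass and 0.8–1.2 combined ("roughly
50%"); (2) the parent's mean-phase trace carries a rising sigmoid fit
before the furrow (mitotic entry); (3) both daughter traces carry
falling fits after it (mitotic exit). Non-adherent cells do not change
shape at division, so only criterion 1 applies and entry/exit times are
flagged undefined. The matched filter slides a logistic template
($\tau = 6$ min, window $\pm 30$ min, replicate-padded at the trace
ends so midpoints near a track boundary — exactly where mitotic entry
sits — remain detectable) and reports local correlation maxima above
0.7 with a fitted swing of at least 20 nm. t = 0 is the first frame in
which the watershed separates the pair (the deep-furrow frame);
time in mitosis is furrow minus entry midpoint, post-furrow rounded
time is the earliest daughter exit midpoint minus furrow. Events within
3 frames of the movie boundary are rejected for lack of trace.

## Partitioning statistics

Per event, `asymmetryDynamics()` reports the signed $\Delta m_0$, the
ordinary least-squares rate $r$ of signed $\Delta m$ over the first 60
min after the furrow (the displayed span of the population heatmap;
the fit window is not otherwise specified), and the ordering key
$\theta = \mathrm{atan2}(r, \Delta m_0)$, which maps initial asymmetry
and its trend onto one axis so the population sorts into contiguous
behavior groups. Population curves aggregate mean $|\Delta m|$ per
10-min bin with s.e.m. over events; the cell-cycle-synchronized mass
CV (sd/mean) is computed per 10-min bin of division-aligned time over
-90..90 min; growth rates are finite differences of track mass binned
over 60-min windows and over relative mass. Welch's two-tailed unequal-
variance t test and the regression F test against a constant-only model
(`stats::t.test`, `stats::lm` under the package's interfaces, verified
in tests against hand-computed formulas) provide the significance
machinery; p-values are reported raw, without multiple-testing
correction.

## Known limitations and measurement properties

* **Watershed tail exchange compresses $|\Delta m|$ by ~8%.** At the
  furrow the daughters are maximally connected; each lobe's OPD tail
  reaches across the watershed line, and the heavier (wider) lobe loses
  more mass across the saddle than it gains. Measured $|\Delta m_0|$ is
  therefore about 0.92x the programmed value, independent of lobe
  radius. A population programmed to 10.0% mean asymmetry measures
  ~9.2%.
* Saddle-line pixel allocation adds a grid-dependent $\pm 0.03$
  jitter to individual $\Delta m_0$ values; it averages out over
  populations but dominates single symmetric events.
* Sigmoid midpoints are quantized to the 3-min frame interval; timing
  recovery is accurate to one frame.
* The unwrap classifier is trained per imaging condition; applying a
  model to frames with different noise or geometry statistics degrades
  the mask and only single positive corrections are ever applied.

## Problem sizes used in the test suite

Unit tests run on 48–128 px frames with single-cell or two-cell scenes;
the division-detector characterization uses 50 division and 50
division-free movies of 48 frames at 72 x 72 px; the population
asymmetry benchmark simulates 500 independent divisions on 48 x 48 px
patches (4 frames each); parameter-recovery properties use 200
ledger-level events. These sizes keep the whole suite within a few
minutes on one core while leaving every assertion at full precision.
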