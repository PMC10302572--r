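---
title: "Quantifying bacterial cell size and initiation mass: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying bacterial cell size and initiation mass: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bactomorph)
```

## The problem

Population-averaged size parameters of rod-shaped bacteria — length $L$,
width $W$, projected area $A$ and volume $V$ — are routinely extracted from
phase-contrast images by segmentation software. Because bacterial widths
(0.5–1 µm) sit near the diffraction limit, the detected cell boundary
depends on where the segmentation threshold is placed, and different tools
or parameter settings yield systematically different absolute sizes from
the *same* images. When a biological conclusion rests on comparing sizes
*across growth conditions* — the validation of the constant-initiation-mass
hypothesis is the canonical example — this setting dependence can flip the
conclusion: one threshold setting shows the initiation mass rising ~50%
from the slowest to the fastest condition, another shows it varying by only
~10%.

`bactomorph` implements both halves of the resulting methodology:

1. an image-based morphometry pipeline whose threshold offset parameter
   reproduces the setting-dependent bias, exercised against synthetic
   images with exact ground truth; and
2. a microscope-independent population workflow (steady-state growth
   verification, mean cell mass from OD and cell counts, replication
   run-out for origin numbers, initiation-mass trend classification) for
   cross-validating image-based conclusions.

## Geometric model

A cell is a spherocylinder: a cylinder of diameter $W$ with hemispherical
caps, total pole-to-pole length $L \ge W$. Its volume and 2-D footprint
(a stadium shape) are

$$V = \tfrac{4}{3}\pi (W/2)^3 + \pi (W/2)^2 (L - W), \qquad
  A = W(L - W) + \tfrac{\pi}{4} W^2 .$$

Two entry points exist deliberately. `spherocylinderVolume()` applied
per cell and then averaged gives the mean of per-cell volumes;
`volumeFromSummary()` applies the formula to *population-mean* dimensions.
The two differ by a Jensen gap of a few percent at typical size CVs
(volume is convex in its arguments), and published summary tables do not
always state which convention they used, so the package names them
distinctly and the cross-checks against bundled summary tables use the
mean-dimension form. Inputs with $L < W$ are rejected rather than swapped:
a width exceeding the length almost always means segmentation failed, and
silent swapping would mask that.

## Synthetic scenes as ground truth

Real micrographs come with no per-cell truth, so every imaging stage is
validated on synthetic scenes (`samplePopulation()`, `renderScene()`,
`generateDataset()`):

* **Dimension sampling.** $(L, W)$ per cell is drawn from a bivariate
  normal with the condition's means and SDs, truncated by rejection to
  $L \ge W > 0$. Summary tables report only means ± SDs, so the
  length–width correlation is not identifiable from them; the default of
  0.3 reflects the mild positive correlation typical of rod-shaped
  bacteria and is configurable. A rejection rate above 50% aborts, since
  it indicates a model whose truncated distribution no longer resembles
  the stated one.
* **Optics.** Cells are dark stadia (interior 150 counts) on a bright
  background (600 counts), with a Gaussian-profile bright halo ring
  (amplitude 100 counts, radial sigma 1.5 px) just outside the boundary,
  then Gaussian blur (sigma 1.2 px) and additive Gaussian noise
  (SD 8 counts). The halo is on by default because it is the dominant
  phase-contrast artefact and the feature that makes measured width
  sensitive to the threshold level. The pixel size defaults to
  0.065 µm/px, typical for a 100× oil objective on an sCMOS sensor.
* **Placement.** Cells are placed by rejection sampling so footprints stay
  disjoint with a 0.3 µm margin. Touching-cell splitting is a separate
  segmentation problem that the package deliberately excludes, so the
  generator never produces it.
* **Determinism.** One master seed fans out to named substreams
  (`stageSeed()`) for sampling, placement and noise, so the same seed
  reproduces a dataset bit for bit while stages remain independently
  re-runnable.

What the generator does *not* emulate: a physical phase-contrast point
spread function, shot noise, illumination gradients, debris, or cells in
contact. Passing tests therefore demonstrate correctness of the
measurement chain under idealized but structurally realistic conditions —
they bound algorithmic error, not instrument error on real data.

## Segmentation and the threshold-offset mechanism

Segmentation (`segmentCells()`) smooths the raster (Gaussian, sigma 1 px
by default), computes Otsu's threshold on the smoothed image, adds the
signed `thresholdOffset` (in camera counts), and takes foreground as
pixels *below* the effective threshold — cells are dark, so a positive
offset moves the boundary outward and enlarges every size parameter. This
sign convention matches the direction seen in published comparisons, where
a higher auto-threshold offset yields larger widths in every medium.
Components are filtered by area bounds, optional mean-intensity bounds and
border contact; "manual correction" of outliers is not implemented, only
the automatic filters. Per region, a sub-pixel contour is extracted as the
iso-intensity line at the effective threshold (marching-squares linear
interpolation via `grDevices::contourLines`): pixel-boundary polygons are
too coarse when widths span only 8–15 px.

The emulation is qualitative by design: the internal numeric scale of any
specific tool's offset parameter is proprietary to that tool, so offsets
here are in this package's own camera counts. What carries over is the
mechanism — on halo scenes, mean measured width and volume are monotone
non-decreasing in the offset (the foreground sets are nested), which is
exactly why a single tunable setting can move all size parameters
coherently and flip a cross-condition comparison.

Otsu's threshold is computed exactly on the distinct intensity values when
they fit in the histogram (at most 256 by default), falling back to binned
cumulative moments otherwise; the test suite checks it against exhaustive
between-class-variance maximization.

## Midline morphometry

`computeMidline()` resamples the contour equally in arclength, takes the
farthest vertex pair as the poles, splits the contour into two sides,
resamples each side to the same node count, and pairs nodes: midpoints
form the midline (smoothed with a short moving average, window 5), and the
distance between paired nodes is the local width sample. "Midline by
interpolation" is underdetermined in the literature; this equal-count
pairing was chosen for robustness on short rods and is documented as one
of several valid readings. Length is the midline arclength; on an analytic
stadium it recovers $L$ within 1%.

Width definitions mirror the conventions of common tools
(`measureCell(width_definition=)`): `mean` averages all samples (the caps
drag it below the cylinder diameter), `max` takes the largest sample, and
`fitted` takes the median of samples over the central region after
excluding one cap length ($W/2$) at each pole — the caps are excluded
because their fall-off biases any cap-inclusive average downward. The
exact fitting procedure behind published "fitted mean width" values is not
specified there; median-of-central-samples is this package's stated
choice. Contours with aspect ratio below 1.2 are flagged rather than
measured, because the farthest-pair pole identification is unstable on
near-circular shapes. Population summaries (`summarizePopulation()`) use
the population-SD convention (divide by $n$) so that fixture-derived
tables are reproducible exactly.

Calibration: segmentation at any fixed threshold has a small systematic
boundary bias, so `calibrateOffset()` sweeps candidate offsets against
ground truth and picks the offset minimizing the combined normalized mean
length/width error — the synthetic analogue of calibrating against beads
of known diameter. On clean scenes of ≥ 500 cells the calibrated pipeline
recovers mean length within 0.1 µm and mean width within 0.05 µm.

## Cooper–Helmstetter model and run-out simulation

With replication period $C$, division delay $D$ (defaults 40 and 20 min,
the classic fast-growth values) and doubling time $\tau$, steady-state
theory gives the population-averaged origin number
$\bar o = 2^{(C+D)/\tau}$ (`meanOriginsClosedForm()`). The run-out
simulator (`simulateRunout()`) draws cell ages from the steady-state age
density $f(a) = (2\ln 2/\tau)\,2^{-a/\tau}$ on $[0, \tau]$ and, writing
$(C+D)/\tau = n + x$, assigns $2^{n+1}$ origins to cells older than
$\tau(1 - x)$ and $2^n$ to the rest — the origin census at the moment
division and new initiations are blocked, which equals the fully
replicated chromosome count after run-out. Initiation-age stochasticity is
deliberately ignored (deterministic timing): the workflow treats run-out
counts as exact, sub-chromosome ploidy is impossible by construction, and
drug-resistant re-initiation is out of scope.

`simulateDnaHistogram()` turns a run-out result into a flow-cytometry-like
DNA histogram (multiplicative Gaussian noise of coefficient of variation
`cv`; instrument gating is abstracted into this single parameter), and
`estimateMeanOrigins()` inverts it by assigning events to the nearest
power-of-two peak in $\log_2$ fluorescence space — multiplicative noise is
symmetric there. If the within-peak spread in $\log_2$ space exceeds a
quarter of the peak spacing, the estimate is flagged low-confidence. At
$cv = 0.03$ the round trip recovers $\bar o$ within 2%.

## Population workflow and trend classification

* `fitGrowthRate()` is a least-squares fit of $\ln(\text{value})$ versus
  time; `stitchDilutions()` adds back $\ln(\text{dilution factor})$
  cumulatively so serially diluted curves fit as one exponential.
* `verifySteadyState()` requires ≥ 10 generations spanned, log-linearity
  ($R^2 \ge 0.98$ by default) of both the OD600 and the cell-count series,
  and agreement of the two rates within 0.05 h⁻¹ by default — balanced
  growth means biomass and number grow at the same rate.
* `meanCellMass()` is OD600 divided by cells/mL, reported in OD600·mL per
  10⁹ cells (an intensive quantity).
* `initiationMass()` computes $m_i = \bar V / (\bar o \ln 2)$ (or with
  $\bar m$ as the mass proxy), and `relativeSeries()` normalizes a
  cross-condition series by its mean.
* `classifyTrend()` labels a series "growth-rate-dependent" only when its
  largest pairwise difference exceeds 25% *and* the series is monotone in
  growth rate; otherwise "constant". The 25% default sits between the
  ~10% variation conventionally read as constancy and the ~50% increase
  read as growth-rate dependence; it is configurable, and the
  monotonicity requirement prevents a single noisy condition from
  producing a spurious "dependent" label.
* `compareSettings()` builds one initiation-mass series per analysis
  setting over a common condition set and raises a conflict flag when the
  trend labels disagree — the formalization of "the setting choice flipped
  the conclusion".

Origin numbers for full four-condition series are generated from the
Cooper–Helmstetter model at each condition's growth rate (with
$C + D = 60$ min, $\bar o = e^{\lambda}$ for $\lambda$ in h⁻¹); the
measured datum available for the bundled conditions is the 2-fold
glucose-versus-glutamine $\bar o$ ratio, which the endpoint calculations
use directly.

## Problem sizes and numerical choices

The test suite and examples use sizes chosen to make sampling error
negligible relative to the tolerances they check: 10⁴–4×10⁴ draws for
distribution-level checks, 10⁵ cells for run-out versus closed form
(3-standard-error criteria), 10⁵ events for histogram round trips,
500+ rendered cells (22 fields of 25) for calibration accuracy, and
100 cells per condition for the end-to-end trend round trip. Voxelization
oracles use a 8 nm pitch (0.5% agreement). Scenes are 512×512 px; the
renderer decides interior/exterior by the pixel-centre rule so that at
zero blur the pixel-count area equals the analytic stadium area to within
one perimeter of pixels. Degenerate inputs are handled by explicit
contracts: constant rasters are an error for Otsu, empty foreground is an
empty result (not an error), near-circular contours are flagged, and ties
in trend classification break toward "constant".

## Limitations

* The threshold-offset emulation reproduces a mechanism, not any specific
  tool's numbers; per-tool absolute sizes are tool-internal and not
  reproducible from outside.
* The generator's idealizations (no PSF physics, no touching cells) mean
  real-data biases can exceed the synthetic calibration accuracy.
* Deterministic cell-cycle timing ignores initiation-age noise; measured
  DNA histograms are broader than simulated ones at equal instrument CV.
* The imaging pipeline targets isolated rod-shaped cells; filamentous,
  branched or curved morphologies are out of scope.
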