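---
title: "Quantifying rod-cell growth, shape and Z-rings: models and methods"
author: "rodquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying rod-cell growth, shape and Z-rings: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodquant)
```

# Scope

`rodquant` quantifies time-lapse microscopy of rod-shaped bacteria such as
*Escherichia coli*: cell length, width and volume from phase-contrast
images via a midline ("pill-mesh") coordinate system; instantaneous
single-cell growth rates; FtsZ-ring detection, scoring and spacing from a
fluorescence channel; cell-cycle statistics (birth/division sizes, added
length, division interval) from tracked lineages; and two bulk-culture
growth-rate estimators from optical density. Because real microscopy data
are large and annotation-free, the package also contains a synthetic-data
generator — an adder-based growth/division simulator plus an image
renderer — so that every quantification stage can be validated against
exact ground truth.

# The growth and division model

Cells elongate exponentially, $dL/dt = \lambda(t)\,L$, with $\lambda$ in
h$^{-1}$. Division follows the adder principle of cell-size homeostasis:
a cell born at length $L_b$ divides when it has added a target increment,
$L - L_b \ge \Delta L \,(1+\varepsilon)$, where $\varepsilon$ is a
per-cycle noise term. The increment noise is lognormal with mean 1 and a
configurable CV (default 0.1) so that lengths remain positive; the
division fraction is $0.5$ plus truncated-normal noise clipped to
$[0.3, 0.7]$. Widths are drawn per cell at birth (lognormal, default CV
0.03) and held constant through the cell's life: the strains being
emulated do not show width dynamics during a cycle, and no width law is
assumed.

Two stress scenarios are built in:

* **ramp** — $\lambda$ and $\Delta L$ fall linearly (default by 40% over
  60 min from induction), emulating activation of the Rcs envelope-stress
  response, which lowers growth rate and the added length per cycle by a
  third or more over about an hour;
* **filament** — division is disabled (as under cephalexin, which blocks
  the divisome transpeptidase), and ground-truth Z-rings are placed every
  $d$ µm along the cell (positions $d/2, 3d/2, \dots$), giving an exact
  ring density of $1/d$.

For the noise-free model the division interval has the closed form
$\tau = \ln((L_b + \Delta L)/L_b)/\lambda$, which the test-suite uses as
an oracle. Within a simulation timestep the division instant is located
by interpolating $\ln L$ linearly — exact for exponential elongation at
constant $\lambda$, and first-order accurate through a ramp — so $\tau$
does not inherit the timestep resolution. A population cap (default
5,000 cells) bounds desk-scale runs with an explicit error.

Two sampling subtleties matter when analyzing completed cycles near the
end of a finite simulation, and are worth knowing about for real movies
too. First, a cycle only enters the completed set if its division fell
inside the observation window, which selects late-born cells for fast
completion (larger birth size, smaller increment noise); distributional
tests of stationarity must therefore stay clear of the final ~2–3 mean
intervals. Second, the two daughters of one division have near-identical
birth lengths, so two-sample tests on birth-size distributions are run
on one daughter per division. The adder diagnostic itself (slope of
$L_d$ on $L_b$; 1 for an adder, 2 for a timer) is unbiased on the full
completed ensemble — we verified a mean slope of 1.001 across ten
independent populations — but a single ~1,000-cycle population leaves
the slope's sampling error near 0.04, so the packaged diagnostic pools
several independent populations.

# Rendering

The renderer turns simulated cells into phase-contrast-like and
fluorescence images. A cell is a capsule (spherocylinder silhouette): all
points within $W/2$ of its centerline segment. Geometry is area-sampled
at 4× supersampling and block-averaged to the pixel grid (default
0.065 µm/px); an isotropic Gaussian PSF (default $\sigma = 0.1$ µm,
about the diffraction scale at this pixel size) is applied at pixel
resolution; optional Poisson noise acts on the signal, then additive
Gaussian read noise, then clipping to the bit depth. Phase images place
dark cells (interior at 35% of background by default) on a bright
background; fluorescence images add, per cell, a uniform cytoplasmic
surface density (counts/µm²) and, per ring, a transverse band with a
Gaussian axial profile (default $\sigma = 0.15$ µm). The renderer's
integrated flux matches the analytic scene integral to better than 1%,
and blurring conserves flux away from the border, which is what makes
the downstream intensity measurements testable.

Pixel $(r, c)$ (1-based) has its center at physical
$((c-\tfrac12)\,p, (r-\tfrac12)\,p)$ with $p$ the pixel size; every
module input and output away from raw images is in µm.

Simulated microcolonies are laid out as a one-dimensional chain: cells
sit end to end along a common axis with a small inter-cell gap (default
0.4 µm), daughters occupy their mother's two halves, and the chain
re-spreads around its center as it elongates. This mimics the local
geometry of dense agarose-pad colonies while keeping frame-to-frame
displacements small enough for overlap-based tracking. Filament fields
for ring analysis are laid out as parallel rows.

# Segmentation and the pill mesh

Phase frames are segmented classically: invert, Otsu threshold (or a
user threshold), connected components, area filter, border-component
exclusion (border-touching cells have unreliable lengths and are dropped
by default), Gaussian smoothing of the binary mask ($\sigma = 1$ px),
and a marching-squares contour at the 0.5 level, resampled to 200 points
in µm coordinates. A frame whose two intensity classes barely separate
(inter-class contrast below 4 within-class SDs) is treated as empty
rather than thresholded into noise; a threshold that claims most of the
frame is reported as a failure. This deliberately simple pipeline is
adequate for rendered images; it does not attempt parity with the
neural-network or Matlab segmentation tools used on real data.

The pill mesh gives each cell a midline coordinate system: poles are the
contour point pair at maximal separation (ties broken by lowest index);
the contour is split at the poles into two sides, paired by normalized
arclength; the midpoint polyline is smoothed with a 5-point moving
average; ribs are re-projected perpendicular to the smoothed midline and
their two boundary crossings give the local width. The number of midline
stations adapts to cell length (one rib per ~0.1 µm, minimum 51) so that
long filaments keep axial resolution. Cells with a max/min caliper ratio
below 1.2 are rejected as "degenerate mesh": pole finding is unstable on
near-round shapes, and downstream size measures would silently mislead.

Length is the total midline arclength; width is the mean rib width over
the **central 60% of arclength**. The cap exclusion is a deliberate
choice: ribs inside the hemispherical caps are geometrically shorter
than the cylinder diameter and would bias the mean width low. Volume
uses the spherocylinder formula
$$V = \pi R^2 (L - 2R) + \tfrac{4}{3}\pi R^3, \qquad R = W/2,$$
a cylinder with hemispherical endcaps; at $L = W$ it degenerates to a
sphere. A cell measured with $L < W$ is an error, not a silent sphere:
such objects are not rods and must be flagged. The formula is verified
against an independent 10-nm voxelization oracle to better than 0.1%
relative error across $L \in [1.5, 10]$, $W \in [0.8, 2]$ µm.

# Growth rates

*Single cell.* The instantaneous rate at time $t$ is the forward
difference $(1/V_t)\,(V_{t+\Delta t} - V_t)/\Delta t$, unsmoothed,
reported per hour. On exact exponential data this estimator returns
$(e^{\lambda \Delta t} - 1)/\Delta t$ — a known upward bias of order
$\lambda^2 \Delta t$ (about 3% at $\lambda = 1.8$ h$^{-1}$,
$\Delta t = 2$ min) that vanishes as $\Delta t \to 0$; the tests pin
this closed form exactly. One practical note: with width constant over a
cell's life, the *volume*-based rate exceeds the elongation rate by the
geometric factor $L/(L - W/3)$ (about 10% for typical aspect ratios),
because spherocylinder volume is affine, not proportional, in $L$. When
a trajectory is compared against a known elongation-rate profile, the
length series is the appropriate input; the estimator accepts any
positive size series.

*Batch OD.* The growth rate is the least-squares slope of $\ln$ OD
versus time using measurements with OD $< 0.4$ (strict inequality, taken
literally) within one dilution segment; segments are split at recorded
dilution events and the longest qualifying segment is used by default.
At least 3 qualifying points are required. The fit is exact on noiseless
exponentials.

*Plate reader.* $\ln$ OD is smoothed with a centered moving average of
window 5 (shrinking symmetric windows at the edges, where no smoothing
convention is established); the pointwise rate is the centered two-point
finite difference of the smoothed series; the reported maximum is taken
over interior points whose stencil touches only fully-windowed values.
Because the moving average of an affine sequence is affine, interior
estimates equal the true rate exactly on noiseless exponentials. On
noisy curves the max statistic carries a small upward noise bias
(≈1.5–2.5% at 1% OD noise with 25 samples), which is part of the
estimator's published definition rather than something we correct.

# FtsZ-ring quantification

The fluorescence background is the median of pixels outside all cell
masks dilated by 3 px (the dilation excludes the PSF halo; the median is
robust to residual structure). The axial profile assigns each rib the
mean of bilinearly interpolated samples along the rib between its
boundary crossings, minus background. Every downstream score is
invariant to adding a constant to the image, which the tests assert
exactly.

Ring calling scans the profile restricted to a pole-margin window
(default 0.3 µm at each end — cap ribs are short, noisy, and depressed
by the PSF rolling into background) after a light moving-average
smoothing on the ring scale (default 0.15 µm). Local maxima qualify if
their topographic prominence exceeds the larger of 20% of the profile
maximum and 2× the profile noise SD (median absolute successive
difference / √2), with a minimum separation of 0.5 µm. Per accepted
peak: the flanking minima are the profile minima between the peak and
its neighbors (or the pole margins); the "minimum" of the peak is their
mean; the width is the full width at half prominence with linear
interpolation of the crossings, and the peak position is refined by a
three-point parabolic fit. The ring intensity score is
$(\text{max} - \text{min}) \times \text{width}$, in counts·µm — the
max-minus-min times peak-width convention used for FtsZ-msfGFP rings.
Ring spacings are successive differences of the sorted positions of one
cell's calls; cells with fewer than two rings contribute nothing.

Two detector properties shape the usable operating range, both measured
on rendered filaments. First, the 20%-of-maximum term means rings with
prominence below ~25% of the cytoplasmic plateau are undetectable
regardless of noise; the synthetic benchmark therefore renders rings at
~3× the cytoplasmic plateau. Second, on long filaments the profile has
hundreds of samples, so the 2×-noise floor admits occasional false
maxima unless the per-sample noise is small; the benchmark fluorescence
channel uses a read noise of 1 count on a 300-count background
(high-sensitivity camera regime), at which ring-free cells yield zero
calls and the detector achieves 100% precision and recall at the
configured spacing.

The rings-per-length slope regresses the summed cell length of a field
of view (response) on its total ring count (predictor) through the
origin — a field with no cells has neither length nor rings, making the
origin the natural anchor; a free-intercept variant is available behind
a flag. Note a small intrinsic bias when comparing the slope to a
configured spacing $d$: a filament of length $L$ carries
$\lfloor L/d \rfloor$ rings, so the expected length per ring is
$d\,(1 + \bar u/\bar n)$ with $u$ the fractional remainder — about
$d\,(1 + 1/(2\bar n))$ for $\bar n$ rings per cell. Longer filaments
shrink the bias; the benchmark uses filaments with ~14 rings (≈4%).

Kymographs resample each frame's profile to a fixed number of
normalized-arclength bins; pole identity is kept consistent across
frames by endpoint proximity (a profile is flipped when its first pole
is nearer the previous frame's last pole).

Whole-cell fluorescence sums the pixels whose centers fall inside the
contour, subtracts background × pixel count, and normalizes by the
spherocylinder volume (counts/µm³). The background may be estimated per
field (default) or supplied per cell.

# Tracking and cycle statistics

Tracking is greedy overlap assignment: contours of consecutive frames
are rasterized on the pixel grid and matched by descending
intersection-over-union, with a 0.3 IoU floor for continuation links. A
predecessor claimed by two successors — each with IoU ≥ 0.15 and with
summed area within 30% of the predecessor's — is tagged as a division.
These thresholds suit dense 2-min sampling and are configurable. There
is no gap closing: a cell absent from one frame ends its track; at 2-min
sampling a true disappearance-and-return is rare, and conservative
termination avoids identity switches.

Cycle records span division edge to division edge. Division events are
placed at the midpoint of the flanking frames, and the division length
is estimated as the mean of the mother's last observed length and the
daughters' summed first lengths; each daughter's birth length apportions
that estimate by the daughters' first-frame ratio. The rationale: at
frame resolution the mother's last length *under*-states and the
daughters' first lengths *over*-state the true division length by half a
frame of growth each, so their mean is unbiased to first order, whereas
the naive last-frame/first-frame convention biases the added length
$\Delta L$ low by $O(\lambda\,\Delta t)$ — about 10% at
$\Delta t = 2$ min and $\lambda = 1.8$ h$^{-1}$, which would swamp the
5% recovery the pipeline otherwise achieves. Incomplete cycles (birth or
division unobserved) are flagged and excluded from means.

Population summaries are time-binned means, SDs, counts and CVs on a
shared grid (default 10-min bins, matching the comparison windows used
for induction time courses); empty bins are reported as missing, never
as zero.

# Problem sizes and runtime choices

The packaged tests and analysis scripts run at desk scale: steady-state
populations of ~1,000–4,000 cycles for adder statistics; microcolony
movies of ~35 frames and up to ~8 cells per frame, pooled across
independent colonies until ≥200 complete cycles for end-to-end recovery;
six filament fields of six cells (~500 rings) for the detection
operating point; 12 replicates per condition for OD-rate recovery. These
sizes keep the full suite in the minutes range while leaving all
acceptance margins comfortably wide of their tolerances.

# What the synthetic data do and do not establish

The generator reproduces the *structure* of the real measurement
problem — exponential elongation with adder division and realistic
noise magnitudes, diffraction-scale PSF, quantized detection, crowding
along colony chains, division-inhibited filaments, serial-dilution OD
curves — and every pipeline stage is validated against its exact ground
truth. It does not reproduce phase-contrast optics (halos, shade-off),
cell curvature or width dynamics, segmentation pathologies of touching
or overlapping real cells, fluorophore photophysics (bleaching,
blinking, maturation), or focus drift. Passing the synthetic suite
therefore certifies the correctness of the computations — meshing,
scoring, tracking, statistics — not the robustness of classical
segmentation on difficult real images, for which purpose-built
segmentation tools remain the right front end; all downstream modules
accept any contour source in physical units.

# Known limitations

* Width is summarized as a single mean over the cell body; curved-rod
  width profiles and septal constriction are out of scope.
* The length-based adder is the only division rule; volume-based
  variants are not implemented.
* Tracking assumes small frame-to-frame displacement and no cell
  contact merging; it is not a learned tracker.
* OD fitting covers exponential growth only — no lag, stationary phase,
  or Gompertz/logistic models.
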