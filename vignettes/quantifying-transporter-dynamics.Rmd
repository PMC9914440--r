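---
title: "Quantifying membrane-transporter diffusion and nanoscale clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying membrane-transporter diffusion and nanoscale clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sptnano)
```

`sptnano` implements the quantification chain used to study how a membrane
transporter (prototypically the Na–K–2Cl cotransporter NKCC1 in cultured
hippocampal neurons) diffuses in the plasma membrane and organizes into
nanoscale clusters: quantum-dot single-particle tracking (QD-SPT) metrics,
STORM nanocluster post-processing, widefield cluster/ratio quantification,
and the statistical layer matched to these data. A seeded synthetic-data
generator stands in for raw acquisitions so that every stage can be
verified against ground truth.

## Single-particle tracking

### The measurement model

A QD-labelled transporter is imaged for $N$ frames (default $N = 1200$) at a
frame interval $\tau$ (default 30 ms). The observed positions are the true
positions plus independent Gaussian localization noise of standard
deviation $\sigma_{loc}$ per axis (default 25 nm, the pointing accuracy of
quantum dots). The time-averaged mean squared displacement of a trajectory
at lag $n$ is

$$\mathrm{MSD}(n\tau) \;=\; \frac{1}{N-n}\sum_{i=1}^{N-n}
\left[(x_{i+n}-x_i)^2 + (y_{i+n}-y_i)^2\right].$$

For free 2D diffusion with coefficient $D$ the expectation is
$4Dn\tau + 4\sigma_{loc}^2$: the localization noise appears as a constant
offset, which is why the diffusion coefficient is fitted as the slope of an
ordinary least-squares line through the **first four lags, excluding the
origin**, with $D = \text{slope}/4$. The fitted intercept estimates
$4\sigma_{loc}^2$ and is a useful internal control (`fit_diffusion()`
reports both and flags negative estimates, which arise from noise on slow
tracks and are excluded from log-scale statistics downstream).

The *explored area* (EA) is the MSD read off at fixed lags — 0.42 s and
0.45 s by default, i.e. lag indices 14 and 15 at $\tau = 30$ ms. It is a
confinement proxy: free diffusion grows linearly through those lags while
confined motion has plateaued. The lag list is configurable; only these two
printed lags are defaults, and no third lag is guessed (the EA sample-size
accounting in `summarize_population()` simply multiplies the number of QDs
by the number of configured lags).

Trajectories with blinking gaps contribute only displacement pairs whose
two endpoints were both observed, and the divisor is the number of valid
pairs. `compute_msd()` is tested against a literal double-loop evaluation
of the defining sum at $10^{-10}$ relative tolerance.

### Linking and crossing removal

The original tracking software is external to this package, so the linker
is a declared design rather than a reconstruction: per frame pair, a
globally optimal assignment (Hungarian algorithm on squared displacement)
with jumps beyond `max_jump` forbidden, gap closing across up to `max_gap`
missing frames (default 3), and new tracks for unmatched detections. The
default `max_jump` is five RMS steps of a 1 µm²/s particle. Pairs of
tracks that pass within `crossing_radius` (default 0.5 µm) of each other in
the same frame are removed wholesale, because identity swaps there would
contaminate both trajectories; the radius is exposed because the original
value is unpublished.

### Compartments and dwell time

Synaptic and endocytic-zone masks live on the camera grid (190 nm pixels —
the pixel size implied by the stated equivalence 4 px = 760 nm). A
trajectory is *synaptic* for a marker if any localization comes within the
inclusion radius (760 nm) of that marker's mask, *extrasynaptic* if every
localization stays at or beyond it; with two markers the nearer one wins
and exact ties are left unclassified. The same rule against a
clathrin-marked endocytic-zone mask yields intra-EZ/extra-EZ. The inclusion
zone (rather than strict mask overlap) is also used for dwell-time
labelling, for consistency between the two analyses. Distances are
evaluated on the mask raster (pixel-centre convention, Euclidean distance
transform semantics), so classification is invariant to how mask connected
components are labelled.

Dwell time is total in-zone time divided by the number of exits; tracks
that never exit are right-censored at their total in-time, and dwell times
under five frames (0.15 s) are flagged as discarded, mirroring the
detection limit of the acquisition.

## The synthetic trajectory generator

`simulate_trajectory()` draws free Brownian increments of per-axis variance
$2D\tau$, or confined motion either as Brownian steps reflected at a disc
boundary or as an Ornstein–Uhlenbeck (OU) pull toward the disc centre. The
OU process is the default confined model because its stationary law is
analytic: the rate is calibrated as $\theta = D/(r/2)^2$ so the stationary
per-axis standard deviation is half the confinement radius $r$, giving an
ensemble MSD plateau of $4(r/2)^2 = r^2$ that tests can check in closed
form. The discretization is exact (AR(1) with coefficient $e^{-\theta\tau}$),
not an Euler step. Localization noise is added after motion, independently
per frame, which is the standard SMLM error model and what makes the MSD
intercept interpretable. Blinking is a two-state Markov chain on
visibility; because the blinking statistics of the actual dyes are not
published, the default is no blinking and the tests that exercise gap
handling switch it on explicitly.

`simulate_scene()` adds compartment discs with per-class motion overrides
(e.g. confined OU inside synaptic discs), emitting the rasterized masks
alongside the trajectories, with ground truth for every frame.

What the generator does *not* emulate: camera physics (EMCCD gain,
Poisson–Gamma noise), anisotropic or anomalous diffusion, 3D motion, and
membrane topography. Passing recovery tests therefore demonstrate that the
estimators are correct for the stated stochastic models at the stated
noise levels — not that real movies meet those assumptions.

## STORM post-processing

Detection tables (frame, x, y in nm; ThunderSTORM-style CSV headers are
accepted) are processed in four stages:

1. **Drift correction** (`estimate_drift()` / `apply_drift()`): centres of
   mass of 2000-frame sliding windows (step 500 frames), relative to the
   first window, interpolated linearly per frame. Each window's estimate is
   anchored at its mean detection frame, where the window COM is an
   unbiased drift reading under locally linear drift. Beyond the first and
   last windows the trace continues the adjacent segment's slope rather
   than holding constant: a constant tail would leave the first and last
   1000 frames uncorrected, which at realistic drift rates contributes more
   error than the whole interpolated interior. By default all detections
   feed the estimate (the intended use is a field dominated by the cluster
   being followed); a fixed ROI or the `densest_roi()` helper restricts it.
2. **Molecule merging** (`merge_detections()`): detections within $2\sigma$
   (default $\sigma = 25$ nm) of a molecule's running mean position and
   within 15 s of its last detection are the same molecule; chaining is
   transitive so long blinking trains stay one molecule. A single global
   $\sigma$ is used because per-detection uncertainties are not part of the
   table format.
3. **Rendering** (`render_detections()`): plain 2D histogram at 20 nm
   pixels; pixel counts sum to the detection count.
4. **Segmentation** (`segment_nanoclusters()`): binarize at 1% of the
   maximum pixel count, take 8-connected components, keep components with
   at least 10 detections and a detection density of at least 0.1 nm⁻²;
   area is pixel count × pixel area and density × area equals the
   detection count exactly. The density threshold is applied at component
   level: a per-pixel reading of 0.1 nm⁻² would demand 40 detections per
   20 nm pixel and contradict the 10-detection minimum. Segmentation runs
   on detections, with molecule counts attached afterwards. The density
   threshold's unit is configurable because the two printed unit
   conventions (nm⁻² in the methods, µm⁻² in figure panels) disagree by
   10⁶; the default follows the methods text.

A resolution caveat worth stating explicitly: for clusters whose radius is
only a few rendering pixels, the binarized pixel area is intrinsically
inflated — every pixel that receives a single detection counts at full
pixel area, so a disc of radius 40 nm rendered at 20 nm pixels covers at
least 16 pixels (6400 nm²) against a true area of 5027 nm². Area estimates
from this segmentation are quantitative for clusters a few hundred nm
across (the planted-recovery tests use radius 300 nm and recover area
within a few percent) and systematically generous below ~100 nm. This is a
property of the histogram-plus-threshold design itself, not of the
implementation.

## Widefield quantification

`flatten_background()` subtracts a k×k median filter (default 3×3,
replicate-padded, exact median) and clips at zero; the flattened image is
used only to *detect* clusters, while areas and intensities are measured on
the raw image. The third parameter of the original software's "3 × 3 × 2"
kernel specification is undocumented and treated as internal scaling that
is not reproduced. The cluster threshold is a required per-experiment
constant — conditions to be compared are imaged at one fixed exposure, so a
single user-chosen threshold is applied to all of them and never
auto-tuned per image. `surface_total_ratio()` and `ratiometric_trace()`
are deliberately thin: background-subtracted means over a common ROI, with
invalid frames (non-positive denominator) flagged rather than dropped
silently. Which excitation channel is the ratio's numerator is the
caller's choice, since the source conventions differ between the methods
text and figure legends.

## The statistical layer

SPT and cluster metrics are approximately log-normal, so two-group
comparisons first divide by the control group's median and take logs
(`lognormalize()`; the transformed control median is exactly 0).
`choose_and_test()` applies Shapiro–Wilk to both groups (α = 0.05): if both
pass, Welch's unequal-variance t-test; otherwise the two-sided Mann–Whitney
U, exact when both n ≤ 20 without ties, continuity-corrected normal
approximation with mid-ranks otherwise.

For super-resolution metrics, observations are nested in neurons and
cultures with very unequal counts, and single bright neurons can dominate a
pooled rank test. `mc_balanced_mw()` therefore repeats, 1000 times: draw
$m$ observations (the global per-neuron minimum) from every neuron without
replacement; divide by the culture-wise median of the *selected* control
values; pool cultures; log; compute the Mann–Whitney U. The selection →
divide → pool → log → U order is deliberate: the per-culture normalization
must see the same balanced subset the statistic sees. Two aggregations of
the 1000 U values into a p-value are defensible, and both are computed: the
primary reading takes the median U's two-sided tail probability under the
MW null for the balanced sample sizes; the alternative
(`p_method = "median_p"`) is the median of per-repetition p-values. They
agree closely in practice; neither is claimed to be the original pipeline's
certified intent.

Calibration as implemented in the acceptance checks: on independent
log-normal nulls the forced MW branch rejects at the nominal 5% within
binomial error; on clustered nulls (the generator below) the balanced
procedure rejects at roughly 5–10% — the balanced draw equalizes leverage
across neurons but is not a cluster-robust variance correction, so a mild
residual anti-conservativeness under between-neuron variability is
expected and observed; power for a two-fold shift at 5 neurons × 20
observations per condition is essentially 1.

`simulate_grouped_sample()` fixes the clustered test-bed: 2 cultures, 5
neurons per condition per culture, per-neuron counts Poisson(25) clamped to
≥ 15 (so the balanced draw actually subsamples), culture effects of log-sd
0.3, neuron effects of log-sd 0.1 against within-neuron log-sd 0.5. These
were chosen once as a realistic mild-clustering regime — the stated
motivation for the balanced procedure is between-cell variability — and the
calibration numbers above are reported under exactly these conditions.

## Problem sizes and numerical choices

The recovery analyses run at the acquisition scales: 500 trajectories of
1200 frames for D/EA recovery; 30,000 frames with 2000-frame windows for
drift; 1000 null repetitions for test calibration; 200 clustered datasets
for the resampling test's null; 300 QDs per group for the
direction-of-effect scenario. Other defaults worth knowing: MSD curves are
capped at the lags a caller needs (`max_lag`) since the fit uses 4 lags and
EA uses 15; ensemble MSD curves average only lags where ≥ 80% of tracks
are defined; assignment ties in the linker resolve deterministically by
input order; `mc_balanced_mw()` sorts rows canonically before sampling so
results are invariant to input row order under a fixed seed; all
simulators give bit-identical output for identical config + seed.

## Known limitations

* The linker is nearest-neighbour-optimal per frame pair, not a multiple-
  hypothesis tracker; it is the declared stand-in for unpublished tracking
  software.
* Small-nanocluster areas are resolution-limited as described above.
* No per-segment diffusion states within a trajectory (no HMM), no
  anomalous-diffusion exponents, no 3D.
* The chloride-probe readout stays on the ratio scale; no concentration
  calibration is attempted.
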