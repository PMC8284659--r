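---
title: "Quantifying axonal microtubule plus-end dynamics and disorganisation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying axonal microtubule plus-end dynamics and disorganisation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(axonmt)
```

## The measurement problem

Axons are supported by bundles of parallel microtubules (MTs). Growing MT
plus-ends recruit end-binding (EB) proteins into comet-shaped
accumulations that can be imaged either in fixed neurons (immunostaining)
or live (EB-binding fluorescent markers). Phenotypes of interest are
quantified through a small set of readouts:

* **comet amount** — the product of a comet's background-subtracted mean
  intensity and its length, a proxy for the amount of EB protein at the
  plus-end;
* **comet number** per axon, and the **lattice intensity** of EB signal
  along the MT shaft between comets;
* **comet velocity and lifetime**, read off kymographs of 1-min
  time-lapse movies (1 s or 2 s frame interval) or from automated 2D
  particle tracking;
* **axon length** and the **MT disorganisation index (MDI)** — the total
  freehand-annotated area of disorganised, curled MT bundles divided by
  axon length times a 0.5 um reference diameter, i.e. curl area in units
  of the area a properly bundled axon of that length would occupy;
* nonparametric group statistics on per-neuron values, normalised to
  parallel (same-repeat) controls.

This package implements each readout as a deterministic, parameterised
procedure, together with a synthetic-data generator that renders axon
stills and comet movies with fully known ground truth. None of the
original microscopy data these procedures were designed around is
publicly deposited, so correctness is demonstrated by recovery of known
truth rather than by reproducing published fold-changes: that is what
`tests/` and `scripts/acceptance.R` do.

## The synthetic generator

`sim_config()` collects acquisition and scene parameters; all public
quantities are in micrometres and seconds. The generator produces three
things:

* `simulate_axon_trace()` — a polyline medial axis laid out horizontally,
  soma end first. Curled regions are inserted as closed loops whose
  polygon encloses exactly the requested area; the loop perimeter is
  carved out of the arclength budget so total arclength is preserved
  exactly. The loop polygons are returned as ground truth and double as
  "freehand annotations" for the MDI stage.
* `simulate_comet_movie()` / `render_movie()` / `render_still()` — comets
  nucleate along the axon as a homogeneous Poisson process (default 0.5
  events/um/min, chosen to give a steady-state density of roughly one
  comet per 6 um at the default 20 s mean lifetime, matching the look of
  sparse EB stainings), advance at a constant signed velocity and die
  after exponential lifetimes or on leaving the axon.
* `simulate_tracking_movie()` — an open 2D field of straight-moving
  comets with random headings, for benchmarking the particle tracker.

**Comet model.** A comet is an intrinsic emission profile — a short
Gaussian leading edge of fixed 0.1 um width and an exponential trailing
tail (decay length `comet_tail_length_um`, tail pointing to the soma for
anterograde motion) — convolved with a Gaussian PSF. The front width is
deliberately a property of the comet, not of the optics: this makes the
total emitted flux independent of `psf_sigma_um` (blur redistributes
photons, it does not create them), which the test suite checks to within
1%. A consequence worth knowing is that `comet_amplitude` is an
integrated linear density (intensity x um): the rendered peak height
depends on the PSF width, and `amplitude_for_snr()` computes the
amplitude that yields a requested peak signal-to-noise ratio under the
configured noise.

**Rendering.** Profiles are integrated over pixel footprints by
depositing dense arclength samples onto a 3x oversampled grid (midpoint
rule), blurring with the PSF and integrating back to sensor pixels; this
avoids the aliasing that nearest-pixel painting would imprint on length
measurements. Pixel values follow a field convention — a pixel holds the
blurred emission field at its footprint, independent of pixel size — so
intensity measurements are comparable across resolutions. Noise is
optional Poisson shot noise on the noiseless image (offset included)
followed by additive Gaussian read noise, the standard sCMOS model; both
are independently switchable so exact noiseless fixtures exist. Equal
configurations (including `rng_seed`) give bit-identical stacks.

**What the generator does not emulate:** photobleaching, out-of-focus
light and z-structure, comet maturation (intensity ramps after
nucleation), lattice binding kinetics, and motion of the axon itself.
Passing recovery tests on this generator therefore demonstrates the
correctness of the measurement code under the stated image model, not
performance on any particular real data set.

## Still-image comet quantification

`trace_profile()` samples an image along a trace at 1 px arclength steps
with bilinear interpolation, averaged across a perpendicular band
(`band_px`, default 3 px), mirroring average-intensity reslicing.
`detect_comets()` finds peaks of the difference-of-Gaussians filtered
profile (scales 0.5x and 2x the PSF sigma) that pass three gates:

1. smoothed intensity above background + `k_mad` (default 5) robust
   noise sd (noise estimated from first differences of the profile);
2. topographic prominence of at least 15% of the peak's own height above
   background, with the local intensity maximum interior to the filter
   support — this rejects shoulder bumps on a brighter comet's tail in a
   way that works identically on noiseless and noisy input, while a
   comet riding on a neighbour's tail (about 20% relative prominence at
   1 um separation) survives;
3. a dynamic-range floor of 5% of the strongest peak's height, since
   residual tail structure sits two orders of magnitude below real
   comets whereas true comet brightness varies a few-fold.

The profile ends inside the filter support are excluded: the lattice
terminus mimics a comet edge there.

`measure_comet()` implements the comet-amount definition: the extent is
the maximal contiguous run around the peak with intensity above
`background + f * (peak - background)` (`f = 0.2` by default; the manual
line-drawing protocol this replaces never states an edge rule, so a
reproducible fractional-peak criterion is used and `f` is exposed);
length is the extent span, mean intensity the background-subtracted mean
over it, and `amount = mean x length` — an identity asserted on every
measurement. Because the absolute intensity units of the original
measurements are unknowable, only ratios and control-normalised values
are comparable to published numbers; the package therefore validates
lengths against a brute-force threshold-crossing oracle computed on the
analytic profile and amounts through their algebraic identity and
control-normalised pipeline behaviour.

`estimate_background()` is the median outside comet exclusion zones
(at least 25% of samples must remain), and `lattice_intensity()`
averages the background-subtracted band intensity along the shaft with a
configurable exclusion window around each comet.

## Kymographs

`build_kymograph()` resamples each frame along the trace (1 px steps,
`band_px`-wide average): column *t* is the frame-*t* profile, so a comet
moving at *v* traces a ridge of slope *v*. `extract_tracks()` detects
per-column peaks with the same rule as the still-image detector, links
them greedily frame-to-frame within `max_step_um` (default twice the
displacement of a 0.5 um/s comet per frame, scaled by the gap length
when frames are missed), bridges gaps up to `max_gap_frames = 2`, and
discards tracks with fewer than 3 observed points. Velocity is the
least-squares slope of arclength against time over all track points —
more noise-robust than an endpoint slope — and lifetime is
`(last frame - first frame) x interval`, gaps included, matching a line
drawn on a kymograph from first to last appearance. Sub-sample peak
positions come from a parabolic refinement on a more heavily smoothed
profile; its small shape-induced bias is identical in every frame and
cancels exactly in slopes and lifetimes.

The recovery benchmark (`benchmark_comets()`) draws comet cohorts whose
trajectories keep at least 1.5 um from temporally overlapping
neighbours, with a 3-frame-interval guard band around each lifespan:
comets closer than about one comet length are optically a single object,
and a comet born moments after another dies at the same spot is
ambiguous for any scorer once gap closing can bridge the pause. Measured
on such cohorts at peak SNR 5, the extractor matches over 90% of truth
tracks with median velocity error below 10% at 0.05-0.3 um/s and median
lifetime error below one frame interval (see `test-acceptance.R` and the
acceptance script for the exact numbers recomputed at run time).

## 2D plus-end tracking

`detect_particles()` finds comets in single frames: DoG local maxima
gated on smoothed intensity above `median + k_mad x mad` (comets are
sparse, so the image median and mad estimate background and noise), a
monotone-slope rejection (the intensity maximum of the candidate's
neighbourhood must be interior), and non-maximum suppression within
`min_sep_px` keyed on the DoG response. Tip positions are refined with a
matched filter: the comet axis is estimated from the candidate-to-
centroid vector of the local noise-cut excess intensity (the tail pulls
the centroid backward, giving axis and polarity in one step), and the
package's own comet template is slid along the axis; the correlation
maximum is an unbiased tip estimate, important because the blurred
comet's intensity summit sits 1-2 px down the tail from the tip.

`link_tracks()` implements the printed parameter semantics
(`tracking_params()`: max gap 8 frames, min track length 3 frames,
search radius 5-12 px, forward angle 50 deg, backward angle 10 deg,
shrinkage factor 0.8, fluctuation radius 2.5 px, 2 s interval). The
original tool's internals are not public, so the semantics here are this
package's explicit interpretation, stated in the documentation and
enforced by an independent checker:

* frame-to-frame assignment minimises total squared displacement
  (an O(n^3) shortest-augmenting-path assignment solver, with a
  birth/death alternative costed at the squared upper search radius);
* a step is feasible when no longer than the upper radius and either at
  least the lower radius or within the fluctuation radius (a pause);
* steps must stay within the forward angle of the current heading, or
  qualify as shrinkage: within the backward angle of the reversed
  heading and no longer than the shrinkage factor times the mean forward
  step. Backward steps carry a 4x cost penalty so they never outbid a
  feasible forward continuation, and they do not update the heading;
* track ends reconnect across up to `max_gap_frames` missed frames when
  the heading-extrapolated position lies within the upper radius scaled
  by the gap length (unscaled for heading-less, i.e. paused, segments);
  every candidate merge is re-validated by the constraint checker, since
  a junction can retroactively violate the angle gates;
* segments abutting in time are repaired by trimming a single offending
  junction point when that restores consistency — one outlier detection
  otherwise splits a track irrecoverably, because the infeasible step
  that caused the split can never be re-admitted.

`validate_tracks()` re-derives all of these constraints from the stored
points alone and is run over every emitted track in the tests.

The 2D benchmark places straight tracks with speeds of 0.35-0.55 um/s
(7-11 px displacements at 2 s and 0.1 um/px, the interior of the search
annulus: displacements at the annulus boundary are infeasible-by-noise
under the stated dead-band semantics for any tracker) and at least 15 px
between concurrent comets.

## Morphometrics

`axon_length()` is the calibrated polyline length; `polygon_area()` the
shoelace area (simple polygons only, orientation-free); `mdi()` divides
the summed curl area by length x reference diameter (0.5 um default,
exposed as a parameter). Multiple curl regions per axon are summed —
the natural reading of an aggregate "area of disorganised curling" —
and `swelling_counts()` tallies annotated swellings with the convention
that a swelling-with-curling also counts as a swelling. Curl and
swelling identification is annotation-driven; automated segmentation of
disorganised regions is out of scope.

## Statistics

The statistical layer mirrors the field's reporting conventions:
per-neuron values are the statistical unit, pooled across biological
repeats, with per-repeat centres reported alongside ("superplot" style);
`normalise_to_control()` divides by the same-repeat control centre so
the control sits at 1 in every repeat; medians with percentile-bootstrap
95% CIs (10,000 resamples, seed recorded) summarise comet amounts,
lengths, velocities and axon lengths, while MDI and counts use mean and
SEM conventions (`default_center()`).

`kruskal_wallis_dunn()` computes the tie-corrected Kruskal-Wallis H with
post hoc Dunn z tests on the shared ranks; because the original analyses
do not state a multiplicity adjustment, both raw and Holm-adjusted
pairwise p-values are reported, with Holm as the headline.
`mann_whitney()` uses exact enumeration (via the null distribution of
the rank-sum statistic) for untied samples with min(n) <= 8 and the
tie-corrected normal approximation otherwise; `spearman_cor()` uses
exact permutation enumeration for n <= 9 without ties and the
t-approximation otherwise, flagging degenerate constant input. All four
are checked against independent reference implementations to 1e-9 in the
tests, and the two-group Kruskal-Wallis is verified to order p-values
identically to Mann-Whitney.

## End-to-end check

`sim_amount_mdi_cohort()` constructs ten conditions whose true comet
amplitude falls while the true curled area grows, renders every neuron,
measures amounts from the images, computes MDIs from the ground-truth
polygons, normalises both metrics to the parallel controls and
correlates the per-genotype centres:

```{r, eval = FALSE}
coh <- sim_amount_mdi_cohort(n_genotypes = 10, n_neurons_per_repeat = 3,
                             seed = 5)
res <- correlate_amount_mdi(coh$table)
res$spearman
#> r = -0.96, p = 7.3e-06
```

The anti-monotone construction is recovered as a strong negative
Spearman correlation through the complete pipeline.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use desk-scale problems
chosen to estimate each quantity stably: 50 random comet layouts for
count recovery, 16-30 one-minute movies across four velocities for
kymograph recovery, 8+ two-hundred-pixel 2D movies for tracker recall,
500 simulated datasets for bootstrap coverage, and a 60-neuron cohort
for the pipeline correlation. Degenerate inputs are handled explicitly:
all-tied groups yield H = 0, p = 1 with a flag; empty track lists yield
zero counts with undefined medians flagged; constant correlation input
is flagged rather than silently dropped; missing calibration always
errors rather than assuming 1 um/px. Peak-linking ties break on the
smallest spatial jump; bootstrap intervals use the percentile method.

## Known limitations

* TIFF storage uses 32-bit samples on a uniform grid over the recorded
  range (the underlying writer does not emit IEEE float samples):
  integer data round-trips exactly, other data to within 2^-32 of the
  range.
* The automated kymograph scorer replaces a manual protocol; on real
  data it may differ systematically from a human scorer, and only
  synthetic-truth validation is claimed.
* The tracker semantics are an explicit interpretation of a printed
  parameter list; the original implementation may differ in its cost
  matrices and adaptive search radii.
* Comets closer than about one comet length, and comets whose
  displacement per frame sits at the boundary of the search annulus,
  are not resolvable under these semantics; the benchmarks exclude such
  configurations by construction and say nothing about them.
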