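---
title: "Simulation and stochastic origin ensemble reconstruction for TOF dual-photon emission tomography"
author: "dupect"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulation and SOE reconstruction for TOF dual-photon emission tomography}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dupect)
```

## The imaging problem

Time-of-flight dual-photon emission computed tomography (TOF-DuPECT) images
cascade gamma emitters with a collimator-less full ring of scintillator
crystals. A nuclide such as Se-75 de-excites through an intermediate nuclear
level, emitting two photons in quick succession. When both photons are
detected in coincidence, the *time difference of arrival* (TDOA) constrains
the decay position: with $d_1, d_2$ the source-to-detector distances and $v$
the speed of light,

$$\mathrm{TDOA} = \frac{1}{v}(d_1 - d_2), \qquad
  |d_1 - d_2| = v\,|\mathrm{TDOA}| = 2a = \text{constant},$$

which is the defining property of a hyperbola with the two detectors as
foci. The locus of candidate decay positions for one event — the analogue of
PET's line of response — is therefore one *branch* of a hyperbola with
semi-major axis $a = \tfrac12 v\,|\mathrm{TDOA}|$, focal separation
$\Delta\ell$ (the distance between the two hit positions) and semi-minor
axis $b = \sqrt{\Delta\ell^2/4 - a^2}$. Only the branch nearer the detector
that fired *first* is physically possible. Unlike annihilation photons,
cascade photons are not back-to-back; the hyperbola is all the geometry
gives.

The coincidence time resolution (CTR, the FWHM of the arrival-time
difference distribution for two simultaneous photons) sets how precisely an
event is localized along and across its curve, and hence the reconstructed
resolution. The package regenerates, at desk scale, the behaviour of such a
system as the CTR is varied from 0 to 200 ps.

## The simulator and what it emulates

`simulate_acquisition()` produces list-mode coincidence data through an
explicit pipeline, each stage also exposed as its own function:

1. **Decay sampling** (`sample_decay_positions`): decay positions i.i.d.
   proportional to the phantom's piecewise-constant activity map (rejection
   sampling), emission times uniform over the acquisition (the 120-day
   parent half-life is negligible over seconds).
2. **Cascade emission** (`emit_cascade`): a decay selects a cascade channel
   by probability; both photon directions are i.i.d. isotropic (the small
   angular correlation of cascade gammas is neglected), and the second
   photon is delayed by an exponential with mean
   $t_{1/2}/\ln 2$ of the intermediate level.
3. **Ray transport** (`propagate_to_ring`): analytic ray-cylinder
   intersection; no attenuation, scatter or crystal interaction physics.
   The hit is binned to a crystal and repositioned at the crystal
   front-face center (no depth of interaction), and survives with the
   detection efficiency (0.9).
4. **Detector response** (`apply_detector_response`): per-crystal energy
   resolution drawn once, uniformly in 12–18% FWHM at 511 keV, scaled as
   $1/\sqrt{E}$; timestamps blurred with
   $\sigma_{\text{single}} = \mathrm{CTR}/(2\sqrt{2\ln 2}\,\sqrt{2})$ so the
   *pair difference* has FWHM equal to the CTR.
5. **Coincidence sorting** (`sort_coincidences`): singles are clustered by
   gaps larger than the 2 ns window; clusters of exactly two become events,
   clusters of three or more are discarded entirely (a conservative
   multiple-coincidence policy).
6. **Dual energy windows** (`energy_window_accept`): exactly one hit in
   108–164 keV and one in 211–318 keV (inclusive).
7. **Single-slice rebinning** (`ssrb_slice`): events with axial ring
   difference at most 2 are assigned to the slice at the mean ring
   (round-half-to-even); larger ring differences are rejected.

The Se-75 model (`se75_nuclide()`) carries the two usable cascades —
136 keV followed by 264.7 keV through the 11.2 ps level (probability 0.55)
and 121.1 keV followed by 279.5 keV through the 273 ps level (probability
0.15). Published level schemes do not give gamma–gamma branching fractions;
these defaults route the dominant statistics through the short-lived level
while leaving 30% of decays unproductive, and they are configurable. Ratio
metrics (contrast recovery, spillover) are insensitive to this choice; the
absolute sensitivity inherits its uncertainty, which is why sensitivity is
checked with a wide band.

**What the simulator deliberately does not model**: photoelectric/Compton
interactions in tissue or crystal, inter-crystal scatter, pile-up, dead
time and depth of interaction. Two consequences matter when comparing
against full Monte Carlo results. First, deposited energies are Gaussian
around the photopeak, so the dual energy windows remove only Gaussian tails
(about 15% of true pairs) rather than the larger partial-deposit continuum;
the windowed/unwindowed sensitivity ratio here is ~0.75 where a full
simulation gives ~0.5. Second, the resolution floor at CTR 0 contains only
crystal-pitch quantization, rebinning slant and intermediate-level delay.

## Reconstruction: stochastic origin ensemble on hyperbolas

Each recorded event $k$ holds one candidate origin voxel on its own
response curve. `reconstruct()`:

* builds every event's hyperbola (`hyperbolas_from_events`); events whose
  measured $v\,\mathrm{TDOA}$ exceeds the focal separation (possible under
  timing blur) are clamped to the degenerate near-focus limit rather than
  dropped, so event accounting matches the sorter;
* enumerates the pixels crossed by the branch inside the circular FOV mask
  (`enumerate_candidates`). The curve is marched adaptively in arc length
  and every polyline segment is rasterized exactly with an
  Amanatides–Woo traversal, which makes the candidate set stable under
  march-step refinement; a TDOA of exactly zero is handled as the
  perpendicular-bisector chord. Events whose curve misses the FOV are
  dropped and counted;
* initializes each origin uniformly over its candidate set, then runs
  Metropolis sweeps ($N$ proposals per sweep, one uniformly chosen event
  per proposal, proposal uniform over the event's candidates). A move from
  a voxel with event count $c_i$ (including the moving event) to one with
  count $c_{i'}$ is accepted with
  $$A = \min\!\left(1,
    \frac{c_i^{\,c_i}\,(c_{i'}+1)^{\,c_{i'}+1}}
         {(c_i+1)^{\,c_i+1}\,c_{i'}^{\,c_{i'}}}\right),$$
  evaluated in log space with $0^0 \equiv 1$. The per-event origin
  probability and per-voxel sensitivity factors that generalize this ratio
  are fixed at 1. The self-count convention ($c_i \ge 1$; proposing the
  current voxel is always accepted) makes the lone-event case
  $A(1,0) = 1/4$ well defined;
* averages the event-density image over the final `n_average` sweeps
  (running mean; total counts are conserved exactly at every step), and
  optionally post-smooths with a Gaussian of SD 0.75 pixels whose
  truncated boundary kernel is renormalized on the source side so totals
  are preserved.

The defaults (1500 sweeps, average of the last 300) follow the full-scale
study conditions; the desk-scale experiments below state their own
schedules.

### Numerical and design choices

* **Event visiting order**: one uniformly random event per proposal rather
  than a fixed permutation — this matches the random-selection description,
  keeps the chain aperiodic, and is configurable in spirit via repeated
  `soe_sweep()` calls.
* **Candidate measure**: proposals are uniform over the *distinct* voxels
  crossed by the curve. An arc-length-weighted variant would weight long
  chords more; at 4.5–6 mm pixels the difference is well below the other
  desk-scale effects.
* **Degenerate inputs**: `tdoa = 0` uses the bisector chord; clamped events
  march a near-degenerate branch whose adaptive step-halving keeps the
  polyline faithful near the sharp vertex.
* **Tie-breaks**: pixel intervals are half-open with 0-based indices from
  the most-negative corner; slice assignment rounds half to even;
  candidate order is the deterministic traversal order, so fixed seeds give
  bit-identical reconstructions.

### Desk-scale behaviour of the chain

At the full study scale (~1.5–5 million events) the origin-ensemble
average is a smooth image. At desk scale (1–4 hundred thousand events)
the clustering reward $\prod_i c_i^{c_i}$ makes the chain coagulate into a
constellation of sub-resolution clusters that drift only slowly — a
metastable state whose *envelope* carries the physical localization
uncertainty. Two practical consequences, both visible in the tests:

* point-spread-function widths are measured on the post-smoothed OE
  average (the study's outputs are all post-smoothed with SD 0.75 pixels);
  the raw image's central cluster would understate the ensemble spread;
* background noise metrics (the background coefficient of variation and
  therefore the contrast-to-noise ratio) are count-limited: they scale
  roughly with the inverse square root of events per voxel and sit well
  above their full-scale values at desk scale, while the ratio metrics
  (contrast recovery, spillover) are already stable. The desk-scale CNR is
  reported with the paper-scale schedule (1500 sweeps, average 300) to
  maximize state averaging; the residual gap to the full-scale value is a
  statement about counts, not about the method.

## Image quality metrics

`evaluate_contrast()` reports, over circular ROIs whose pixels are selected
by center-inclusion:

* $\mathrm{CV_B} = \sigma/\mu$ over a 10 cm background ROI (population SD;
  the convention is documented because the source text does not specify);
* $\mathrm{CRC} = (C_{hot}/C_{bkgd} - 1)/(a_{hot}/a_{bkgd} - 1)$;
* $\mathrm{CNR} = (C_{ROI} - C_{bkgd})/\sigma_{bkgd}$;
* $\mathrm{SOR} = C_{cold}/C_{bkgd}$.

The background ROI defaults to a 10 cm circle at (0, −75) mm — away from
both rods, symmetric between them; trend results are insensitive to
±1-pixel ROI shifts. `psf_fwhm()` takes the row and column profiles through
the image maximum and interpolates the half-maximum crossings linearly,
reporting the mean of the two in mm. `line_profile()` uses 1-based row
indices counted from the most-negative y, matching the usual figure
convention. Rod resolvability is quantified with `count_profile_peaks()`
(topographic prominence above 10% of the profile maximum).

## Phantoms

* `make_point_source()` — a 2 mCi point at the FOV center (sensitivity and
  PSF studies). For candidate-membership checks the source is placed at a
  *pixel center*; the FOV center itself is a corner of four pixels on an
  even grid, which makes "the true pixel" ill-posed.
* `make_contrast_phantom()` — 30 cm background cylinder with 10 cm hot and
  cold rods at (±75, 0) mm, concentrations 2:1:0. The rod centers are a
  package choice (the source layout is schematic); they are symmetric,
  non-overlapping and configurable.
* `make_jaszczak_phantom()` — 19 hot rods (9 × 15.4, 6 × 19.1,
  4 × 25.4 mm, 15 cm long) in three sectors on triangular lattices with
  spacing twice the rod diameter, inside a cold 25.6 cm boundary; exact
  coordinates are a package choice validated for containment and
  non-overlap, and the resolvability experiments test peaks per diameter,
  not exact positions.

By default decays are sampled in an axial band of ±2.5 axial crystal
pitches around the central slice, so desk-scale runs concentrate events in
the analysed slices; the full axial extent is available via `z_band = NULL`.

## Problem sizes used by the shipped experiments

The acceptance experiments state their sizes explicitly as the package's
desk-scale choices: sensitivity from ~2 × 10⁶ decays; point-source PSF from
~10⁵ windowed primary coincidences per CTR, reconstructed with 300 sweeps
averaging the last 100; the contrast phantom from ~3.5 × 10⁵ coincidences; and rod
resolvability from ~6 × 10⁵ coincidences with the full 1500/300 schedule,
since resolving the smallest rods is the most statistics-hungry check. Full-scale replication (5 × 10⁶ events,
as in the source study) uses the same code paths with longer durations.

## Known limitations

* No attenuation, scatter, randoms-from-background or crystal-physics
  corrections: quantitative accuracy beyond the simulated conditions is out
  of scope.
* The 2D reconstruction treats rebinned events in the transaxial plane;
  the small slant path-length error of oblique coincidences is part of the
  resolution floor, as in the rebinning approximation itself.
* Only the two dominant Se-75 cascades are modelled, with assumed branching
  fractions.
* Desk-scale noise metrics are count-limited as described above.
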