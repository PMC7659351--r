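# dupect

Simulation and reconstruction toolkit for **time-of-flight dual-photon
emission computed tomography** (TOF-DuPECT): a collimator-less full-ring
scanner that images cascade gamma emitters (e.g. Se-75) from the
time-difference-of-arrival (TDOA) of the two cascade photons.

For one coincidence the TDOA confines the decay to one branch of a
hyperbola with the two detectors as foci:

```
TDOA = (d1 - d2) / v,   |d1 - d2| = v |TDOA| = 2a,
a = v |TDOA| / 2,  Δℓ = |focus2 - focus1|,  b = sqrt(Δℓ²/4 - a²),
```

with the physical branch the one nearer the detector that fired first.
Images are reconstructed from list-mode events with the **stochastic
origin ensemble** (SOE) algorithm: every event holds one candidate origin
voxel on its own curve, moved by a Metropolis-Hastings chain on the global
event-density image `c`, with acceptance

```
A = min(1, c_i^c_i (c_i'+1)^(c_i'+1) / ((c_i+1)^(c_i+1) c_i'^c_i')),
```

and the reconstruction is the event-density average over the final sweeps.

The package provides:

* `simulate_acquisition()` — list-mode Monte Carlo: cascade decay scheme
  with intermediate-state half-lives, isotropic emission, analytic ray
  transport to a Biograph-6-like ring (48 modules x 13 x 13 crystals,
  424.5 mm radius), per-crystal energy resolution (12-18% at 511 keV),
  pair timing resolution (CTR), 2 ns coincidence sorting, dual energy
  windows (108-164 / 211-318 keV), single-slice rebinning (ring
  difference <= 2);
* `hyperbolas_from_events()` / `enumerate_candidates()` — the TDOA
  hyperbola-of-response model and exact rasterization of each branch onto
  the image grid;
* `reconstruct()` — SOE reconstruction with optional Gaussian
  post-smoothing (`post_smooth()`);
* `evaluate_contrast()`, `psf_fwhm()`, `line_profile()`,
  `count_profile_peaks()` — image-quality metrics (background CV, CRC,
  CNR, SOR, PSF FWHM, rod resolvability);
* phantoms: `make_point_source()`, `make_contrast_phantom()` (2:1:0
  hot/background/cold), `make_jaszczak_phantom()` (19 rods of 15.4, 19.1,
  25.4 mm);
* `run_ctr_sweep()` — the CTR sweep experiment driver, plus a thin CLI in
  `inst/cli/dupect.R` (`simulate`, `reconstruct`, `evaluate`, `sweep`).

## Worked example

A 2 mCi point source at the scanner center, 100 ps CTR:

```r
library(dupect)
geom  <- scanner_geometry()                 # Biograph-6-like ring
ph    <- make_point_source(mci_to_bq(2))    # 7.4e7 Bq at (0, 0, 0)
lm    <- simulate_acquisition(ph, geom, duration_s = 0.027,
                              ctr_ps = 100, seed = 42)
lm
#> List-mode acquisition: 4422 events (3880 primary), CTR 100 ps
#> pipeline counters:
#>          n_decays         n_photons         n_singles n_multiple_killed
#>           1999937           2800658            471417              8315
#>    n_coincidences n_energy_windowed      n_ssrb_nowin           n_final
#>             47819             36338              5851              4422

sensitivity(lm$counts[["n_ssrb_nowin"]], 7.4e7, 0.027)  # no energy windows
#> [1] 0.002928  (~0.29%)
sensitivity(lm$counts[["n_final"]], 7.4e7, 0.027)       # dual windows
#> [1] 0.002213  (~0.22%)
```

About 0.3% of decays end up as usable coincidences, dropping to ~0.2%
after the dual energy window — an order of magnitude above collimated
single-photon systems, which is the motivation for the modality.
Reconstructing a longer acquisition (~10^5 primary events) and measuring
the point-spread function:

```r
ev   <- lm$events[lm$events$primary, ]      # same-decay coincidences
grid <- image_grid(64, 64, pixel_size = 4.5)
rec  <- reconstruct(ev, grid, n_sweeps = 300, n_average = 100,
                    seed = 1, smooth_sd = 0.75)
psf_fwhm(rec$image, grid)
#> [1] 21.7   # mm at CTR 100 ps; ~28.5 at 150 ps, ~37.4 at 200 ps
```

The FWHM grows with the detector CTR — timing uncertainty spreads each
event's admissible positions along its hyperbola, and the reconstructed
spot widens accordingly.

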