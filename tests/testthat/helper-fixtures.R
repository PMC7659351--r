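# Shared fixtures: small geometries and quick simulated datasets.

biograph_like <- scanner_geometry()

tiny_ring <- function(n_modules = 4, crystals = 1, radius = 100) {
  scanner_geometry(ring_radius = radius, n_modules = n_modules,
                   crystals_per_module_transaxial = crystals,
                   crystals_per_module_axial = 2, n_block_rings = 1,
                   transaxial_fov = 1.2 * radius, axial_fov = 20,
                   ctr_fwhm_ps = 0)
}

# events with both detectors on the x axis (the two-focus textbook setup)
axis_event <- function(tdoa_ns, r = 424.5) {
  data.frame(x_a = r, y_a = 0, x_b = -r, y_b = 0, tdoa_ns = tdoa_ns)
}

# random coincidence events on the detector ring with physical TDOAs
random_ring_events <- function(n, r = 424.5, seed = 1) {
  set.seed(seed)
  th1 <- runif(n, 0, 2 * pi)
  th2 <- runif(n, 0, 2 * pi)
  same <- abs(th1 - th2) < 1e-3
  th2[same] <- th2[same] + 0.5
  x1 <- r * cos(th1); y1 <- r * sin(th1)
  x2 <- r * cos(th2); y2 <- r * sin(th2)
  dell <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
  tdoa <- runif(n, 0, 0.95) * dell / C_MM_NS
  data.frame(x_a = x1, y_a = y1, x_b = x2, y_b = y2, tdoa_ns = tdoa)
}

# small point-source acquisition shared across tests (cheap, one-time)
quick_point_lm <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- make_point_source(mci_to_bq(2))
      cache <<- simulate_acquisition(ph, biograph_like,
                                     duration_s = 3e5 / mci_to_bq(2),
                                     ctr_ps = 0, seed = 7)
    }
    cache
  }
})
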