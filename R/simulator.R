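# List-mode Monte Carlo simulator: cascade emission, analytic ray transport
# to the detector ring, detector response, coincidence sorting, dual energy
# windows and single-slice rebinning. Scatter, attenuation and photon
# interactions in the crystal are deliberately not modelled.

#' Emit cascade photon pairs from decay positions
#'
#' For each decay a cascade channel is selected by its probability (decays
#' selecting no channel yield no photons). Both photon directions are
#' i.i.d. uniform on the sphere (cascade angular correlation is neglected);
#' the first photon is emitted at the decay time and the second after an
#' exponential delay with mean `halflife_ps / log(2)`.
#'
#' @param decays data.frame with columns `x`, `y`, `z` (mm) and `t` (ns),
#'   e.g. from [sample_decay_positions()].
#' @param nuclide A [nuclide_model()].
#' @param seed Optional integer seed.
#' @return data.frame of photons (two rows per productive decay) with
#'   columns `decay_id` (1-based row index into `decays`), `photon`
#'   (1 or 2), `x`, `y`, `z`, `t_emit` (ns), `energy` (keV) and direction
#'   cosines `ux`, `uy`, `uz`.
#' @export
emit_cascade <- function(decays, nuclide, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(decays)
  ch <- nuclide$channels
  edges <- cumsum(ch$prob)
  u <- stats::runif(n)
  channel <- findInterval(u, c(0, edges), left.open = TRUE, rightmost.closed = FALSE)
  channel[u >= edges[length(edges)]] <- 0L   # unproductive decay
  keep <- which(channel > 0L)
  m <- length(keep)
  if (m == 0) {
    return(data.frame(decay_id = integer(0), photon = integer(0),
                      x = numeric(0), y = numeric(0), z = numeric(0),
                      t_emit = numeric(0), energy = numeric(0),
                      ux = numeric(0), uy = numeric(0), uz = numeric(0)))
  }
  chk <- channel[keep]
  hl <- ch$halflife_ps[chk]
  delay_ns <- ifelse(hl > 0, stats::rexp(m, rate = log(2)) * hl, 0) / 1000

  dir_sample <- function(k) {
    cz <- stats::runif(k, -1, 1)
    phi <- stats::runif(k, 0, 2 * pi)
    s <- sqrt(pmax(0, 1 - cz^2))
    cbind(ux = s * cos(phi), uy = s * sin(phi), uz = cz)
  }
  d1 <- dir_sample(m)
  d2 <- dir_sample(m)

  data.frame(
    decay_id = rep(keep, 2L),
    photon = rep(c(1L, 2L), each = m),
    x = rep(decays$x[keep], 2L),
    y = rep(decays$y[keep], 2L),
    z = rep(decays$z[keep], 2L),
    t_emit = c(decays$t[keep], decays$t[keep] + delay_ns),
    energy = c(ch$e1_keV[chk], ch$e2_keV[chk]),
    ux = c(d1[, "ux"], d2[, "ux"]),
    uy = c(d1[, "uy"], d2[, "uy"]),
    uz = c(d1[, "uz"], d2[, "uz"])
  )
}

#' Propagate photons to the detector ring
#'
#' Analytic ray-cylinder transport: each photon flies along its direction
#' from the emission point to the forward intersection with the detector
#' cylinder. The hit is assigned to the crystal whose angular/axial bin
#' contains the intersection (hit position = crystal front-face center; no
#' depth of interaction), the timestamp is `t_emit + path / c`, and the
#' photon survives detection with probability
#' `geometry$detection_efficiency`. Photons whose intersection falls
#' outside the axial crystal coverage are lost.
#'
#' @param photons data.frame as returned by [emit_cascade()].
#' @param geometry A [scanner_geometry()].
#' @param seed Optional integer seed.
#' @return data.frame of detected singles: `decay_id`, `photon`,
#'   `crystal_id`, `ring_index`, `x`, `y` (crystal front-face center, mm),
#'   `energy_true` (keV), `t_true` (ns).
#' @export
propagate_to_ring <- function(photons, geometry, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  R <- geometry$ring_radius
  if (any(photons$x^2 + photons$y^2 >= R^2))
    stop("emission point outside the detector ring")
  # |p + u d|^2 = R^2, transaxial components only
  a <- photons$ux^2 + photons$uy^2
  b <- photons$x * photons$ux + photons$y * photons$uy
  cc <- photons$x^2 + photons$y^2 - R^2
  ok <- a > 0
  u <- rep(NA_real_, nrow(photons))
  u[ok] <- (-b[ok] + sqrt(b[ok]^2 - a[ok] * cc[ok])) / a[ok]
  z_hit <- photons$z + u * photons$uz
  ring <- crystal_ring_index(geometry, z_hit)
  hit <- ok & !is.na(ring)
  hit[hit] <- stats::runif(sum(hit)) < geometry$detection_efficiency
  idx <- which(hit)
  if (length(idx) == 0) {
    return(data.frame(decay_id = integer(0), photon = integer(0),
                      crystal_id = integer(0), ring_index = integer(0),
                      x = numeric(0), y = numeric(0),
                      energy_true = numeric(0), t_true = numeric(0)))
  }
  xh <- photons$x[idx] + u[idx] * photons$ux[idx]
  yh <- photons$y[idx] + u[idx] * photons$uy[idx]
  ang <- atan2(yh, xh)
  ang[ang < 0] <- ang[ang < 0] + 2 * pi
  ti <- crystal_trans_index(geometry, ang)
  ri <- ring[idx]
  # 3D path length: u is the transaxial parameter of a unit-norm direction,
  # so u is already the full path length in mm.
  path <- u[idx]
  cang <- 2 * pi * ti / geometry$n_crystals_transaxial
  data.frame(
    decay_id = photons$decay_id[idx],
    photon = photons$photon[idx],
    crystal_id = ri * geometry$n_crystals_transaxial + ti,
    ring_index = ri,
    x = R * cos(cang),
    y = R * sin(cang),
    energy_true = photons$energy[idx],
    t_true = photons$t_emit[idx] + path / C_MM_NS
  )
}

#' Draw per-crystal energy resolutions
#'
#' Each crystal's fractional energy resolution (FWHM/E at 511 keV) is
#' drawn once, uniformly over `geometry$energy_resolution_range`, and then
#' held fixed for the whole acquisition.
#'
#' @param geometry A [scanner_geometry()].
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n_crystals_transaxial * n_axial_rings`,
#'   indexed by `crystal_id + 1`.
#' @export
draw_crystal_resolutions <- function(geometry, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- geometry$n_crystals_transaxial * geometry$n_axial_rings
  stats::runif(n, geometry$energy_resolution_range[1],
               geometry$energy_resolution_range[2])
}

FWHM_TO_SD <- 1 / (2 * sqrt(2 * log(2)))

#' Apply detector energy and timing response
#'
#' Energies are blurred by a Gaussian whose FWHM is `R_c(E) * E` with
#' `R_c(E) = R_c(511) * sqrt(511 / E)` and `R_c(511)` the crystal's fixed
#' resolution; negative blurred energies are redrawn (truncation at 0).
#' Timestamps are blurred by a Gaussian with
#' `sd = ctr_fwhm / (2 sqrt(2 log 2) * sqrt(2))`, so the *difference* of
#' two independent singles has FWHM equal to the coincidence time
#' resolution. `ctr_ps = 0` leaves timestamps unchanged.
#'
#' @param singles data.frame from [propagate_to_ring()].
#' @param geometry A [scanner_geometry()].
#' @param r511 Per-crystal resolutions from [draw_crystal_resolutions()];
#'   drawn on the fly when NULL.
#' @param ctr_ps Coincidence time resolution FWHM in ps (default: the
#'   geometry's `ctr_fwhm_ps`).
#' @param seed Optional integer seed.
#' @return `singles` with added columns `energy_keV` (blurred) and `t_ns`
#'   (blurred timestamp).
#' @export
apply_detector_response <- function(singles, geometry, r511 = NULL,
                                    ctr_ps = NULL, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(r511)) r511 <- draw_crystal_resolutions(geometry)
  if (is.null(ctr_ps)) ctr_ps <- geometry$ctr_fwhm_ps
  n <- nrow(singles)
  rc <- r511[singles$crystal_id + 1L] * sqrt(511 / singles$energy_true)
  sd_e <- rc * singles$energy_true * FWHM_TO_SD
  e <- singles$energy_true + stats::rnorm(n, 0, 1) * sd_e
  bad <- which(e <= 0)
  while (length(bad) > 0) {
    e[bad] <- singles$energy_true[bad] + stats::rnorm(length(bad), 0, 1) * sd_e[bad]
    bad <- bad[e[bad] <= 0]
  }
  singles$energy_keV <- e
  if (ctr_ps > 0) {
    sd_t <- ctr_ps / 1000 * FWHM_TO_SD / sqrt(2)
    singles$t_ns <- singles$t_true + stats::rnorm(n, 0, sd_t)
  } else {
    singles$t_ns <- singles$t_true
  }
  singles
}

#' Sort a singles stream into coincidence events
#'
#' Singles are grouped into clusters separated by gaps larger than the
#' coincidence window; a cluster of exactly two singles becomes one event
#' (hit `a` = earlier), clusters of three or more are discarded entirely
#' (multiple-coincidence kill), and isolated singles are dropped. Events
#' whose two hits land in the same crystal are discarded.
#'
#' @param singles data.frame with at least `t_ns` and `crystal_id`,
#'   sorted by `t_ns`.
#' @param window_ns Coincidence time window (ns).
#' @return List with `events` (data.frame, one row per coincidence, with
#'   `_a`/`_b` suffixed hit columns and `tdoa_ns = t_b - t_a >= 0`) and
#'   counters `n_singles`, `n_multiple_killed` (singles lost to clusters
#'   of >= 3).
#' @export
sort_coincidences <- function(singles, window_ns = 2) {
  t <- singles$t_ns
  if (is.unsorted(t)) stop("singles must be sorted by timestamp")
  n <- length(t)
  counters <- c(n_singles = n, n_multiple_killed = 0)
  if (n < 2) return(list(events = coincidence_events(singles, integer(0), integer(0)),
                         counters = counters))
  new_cluster <- c(TRUE, diff(t) > window_ns)
  cl <- cumsum(new_cluster)
  size <- tabulate(cl)
  counters["n_multiple_killed"] <- sum(size[size > 2])
  first <- which(new_cluster)
  pair_cl <- which(size == 2L)
  ia <- first[pair_cl]
  ib <- ia + 1L
  keep <- singles$crystal_id[ia] != singles$crystal_id[ib]
  list(events = coincidence_events(singles, ia[keep], ib[keep]),
       counters = counters)
}

# Assemble the per-event table from paired single indices.
coincidence_events <- function(singles, ia, ib) {
  df <- data.frame(
    crystal_a = singles$crystal_id[ia], crystal_b = singles$crystal_id[ib],
    ring_a = singles$ring_index[ia], ring_b = singles$ring_index[ib],
    x_a = singles$x[ia], y_a = singles$y[ia],
    x_b = singles$x[ib], y_b = singles$y[ib],
    energy_a_keV = singles$energy_keV[ia], energy_b_keV = singles$energy_keV[ib],
    t_a_ns = singles$t_ns[ia], t_b_ns = singles$t_ns[ib]
  )
  df$tdoa_ns <- df$t_b_ns - df$t_a_ns
  if (!is.null(singles$decay_id)) {
    df$decay_a <- singles$decay_id[ia]
    df$decay_b <- singles$decay_id[ib]
    df$primary <- df$decay_a == df$decay_b
  }
  df
}

#' Dual energy window filter
#'
#' Accepts an event iff exactly one hit's energy falls in the low window
#' and the other's in the high window (bounds inclusive).
#'
#' @param events Coincidence event data.frame.
#' @param low,high Length-2 numeric windows in keV.
#' @return Logical vector of acceptances.
#' @export
energy_window_accept <- function(events, low = c(108, 164), high = c(211, 318)) {
  in_lo_a <- events$energy_a_keV >= low[1] & events$energy_a_keV <= low[2]
  in_hi_a <- events$energy_a_keV >= high[1] & events$energy_a_keV <= high[2]
  in_lo_b <- events$energy_b_keV >= low[1] & events$energy_b_keV <= low[2]
  in_hi_b <- events$energy_b_keV >= high[1] & events$energy_b_keV <= high[2]
  (in_lo_a & in_hi_b) | (in_hi_a & in_lo_b)
}

#' Single-slice rebinning
#'
#' Assigns each event to the 2D transverse slice at the mean of its two
#' axial ring indices (round-half-to-even); events with ring difference
#' larger than `max_ring_difference` are rejected (slice = NA).
#'
#' @param events Coincidence event data.frame with `ring_a`, `ring_b`.
#' @param max_ring_difference Maximum |ring_a - ring_b|.
#' @return Integer vector of slice indices, NA where rejected.
#' @export
ssrb_slice <- function(events, max_ring_difference = 2) {
  slice <- as.integer(round((events$ring_a + events$ring_b) / 2))
  slice[abs(events$ring_a - events$ring_b) > max_ring_difference] <- NA_integer_
  slice
}

# Fused emission + transport + response for one chunk, avoiding the
# per-stage data.frame allocations of the modular operations (the staged
# and fused paths are statistically identical; a test compares them).
# Returns a data.frame of detected singles sorted by blurred timestamp.
sim_chunk_singles <- function(decays, nuclide, geometry, r511, ctr_ps,
                              backend = "cpp") {
  if (backend == "cpp") {
    ch <- nuclide$channels
    res <- cpp_sim_chunk(decays$x, decays$y, decays$z, decays$t,
                         ch$e1_keV, ch$e2_keV, ch$halflife_ps,
                         cumsum(ch$prob), geometry$ring_radius,
                         geometry$detection_efficiency,
                         geometry$n_crystals_transaxial,
                         geometry$n_axial_rings,
                         geometry$crystal_pitch_axial, r511, ctr_ps)
    n_photons <- res$n_photons
    res$n_photons <- NULL
    singles <- structure(res, class = "data.frame",
                         row.names = seq_along(res$decay_id))
    if (nrow(singles) == 0) return(NULL)
    attr(singles, "n_photons") <- n_photons
    return(singles)
  }
  n <- length(decays$x)
  ch <- nuclide$channels
  edges <- cumsum(ch$prob)
  u <- stats::runif(n)
  channel <- findInterval(u, c(0, edges), left.open = TRUE)
  channel[u >= edges[length(edges)]] <- 0L
  keep <- which(channel > 0L)
  if (length(keep) == 0) return(NULL)
  chk <- channel[keep]
  m <- length(keep)
  hl <- ch$halflife_ps[chk]
  delay_ns <- numeric(m)
  pos_hl <- hl > 0
  delay_ns[pos_hl] <- stats::rexp(sum(pos_hl), rate = log(2)) * hl[pos_hl] / 1000

  R <- geometry$ring_radius
  eff <- geometry$detection_efficiency
  n_t <- geometry$n_crystals_transaxial
  out <- vector("list", 2L)
  for (ph in 1:2) {
    cz <- stats::runif(m, -1, 1)
    phi <- stats::runif(m, 0, 2 * pi)
    s <- sqrt(1 - cz * cz)
    ux <- s * cos(phi); uy <- s * sin(phi)
    x <- decays$x[keep]; y <- decays$y[keep]
    a <- ux * ux + uy * uy
    b <- x * ux + y * uy
    cc <- x * x + y * y - R * R
    u_par <- (-b + sqrt(b * b - a * cc)) / a      # a > 0 a.s.
    z_hit <- decays$z[keep] + u_par * cz
    ring <- crystal_ring_index(geometry, z_hit)
    hit <- which(!is.na(ring))
    hit <- hit[stats::runif(length(hit)) < eff]
    if (length(hit) == 0) { out[[ph]] <- NULL; next }
    ang <- atan2(y[hit] + u_par[hit] * uy[hit], x[hit] + u_par[hit] * ux[hit])
    ang[ang < 0] <- ang[ang < 0] + 2 * pi
    ti <- crystal_trans_index(geometry, ang)
    energy <- if (ph == 1) ch$e1_keV[chk[hit]] else ch$e2_keV[chk[hit]]
    t_emit <- decays$t[keep][hit] + if (ph == 1) 0 else delay_ns[hit]
    out[[ph]] <- list(
      decay_id = keep[hit],
      crystal_id = ring[hit] * n_t + ti,
      ring_index = ring[hit],
      x = R * cos(2 * pi * ti / n_t),
      y = R * sin(2 * pi * ti / n_t),
      energy_true = energy,
      t_true = t_emit + u_par[hit] / C_MM_NS
    )
  }
  parts <- out[!vapply(out, is.null, TRUE)]
  if (length(parts) == 0) return(NULL)
  singles <- data.frame(
    decay_id = unlist(lapply(parts, `[[`, "decay_id")),
    crystal_id = unlist(lapply(parts, `[[`, "crystal_id")),
    ring_index = unlist(lapply(parts, `[[`, "ring_index")),
    x = unlist(lapply(parts, `[[`, "x")),
    y = unlist(lapply(parts, `[[`, "y")),
    energy_true = unlist(lapply(parts, `[[`, "energy_true")),
    t_true = unlist(lapply(parts, `[[`, "t_true"))
  )
  singles <- apply_detector_response(singles, geometry, r511 = r511,
                                     ctr_ps = ctr_ps)
  singles <- singles[order(singles$t_ns, method = "radix"), ]
  attr(singles, "n_photons") <- 2L * m
  singles
}

#' Simulate a full list-mode acquisition
#'
#' Runs the whole pipeline (decay sampling, cascade emission, ray
#' transport, detector response, coincidence sorting, optional dual energy
#' windows, single-slice rebinning) in time-slice chunks. The number of
#' decays is Poisson with mean `activity x duration`. The returned events
#' carry truth columns (`true_x/y/z`, the decay position of the earlier
#' hit, and `primary`, TRUE when both hits come from the same decay) for
#' validation; reconstruction-facing exports strip them.
#'
#' @param phantom An [activity_phantom()].
#' @param geometry A [scanner_geometry()].
#' @param nuclide A [nuclide_model()].
#' @param duration_s Acquisition duration in seconds.
#' @param ctr_ps CTR FWHM (ps); default from `geometry`.
#' @param seed Integer seed (controls the whole acquisition).
#' @param energy_windows Apply the dual energy window to the stored events
#'   (counts for both choices are always logged).
#' @param low_window,high_window Energy windows in keV.
#' @param window_ns Coincidence time window (ns).
#' @param max_ring_difference Single-slice rebinning limit.
#' @param z_band Axial decay sampling band half-width (mm); default
#'   `2.5 x crystal_pitch_axial` (NULL for the full phantom length).
#' @param chunk_decays Decays per processing chunk.
#' @param backend "cpp" (compiled fused kernel, default) or "r" (the
#'   staged vectorized R path); the two are statistically identical.
#' @return Object of class `listmode`: list with `events` (data.frame),
#'   `counts` (named vector of pipeline counters), `meta`.
#' @export
simulate_acquisition <- function(phantom, geometry, nuclide = se75_nuclide(),
                                 duration_s, ctr_ps = NULL, seed = NULL,
                                 energy_windows = TRUE,
                                 low_window = c(108, 164),
                                 high_window = c(211, 318),
                                 window_ns = 2, max_ring_difference = 2,
                                 z_band = 2.5 * geometry$crystal_pitch_axial,
                                 chunk_decays = 4e6, backend = c("cpp", "r")) {
  backend <- match.arg(backend)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(ctr_ps)) ctr_ps <- geometry$ctr_fwhm_ps
  activity <- phantom$total_activity_bq
  live <- phantom$primitives$activity > 0
  if (max(sqrt(phantom$primitives$x[live]^2 + phantom$primitives$y[live]^2) +
            phantom$primitives$diameter[live] / 2) >= geometry$ring_radius)
    stop("phantom extends outside the detector ring")
  n_decays <- if (duration_s > 0) stats::rpois(1, activity * duration_s) else 0L
  r511 <- draw_crystal_resolutions(geometry)

  counts <- c(n_decays = n_decays, n_photons = 0, n_singles = 0,
              n_multiple_killed = 0, n_coincidences = 0,
              n_energy_windowed = 0, n_ssrb_nowin = 0, n_final = 0,
              n_primary_final = 0)
  chunks <- list()
  n_chunks <- max(1L, as.integer(ceiling(n_decays / chunk_decays)))
  # partition the Poisson process into equal time slices
  per_chunk <- if (n_decays > 0)
    as.vector(stats::rmultinom(1, n_decays, rep(1 / n_chunks, n_chunks)))
  else integer(0)
  t_edges <- seq(0, duration_s, length.out = n_chunks + 1)

  for (ci in seq_along(per_chunk)) {
    nc <- per_chunk[ci]
    if (nc == 0) next
    decays <- sample_decay_positions(phantom, nc,
                                     duration_s = t_edges[ci + 1] - t_edges[ci],
                                     z_band = z_band)
    decays$t <- decays$t + t_edges[ci] * 1e9
    singles <- sim_chunk_singles(decays, nuclide, geometry, r511, ctr_ps,
                                 backend = backend)
    if (is.null(singles) || nrow(singles) == 0) next
    counts["n_photons"] <- counts["n_photons"] + attr(singles, "n_photons")
    sorted <- sort_coincidences(singles, window_ns = window_ns)
    counts["n_singles"] <- counts["n_singles"] + sorted$counters["n_singles"]
    counts["n_multiple_killed"] <- counts["n_multiple_killed"] +
      sorted$counters["n_multiple_killed"]
    ev <- sorted$events
    counts["n_coincidences"] <- counts["n_coincidences"] + nrow(ev)
    if (nrow(ev) == 0) next
    ev$slice <- ssrb_slice(ev, max_ring_difference)
    win <- energy_window_accept(ev, low_window, high_window)
    counts["n_energy_windowed"] <- counts["n_energy_windowed"] + sum(win)
    counts["n_ssrb_nowin"] <- counts["n_ssrb_nowin"] + sum(!is.na(ev$slice))
    keep <- !is.na(ev$slice) & (if (energy_windows) win else TRUE)
    ev <- ev[keep, ]
    counts["n_final"] <- counts["n_final"] + nrow(ev)
    counts["n_primary_final"] <- counts["n_primary_final"] + sum(ev$primary)
    if (nrow(ev) > 0) {
      # truth position: decay of the earlier hit
      ev$true_x <- decays$x[ev$decay_a]
      ev$true_y <- decays$y[ev$decay_a]
      ev$true_z <- decays$z[ev$decay_a]
      chunks[[length(chunks) + 1L]] <- ev
    }
  }
  events <- if (length(chunks) > 0) do.call(rbind, chunks) else
    cbind(coincidence_events(data.frame(t_ns = numeric(0), crystal_id = integer(0),
                                        ring_index = integer(0), x = numeric(0),
                                        y = numeric(0), energy_keV = numeric(0),
                                        decay_id = integer(0)),
                             integer(0), integer(0)),
          slice = integer(0), true_x = numeric(0), true_y = numeric(0),
          true_z = numeric(0))
  rownames(events) <- NULL
  events$event_id <- seq_len(nrow(events))
  structure(list(
    events = events,
    counts = counts,
    meta = list(seed = seed, ctr_ps = ctr_ps, duration_s = duration_s,
                activity_bq = activity, energy_windows = energy_windows,
                low_window = low_window, high_window = high_window,
                window_ns = window_ns, max_ring_difference = max_ring_difference,
                z_band = z_band,
                geometry_hash = fnv1a_hash(geometry))
  ), class = "listmode")
}

#' @export
print.listmode <- function(x, ...) {
  cat(sprintf("List-mode acquisition: %d events (%d primary), CTR %.0f ps\n",
              nrow(x$events), sum(x$events$primary), x$meta$ctr_ps))
  cat("pipeline counters:\n")
  print(x$counts)
  invisible(x)
}

#' Coincidence sensitivity
#'
#' Detected coincidence events per decay: `n_events / (activity x duration)`.
#'
#' @param n_events Number of coincidence events.
#' @param activity_bq Source activity in Bq.
#' @param duration_s Acquisition duration in s.
#' @return Sensitivity as a fraction.
#' @export
sensitivity <- function(n_events, activity_bq, duration_s) {
  stopifnot(activity_bq > 0, duration_s > 0)
  n_events / (activity_bq * duration_s)
}

# djb2-style rolling hash of a deparsed R object, as a provenance tag.
fnv1a_hash <- function(obj) {
  bytes <- utf8ToInt(paste(deparse(obj), collapse = ""))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}
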