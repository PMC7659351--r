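# Stochastic origin ensemble reconstruction: list-mode Markov chain Monte
# Carlo. Each event holds one candidate origin voxel on its hyperbolic
# response curve; origins are moved by Metropolis-Hastings on the global
# event-density image, and the reconstructed image is the average density
# over the post-burn-in sweeps.

#' Metropolis acceptance probability for an origin move
#'
#' Probability of moving an event from its current voxel (event-density
#' count `c_i`, *including the event itself*, so `c_i >= 1`) to a proposed
#' voxel with count `c_iprime`:
#' `A = min(1, c_i^c_i (c_iprime+1)^(c_iprime+1) / ((c_i+1)^(c_i+1) c_iprime^c_iprime))`
#' with the convention `0^0 = 1`, evaluated in log space. The origin
#' probability and per-voxel sensitivity factors that generalize this
#' ratio are fixed at 1 here. Proposing the current voxel itself is always
#' accepted.
#'
#' @param c_i Count at the current voxel (>= 1), vectorized.
#' @param c_iprime Count at the proposed voxel (>= 0), vectorized.
#' @return Acceptance probabilities in (0, 1].
#' @export
acceptance_probability <- function(c_i, c_iprime) {
  if (any(c_i < 1)) stop("state corruption: c_i must be >= 1")
  if (any(c_iprime < 0)) stop("c_iprime must be >= 0")
  xlx <- function(n) ifelse(n > 0, n * log(n), 0)
  logA <- xlx(c_i) + xlx(c_iprime + 1) - xlx(c_i + 1) - xlx(c_iprime)
  pmin(1, exp(logA))
}

#' Initialize an origin ensemble
#'
#' Draws each event's starting origin uniformly from its candidate set and
#' tallies the event-density image.
#'
#' @param cand Candidate sets from [enumerate_candidates()] (all events
#'   must have non-empty sets; drop empty ones upstream).
#' @param grid An [image_grid()].
#' @param seed Optional integer seed.
#' @return Object of class `origin_ensemble`: list with `origins`
#'   (per-event 0-based voxel index), `density` (integer vector, length
#'   `nx * ny`), `cand`, `grid`, `n_events`, `sweeps_done`.
#' @export
soe_initialize <- function(cand, grid, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  len <- diff(cand$offsets)
  if (any(len == 0))
    stop("empty candidate set: such events must be dropped before initialization")
  n <- length(len)
  pick <- cand$offsets[-length(cand$offsets)] +
    pmin(len - 1L, as.integer(stats::runif(n) * len))
  origins <- cand$voxels[pick + 1L]
  density <- integer(grid$nx * grid$ny)
  tab <- tabulate(origins + 1L, nbins = grid$nx * grid$ny)
  density <- as.integer(tab)
  structure(list(origins = origins, density = density, cand = cand,
                 grid = grid, n_events = n, sweeps_done = 0L),
            class = "origin_ensemble")
}

#' Run one sweep of the origin ensemble chain
#'
#' One sweep is `N` proposal steps (`N` = number of events): each step
#' picks an event uniformly at random, proposes a uniform draw from its
#' candidate set and accepts with [acceptance_probability()]. The total
#' event count is conserved by every step.
#'
#' @param ensemble An `origin_ensemble` from [soe_initialize()].
#' @param n_sweeps Number of sweeps to run.
#' @return The updated ensemble, with `last_accept_rate` set.
#' @export
soe_sweep <- function(ensemble, n_sweeps = 1L) {
  n_steps <- ensemble$n_events * n_sweeps
  res <- cpp_soe_steps(ensemble$cand$voxels, ensemble$cand$offsets,
                       ensemble$origins, ensemble$density, n_steps)
  ensemble$origins <- res$assign
  ensemble$density <- res$density
  ensemble$sweeps_done <- ensemble$sweeps_done + n_sweeps
  ensemble$last_accept_rate <- res$n_accepted / max(1, n_steps)
  ensemble
}

#' Reconstruct an image from list-mode events
#'
#' Full stochastic origin ensemble reconstruction: builds the hyperbolic
#' response curve of every event, enumerates candidate voxels inside the
#' FOV, initializes origins uniformly on the curves, runs `n_sweeps`
#' Metropolis sweeps and averages the event-density image over the final
#' `n_average` sweeps (running mean). Events whose curve misses the FOV
#' are dropped and counted.
#'
#' @param events Coincidence event data.frame (needs `x_a`, `y_a`, `x_b`,
#'   `y_b`, `tdoa_ns`), or a `listmode` object (its `events` are used).
#' @param grid An [image_grid()].
#' @param n_sweeps Total sweeps (default 1500).
#' @param n_average Number of final sweeps averaged into the image
#'   (default 300).
#' @param seed Optional integer seed for initialization + chain.
#' @param smooth_sd Gaussian post-smoothing SD in pixels (0 = none).
#' @param record_trace Keep per-sweep density snapshots (matrix
#'   `n_sweeps x n_voxels`) for convergence diagnostics.
#' @param step Curve-marching step in mm (see [enumerate_candidates()]).
#' @return Object of class `soe_result`: `image` (nx x ny matrix, the OE
#'   average, post-smoothed when requested), `oe_average` (unsmoothed),
#'   `accept_rate` (per sweep), `n_events`, `n_dropped`, `trace`
#'   (optional), `grid`, `config`.
#' @export
reconstruct <- function(events, grid, n_sweeps = 1500L, n_average = 300L,
                        seed = NULL, smooth_sd = 0, record_trace = FALSE,
                        step = grid$pixel_size / 2) {
  if (inherits(events, "listmode")) events <- events$events
  if (nrow(events) == 0) stop("no events to reconstruct")
  if (n_average > n_sweeps) stop("n_average must be <= n_sweeps")
  if (!is.null(seed)) set.seed(seed)

  hyp <- hyperbolas_from_events(events)
  cand <- enumerate_candidates(hyp, grid, step = step)
  if (cand$n_dropped > 0) {
    keep_off <- which(cand$keep)
    # rebuild flattened candidate arrays without the dropped events
    len <- diff(cand$offsets)
    idx <- sequence(len[keep_off]) +
      rep(cand$offsets[keep_off], len[keep_off])
    cand <- list(voxels = cand$voxels[idx],
                 offsets = c(0L, cumsum(len[keep_off])),
                 keep = rep(TRUE, length(keep_off)),
                 n_dropped = cand$n_dropped)
  }
  n_events <- length(cand$offsets) - 1L

  res <- cpp_soe_chain(cand$voxels, cand$offsets, grid$nx * grid$ny,
                       as.integer(n_sweeps), as.integer(n_average),
                       record_trace)
  oe <- matrix(res$oe_average, nrow = grid$nx, ncol = grid$ny)
  img <- if (smooth_sd > 0) post_smooth(oe, smooth_sd) else oe
  structure(list(
    image = img,
    oe_average = oe,
    accept_rate = res$accept_rate,
    n_events = n_events,
    n_dropped = cand$n_dropped,
    trace = if (record_trace) res$trace else NULL,
    final_density = matrix(res$density, nrow = grid$nx, ncol = grid$ny),
    grid = grid,
    config = list(n_sweeps = n_sweeps, n_average = n_average, seed = seed,
                  smooth_sd = smooth_sd, step = step)
  ), class = "soe_result")
}

#' @export
print.soe_result <- function(x, ...) {
  cat(sprintf("SOE reconstruction: %d events (%d dropped), %d sweeps (avg of last %d)\n",
              x$n_events, x$n_dropped, x$config$n_sweeps, x$config$n_average))
  cat(sprintf("  grid %d x %d @ %.2f mm; mean acceptance %.3f\n",
              x$grid$nx, x$grid$ny, x$grid$pixel_size, mean(x$accept_rate)))
  invisible(x)
}

#' Gaussian post-smoothing
#'
#' Separable Gaussian convolution with the SD given in pixel units. The
#' kernel is renormalized at the image boundary so that the total count is
#' preserved.
#'
#' @param image 2D numeric matrix.
#' @param sd_pixels Gaussian SD in pixels (0 returns the input unchanged).
#' @return Smoothed matrix of the same dimensions.
#' @export
post_smooth <- function(image, sd_pixels = 0.75) {
  if (sd_pixels <= 0) return(image)
  r <- max(1L, ceiling(4 * sd_pixels))
  k <- stats::dnorm(seq(-r, r), sd = sd_pixels)
  k <- k / sum(k)
  smooth_1d <- function(m) {
    # Convolve columns of m with k. Each *input* pixel redistributes its
    # full mass over the in-bounds part of its kernel (the truncated
    # kernel is renormalized on the source side), so totals are preserved
    # exactly, including at the boundary.
    n <- nrow(m)
    weight <- numeric(n)
    for (j in seq_along(k)) {
      off <- j - r - 1L
      ok <- seq_len(n) + off >= 1 & seq_len(n) + off <= n
      weight[ok] <- weight[ok] + k[j]
    }
    mn <- m / weight
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + k[j] * mn[src[ok], ]
    }
    out
  }
  t(smooth_1d(t(smooth_1d(image))))
}
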