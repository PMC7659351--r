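# Hyperbola-of-response model: each coincidence event constrains its
# origin to one branch of a hyperbola whose foci are the two detectors,
# with focal distance difference v * TDOA; the physical branch is the one
# nearer the detector that fired first.

#' Hyperbola parameters for coincidence events
#'
#' Computes, for each event, the semi-major axis `a = v * TDOA / 2`, the
#' focal separation `delta_ell` (distance between the two 2D hit
#' positions), the semi-minor axis `b = sqrt(delta_ell^2/4 - a^2)`, the
#' center (midpoint of the foci) and the unit vector `u` pointing from
#' the center toward the early focus. Events whose measured
#' `v * TDOA` exceeds `delta_ell` (possible under timing blur) are
#' geometrically impossible; by default their `a` is clamped to
#' `delta_ell/2 * (1 - 1e-9)`, degenerating the branch toward the ray
#' beyond the early detector, and flagged in `clamped`.
#'
#' @param events Coincidence event data.frame with columns `x_a`, `y_a`,
#'   `x_b`, `y_b` and `tdoa_ns` (hit `a` earlier).
#' @param v Speed of light in mm/ns.
#' @param clamp_invalid Clamp unphysical events (default) instead of
#'   flagging them for dropping.
#' @return data.frame with columns `ex`, `ey` (early focus), `lx`, `ly`
#'   (late focus), `cx`, `cy`, `ux`, `uy`, `a`, `b`, `delta_ell`,
#'   `clamped`, `valid`.
#' @export
hyperbolas_from_events <- function(events, v = C_MM_NS, clamp_invalid = TRUE) {
  if (any(events$tdoa_ns < 0)) stop("tdoa_ns must be >= 0 (hit a is earlier)")
  ex <- events$x_a; ey <- events$y_a
  lx <- events$x_b; ly <- events$y_b
  dx <- lx - ex; dy <- ly - ey
  delta_ell <- sqrt(dx^2 + dy^2)
  a <- v * events$tdoa_ns / 2
  clamped <- 2 * a > delta_ell
  valid <- rep(TRUE, length(a))
  if (clamp_invalid) {
    a[clamped] <- delta_ell[clamped] / 2 * (1 - 1e-9)
  } else {
    valid <- !clamped
  }
  b <- sqrt(pmax(0, delta_ell^2 / 4 - a^2))
  cx <- (ex + lx) / 2; cy <- (ey + ly) / 2
  ux <- (ex - cx) / (delta_ell / 2)
  uy <- (ey - cy) / (delta_ell / 2)
  data.frame(ex = ex, ey = ey, lx = lx, ly = ly, cx = cx, cy = cy,
             ux = ux, uy = uy, a = a, b = b, delta_ell = delta_ell,
             clamped = clamped, valid = valid)
}

#' Hyperbola response for a single event
#'
#' @param event One-row event data.frame (see [hyperbolas_from_events()]).
#' @inheritParams hyperbolas_from_events
#' @return Object of class `hyperbola` (one-row parameter list).
#' @export
hyperbola_from_event <- function(event, v = C_MM_NS, clamp_invalid = TRUE) {
  h <- hyperbolas_from_events(event[1, , drop = FALSE], v = v,
                              clamp_invalid = clamp_invalid)
  structure(as.list(h), class = "hyperbola")
}

#' Evaluate a point on the physical branch of a hyperbola
#'
#' Canonical parameterization `(a cosh t, b sinh t)` of the branch nearer
#' the early focus, rotated and translated into world coordinates:
#' `p(t) = center + u * a * cosh(t) + u_perp * b * sinh(t)` with
#' `u_perp = (-uy, ux)`. Every returned point satisfies
#' `dist(p, late focus) - dist(p, early focus) = 2 a`.
#'
#' @param h A `hyperbola` from [hyperbola_from_event()].
#' @param t Curve parameter, vectorized.
#' @return data.frame with world coordinates `x`, `y`.
#' @export
point_on_branch <- function(h, t) {
  ch <- cosh(t); sh <- sinh(t)
  data.frame(x = h$cx + h$ux * h$a * ch - h$uy * h$b * sh,
             y = h$cy + h$uy * h$a * ch + h$ux * h$b * sh)
}

#' Enumerate candidate origin voxels for events
#'
#' Rasterizes each event's hyperbolic response branch (or, for
#' `TDOA = 0`, the perpendicular bisector chord) onto the image grid and
#' returns, per event, the ordered unique pixels crossed by the curve
#' inside the circular FOV mask. The curve is marched adaptively in arc
#' length and each polyline segment is traversed exactly
#' (Amanatides-Woo), so the candidate set is stable under step
#' refinement. Events whose curve misses the FOV entirely are dropped
#' (counted in `n_dropped`).
#'
#' @param hyp data.frame from [hyperbolas_from_events()].
#' @param grid An [image_grid()].
#' @param step Marching step in mm (default `pixel_size / 2`).
#' @return List with `voxels` (integer vector of 0-based linear pixel
#'   indices `ix + iy * nx`, concatenated over events), `offsets`
#'   (0-based, length `n_events + 1`), `keep` (logical: event has a
#'   non-empty candidate set) and `n_dropped`.
#' @export
enumerate_candidates <- function(hyp, grid, step = grid$pixel_size / 2) {
  res <- cpp_enumerate_candidates(
    hyp$cx, hyp$cy, hyp$ux, hyp$uy, hyp$a, hyp$b,
    grid$nx, grid$ny, grid$pixel_size, grid$x0, grid$y0,
    grid$center[1], grid$center[2], grid$fov_radius, step)
  len <- diff(res$offsets)
  res$keep <- len > 0
  res$n_dropped <- sum(!res$keep)
  res
}

#' Candidate voxels of one event as pixel indices
#'
#' Convenience accessor over [enumerate_candidates()] output.
#'
#' @param cand Result of [enumerate_candidates()].
#' @param k Event number (1-based).
#' @return Integer vector of 0-based linear pixel indices.
#' @export
candidate_voxels <- function(cand, k) {
  cand$voxels[(cand$offsets[k] + 1L):cand$offsets[k + 1L]][
    seq_len(cand$offsets[k + 1L] - cand$offsets[k])]
}
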