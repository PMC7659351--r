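# Activity phantoms and decay-position sampling.

#' Build an activity phantom from primitives
#'
#' A phantom is an ordered list of primitives (cylinders/rods, plus a
#' degenerate `point` shape). Where primitives overlap, *later entries
#' override earlier ones*, so hot or cold rods are punched into a
#' background cylinder by listing them after it.
#'
#' @param primitives data.frame with columns `shape` ("cylinder", "rod" or
#'   "point"), `x`, `y` (center, mm), `diameter` (mm), `length_z` (mm) and
#'   `activity` (relative activity concentration, >= 0).
#' @param total_activity_bq Total activity of the phantom in Bq.
#' @return An object of class `activity_phantom`.
#' @export
activity_phantom <- function(primitives, total_activity_bq) {
  stopifnot(is.data.frame(primitives),
            all(c("shape", "x", "y", "diameter", "length_z", "activity") %in%
                  names(primitives)))
  if (total_activity_bq <= 0) stop("total_activity_bq must be > 0")
  if (any(primitives$activity < 0)) stop("relative activities must be >= 0")
  if (!any(primitives$activity > 0))
    stop("phantom needs at least one primitive with activity > 0")
  structure(list(primitives = primitives,
                 total_activity_bq = total_activity_bq),
            class = "activity_phantom")
}

#' @export
print.activity_phantom <- function(x, ...) {
  cat(sprintf("Activity phantom: %.3g Bq total, %d primitives\n",
              x$total_activity_bq, nrow(x$primitives)))
  print(x$primitives, row.names = FALSE)
  invisible(x)
}

#' Point source phantom
#'
#' @param activity_bq Source activity in Bq (e.g. `mci_to_bq(2)`).
#' @param position Length-3 numeric, source position (mm).
#' @return An [activity_phantom()] whose sampled decays all sit exactly at
#'   `position`.
#' @export
make_point_source <- function(activity_bq, position = c(0, 0, 0)) {
  if (activity_bq <= 0) stop("activity_bq must be > 0")
  stopifnot(length(position) == 3)
  ph <- activity_phantom(
    data.frame(shape = "point", x = position[1], y = position[2],
               diameter = 0, length_z = 0, activity = 1),
    total_activity_bq = activity_bq
  )
  ph$point_z <- position[3]
  ph
}

#' Contrast phantom (hot/cold rods in a warm cylinder)
#'
#' A 30 cm diameter uniform background cylinder containing one 10 cm hot
#' rod and one 10 cm cold rod, with activity concentration ratio
#' hot:background:cold = 2:1:0. Rod centers default to (+75, 0) and
#' (-75, 0) mm, symmetric and non-overlapping inside the background.
#'
#' @param total_activity_bq Total phantom activity in Bq.
#' @param hot_center,cold_center Rod centers (mm).
#' @param length_z Axial extent of the cylinder and rods (mm).
#' @return An [activity_phantom()].
#' @export
make_contrast_phantom <- function(total_activity_bq = mci_to_bq(2),
                                  hot_center = c(75, 0),
                                  cold_center = c(-75, 0),
                                  length_z = 150) {
  activity_phantom(
    data.frame(
      shape = c("cylinder", "rod", "rod"),
      x = c(0, hot_center[1], cold_center[1]),
      y = c(0, hot_center[2], cold_center[2]),
      diameter = c(300, 100, 100),
      length_z = length_z,
      activity = c(1, 2, 0)
    ),
    total_activity_bq = total_activity_bq
  )
}

# Default rod layout for the Jaszczak-like phantom: three sectors, one per
# rod diameter, rods on a triangular lattice with center-to-center spacing
# 2 x diameter (standard Jaszczak convention), trimmed to 19 rods total.
jaszczak_rod_layout <- function() {
  rbind(
    # 9 rods, 15.4 mm, lower sector (rows of 4/3/2, spacing 30.8 mm)
    data.frame(x = c(-46.2, -15.4, 15.4, 46.2,
                     -30.8, 0, 30.8,
                     -15.4, 15.4),
               y = c(rep(-40, 4), rep(-66.7, 3), rep(-93.4, 2)),
               diameter = 15.4),
    # 6 rods, 19.1 mm, upper-left sector (spacing 38.2 mm)
    data.frame(x = c(-28, -66.2, -104.4, -47.1, -85.3, -66.2),
               y = c(28, 28, 28, 61.1, 61.1, 94.2),
               diameter = 19.1),
    # 4 rods, 25.4 mm, upper-right sector (spacing 50.8 mm)
    data.frame(x = c(35, 85.8, 9.6, 60.4),
               y = c(30, 30, 74, 74),
               diameter = 25.4)
  )
}

#' Jaszczak-like hot-rod phantom
#'
#' 19 hot rods (activity 1) inside a cold 25.6 cm diameter boundary
#' cylinder: 9 rods of 15.4 mm, 6 of 19.1 mm and 4 of 25.4 mm diameter,
#' each 15 cm long, arranged in three sectors on triangular lattices with
#' center-to-center spacing twice the rod diameter.
#'
#' @param total_activity_bq Total phantom activity in Bq.
#' @param background_activity Relative activity of the boundary cylinder
#'   (default 0: cold background).
#' @param rods Optional replacement rod table (columns `x`, `y`,
#'   `diameter`); rods are validated for mutual overlap and containment.
#' @return An [activity_phantom()].
#' @export
make_jaszczak_phantom <- function(total_activity_bq = mci_to_bq(2),
                                  background_activity = 0,
                                  rods = jaszczak_rod_layout()) {
  boundary_r <- 128
  # containment
  if (any(sqrt(rods$x^2 + rods$y^2) + rods$diameter / 2 > boundary_r + 1e-9))
    stop("configuration error: rod extends outside the phantom boundary")
  # pairwise overlap
  n <- nrow(rods)
  for (i in seq_len(n - 1)) {
    d <- sqrt((rods$x[-(1:i)] - rods$x[i])^2 + (rods$y[-(1:i)] - rods$y[i])^2)
    if (any(d < (rods$diameter[-(1:i)] + rods$diameter[i]) / 2 - 1e-9))
      stop("configuration error: overlapping rods")
  }
  prim <- rbind(
    data.frame(shape = "cylinder", x = 0, y = 0, diameter = 2 * boundary_r,
               length_z = 150, activity = background_activity),
    data.frame(shape = "rod", x = rods$x, y = rods$y, diameter = rods$diameter,
               length_z = 150, activity = 1)
  )
  activity_phantom(prim, total_activity_bq)
}

#' Relative activity concentration at world positions
#'
#' Later primitives override earlier ones; outside every primitive the
#' activity is zero. Containment tests use the transaxial circle
#' (inclusive) and `|z| <= length_z / 2`.
#'
#' @param phantom An [activity_phantom()].
#' @param x,y,z World coordinates (mm), vectorized.
#' @return Numeric vector of relative activities.
#' @export
activity_at <- function(phantom, x, y, z = 0) {
  n <- length(x)
  if (length(z) == 1) z <- rep(z, n)
  act <- numeric(n)
  prim <- phantom$primitives
  for (i in seq_len(nrow(prim))) {
    if (prim$shape[i] == "point") next
    inside <- ((x - prim$x[i])^2 + (y - prim$y[i])^2 <= (prim$diameter[i] / 2)^2) &
      (abs(z) <= prim$length_z[i] / 2)
    act[inside] <- prim$activity[i]
  }
  act
}

#' Sample decay positions and emission times from a phantom
#'
#' Positions are drawn i.i.d. with density proportional to the local
#' relative activity (rejection sampling from the phantom's bounding
#' cylinder); emission times are i.i.d. uniform on `[0, duration_s]`
#' (parent decay is negligible over the short acquisitions considered).
#' The axial extent can be restricted to a band around the central slice
#' with `z_band` so that desk-scale runs concentrate events in the
#' analysed slices.
#'
#' @param phantom An [activity_phantom()].
#' @param n Number of decays to sample.
#' @param duration_s Acquisition duration (s) for the emission times.
#' @param z_band Optional half-width (mm) of the axial sampling band; the
#'   effective band is the smaller of this and the phantom half-length.
#' @param seed Optional integer seed.
#' @return data.frame with columns `x`, `y`, `z` (mm) and `t` (ns).
#' @export
sample_decay_positions <- function(phantom, n, duration_s = 1,
                                   z_band = NULL, seed = NULL) {
  stopifnot(n >= 0)
  if (!is.null(seed)) set.seed(seed)
  n <- as.integer(n)
  empty <- data.frame(x = numeric(0), y = numeric(0), z = numeric(0),
                      t = numeric(0))
  if (n == 0) return(empty)

  prim <- phantom$primitives
  if (all(prim$shape == "point")) {
    i <- which(prim$activity > 0)[1]
    return(data.frame(x = rep(prim$x[i], n), y = rep(prim$y[i], n),
                      z = rep(phantom$point_z %||% 0, n),
                      t = sort_stable(stats::runif(n, 0, duration_s * 1e9))))
  }

  live <- prim$activity > 0
  bound_r <- max(sqrt(prim$x[live]^2 + prim$y[live]^2) + prim$diameter[live] / 2)
  half_z <- max(prim$length_z[live]) / 2
  if (!is.null(z_band)) half_z <- min(half_z, z_band)
  act_max <- max(prim$activity)

  pos <- NULL
  live_idx <- which(live)
  if (length(live_idx) >= 1) {
    # Direct sampling fast path: when every positive primitive is disjoint
    # from all other positive primitives and is not overridden by a later
    # one, draw the primitive by activity x area weight, then a uniform
    # point in its disk. Exactly equivalent to rejection sampling.
    # all positive primitives must span the whole sampling band so the
    # activity x area weights are exact
    disjoint <- all(prim$length_z[live_idx] / 2 >= half_z - 1e-9)
    for (i in live_idx) {
      if (!disjoint) break
      others <- setdiff(union(live_idx, which(seq_len(nrow(prim)) > i)), i)
      for (j in others) {
        d2 <- (prim$x[i] - prim$x[j])^2 + (prim$y[i] - prim$y[j])^2
        if (d2 < ((prim$diameter[i] + prim$diameter[j]) / 2)^2) {
          disjoint <- FALSE
          break
        }
      }
      if (!disjoint) break
    }
    if (disjoint) {
      w <- prim$activity[live_idx] * prim$diameter[live_idx]^2
      pick <- live_idx[sample.int(length(live_idx), n, replace = TRUE,
                                  prob = w)]
      r <- prim$diameter[pick] / 2 * sqrt(stats::runif(n))
      th <- stats::runif(n, 0, 2 * pi)
      pos <- list(x = prim$x[pick] + r * cos(th),
                  y = prim$y[pick] + r * sin(th),
                  z = stats::runif(n, -half_z, half_z))
    }
  }
  if (is.null(pos))
    pos <- cpp_sample_phantom(n, prim$x, prim$y, (prim$diameter / 2)^2,
                              prim$length_z / 2, prim$activity,
                              bound_r, half_z, act_max)
  data.frame(x = pos$x, y = pos$y, z = pos$z,
             t = sort_stable(stats::runif(n, 0, duration_s * 1e9)))
}

# internal helpers
`%||%` <- function(a, b) if (is.null(a)) b else a
sort_stable <- function(x) sort(x, method = "radix")
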