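# Scanner ring and reconstruction grid definitions.

#' Speed of light in mm/ns
#'
#' Used throughout to convert time differences of arrival into path-length
#' differences.
#' @export
C_MM_NS <- 299.792458

#' Define a cylindrical full-ring scanner
#'
#' Describes a PET-like full ring of scintillator crystals used as a
#' collimator-less coincidence camera for cascade gamma pairs. Defaults
#' follow a Biograph-6-like geometry: 48 detector modules of 13 x 13
#' crystals arranged in three block rings, a 424.5 mm detector radius,
#' a 585 mm transaxial and 162 mm axial field of view.
#'
#' Crystal pitches default to exact tilings of the ring circumference and
#' the axial FOV, so the transaxial angular bins partition 360 degrees
#' without overlap.
#'
#' @param ring_radius Detector ring radius in mm (crystal front-face
#'   centers sit on this cylinder).
#' @param n_modules Number of detector modules around the ring.
#' @param crystals_per_module_transaxial,crystals_per_module_axial Crystals
#'   per module in the transaxial/axial direction.
#' @param n_block_rings Number of axial block rings.
#' @param crystal_pitch_transaxial Arc pitch between neighbouring crystals
#'   in mm; default tiles the circumference exactly.
#' @param crystal_pitch_axial Axial pitch in mm; default tiles the axial FOV.
#' @param transaxial_fov,axial_fov Field of view in mm.
#' @param detection_efficiency Per-photon detection probability in (0, 1].
#' @param energy_resolution_range Length-2 numeric, min/max fractional
#'   energy resolution (FWHM/E) referenced at 511 keV; each crystal is
#'   assigned a fixed resolution drawn uniformly from this range.
#' @param ctr_fwhm_ps Default coincidence time resolution (FWHM of the
#'   arrival-time-difference distribution for two simultaneous photons),
#'   in picoseconds.
#' @return An object of class `scanner_geometry`.
#' @export
scanner_geometry <- function(ring_radius = 424.5,
                             n_modules = 48L,
                             crystals_per_module_transaxial = 13L,
                             crystals_per_module_axial = 13L,
                             n_block_rings = 3L,
                             crystal_pitch_transaxial = NULL,
                             crystal_pitch_axial = NULL,
                             transaxial_fov = 585,
                             axial_fov = 162,
                             detection_efficiency = 0.9,
                             energy_resolution_range = c(0.12, 0.18),
                             ctr_fwhm_ps = 100) {
  stopifnot(ring_radius > 0, n_modules >= 1, crystals_per_module_transaxial >= 1,
            crystals_per_module_axial >= 1, n_block_rings >= 1)
  if (!(detection_efficiency > 0 && detection_efficiency <= 1))
    stop("detection_efficiency must be in (0, 1]")
  if (length(energy_resolution_range) != 2 ||
      energy_resolution_range[1] < 0 ||
      energy_resolution_range[1] > energy_resolution_range[2])
    stop("energy_resolution_range must be (min, max) with 0 <= min <= max")
  if (transaxial_fov >= 2 * ring_radius)
    stop("transaxial_fov must be smaller than the ring diameter")
  if (ctr_fwhm_ps < 0) stop("ctr_fwhm_ps must be >= 0")

  n_trans <- as.integer(n_modules) * as.integer(crystals_per_module_transaxial)
  n_rings <- as.integer(n_block_rings) * as.integer(crystals_per_module_axial)
  circumference <- 2 * pi * ring_radius
  if (is.null(crystal_pitch_transaxial))
    crystal_pitch_transaxial <- circumference / n_trans
  if (crystal_pitch_transaxial * n_trans > circumference * (1 + 1e-9))
    stop("crystal overlap: transaxial pitch x count exceeds the ring circumference")
  if (is.null(crystal_pitch_axial))
    crystal_pitch_axial <- axial_fov / n_rings

  structure(list(
    ring_radius = ring_radius,
    n_modules = as.integer(n_modules),
    crystals_per_module_transaxial = as.integer(crystals_per_module_transaxial),
    crystals_per_module_axial = as.integer(crystals_per_module_axial),
    n_block_rings = as.integer(n_block_rings),
    n_crystals_transaxial = n_trans,
    n_axial_rings = n_rings,
    crystal_pitch_transaxial = crystal_pitch_transaxial,
    crystal_pitch_axial = crystal_pitch_axial,
    transaxial_fov = transaxial_fov,
    axial_fov = axial_fov,
    detection_efficiency = detection_efficiency,
    energy_resolution_range = energy_resolution_range,
    ctr_fwhm_ps = ctr_fwhm_ps
  ), class = "scanner_geometry")
}

#' @export
print.scanner_geometry <- function(x, ...) {
  cat("Full-ring scanner geometry\n")
  cat(sprintf("  ring radius      : %.1f mm\n", x$ring_radius))
  cat(sprintf("  crystals         : %d transaxial x %d axial rings\n",
              x$n_crystals_transaxial, x$n_axial_rings))
  cat(sprintf("  pitch            : %.3f mm (trans), %.3f mm (axial)\n",
              x$crystal_pitch_transaxial, x$crystal_pitch_axial))
  cat(sprintf("  FOV              : %.0f mm transaxial, %.0f mm axial\n",
              x$transaxial_fov, x$axial_fov))
  cat(sprintf("  efficiency       : %.2f,  energy res @511 keV: %.0f-%.0f%%\n",
              x$detection_efficiency, 100 * x$energy_resolution_range[1],
              100 * x$energy_resolution_range[2]))
  cat(sprintf("  CTR (FWHM)       : %.0f ps\n", x$ctr_fwhm_ps))
  invisible(x)
}

#' Enumerate the crystal elements of a scanner ring
#'
#' Lays out every crystal element on the detector cylinder. Elements are
#' ordered by `(ring_index, trans_index)`; the element with `trans_index`
#' `i` is centred at angle `2 * pi * i / n` from the +x axis, and axial
#' rings are centred on z = 0.
#'
#' @param geometry A [scanner_geometry()].
#' @return A data.frame with columns `crystal_id` (0-based, unique),
#'   `ring_index` (0-based axial ring), `trans_index`, `angle` (radians),
#'   and the front-face-center coordinates `x`, `y`, `z` (mm).
#' @export
build_ring <- function(geometry) {
  stopifnot(inherits(geometry, "scanner_geometry"))
  n_t <- geometry$n_crystals_transaxial
  n_r <- geometry$n_axial_rings
  trans <- rep(seq_len(n_t) - 1L, times = n_r)
  ring <- rep(seq_len(n_r) - 1L, each = n_t)
  angle <- 2 * pi * trans / n_t
  z <- (ring + 0.5 - n_r / 2) * geometry$crystal_pitch_axial
  data.frame(
    crystal_id = ring * n_t + trans,
    ring_index = ring,
    trans_index = trans,
    angle = angle,
    x = geometry$ring_radius * cos(angle),
    y = geometry$ring_radius * sin(angle),
    z = z
  )
}

# Transaxial crystal index for an azimuthal angle (vectorized).
# Angular bins are centred on the crystal centers, so bin i covers
# [ (i - 1/2) * delta, (i + 1/2) * delta ).
crystal_trans_index <- function(geometry, angle) {
  n_t <- geometry$n_crystals_transaxial
  idx <- round(angle / (2 * pi) * n_t)
  as.integer(idx %% n_t)
}

# Axial ring index for a hit z, or NA when outside the crystal coverage.
crystal_ring_index <- function(geometry, z) {
  n_r <- geometry$n_axial_rings
  z0 <- -n_r / 2 * geometry$crystal_pitch_axial
  idx <- floor((z - z0) / geometry$crystal_pitch_axial)
  idx[idx < 0 | idx >= n_r] <- NA_integer_
  as.integer(idx)
}

#' Define a reconstruction image grid
#'
#' A square-pixel 2D grid in the transaxial plane. Pixel `(0, 0)` (0-based)
#' sits at the most-negative (x, y) corner; pixel intervals are half-open
#' (a point on a boundary belongs to the pixel on its +x/+y side). Images
#' on the grid are stored as `nx` x `ny` matrices indexed `[ix, iy]`.
#'
#' @param nx,ny Number of pixels.
#' @param pixel_size Pixel size in mm.
#' @param center Grid center in world coordinates (mm).
#' @param fov_radius Radius (mm) of the circular reconstruction mask;
#'   defaults to the inscribed circle of the grid.
#' @return An object of class `image_grid`.
#' @export
image_grid <- function(nx = 64L, ny = 64L, pixel_size = 4.5,
                       center = c(0, 0), fov_radius = NULL) {
  stopifnot(nx >= 1, ny >= 1, pixel_size > 0, length(center) == 2)
  if (is.null(fov_radius)) fov_radius <- min(nx, ny) * pixel_size / 2
  structure(list(
    nx = as.integer(nx), ny = as.integer(ny),
    pixel_size = pixel_size,
    center = as.numeric(center),
    x0 = center[1] - nx * pixel_size / 2,  # left/bottom edges
    y0 = center[2] - ny * pixel_size / 2,
    fov_radius = fov_radius
  ), class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat(sprintf("Image grid: %d x %d pixels, %.2f mm pixel size, FOV mask radius %.1f mm\n",
              x$nx, x$ny, x$pixel_size, x$fov_radius))
  invisible(x)
}

#' Map world coordinates to pixel indices
#'
#' @param grid An [image_grid()].
#' @param x,y World coordinates (mm), vectorized.
#' @return A data.frame with 0-based pixel indices `ix`, `iy` (NA when the
#'   point falls outside the grid).
#' @export
world_to_voxel <- function(grid, x, y) {
  ix <- floor((x - grid$x0) / grid$pixel_size)
  iy <- floor((y - grid$y0) / grid$pixel_size)
  out <- ix < 0 | ix >= grid$nx | iy < 0 | iy >= grid$ny
  ix[out] <- NA_integer_
  iy[out] <- NA_integer_
  data.frame(ix = as.integer(ix), iy = as.integer(iy))
}

#' Map pixel indices to the world coordinates of pixel centers
#'
#' Inverse of [world_to_voxel()] on pixel centers.
#'
#' @param grid An [image_grid()].
#' @param ix,iy 0-based pixel indices, vectorized.
#' @return A data.frame with world coordinates `x`, `y` (mm).
#' @export
voxel_to_world <- function(grid, ix, iy) {
  data.frame(x = grid$x0 + (ix + 0.5) * grid$pixel_size,
             y = grid$y0 + (iy + 0.5) * grid$pixel_size)
}

#' Logical mask of in-FOV pixels
#'
#' @param grid An [image_grid()].
#' @return An `nx` x `ny` logical matrix, TRUE where the pixel center lies
#'   within the circular FOV mask.
#' @export
fov_mask <- function(grid) {
  cx <- grid$x0 + (seq_len(grid$nx) - 0.5) * grid$pixel_size
  cy <- grid$y0 + (seq_len(grid$ny) - 0.5) * grid$pixel_size
  dx2 <- (cx - grid$center[1])^2
  dy2 <- (cy - grid$center[2])^2
  outer(dx2, dy2, "+") <= grid$fov_radius^2 + 1e-9
}
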