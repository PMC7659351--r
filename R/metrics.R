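# Image quality metrics: background coefficient of variation, contrast
# recovery coefficient, contrast-to-noise ratio, spillover ratio, PSF
# FWHM and line profiles.

#' Circular region of interest
#'
#' @param center Length-2 numeric, ROI center (mm).
#' @param diameter ROI diameter (mm).
#' @param label One of "hot", "cold", "background".
#' @return Object of class `circular_roi`.
#' @export
circular_roi <- function(center, diameter,
                         label = c("background", "hot", "cold")) {
  label <- match.arg(label)
  stopifnot(length(center) == 2, diameter > 0)
  structure(list(center = as.numeric(center), diameter = diameter,
                 label = label), class = "circular_roi")
}

#' Pixel mask of a circular ROI
#'
#' A pixel belongs to the ROI iff its center lies within the circle
#' (inclusive).
#'
#' @param grid An [image_grid()].
#' @param roi A [circular_roi()].
#' @return `nx` x `ny` logical matrix.
#' @export
roi_mask <- function(grid, roi) {
  cx <- grid$x0 + (seq_len(grid$nx) - 0.5) * grid$pixel_size
  cy <- grid$y0 + (seq_len(grid$ny) - 0.5) * grid$pixel_size
  outer((cx - roi$center[1])^2, (cy - roi$center[2])^2, "+") <=
    (roi$diameter / 2)^2 + 1e-9
}

# population standard deviation
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Background coefficient of variation
#'
#' `CV_B = sigma / mu` over the background-ROI pixels (population SD).
#'
#' @param image Image matrix.
#' @param mask_bkgd Logical ROI mask (see [roi_mask()]).
#' @return Scalar CV.
#' @export
cv_background <- function(image, mask_bkgd) {
  v <- image[mask_bkgd]
  if (mean(v) <= 0) stop("background mean must be > 0")
  pop_sd(v) / mean(v)
}

#' Contrast recovery coefficient
#'
#' `CRC = (C_hot / C_bkgd - 1) / (a_hot / a_bkgd - 1)` with `C` the ROI
#' mean counts and `a` the true activity concentrations.
#'
#' @param image Image matrix.
#' @param mask_hot,mask_bkgd Logical ROI masks.
#' @param activity_ratio True hot/background activity concentration ratio.
#' @return Scalar CRC (1 = perfect recovery).
#' @export
crc <- function(image, mask_hot, mask_bkgd, activity_ratio = 2) {
  if (activity_ratio == 1) stop("activity ratio must differ from 1")
  c_bkgd <- mean(image[mask_bkgd])
  if (c_bkgd <= 0) stop("background mean must be > 0")
  (mean(image[mask_hot]) / c_bkgd - 1) / (activity_ratio - 1)
}

#' Contrast-to-noise ratio
#'
#' `CNR = (C_ROI - C_bkgd) / sigma_bkgd` (population SD in the
#' background).
#'
#' @param image Image matrix.
#' @param mask_roi,mask_bkgd Logical ROI masks.
#' @return Scalar CNR.
#' @export
cnr <- function(image, mask_roi, mask_bkgd) {
  s <- pop_sd(image[mask_bkgd])
  if (s <= 0) stop("background SD must be > 0")
  (mean(image[mask_roi]) - mean(image[mask_bkgd])) / s
}

#' Spillover ratio
#'
#' `SOR = C_cold / C_bkgd`, the cold-ROI mean over the background mean.
#'
#' @param image Image matrix.
#' @param mask_cold,mask_bkgd Logical ROI masks.
#' @return Scalar SOR (0 = no spillover, 1 = no contrast).
#' @export
sor <- function(image, mask_cold, mask_bkgd) {
  c_bkgd <- mean(image[mask_bkgd])
  if (c_bkgd <= 0) stop("background mean must be > 0")
  mean(image[mask_cold]) / c_bkgd
}

# FWHM of a 1D profile around a peak by linear interpolation of the
# half-maximum crossings; returns width in index units, or NA when the
# profile never falls below half maximum on either side.
profile_fwhm <- function(profile, peak = which.max(profile)) {
  half <- profile[peak] / 2
  n <- length(profile)
  left <- NA_real_
  if (peak > 1) for (i in seq(peak, 2)) {
    if (profile[i - 1] < half) {
      left <- (i - 1) + (half - profile[i - 1]) / (profile[i] - profile[i - 1])
      break
    }
  }
  right <- NA_real_
  if (peak < n) for (i in seq(peak, n - 1)) {
    if (profile[i + 1] < half) {
      right <- i + (profile[i] - half) / (profile[i] - profile[i + 1])
      break
    }
  }
  right - left
}

#' Point-spread-function FWHM
#'
#' Extracts the row and column profiles through the image maximum and
#' measures each profile's FWHM by linear interpolation of the
#' half-maximum crossings; returns the mean of the two, in mm.
#'
#' @param image Image matrix (`[ix, iy]` indexing).
#' @param grid An [image_grid()].
#' @return FWHM in mm, or NA (with a warning) when a profile never falls
#'   below half maximum inside the grid.
#' @export
psf_fwhm <- function(image, grid) {
  pk <- arrayInd(which.max(image), dim(image))
  fx <- profile_fwhm(image[, pk[2]], pk[1])
  fy <- profile_fwhm(image[pk[1], ], pk[2])
  if (is.na(fx) || is.na(fy)) {
    warning("profile does not fall below half maximum inside the grid")
    return(NA_real_)
  }
  mean(c(fx, fy)) * grid$pixel_size
}

#' Horizontal or vertical line profile
#'
#' Returns the pixel values along one image row or column. Rows are
#' numbered 1-based from the most-negative y (row `r` is the horizontal
#' profile at the r-th y index); columns 1-based from the most-negative x.
#'
#' @param image Image matrix (`[ix, iy]`).
#' @param row,col 1-based index (give exactly one).
#' @return Numeric vector of pixel values.
#' @export
line_profile <- function(image, row = NULL, col = NULL) {
  if (is.null(row) == is.null(col))
    stop("give exactly one of `row` or `col`")
  if (!is.null(row)) {
    if (row < 1 || row > ncol(image)) stop("row index outside the grid")
    image[, row]
  } else {
    if (col < 1 || col > nrow(image)) stop("column index outside the grid")
    image[col, ]
  }
}

#' Count prominent peaks in a profile
#'
#' Local maxima whose topographic prominence exceeds
#' `prominence_frac * max(profile)`. Used to count resolved rods along a
#' phantom profile.
#'
#' @param profile Numeric vector.
#' @param prominence_frac Minimum prominence as a fraction of the profile
#'   maximum.
#' @return Number of prominent peaks.
#' @export
count_profile_peaks <- function(profile, prominence_frac = 0.1) {
  n <- length(profile)
  if (n < 3) return(0L)
  is_peak <- which(profile[2:(n - 1)] > profile[1:(n - 2)] &
                     profile[2:(n - 1)] >= profile[3:n]) + 1L
  thr <- prominence_frac * max(profile)
  count <- 0L
  for (p in is_peak) {
    # prominence: height above the higher of the two key saddles
    left_min <- Inf
    i <- p
    while (i > 1) {
      i <- i - 1
      left_min <- min(left_min, profile[i])
      if (profile[i] > profile[p]) break
    }
    right_min <- Inf
    i <- p
    while (i < n) {
      i <- i + 1
      right_min <- min(right_min, profile[i])
      if (profile[i] > profile[p]) break
    }
    prominence <- profile[p] - max(min(left_min, profile[p]),
                                   min(right_min, profile[p]))
    # peaks at the global max have no higher ground: prominence = height
    if (!is.finite(left_min) && !is.finite(right_min))
      prominence <- profile[p]
    if (prominence > thr) count <- count + 1L
  }
  count
}

#' Contrast-phantom metric report
#'
#' Computes CV_B, CRC, CNR (hot vs background) and SOR for a reconstructed
#' contrast-phantom image with the standard ROI layout: hot and cold ROIs
#' sized and placed like the rods, and a 10 cm background ROI placed away
#' from both (default center (0, -75) mm).
#'
#' @param image Reconstructed image matrix.
#' @param grid An [image_grid()].
#' @param roi_hot,roi_cold,roi_bkgd [circular_roi()]s; defaults match the
#'   default [make_contrast_phantom()].
#' @param activity_ratio True hot/background activity ratio.
#' @return List of class `metric_report` with `cv_b`, `crc`, `cnr`, `sor`
#'   and the ROI definitions.
#' @export
evaluate_contrast <- function(image, grid,
                              roi_hot = circular_roi(c(75, 0), 100, "hot"),
                              roi_cold = circular_roi(c(-75, 0), 100, "cold"),
                              roi_bkgd = circular_roi(c(0, -75), 100, "background"),
                              activity_ratio = 2) {
  m_hot <- roi_mask(grid, roi_hot)
  m_cold <- roi_mask(grid, roi_cold)
  m_bkgd <- roi_mask(grid, roi_bkgd)
  structure(list(
    cv_b = cv_background(image, m_bkgd),
    crc = crc(image, m_hot, m_bkgd, activity_ratio),
    cnr = cnr(image, m_hot, m_bkgd),
    sor = sor(image, m_cold, m_bkgd),
    rois = list(hot = roi_hot, cold = roi_cold, background = roi_bkgd),
    activity_ratio = activity_ratio
  ), class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("CV_B = %.3f  CRC = %.3f  CNR = %.3f  SOR = %.3f\n",
              x$cv_b, x$crc, x$cnr, x$sor))
  invisible(x)
}
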