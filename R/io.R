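# List-mode file I/O, configuration files and the CTR-sweep experiment
# driver.

LM_COLUMNS <- c("event_id", "crystal_a", "crystal_b", "x_a", "y_a",
                "x_b", "y_b", "energy_a_keV", "energy_b_keV",
                "t_a_ns", "t_b_ns", "tdoa_ns", "slice")
TRUTH_COLUMNS <- c("event_id", "true_x", "true_y", "true_z", "primary")

#' Write a list-mode dataset
#'
#' Writes the columnar event table as CSV with a `#`-prefixed metadata
#' header (geometry hash, seed, CTR, duration, activity) and, alongside
#' it, a `<path>.truth` sidecar with the per-event true decay positions
#' and the primary flag.
#'
#' @param lm A `listmode` object from [simulate_acquisition()].
#' @param path Output CSV path.
#' @param truth Also write the truth sidecar.
#' @return `path`, invisibly.
#' @export
write_listmode <- function(lm, path, truth = TRUE) {
  stopifnot(inherits(lm, "listmode"))
  ev <- lm$events
  meta <- lm$meta
  hdr <- c(
    sprintf("# dupect listmode v1"),
    sprintf("# geometry_hash=%s", meta$geometry_hash),
    sprintf("# seed=%s", meta$seed %||% "NA"),
    sprintf("# ctr_ps=%g", meta$ctr_ps),
    sprintf("# duration_s=%g", meta$duration_s),
    sprintf("# activity_bq=%g", meta$activity_bq),
    sprintf("# energy_windows=%s", meta$energy_windows)
  )
  writeLines(hdr, path)
  data.table::fwrite(ev[, LM_COLUMNS], path, append = TRUE, col.names = TRUE)
  if (truth) {
    writeLines(hdr[1:2], paste0(path, ".truth"))
    data.table::fwrite(ev[, TRUTH_COLUMNS], paste0(path, ".truth"),
                       append = TRUE, col.names = TRUE)
  }
  invisible(path)
}

#' Read a list-mode dataset
#'
#' Inverse of [write_listmode()]; validates the column schema and raises
#' an explicit error naming any missing column.
#'
#' @param path CSV path written by [write_listmode()].
#' @param truth Merge the `<path>.truth` sidecar when present.
#' @return A `listmode` object (counters are not preserved by the file
#'   format and are returned empty).
#' @export
read_listmode <- function(path, truth = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- character(0)
  con <- file(path, "r")
  on.exit(close(con))
  while (length(line <- readLines(con, n = 1)) == 1 && startsWith(line, "#"))
    hdr <- c(hdr, line)
  close(con); on.exit()
  ev <- as.data.frame(data.table::fread(path, skip = length(hdr)))
  missing_cols <- setdiff(LM_COLUMNS, names(ev))
  if (length(missing_cols) > 0)
    stop("list-mode schema error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  tpath <- paste0(path, ".truth")
  if (truth && file.exists(tpath)) {
    tr <- as.data.frame(data.table::fread(tpath, skip = 2))
    ev <- merge(ev, tr, by = "event_id", sort = TRUE)
  }
  meta <- list()
  for (h in hdr[-1]) {
    kv <- strsplit(sub("^#\\s*", "", h), "=", fixed = TRUE)[[1]]
    if (length(kv) == 2) meta[[kv[1]]] <- utils::type.convert(kv[2], as.is = TRUE)
  }
  structure(list(events = ev, counts = numeric(0), meta = meta),
            class = "listmode")
}

#' Read a scanner configuration file
#'
#' YAML key/value file with [scanner_geometry()] fields; the shipped
#' default is `system.file("extdata", "biograph6_like.yaml", package =
#' "dupect")`.
#'
#' @param path YAML file path.
#' @return A [scanner_geometry()].
#' @export
read_scanner_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  do.call(scanner_geometry, cfg)
}

#' Read a phantom preset file
#'
#' YAML file with either `preset: point|contrast|jaszczak` plus arguments,
#' or an explicit `primitives` list and `total_activity_bq`.
#'
#' @param path YAML file path.
#' @return An [activity_phantom()].
#' @export
read_phantom_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$preset)) {
    act <- cfg$activity_bq %||% mci_to_bq(cfg$activity_mci %||% 2)
    return(switch(cfg$preset,
      point = make_point_source(act, unlist(cfg$position %||% c(0, 0, 0))),
      contrast = make_contrast_phantom(act),
      jaszczak = make_jaszczak_phantom(act),
      stop("unknown phantom preset: ", cfg$preset)))
  }
  prim <- do.call(rbind, lapply(cfg$primitives, as.data.frame))
  activity_phantom(prim, cfg$total_activity_bq)
}

#' Run a coincidence-time-resolution sweep experiment
#'
#' For each CTR value: simulate an acquisition, reconstruct the primary
#' events with the stochastic origin ensemble, and evaluate image quality.
#' Point-source runs report the PSF FWHM; phantom runs report
#' CV_B/CRC/CNR/SOR on the post-smoothed image. A failed CTR is marked in
#' the bundle and the sweep continues.
#'
#' @param phantom An [activity_phantom()].
#' @param geometry A [scanner_geometry()].
#' @param grid An [image_grid()].
#' @param ctr_ps Numeric vector of CTR FWHM values (ps).
#' @param duration_s Acquisition duration (s).
#' @param n_sweeps,n_average Reconstruction schedule.
#' @param smooth_sd Post-smoothing SD in pixels (applied to phantom
#'   metrics; set 0 for none).
#' @param seed Base seed; per-CTR child seeds are derived
#'   deterministically.
#' @param kind "point" (PSF FWHM) or "contrast" (ROI metrics).
#' @param primaries_only Reconstruct only same-decay coincidences.
#' @return List of class `ctr_sweep`: per-CTR results and a `summary`
#'   data.frame.
#' @export
run_ctr_sweep <- function(phantom, geometry, grid,
                          ctr_ps = c(0, 50, 100, 150, 200),
                          duration_s, n_sweeps = 1500L, n_average = 300L,
                          smooth_sd = 0.75, seed = 1L,
                          kind = c("contrast", "point"),
                          primaries_only = TRUE) {
  kind <- match.arg(kind)
  if (length(ctr_ps) == 0) {
    warning("empty CTR list: nothing to do")
    return(structure(list(runs = list(),
                          summary = data.frame()), class = "ctr_sweep"))
  }
  runs <- list()
  rows <- list()
  for (i in seq_along(ctr_ps)) {
    ctr <- ctr_ps[i]
    child <- (seed + 7919L * i) %% .Machine$integer.max
    res <- tryCatch({
      lm <- simulate_acquisition(phantom, geometry, duration_s = duration_s,
                                 ctr_ps = ctr, seed = child)
      ev <- lm$events
      if (primaries_only) ev <- ev[ev$primary, ]
      rec <- reconstruct(ev, grid, n_sweeps = n_sweeps,
                         n_average = n_average, seed = child + 1L,
                         smooth_sd = if (kind == "contrast") smooth_sd else 0)
      out <- list(ctr_ps = ctr, listmode_counts = lm$counts, recon = rec,
                  failed = FALSE)
      if (kind == "point") {
        out$fwhm_mm <- psf_fwhm(rec$image, grid)
        rows[[i]] <- data.frame(ctr_ps = ctr, n_events = rec$n_events,
                                fwhm_mm = out$fwhm_mm)
      } else {
        out$metrics <- evaluate_contrast(rec$image, grid)
        rows[[i]] <- data.frame(ctr_ps = ctr, n_events = rec$n_events,
                                cv_b = out$metrics$cv_b, crc = out$metrics$crc,
                                cnr = out$metrics$cnr, sor = out$metrics$sor)
      }
      out
    }, error = function(e) {
      warning(sprintf("CTR %g ps failed: %s", ctr, conditionMessage(e)))
      rows[[i]] <<- data.frame(ctr_ps = ctr, n_events = NA_integer_)
      list(ctr_ps = ctr, failed = TRUE, error = conditionMessage(e))
    })
    runs[[as.character(ctr)]] <- res
  }
  summary <- do.call(rbind, lapply(rows, function(r) {
    # pad columns so failed runs bind with successful ones
    all_cols <- unique(unlist(lapply(rows, names)))
    for (cn in setdiff(all_cols, names(r))) r[[cn]] <- NA
    r[all_cols]
  }))
  structure(list(runs = runs, summary = summary, seed = seed),
            class = "ctr_sweep")
}

#' @export
print.ctr_sweep <- function(x, ...) {
  cat("CTR sweep\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
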