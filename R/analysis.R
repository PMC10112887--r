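#' Full defect/extrusion analysis of a trajectory
#'
#' Runs the whole analysis stack on a simulated trajectory: per-frame defect
#' detection on the coarse-grained director, defect tracking, per-event
#' minimum extrusion-to-defect distances, coordination histories of the
#' extruding cells, per-event normalized stress series and the defect-frame
#' averaged isotropic stress map.
#'
#' @param traj An `mpf_trajectory` from [run_simulation()] (with analysis
#'   frames).
#' @param dmin_window Normalized-time window for the minimum-distance
#'   statistic (default `c(-5.625, 0.625)` in units of tau0).
#' @param z_window Window for the coordination history (default
#'   `c(-2.5, 0.3125)`).
#' @param L Side of the defect-frame stress window (default `1.5 R0`).
#' @return A list of class `mpf_analysis`: `detections` (per frame),
#'   `tracks`, `dmin`, `zbar`, `stress_series` (NULL without stress frames),
#'   `defect_map` (NULL without +1/2 tracks or stress frames), `events`.
#' @export
analyze_trajectory <- function(traj, dmin_window = c(-5.625, 0.625),
                               z_window = c(-2.5, 0.3125), L = 1.5 * traj$R0) {
  cfg <- traj$config
  if (!length(traj$frames)) stop("trajectory has no analysis frames")
  empty_det <- data.frame(charge = numeric(0), x = numeric(0), y = numeric(0),
                          psi = numeric(0))
  detections <- lapply(traj$frames, function(fr) {
    ok <- !fr$orient$empty & !is.na(fr$orient$angle) &
      !is.na(fr$orient$anisotropy) & fr$orient$anisotropy >= 0.005
    if (sum(ok) < 3) return(empty_det)
    df <- coarse_grain_director(fr$orient$angle,
                                cbind(fr$orient$x, fr$orient$y),
                                cfg$l_dir, cfg$lattice,
                                anisotropy = fr$orient$anisotropy)
    detect_defects(df)
  })
  steps <- vapply(traj$frames, function(fr) fr$step, numeric(1))
  tracks <- track_defects(detections, cfg$lattice, gate = cfg$R0, steps = steps)
  events <- traj$events
  dmin <- if (nrow(events)) min_distance_series(traj, tracks, events,
                                                window = dmin_window) else NULL
  zbar <- if (nrow(events)) coordination_history(traj, events,
                                                 window = z_window) else NULL
  has_stress <- !is.null(traj$frames[[1]]$sigma_iso_basal)
  stress_series <- if (has_stress && nrow(events))
    cell_stress_series(traj, events, window = z_window) else NULL
  defect_map <- NULL
  if (has_stress) {
    pts <- tracks$points
    if (any(pts$charge > 0 & !is.na(pts$psi)))
      defect_map <- defect_frame_average(traj, tracks, L = L)
  }
  structure(list(detections = detections, tracks = tracks, dmin = dmin,
                 zbar = zbar, stress_series = stress_series,
                 defect_map = defect_map, events = events),
            class = "mpf_analysis")
}

#' @export
print.mpf_analysis <- function(x, ...) {
  cat(sprintf("<mpf_analysis> %d defect tracks, %d extrusion events\n",
              nrow(x$tracks$tracks), nrow(x$events)))
  if (!is.null(x$dmin)) {
    cat(sprintf("  mean dmin(+1/2) = %.3g R0 (n = %d non-missing)\n",
                mean(x$dmin$dmin_plus, na.rm = TRUE),
                sum(!is.na(x$dmin$dmin_plus))))
  }
  invisible(x)
}

#' Minimum distances from arbitrary (null) events to tracked defects
#'
#' The same per-event minimum-distance statistic as [min_distance_series()],
#' but for externally supplied event positions/times (e.g. the Poisson null
#' realizations), which have no cell trajectory: the event position is fixed
#' over the window.
#'
#' @param events data.frame with `x`, `y`, `t_e` (steps).
#' @param tracks A [track_defects()] result with `step` columns.
#' @param traj The trajectory providing the time base (dt, tau0, lattice).
#' @param window Window in units of tau0.
#' @param charge Defect charge to measure against (default +1/2).
#' @return Numeric vector of normalized minimum distances (NA where the
#'   window holds no defects of that charge).
#' @export
null_min_distances <- function(events, tracks, traj,
                               window = c(-5.625, 0.625), charge = 0.5) {
  lat <- traj$config$lattice
  pts <- tracks$points
  pts <- pts[pts$charge == charge, , drop = FALSE]
  tnorm <- pts$step * traj$dt / traj$tau0
  vapply(seq_len(nrow(events)), function(r) {
    te <- events$t_e[r] * traj$dt / traj$tau0
    sel <- pts[tnorm >= te + window[1] & tnorm <= te + window[2], , drop = FALSE]
    if (!nrow(sel)) return(NA_real_)
    min(periodic_distance(cbind(sel$x, sel$y),
                          matrix(c(events$x[r], events$y[r]), nrow(sel), 2,
                                 byrow = TRUE), lat)) / traj$R0
  }, numeric(1))
}
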