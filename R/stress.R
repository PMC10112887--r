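#' Traction density field
#'
#' The pointwise integrand of the cell traction: `T(x) = S(x) grad(pi)(x)`
#' where `S = sum_i phi_i` and `pi = sum_j (-dF/dphi_j)` is the scalar of the
#' isotropic interaction tensor. Integrating `phi_i T / S`-weighted
#' contributions over a cell's support recovers its traction `t_i`.
#'
#' @param state A `monolayer_state`.
#' @param params An [energy_params()].
#' @return A list of class `traction_density` with the three component arrays
#'   `Tx`, `Ty`, `Tz` on the full lattice.
#' @export
traction_density <- function(state, params) {
  f <- monolayer_forces(state, params, keep_fields = TRUE)
  gd <- gdim(state$lattice)
  structure(list(Tx = array(f$cache$S * f$grad_pi$gx, gd),
                 Ty = array(f$cache$S * f$grad_pi$gy, gd),
                 Tz = array(f$cache$S * f$grad_pi$gz, gd),
                 lattice = state$lattice),
            class = "traction_density")
}

#' Coarse-grained 3D stress tensor
#'
#' Partitions the lattice into cubic volumes of side `l_stress` and computes
#' in each the symmetrized moment of the traction density about the volume
#' center:
#' `sigma_ij = 1/(2 Vcg) sum_m (T_i(x_m) e_j(x_m) + T_j(x_m) e_i(x_m))`,
#' `e(x_m) = (x0 - x_m)/|x0 - x_m|`, excluding the (undefined) self point.
#' Negative isotropic stress denotes compression throughout the package.
#'
#' @param td A [traction_density()] result, or a list with `Tx`, `Ty`, `Tz`.
#' @param lattice A [lattice_spec()].
#' @param l_stress Coarse-graining length (default `R0/4` should be supplied
#'   by the caller; must be >= 2 a0).
#' @return An object of class `stress_field`: six component arrays (`xx`,
#'   `yy`, `zz`, `xy`, `xz`, `yz`) at the coarse resolution, block size `b`
#'   and coarse dims `cdim`.
#' @export
coarse_grained_stress <- function(td, lattice, l_stress) {
  b <- as.integer(round(l_stress / lattice$a0))
  if (b < 2) stop("l_stress must be at least 2 * a0")
  gd <- gdim(lattice)
  comp <- cpp_coarse_stress(td$Tx, td$Ty, td$Tz, gd, b, lattice$a0)
  cdim <- gd %/% b
  comp <- lapply(comp, array, dim = cdim)
  structure(c(comp, list(b = b, cdim = cdim, l_stress = l_stress,
                         lattice = lattice)),
            class = "stress_field")
}

#' Isotropic and out-of-plane shear stress maps
#'
#' `sigma_iso` is the 3D trace third (`trace = "3d"`, default) or the
#' in-plane half trace (`trace = "2d"`, for comparison with planar
#' experiments); `sigma_xz` is read off the tensor. Normalized variants
#' divide by the maximum absolute value of the frame (an all-zero field
#' normalizes to zero by convention).
#'
#' @param sf A [coarse_grained_stress()] result.
#' @param trace `"3d"` or `"2d"`.
#' @return A list with `iso`, `xz` and normalized `iso_norm`, `xz_norm`.
#' @export
isotropic_and_shear_maps <- function(sf, trace = c("3d", "2d")) {
  trace <- match.arg(trace)
  iso <- if (trace == "3d") (sf$xx + sf$yy + sf$zz) / 3 else (sf$xx + sf$yy) / 2
  xz <- sf$xz
  norm0 <- function(a) {
    m <- max(abs(a))
    if (m == 0) a else a / m
  }
  list(iso = iso, xz = xz, iso_norm = norm0(iso), xz_norm = norm0(xz))
}

# coarse z index of the basal plane
basal_coarse_index <- function(state, b) {
  zb <- as.integer(floor(state$substrate$z_surface / state$lattice$a0)) + 1L
  min(zb %/% b + 1L, state$lattice$nz %/% b)
}

# Spatial means of sigma_iso / sigma_xz over each cell's body (phi >= 0.5)
# and over the union of all bodies.
stress_region_means <- function(state, sf, maps) {
  gd <- gdim(state$lattice)
  n <- length(state$cells)
  iso_cell <- rep(NA_real_, n); xz_cell <- rep(NA_real_, n)
  iso_sum <- 0; xz_sum <- 0; cnt <- 0
  for (i in seq_len(n)) {
    cell <- state$cells[[i]]
    if (cell$removed) next
    ri <- cpp_region_mean(cell$phi, dim(cell$phi), cell$offset,
                          maps$iso, sf$cdim, sf$b, gd)
    rx <- cpp_region_mean(cell$phi, dim(cell$phi), cell$offset,
                          maps$xz, sf$cdim, sf$b, gd)
    if (ri[2] > 0) {
      iso_cell[i] <- ri[1] / ri[2]
      xz_cell[i] <- rx[1] / rx[2]
      iso_sum <- iso_sum + ri[1]; xz_sum <- xz_sum + rx[1]; cnt <- cnt + ri[2]
    }
  }
  list(iso_cell = iso_cell, xz_cell = xz_cell,
       iso_union = if (cnt > 0) iso_sum / cnt else NA_real_,
       xz_union = if (cnt > 0) xz_sum / cnt else NA_real_)
}

#' Per-event normalized stress time series
#'
#' For each extrusion event, the spatial mean of the isotropic (resp. xz
#' shear) stress over the extruding cell's body, normalized by the mean over
#' the union of all cell bodies, at every analysis frame in a window of
#' normalized time around the extrusion. Frames where the cell has fully
#' detached (empty body) truncate the series with a flag.
#'
#' @param traj An `mpf_trajectory` run with stress analysis enabled.
#' @param events Extrusion events; default `traj$events`.
#' @param window Window in units of tau0 (default `c(-2.5, 0.3125)`).
#' @return A data.frame with `cell_id`, `step`, `t_rel` (time from extrusion
#'   in tau0), `iso_ratio`, `xz_ratio`, `truncated`.
#' @export
cell_stress_series <- function(traj, events = traj$events,
                               window = c(-2.5, 0.3125)) {
  frames <- traj$frames
  if (!length(frames) || is.null(frames[[1]]$iso_cell_mean))
    stop("trajectory has no stress frames (run with analyze_stress = TRUE)")
  fsteps <- vapply(frames, `[[`, numeric(1), "step")
  ftimes <- fsteps * traj$dt / traj$tau0
  out <- list()
  for (r in seq_len(nrow(events))) {
    ev <- events[r, ]
    sel <- which(ftimes >= ev$t_norm + window[1] &
                 ftimes <= ev$t_norm + window[2])
    for (f in sel) {
      fr <- frames[[f]]
      iso_i <- fr$iso_cell_mean[ev$cell_id]
      xz_i <- fr$xz_cell_mean[ev$cell_id]
      truncated <- is.na(iso_i)
      out[[length(out) + 1L]] <- data.frame(
        cell_id = ev$cell_id, step = fr$step,
        t_rel = ftimes[f] - ev$t_norm,
        iso_ratio = if (truncated) NA_real_ else iso_i / fr$iso_union_mean,
        xz_ratio = if (truncated) NA_real_ else xz_i / fr$xz_union_mean,
        truncated = truncated)
    }
  }
  if (!length(out))
    return(data.frame(cell_id = integer(0), step = integer(0),
                      t_rel = numeric(0), iso_ratio = numeric(0),
                      xz_ratio = numeric(0), truncated = logical(0)))
  do.call(rbind, out)
}

# bilinear periodic interpolation on a 2D map whose pixel (i, j) is centered
# at ((i - 0.5) * hx, (j - 0.5) * hy)
bilinear_periodic <- function(map, x, y, Lx, Ly) {
  nx <- nrow(map); ny <- ncol(map)
  hx <- Lx / nx; hy <- Ly / ny
  fx <- (x / hx - 0.5) %% nx
  fy <- (y / hy - 0.5) %% ny
  i0 <- floor(fx); j0 <- floor(fy)
  tx <- fx - i0; ty <- fy - j0
  i0 <- (as.integer(i0) %% nx) + 1L; j0 <- (as.integer(j0) %% ny) + 1L
  i1 <- (i0 %% nx) + 1L; j1 <- (j0 %% ny) + 1L
  map[cbind(i0, j0)] * (1 - tx) * (1 - ty) +
    map[cbind(i1, j0)] * tx * (1 - ty) +
    map[cbind(i0, j1)] * (1 - tx) * ty +
    map[cbind(i1, j1)] * tx * ty
}

#' Defect-frame averaged stress map
#'
#' For every recorded frame of every +1/2 defect track, samples the basal
#' isotropic stress on a square window of side `L` centered on the defect and
#' rotated so the comet axis points along +x, then averages over all samples
#' and normalizes by the maximum absolute value. Reproduces the
#' compressive-head / tensile-tail structure of motile +1/2 defects when it
#' is present in the data.
#'
#' @param traj An `mpf_trajectory` with stress frames.
#' @param tracks A [track_defects()] result; only +1/2 points with a recorded
#'   orientation are used.
#' @param L Window side (default `1.5 * R0`).
#' @param res Sampling resolution (default a0).
#' @return A list with the averaged map (`map`, normalized), `raw` (before
#'   normalization), sample count `n_samples`, and axis coordinates `xs`
#'   (comet axis) and `ys`.
#' @export
defect_frame_average <- function(traj, tracks, L = 1.5 * traj$R0,
                                 res = traj$config$lattice$a0) {
  lat <- traj$config$lattice
  frames <- traj$frames
  if (!length(frames) || is.null(frames[[1]]$sigma_iso_basal))
    stop("trajectory has no stress frames (run with analyze_stress = TRUE)")
  fsteps <- vapply(frames, `[[`, numeric(1), "step")
  pts <- tracks$points
  pts <- pts[pts$charge > 0 & !is.na(pts$psi), , drop = FALSE]
  if (!nrow(pts)) stop("no +1/2 defect points with recorded orientation")
  m <- max(3L, as.integer(round(L / res)))
  u <- (seq_len(m) - (m + 1) / 2) * (L / m)  # window coordinates
  acc <- matrix(0, m, m); wsum <- matrix(0, m, m)
  n_samples <- 0L
  for (r in seq_len(nrow(pts))) {
    f <- match(pts$step[r], fsteps)
    if (is.na(f)) next
    map <- frames[[f]]$sigma_iso_basal
    psi <- pts$psi[r]
    cpsi <- cos(psi); spsi <- sin(psi)
    for (j in seq_len(m)) {
      gx <- pts$x[r] + u * cpsi - u[j] * spsi
      gy <- pts$y[r] + u * spsi + u[j] * cpsi
      acc[, j] <- acc[, j] + bilinear_periodic(map, gx %% lat$Lx, gy %% lat$Ly,
                                               lat$Lx, lat$Ly)
      wsum[, j] <- wsum[, j] + 1
    }
    n_samples <- n_samples + 1L
  }
  if (n_samples == 0L) stop("no defect points matched the stress frames")
  raw <- acc / wsum
  mx <- max(abs(raw))
  list(map = if (mx > 0) raw / mx else raw, raw = raw,
       n_samples = n_samples, xs = u, ys = u)
}
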