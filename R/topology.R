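#' Basal projection of the cell fields
#'
#' Extracts each cell's phase field on the basal plane, the first lattice
#' plane above the substrate midpoint surface. Cells without substrate
#' contact (e.g. extruded ones) yield an empty, masked footprint.
#'
#' @param state A `monolayer_state`.
#' @return A list of class `basal_projection`: per-cell footprints (2D matrix
#'   `vals`, 0-based x/y `offset`, `empty` flag) plus the basal plane index.
#' @export
basal_projection <- function(state) {
  lat <- state$lattice
  live <- Filter(function(c) !c$removed, state$cells)
  if (!length(live)) stop("state has no live cells")
  zb <- as.integer(floor(state$substrate$z_surface / lat$a0)) + 1L
  fps <- lapply(state$cells, function(cell) {
    if (cell$removed)
      return(list(id = cell$id, vals = NULL, offset = c(0L, 0L), empty = TRUE))
    k <- zb - cell$offset[3] + 1L  # 1-based slice index in the subdomain
    sdim <- dim(cell$phi)
    if (k < 1L || k > sdim[3]) {
      vals <- matrix(0, sdim[1], sdim[2])
    } else {
      vals <- cell$phi[, , k]
    }
    list(id = cell$id, vals = vals, offset = cell$offset[1:2],
         empty = max(vals) < 0.5)  # no substrate contact: no body on the plane
  })
  structure(list(footprints = fps, z_index = zb, lattice = lat),
            class = "basal_projection")
}

#' Shape orientation of a 2D footprint
#'
#' Principal-axis angle (modulo pi) and anisotropy of the second-moment
#' (shape) tensor of a weighted 2D field about its centroid. The anisotropy
#' is the normalized eigenvalue difference in `[0, 1]`; isotropic footprints
#' get anisotropy 0 and an unreliable-angle flag.
#'
#' @param footprint Numeric matrix of field values (a basal footprint).
#' @param a0 Grid spacing.
#' @return List with `angle` (in `[0, pi)`), `anisotropy`, `area` (of the
#'   `phi >= 0.5` region), `centroid` (in footprint coordinates, length
#'   units) and `reliable`.
#' @export
cell_orientation <- function(footprint, a0 = 1) {
  w <- footprint
  tot <- sum(w)
  if (!is.finite(tot) || tot <= 0) stop("empty footprint")
  nx <- nrow(w); ny <- ncol(w)
  xs <- (seq_len(nx) - 1) * a0
  ys <- (seq_len(ny) - 1) * a0
  cx <- sum(xs * rowSums(w)) / tot
  cy <- sum(ys * colSums(w)) / tot
  dx <- xs - cx; dy <- ys - cy
  Ixx <- sum(dx^2 * rowSums(w)) / tot
  Iyy <- sum(dy^2 * colSums(w)) / tot
  Ixy <- sum(outer(dx, dy) * w) / tot
  tr <- Ixx + Iyy
  disc <- sqrt(((Ixx - Iyy) / 2)^2 + Ixy^2)
  aniso <- if (tr > 0) 2 * disc / tr else 0
  angle <- 0.5 * atan2(2 * Ixy, Ixx - Iyy)
  angle <- angle %% pi
  list(angle = angle, anisotropy = aniso,
       area = sum(w >= 0.5) * a0^2,
       centroid = c(cx, cy),
       reliable = aniso > 1e-8)
}

# orientation table for all footprints of a basal projection
footprint_orientations <- function(bp, lattice) {
  rows <- lapply(bp$footprints, function(fp) {
    if (isTRUE(fp$empty))
      return(data.frame(id = fp$id, x = NA_real_, y = NA_real_,
                        angle = NA_real_, anisotropy = NA_real_,
                        area = 0, empty = TRUE))
    o <- cell_orientation(fp$vals, lattice$a0)
    data.frame(id = fp$id,
               x = (o$centroid[1] + fp$offset[1] * lattice$a0) %% lattice$Lx,
               y = (o$centroid[2] + fp$offset[2] * lattice$a0) %% lattice$Ly,
               angle = o$angle, anisotropy = o$anisotropy, area = o$area,
               empty = FALSE)
  })
  do.call(rbind, rows)
}

#' Coarse-grained director field
#'
#' Averages the nematic tensor `Q = <2 n (x) n - I>` of cell orientations over
#' a Gaussian kernel of width `l_dir` on a regular grid over the periodic
#' basal plane; the director is the principal eigenvector of the averaged Q.
#' Cells with unreliable (near-isotropic) shapes can be excluded before
#' averaging; nodes with no cells in kernel range are masked.
#'
#' @param orientations Angles (mod pi) per cell, NA allowed.
#' @param positions N x 2 matrix of in-plane cell positions.
#' @param l_dir Coarse-graining length (default one cell radius).
#' @param lattice A [lattice_spec()].
#' @param spacing Director grid spacing; default `l_dir / 2`.
#' @param anisotropy Optional per-cell anisotropies; cells below
#'   `min_anisotropy` are excluded before averaging (their orientation is
#'   unreliable).
#' @param min_anisotropy Anisotropy mask threshold (default 0.005; typical shape
#'   anisotropies of near-confluent round cells are a few percent).
#' @return An object of class `director_field` with node coordinates, angle,
#'   order `S`, tensor components and a validity `mask` (TRUE where at least
#'   one cell is in kernel range; defect cores legitimately have low order
#'   and stay unmasked).
#' @export
coarse_grain_director <- function(orientations, positions, l_dir, lattice,
                                  spacing = l_dir / 2, anisotropy = NULL,
                                  min_anisotropy = 0.005) {
  keep <- !is.na(orientations) & !is.na(positions[, 1])
  if (!is.null(anisotropy)) keep <- keep & !is.na(anisotropy) &
    anisotropy >= min_anisotropy
  orientations <- orientations[keep]
  positions <- positions[keep, , drop = FALSE]
  if (length(orientations) < 3) stop("need at least 3 oriented cells")
  nxn <- max(4L, round(lattice$Lx / spacing))
  nyn <- max(4L, round(lattice$Ly / spacing))
  sx <- lattice$Lx / nxn; sy <- lattice$Ly / nyn
  xs <- (seq_len(nxn) - 0.5) * sx
  ys <- (seq_len(nyn) - 0.5) * sy
  c2 <- cos(2 * orientations); s2 <- sin(2 * orientations)
  gx <- rep(xs, times = nyn); gy <- rep(ys, each = nxn)
  dx <- wrap_delta(outer(gx, positions[, 1], `-`), lattice$Lx)
  dy <- wrap_delta(outer(gy, positions[, 2], `-`), lattice$Ly)
  W <- exp(-(dx^2 + dy^2) / (2 * l_dir^2))
  W[W < exp(-9 / 2)] <- 0  # 3 sigma cutoff
  wtot <- rowSums(W)
  Qxx <- as.vector(W %*% c2)
  Qxy <- as.vector(W %*% s2)
  ok <- wtot > 1e-8
  Qxx[ok] <- Qxx[ok] / wtot[ok]; Qxy[ok] <- Qxy[ok] / wtot[ok]
  S <- sqrt(Qxx^2 + Qxy^2)
  angle <- (0.5 * atan2(Qxy, Qxx)) %% pi
  mask <- ok
  structure(list(xs = xs, ys = ys,
                 angle = matrix(angle, nxn, nyn),
                 S = matrix(S, nxn, nyn),
                 Qxx = matrix(Qxx, nxn, nyn),
                 Qxy = matrix(Qxy, nxn, nyn),
                 mask = matrix(mask, nxn, nyn),
                 spacing = c(sx, sy), l_dir = l_dir, lattice = lattice),
            class = "director_field")
}

# wrap an angle difference into (-pi/2, pi/2] (nematic symmetry)
wrap_nematic <- function(d) {
  d <- (d + pi / 2) %% pi - pi / 2
  d[d == -pi / 2] <- pi / 2
  d
}

#' Detect half-integer nematic defects
#'
#' Computes the winding number of the director around every grid plaquette by
#' summing orientation differences re-wrapped to `(-pi/2, pi/2]`; plaquettes
#' with winding +-pi carry a +-1/2 defect at the plaquette center. The
#' orientation psi of a +1/2 defect (its comet axis) is the direction of
#' div(Q) at the core.
#'
#' @param director A [coarse_grain_director()] result.
#' @return A data.frame with one row per defect: `charge` (+0.5 / -0.5),
#'   `x`, `y`, `psi` (NA for -1/2).
#' @export
detect_defects <- function(director) {
  a <- director$angle; m <- director$mask
  nxn <- nrow(a); nyn <- ncol(a)
  sx <- director$spacing[1]; sy <- director$spacing[2]
  out <- list()
  for (j in seq_len(nyn)) {
    jp <- if (j == nyn) 1L else j + 1L
    for (i in seq_len(nxn)) {
      ip <- if (i == nxn) 1L else i + 1L
      if (!(m[i, j] && m[ip, j] && m[ip, jp] && m[i, jp])) next
      w <- wrap_nematic(a[ip, j] - a[i, j]) +
           wrap_nematic(a[ip, jp] - a[ip, j]) +
           wrap_nematic(a[i, jp] - a[ip, jp]) +
           wrap_nematic(a[i, j] - a[i, jp])
      if (abs(w) < pi / 2) next
      charge <- sign(w) * 0.5
      x <- (director$xs[i] + sx / 2) %% director$lattice$Lx
      y <- (director$ys[j] + sy / 2) %% director$lattice$Ly
      psi <- NA_real_
      if (charge > 0) {
        dxQxx <- (director$Qxx[ip, j] + director$Qxx[ip, jp] -
                  director$Qxx[i, j] - director$Qxx[i, jp]) / (2 * sx)
        dxQxy <- (director$Qxy[ip, j] + director$Qxy[ip, jp] -
                  director$Qxy[i, j] - director$Qxy[i, jp]) / (2 * sx)
        dyQxx <- (director$Qxx[i, jp] + director$Qxx[ip, jp] -
                  director$Qxx[i, j] - director$Qxx[ip, j]) / (2 * sy)
        dyQxy <- (director$Qxy[i, jp] + director$Qxy[ip, jp] -
                  director$Qxy[i, j] - director$Qxy[ip, j]) / (2 * sy)
        psi <- atan2(dxQxy - dyQxx, dxQxx + dyQxy)
      }
      out[[length(out) + 1L]] <- data.frame(charge = charge, x = x, y = y,
                                            psi = psi)
    }
  }
  if (!length(out))
    return(data.frame(charge = numeric(0), x = numeric(0), y = numeric(0),
                      psi = numeric(0)))
  do.call(rbind, out)
}

#' Track defects across frames
#'
#' Greedy nearest-neighbor frame-to-frame linking of same-charge detections
#' within a maximum displacement gate; unmatched detections start new tracks,
#' unmatched tracks end.
#'
#' @param detections A list of per-frame data.frames as returned by
#'   [detect_defects()]; names or a `steps` vector give the frame time base.
#' @param lattice A [lattice_spec()] for periodic distances.
#' @param gate Maximum displacement between consecutive frames (default R0
#'   should be passed by the caller; fallback 8).
#' @param steps Optional integer vector of simulation steps, one per frame.
#' @return A list with `points` (track_id, charge, frame, step, x, y, psi) and
#'   `tracks` (track_id, charge, birth, death, lifetime in frames).
#' @export
track_defects <- function(detections, lattice, gate = 8, steps = NULL) {
  nf <- length(detections)
  if (nf < 1) stop("need at least one frame of detections")
  if (is.null(steps)) steps <- seq_len(nf)
  pts <- list(); active <- list(); next_id <- 1L
  for (f in seq_len(nf)) {
    det <- detections[[f]]
    assigned <- rep(FALSE, nrow(det))
    if (length(active) && nrow(det)) {
      cand <- list()
      for (ai in seq_along(active)) {
        tr <- active[[ai]]
        for (di in seq_len(nrow(det))) {
          if (det$charge[di] != tr$charge) next
          d <- periodic_distance(c(tr$x, tr$y), c(det$x[di], det$y[di]), lattice)
          if (d <= gate) cand[[length(cand) + 1L]] <- c(ai, di, d)
        }
      }
      if (length(cand)) {
        cand <- do.call(rbind, cand)
        cand <- cand[order(cand[, 3]), , drop = FALSE]
        used_a <- logical(length(active)); used_d <- logical(nrow(det))
        for (r in seq_len(nrow(cand))) {
          ai <- cand[r, 1]; di <- cand[r, 2]
          if (used_a[ai] || used_d[di]) next
          used_a[ai] <- TRUE; used_d[di] <- TRUE
          active[[ai]]$x <- det$x[di]; active[[ai]]$y <- det$y[di]
          active[[ai]]$last <- f
          pts[[length(pts) + 1L]] <- data.frame(
            track_id = active[[ai]]$id, charge = det$charge[di], frame = f,
            step = steps[f], x = det$x[di], y = det$y[di], psi = det$psi[di])
          assigned[di] <- TRUE
        }
      }
    }
    # retire tracks not matched this frame
    if (length(active))
      active <- Filter(function(tr) tr$last == f, active)
    # new tracks from unmatched detections
    for (di in which(!assigned)) {
      tr <- list(id = next_id, charge = det$charge[di],
                 x = det$x[di], y = det$y[di], last = f)
      next_id <- next_id + 1L
      active[[length(active) + 1L]] <- tr
      pts[[length(pts) + 1L]] <- data.frame(
        track_id = tr$id, charge = det$charge[di], frame = f, step = steps[f],
        x = det$x[di], y = det$y[di], psi = det$psi[di])
    }
  }
  points <- if (length(pts)) do.call(rbind, pts) else
    data.frame(track_id = integer(0), charge = numeric(0), frame = integer(0),
               step = integer(0), x = numeric(0), y = numeric(0),
               psi = numeric(0))
  tracks <- if (nrow(points)) {
    agg <- split(points, points$track_id)
    do.call(rbind, lapply(agg, function(d) data.frame(
      track_id = d$track_id[1], charge = d$charge[1],
      birth = min(d$frame), death = max(d$frame),
      lifetime = max(d$frame) - min(d$frame) + 1L)))
  } else data.frame(track_id = integer(0), charge = numeric(0),
                    birth = integer(0), death = integer(0),
                    lifetime = integer(0))
  list(points = points, tracks = tracks)
}

# Reference overlap integral of an ideally tangent droplet pair, used to
# calibrate the neighbor-graph threshold.  Cached per (R0, lambda).
.overlap_cache <- new.env(parent = emptyenv())

tangent_pair_overlap <- function(R0, lambda, a0 = 1) {
  key <- paste(R0, lambda, a0, sep = "_")
  if (!is.null(.overlap_cache[[key]])) return(.overlap_cache[[key]])
  half <- ceiling(R0 + 6 * lambda)
  n <- as.integer(2 * half + 2 * R0 + 8)
  lat <- lattice_spec(max(n, 8L), max(2L * half + 8L, 8L), max(2L * half + 8L, 8L),
                      a0 = a0)
  ctr <- c(lat$Lx / 2, lat$Ly / 2, lat$Lz / 2)
  c1 <- new_cell_field(1L, lat, ctr - c(R0, 0, 0), R0, lambda)
  c2 <- new_cell_field(2L, lat, ctr + c(R0, 0, 0), R0, lambda)
  v <- cpp_pair_overlap(c1$phi, dim(c1$phi), c1$offset,
                        c2$phi, dim(c2$phi), c2$offset, gdim(lat)) * a0^3
  .overlap_cache[[key]] <- v
  v
}

#' Neighbor graph from phase-field overlaps
#'
#' Two cells are neighbors iff their whole-body overlap integral
#' `int phi_i^2 phi_j^2 dx` exceeds a threshold; the coordination number z of
#' a cell is its degree. Cells with z = 5 / z = 7 are fivefold / sevenfold
#' disclinations. The default threshold is `1e-3` times the overlap of an
#' ideally tangent pair of relaxed droplets, which makes the edge criterion
#' insensitive to the threshold over about two decades.
#'
#' @param state A `monolayer_state`.
#' @param overlap_threshold Edge threshold on the overlap integral.
#' @return A list of class `neighbor_graph`: `edges` (i, j, weight), `z`
#'   (coordination per cell id), `threshold`.
#' @export
neighbor_graph <- function(state, overlap_threshold = NULL) {
  lat <- state$lattice
  if (is.null(overlap_threshold))
    overlap_threshold <- 1e-3 * tangent_pair_overlap(state$R0, state$lambda, lat$a0)
  cells <- Filter(function(c) !c$removed, state$cells)
  n <- length(cells)
  ids <- vapply(cells, `[[`, integer(1), "id")
  coms <- t(vapply(cells, `[[`, numeric(3), "com"))
  # support radius bound for the pre-filter
  rs <- state$R0 + state$lambda * atanh(1 - 2 * .support_thr) + 2 * lat$a0
  edges <- list()
  z <- stats::setNames(integer(n), ids)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        if (periodic_distance(coms[i, ], coms[j, ], lat) > 2 * rs) next
        w <- cpp_pair_overlap(cells[[i]]$phi, dim(cells[[i]]$phi), cells[[i]]$offset,
                              cells[[j]]$phi, dim(cells[[j]]$phi), cells[[j]]$offset,
                              gdim(lat)) * lat$a0^3
        if (w > overlap_threshold) {
          edges[[length(edges) + 1L]] <- data.frame(i = ids[i], j = ids[j], w = w)
          z[as.character(ids[i])] <- z[as.character(ids[i])] + 1L
          z[as.character(ids[j])] <- z[as.character(ids[j])] + 1L
        }
      }
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(i = integer(0), j = integer(0), w = numeric(0))
  structure(list(edges = edges, z = z, threshold = overlap_threshold),
            class = "neighbor_graph")
}

#' Lewis-law diagnostics
#'
#' Tabulates the normalized mean basal area per coordination class against the
#' linear Lewis relation `(z - 2) / 4` and the quadratic relation `(z / 6)^2`.
#'
#' @param z Integer coordination numbers, one per cell.
#' @param areas Basal areas, one per cell.
#' @return A data.frame with columns `z`, `n`, `area_ratio`, `linear`,
#'   `quadratic`.
#' @export
lewis_law_stats <- function(z, areas) {
  keep <- !is.na(z) & !is.na(areas) & areas > 0
  z <- z[keep]; areas <- areas[keep]
  if (length(unique(z)) < 2) stop("need at least 2 distinct coordination classes")
  abar <- mean(areas)
  classes <- sort(unique(z))
  data.frame(z = classes,
             n = vapply(classes, function(k) sum(z == k), integer(1)),
             area_ratio = vapply(classes, function(k) mean(areas[z == k]) / abar,
                                 numeric(1)),
             linear = (classes - 2) / 4,
             quadratic = (classes / 6)^2)
}

#' Lewis-law predictions
#'
#' @param z Coordination number(s).
#' @return data.frame with the linear `(z-2)/4` and quadratic `(z/6)^2`
#'   normalized-area predictions.
#' @export
lewis_law_predictions <- function(z) {
  data.frame(z = z, linear = (z - 2) / 4, quadratic = (z / 6)^2)
}

#' Minimum extrusion-to-defect distance per event
#'
#' For each extrusion event and each defect charge separately, the minimum
#' over a normalized-time window around the extrusion of the periodic
#' in-plane distance between the extruding cell's center of mass and any
#' same-charge defect, divided by R0. Windows without defects of a sign give
#' a missing value, not zero.
#'
#' @param traj An `mpf_trajectory`.
#' @param tracks A [track_defects()] result (its `points` carry steps).
#' @param events Extrusion events; default `traj$events`.
#' @param window Window in units of tau0 relative to the extrusion time
#'   (default `c(-5.625, 0.625)`).
#' @return data.frame with `cell_id`, `step`, `dmin_plus`, `dmin_minus`
#'   (normalized by R0; NA when missing).
#' @export
min_distance_series <- function(traj, tracks, events = traj$events,
                                window = c(-5.625, 0.625)) {
  lat <- traj$config$lattice
  pts <- tracks$points
  out <- lapply(seq_len(nrow(events)), function(r) {
    ev <- events[r, ]
    tlo <- ev$t_norm + window[1]; thi <- ev$t_norm + window[2]
    tnorm <- pts$step * traj$dt / traj$tau0
    sel <- pts[tnorm >= tlo & tnorm <= thi, , drop = FALSE]
    dmin_for <- function(chg) {
      sub <- sel[sel$charge == chg, , drop = FALSE]
      if (!nrow(sub)) return(NA_real_)
      d <- vapply(seq_len(nrow(sub)), function(k) {
        rowidx <- match(sub$step[k], traj$steps)
        pos <- traj$com[rowidx, ev$cell_id, 1:2]
        periodic_distance(pos, c(sub$x[k], sub$y[k]), lat)
      }, numeric(1))
      min(d, na.rm = TRUE) / traj$R0
    }
    data.frame(cell_id = ev$cell_id, step = ev$step,
               dmin_plus = dmin_for(0.5), dmin_minus = dmin_for(-0.5))
  })
  if (!length(out))
    return(data.frame(cell_id = integer(0), step = integer(0),
                      dmin_plus = numeric(0), dmin_minus = numeric(0)))
  do.call(rbind, out)
}

#' Coordination history of extruding cells
#'
#' Time-average of an extruding cell's coordination number over a window in
#' normalized time around its extrusion.
#'
#' @param traj An `mpf_trajectory` with analysis frames.
#' @param events Extrusion events; default `traj$events`.
#' @param window Window in units of tau0 (default `c(-2.5, 0.3125)`).
#' @return data.frame with `cell_id`, `zbar`, `n_frames`, `clipped` (TRUE if
#'   the window extended beyond the available frames).
#' @export
coordination_history <- function(traj, events = traj$events,
                                 window = c(-2.5, 0.3125)) {
  frames <- traj$frames
  fsteps <- vapply(frames, `[[`, numeric(1), "step")
  ftimes <- fsteps * traj$dt / traj$tau0
  out <- lapply(seq_len(nrow(events)), function(r) {
    ev <- events[r, ]
    tlo <- ev$t_norm + window[1]; thi <- ev$t_norm + window[2]
    sel <- which(ftimes >= tlo & ftimes <= thi)
    clipped <- length(ftimes) > 0 &&
      (tlo < min(ftimes) - 1e-12 || thi > max(ftimes) + 1e-12)
    zs <- vapply(sel, function(f) {
      zv <- frames[[f]]$z
      as.numeric(zv[as.character(ev$cell_id)])
    }, numeric(1))
    zs <- zs[!is.na(zs)]
    data.frame(cell_id = ev$cell_id,
               zbar = if (length(zs)) mean(zs) else NA_real_,
               n_frames = length(zs), clipped = clipped)
  })
  if (!length(out))
    return(data.frame(cell_id = integer(0), zbar = numeric(0),
                      n_frames = integer(0), clipped = logical(0)))
  do.call(rbind, out)
}
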