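#' Dynamical parameters
#'
#' Parameters of the over-damped force balance and the contact-inhibition-of-
#' locomotion (CIL) polarity dynamics: cell velocity
#' `v_i = (t_i + alpha p_i) / xi` with traction `t_i` and in-plane polarity
#' `p_i = (cos theta_i, sin theta_i, 0)`, and
#' `d theta_i = -J |t_i| dtheta_i dt + sqrt(2 Dr dt) N(0,1)` with `dtheta_i`
#' the signed deviation of the polarity from the in-plane traction direction.
#' The intrinsic time unit is `tau0 = xi R0 / alpha`.
#'
#' @param xi Substrate friction (> 0).
#' @param alpha Polarity (self-propulsion) force strength (> 0; set the
#'   simulation's `active = FALSE` phases rather than alpha = 0 here if you
#'   need a passive run with a defined tau0).
#' @param J Alignment rate constant (>= 0).
#' @param Dr Rotational diffusivity (>= 0).
#' @param dt Time step (> 0).
#' @param n_steps Number of production steps.
#' @param R0 Cell radius used for tau0.
#' @param seed Integer seed.
#' @return An object of class `dynamics_params` with derived `tau0`.
#' @export
dynamics_params <- function(xi = 1, alpha = 0.1, J = 0.2, Dr = 0.005,
                            dt = 0.25, n_steps = 1000L, R0 = 8, seed = 1L,
                            advect = c("upwind", "central")) {
  stopifnot(xi > 0, dt >= 0, J >= 0, Dr >= 0, alpha >= 0)
  advect <- match.arg(advect)
  tau0 <- if (alpha > 0) xi * R0 / alpha else Inf
  structure(list(xi = xi, alpha = alpha, J = J, Dr = Dr, dt = dt,
                 n_steps = as.integer(n_steps), R0 = R0, seed = as.integer(seed),
                 advect = advect, tau0 = tau0),
            class = "dynamics_params")
}

#' @export
print.dynamics_params <- function(x, ...) {
  cat(sprintf("<dynamics_params> xi=%g alpha=%g J=%g Dr=%g dt=%g n_steps=%d tau0=%g\n",
              x$xi, x$alpha, x$J, x$Dr, x$dt, x$n_steps, x$tau0))
  invisible(x)
}

# Tractions and velocities for every live cell of a state.
# The interaction tensor is isotropic, Pi_int = (sum_j -dF/dphi_j) * Identity,
# so div(Pi_int) = grad(pi) with pi the summed negative functional derivative;
# t_i = integral phi_i grad(pi) dx.
monolayer_forces <- function(state, energy_params, alpha = 0, xi = 1,
                             cache = NULL, keep_fields = FALSE) {
  lat <- state$lattice; a0 <- lat$a0; gd <- gdim(lat)
  if (is.null(cache)) cache <- energy_cache(state)
  n <- length(state$cells)
  pi_field <- numeric(prod(gd))
  dFs <- vector("list", n)
  p <- energy_params
  for (i in seq_len(n)) {
    cell <- state$cells[[i]]
    if (cell$removed) next
    Vi <- cpp_sumsq(cell$phi) * a0^3
    dF <- cpp_func_deriv_fused(cell$phi, dim(cell$phi), cell$offset, gd,
                               cache$S2, cache$lapS,
                               state$substrate$phiw2, state$substrate$d2z,
                               8 * p$gamma / p$lambda,
                               2 * p$gamma * p$lambda / a0^2,
                               4 * p$mu / p$V0 * (1 - Vi / p$V0),
                               4 * p$kappa_cc / p$lambda,
                               2 * p$omega_cc * p$lambda^2 / a0^2,
                               2 * p$kappa_cw / p$lambda,
                               p$omega_cw * p$lambda^2 / a0^2,
                               pi_field)
    dFs[[i]] <- array(dF, dim = dim(cell$phi))
  }
  g <- cpp_grad_global(pi_field, gd)
  tr <- matrix(NA_real_, n, 3)
  vel <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    cell <- state$cells[[i]]
    if (cell$removed) next
    tr[i, ] <- cpp_weighted_grad_sum(cell$phi, dim(cell$phi), cell$offset,
                                     g$gx, g$gy, g$gz, gd) * a0^3 / a0
    vel[i, ] <- (tr[i, ] + alpha * c(cos(cell$theta), sin(cell$theta), 0)) / xi
  }
  out <- list(tractions = tr, velocities = vel, dFs = dFs, cache = cache)
  if (keep_fields) {
    out$pi_field <- pi_field
    out$grad_pi <- lapply(g, function(v) v / a0)
  }
  out
}

#' Interaction traction on one cell
#'
#' `t_i = int phi_i  grad(Pi_int) dx` with the isotropic interaction tensor
#' `Pi_int = (sum_j -dF/dphi_j) I`. The traction balances friction against
#' self-propulsion in the over-damped force balance
#' `t_i = xi v_i - alpha p_i`.
#'
#' @param state A `monolayer_state`.
#' @param params An [energy_params()].
#' @param cell_id Cell id.
#' @return Numeric length-3 traction vector.
#' @export
interaction_traction <- function(state, params, cell_id) {
  f <- monolayer_forces(state, params)
  ids <- vapply(state$cells, `[[`, integer(1), "id")
  pos <- match(as.integer(cell_id), ids)
  if (is.na(pos)) stop("unknown cell id: ", cell_id)
  f$tractions[pos, ]
}

#' Cell velocity from the over-damped force balance
#'
#' `v_i = (t_i + alpha p_i) / xi`, with the polarity `p_i` strictly in-plane;
#' out-of-plane velocity enters only through the traction.
#'
#' @param t_i Length-3 traction vector.
#' @param theta Polarity angle.
#' @param params A [dynamics_params()] (uses `alpha` and `xi`).
#' @return Length-3 velocity.
#' @export
cell_velocity <- function(t_i, theta, params) {
  (t_i + params$alpha * c(cos(theta), sin(theta), 0)) / params$xi
}

#' Advance all cell fields one time step
#'
#' Explicit Euler update of the advected gradient flow
#' `d phi_i / dt = -v_i . grad(phi_i) - dF/dphi_i` with first-order upwind
#' advection at the rigid per-cell velocity. Subdomains are re-boxed so the
#' diffuse interface never touches their edges. With `dt = 0` the state is
#' returned unchanged.
#'
#' @param state A `monolayer_state`.
#' @param energy_params An [energy_params()].
#' @param dyn_params A [dynamics_params()].
#' @param forces Optional precomputed [monolayer_forces()] result.
#' @return The advanced state, with the step's tractions and velocities
#'   attached as `state$tractions` / `state$velocities`.
#' @export
advance_fields <- function(state, energy_params, dyn_params, forces = NULL) {
  if (dyn_params$dt == 0) return(state)
  lat <- state$lattice; a0 <- lat$a0
  if (is.null(forces))
    forces <- monolayer_forces(state, energy_params,
                               alpha = dyn_params$alpha, xi = dyn_params$xi)
  dt <- dyn_params$dt
  vmax <- max(abs(forces$velocities), na.rm = TRUE)
  if (vmax * dt / a0 >= 1)
    stop(sprintf("stability error at step %d: max |v| dt / a0 = %.3g >= 1",
                 state$step, vmax * dt / a0))
  pad <- subdomain_pad(state$lambda, a0)
  cap <- subdomain_cap(state$R0, state$lambda, a0)
  for (i in seq_along(state$cells)) {
    cell <- state$cells[[i]]
    if (cell$removed) next
    v <- forces$velocities[i, ]
    phi <- cpp_advect_update(cell$phi, dim(cell$phi), forces$dFs[[i]],
                             v[1] / a0, v[2] / a0, v[3] / a0, dt,
                             identical(dyn_params$advect, "upwind"))
    stats <- cpp_field_stats(phi, dim(cell$phi), .support_thr)
    if (stats[12] > 2 || stats[11] < -2)
      stop(sprintf("numerical state error at step %d: |phi| > 2 for cell %d",
                   state$step, cell$id))
    cell$phi <- array(phi, dim = dim(cell$phi))
    if (stats[4] > 0) {
      pos <- (stats[1:3] / stats[4] + cell$offset) * a0
      cell$com <- c(pos[1] %% lat$Lx, pos[2] %% lat$Ly, pos[3])
      cell <- regrow_cell(cell, lat, pad, cap, stats)
    }
    state$cells[[i]] <- cell
  }
  state$tractions <- forces$tractions
  state$velocities <- forces$velocities
  state$step <- state$step + 1L
  state$time <- state$time + dt
  state
}

#' CIL polarity update
#'
#' Rotates each polarity angle toward the in-plane direction of its traction
#' at rate `J |t_i|`, plus rotational diffusion: explicit Euler-Maruyama with
#' Ito increment `sqrt(2 Dr dt) N(0,1)`. The deviation `dtheta_i` is the
#' signed smallest angle from the in-plane traction direction to the polarity
#' (an exact tie at pi is broken toward +pi). Angles are re-wrapped to
#' `[-pi, pi]`.
#'
#' @param state A `monolayer_state` carrying `state$tractions` (set by
#'   [advance_fields()]).
#' @param dyn_params A [dynamics_params()].
#' @return The state with updated polarity angles.
#' @export
update_polarity <- function(state, dyn_params) {
  tr <- state$tractions
  if (is.null(tr)) stop("no tractions available: call advance_fields() first")
  dt <- dyn_params$dt
  n <- length(state$cells)
  noise <- if (dyn_params$Dr > 0)
    sqrt(2 * dyn_params$Dr * dt) * stats::rnorm(n) else numeric(n)
  for (i in seq_len(n)) {
    cell <- state$cells[[i]]
    if (cell$removed) next
    tx <- tr[i, 1]; ty <- tr[i, 2]
    tmag <- sqrt(sum(tr[i, ]^2))
    dtheta <- if (tx == 0 && ty == 0) 0 else
      atan2(tx * sin(cell$theta) - ty * cos(cell$theta),
            tx * cos(cell$theta) + ty * sin(cell$theta))
    th <- cell$theta - dt * dyn_params$J * tmag * dtheta + noise[i]
    state$cells[[i]]$theta <- wrap_angle(th)
  }
  state
}

# Pure gradient-flow relaxation: advection switched off, step size limited so
# the field update stays well inside the stability region.
relax_state <- function(state, energy_params, dyn_params, n_steps) {
  for (s in seq_len(n_steps)) {
    f <- monolayer_forces(state, energy_params, alpha = 0, xi = dyn_params$xi)
    f$velocities[] <- 0
    dmax <- max(vapply(f$dFs, function(d) if (is.null(d)) 0 else max(abs(d)),
                       numeric(1)), 1e-12)
    dpr <- dyn_params
    dpr$dt <- min(dyn_params$dt, 0.5 / dmax)
    state <- advance_fields(state, energy_params, dpr, forces = f)
  }
  state$step <- 0L
  state$time <- 0
  state
}

# wrap to [-pi, pi]
wrap_angle <- function(th) {
  th <- (th + pi) %% (2 * pi) - pi
  th
}

#' Detect extrusion events from a center-of-mass history
#'
#' A cell extrudes when its vertical center-of-mass displacement, relative to
#' the median height of the other (not-yet-extruded) cells, first exceeds
#' `R0 / 2`. The median makes the reference robust to the extruding cell
#' itself; extruded cells are excluded from the reference thereafter.
#'
#' @param z Either an `mpf_trajectory` (from [run_simulation()]) or a numeric
#'   matrix of z centers of mass with one row per frame and one column per
#'   cell.
#' @param R0 Initial cell radius (taken from the trajectory when available).
#' @return A data.frame with one row per event: `cell_id`, `t_e` (frame
#'   index, 1-based), and (when the input is a trajectory) `step`, `t_norm`,
#'   `x`, `y`, `z`.
#' @export
detect_extrusions <- function(z, R0 = NULL) {
  traj <- NULL
  if (inherits(z, "mpf_trajectory")) {
    traj <- z
    if (is.null(R0)) R0 <- traj$R0
    z <- traj$com[, , 3, drop = TRUE]
    if (is.null(dim(z))) z <- matrix(z, ncol = 1)
  }
  if (is.null(R0)) stop("R0 required")
  if (nrow(z) < 2) stop("need at least 2 frames of centers of mass")
  n <- ncol(z)
  extruded <- rep(FALSE, n)
  ev <- list()
  for (f in seq_len(nrow(z))) {
    ref <- stats::median(z[f, !extruded], na.rm = TRUE)
    if (!is.finite(ref)) break
    crossing <- which(!extruded & !is.na(z[f, ]) & (z[f, ] - ref > R0 / 2))
    for (i in crossing) {
      extruded[i] <- TRUE
      ev[[length(ev) + 1]] <- data.frame(cell_id = i, t_e = f)
    }
  }
  out <- if (length(ev)) do.call(rbind, ev) else
    data.frame(cell_id = integer(0), t_e = integer(0))
  if (!is.null(traj) && nrow(out) > 0) {
    out$step <- traj$steps[out$t_e]
    out$t_norm <- out$step * traj$dt / traj$tau0
    out$x <- traj$com[cbind(out$t_e, out$cell_id, 1)]
    out$y <- traj$com[cbind(out$t_e, out$cell_id, 2)]
    out$z <- traj$com[cbind(out$t_e, out$cell_id, 3)]
  }
  out
}

#' Run a monolayer simulation
#'
#' Orchestrates the field update, polarity update, extrusion bookkeeping and
#' periodic analysis snapshots. A short passive relaxation (alpha = 0, no
#' polarity dynamics) precedes the production run so that the seeded droplet
#' shape is forgotten. Fully reproducible from the seed.
#'
#' @param config A run configuration, see [run_config()]. Alternatively a
#'   ready `monolayer_state` may be passed via `state` with parameters given
#'   in `config`.
#' @param state Optional pre-initialized `monolayer_state`.
#' @param progress Print progress every this many steps (0 = silent).
#' @return An object of class `mpf_trajectory`: recorded centers of mass and
#'   polarity angles per step, extrusion `events`, analysis `frames` at the
#'   snapshot cadence, and the final state.
#' @export
run_simulation <- function(config, state = NULL, progress = 0) {
  config <- validate_config(config)
  ep <- config$energy; dp <- config$dynamics
  set.seed(dp$seed)
  lat <- config$lattice
  if (is.null(state))
    state <- initialize_monolayer(lat, config$n_cells, config$R0,
                                  lambda = ep$lambda, jitter = config$jitter)
  n <- length(state$cells)

  # passive shape relaxation (pure gradient flow, no advection): the seeded
  # droplets start far from stationarity, which would otherwise translate
  # into large spurious startup tractions
  if (config$n_relax > 0) state <- relax_state(state, ep, dp, config$n_relax)

  n_steps <- dp$n_steps
  n_rec <- n_steps + 1L
  com <- array(NA_real_, c(n_rec, n, 3))
  theta <- matrix(NA_real_, n_rec, n)
  steps <- integer(n_rec)
  frames <- list()
  events <- list()
  extruded <- vapply(state$cells, `[[`, logical(1), "extruded")

  record <- function(r, state) {
    com[r, , ] <<- state_coms(state)
    theta[r, ] <<- vapply(state$cells, `[[`, numeric(1), "theta")
    steps[r] <<- state$step
  }
  record(1L, state)

  snap_due <- function(step) config$snapshot_every > 0 &&
    step %% config$snapshot_every == 0

  for (s in seq_len(max(n_steps, 0L))) {
    f <- monolayer_forces(state, ep, alpha = dp$alpha, xi = dp$xi,
                          keep_fields = snap_due(state$step))
    if (snap_due(state$step))
      frames[[length(frames) + 1L]] <- analyze_frame(state, f, config)
    state <- advance_fields(state, ep, dp, forces = f)
    state <- update_polarity(state, dp)
    record(s + 1L, state)

    # online extrusion bookkeeping at step resolution
    zs <- com[s + 1L, , 3]
    ref <- stats::median(zs[!extruded & !is.na(zs)])
    newly <- which(!extruded & !is.na(zs) & (zs - ref > config$R0 / 2))
    for (i in newly) {
      extruded[i] <- TRUE
      state$cells[[i]]$extruded <- TRUE
      events[[length(events) + 1L]] <- data.frame(
        cell_id = i, step = state$step,
        t_norm = state$step * dp$dt / dp$tau0,
        x = com[s + 1L, i, 1], y = com[s + 1L, i, 2], z = com[s + 1L, i, 3])
      if (isTRUE(config$remove_extruded)) state$cells[[i]]$removed <- TRUE
    }
    if (progress > 0 && s %% progress == 0)
      message(sprintf("step %d / %d (%d extruded)", s, n_steps, sum(extruded)))
  }
  # analyse the final state too when it falls on the cadence
  if (snap_due(state$step)) {
    f <- monolayer_forces(state, ep, alpha = dp$alpha, xi = dp$xi,
                          keep_fields = TRUE)
    frames[[length(frames) + 1L]] <- analyze_frame(state, f, config)
  }

  events <- if (length(events)) do.call(rbind, events) else
    data.frame(cell_id = integer(0), step = integer(0), t_norm = numeric(0),
               x = numeric(0), y = numeric(0), z = numeric(0))
  structure(list(config = config, R0 = config$R0, dt = dp$dt, tau0 = dp$tau0,
                 steps = steps, com = com, theta = theta,
                 events = events, frames = frames, final_state = state),
            class = "mpf_trajectory")
}

#' @export
print.mpf_trajectory <- function(x, ...) {
  cat(sprintf("<mpf_trajectory> %d cells, %d steps recorded, %d events, %d frames\n",
              dim(x$com)[2], length(x$steps) - 1L, nrow(x$events),
              length(x$frames)))
  invisible(x)
}

# One analysis snapshot: basal footprints, shape orientation, neighbor graph,
# coarse-grained stress and its per-cell region means.
analyze_frame <- function(state, forces, config) {
  fr <- list(step = state$step, time = state$time,
             coms = state_coms(state),
             theta = vapply(state$cells, `[[`, numeric(1), "theta"),
             extruded = vapply(state$cells, `[[`, logical(1), "extruded"))
  fp <- basal_projection(state)
  orient <- footprint_orientations(fp, state$lattice)
  fr$orient <- orient
  g <- neighbor_graph(state, overlap_threshold = config$overlap_threshold)
  fr$edges <- g$edges
  fr$z <- g$z
  if (isTRUE(config$analyze_stress)) {
    td <- list(Tx = forces$cache$S * forces$grad_pi$gx,
               Ty = forces$cache$S * forces$grad_pi$gy,
               Tz = forces$cache$S * forces$grad_pi$gz)
    sf <- coarse_grained_stress(td, state$lattice, config$l_stress)
    maps <- isotropic_and_shear_maps(sf)
    fr$sigma_iso <- maps$iso
    fr$sigma_xz <- maps$xz
    fr$stress_meta <- list(b = sf$b, cdim = sf$cdim)
    basal_k <- basal_coarse_index(state, sf$b)
    fr$sigma_iso_basal <- maps$iso[, , basal_k]
    fr$sigma_xz_basal <- maps$xz[, , basal_k]
    rm <- stress_region_means(state, sf, maps)
    fr$iso_cell_mean <- rm$iso_cell
    fr$xz_cell_mean <- rm$xz_cell
    fr$iso_union_mean <- rm$iso_union
    fr$xz_union_mean <- rm$xz_union
  }
  fr
}
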