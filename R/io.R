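.config_keys <- c(
  "nx", "ny", "nz", "a0", "n_cells", "R0", "lambda",
  "gamma", "mu", "kappa_cc", "kappa_cw", "omega_cc", "omega_cw", "Omega",
  "xi", "alpha", "J", "Dr", "dt", "n_steps", "seed",
  "n_relax", "snapshot_every", "jitter", "overlap_threshold",
  "analyze_stress", "l_dir", "l_stress", "remove_extruded")

#' Build a run configuration
#'
#' Bundles lattice geometry, energetic and dynamical parameters, and analysis
#' options into one validated record. All lengths are in units of the grid
#' spacing; `Omega`, when given, sets `omega_cc = Omega * omega_cw`.
#'
#' @param nx,ny,nz,a0 Lattice geometry (see [lattice_spec()]).
#' @param n_cells,R0,lambda Monolayer seeding parameters.
#' @param gamma,mu,kappa_cc,kappa_cw,omega_cc,omega_cw,Omega Energy
#'   parameters (see [energy_params()]).
#' @param xi,alpha,J,Dr,dt,n_steps,seed Dynamics parameters (see
#'   [dynamics_params()]).
#' @param n_relax Passive relaxation steps before production.
#' @param snapshot_every Analysis cadence in steps (0 disables frames).
#' @param jitter In-plane seeding jitter half-width.
#' @param overlap_threshold Neighbor-graph threshold (NULL = calibrated
#'   default).
#' @param analyze_stress Compute coarse-grained stress at each snapshot.
#' @param l_dir Director coarse-graining length (default R0).
#' @param l_stress Stress coarse-graining length (default R0/4).
#' @param remove_extruded Remove extruded cells from the dynamics (default
#'   FALSE: they keep evolving and detach naturally).
#' @return An object of class `run_config`.
#' @export
run_config <- function(nx = 320L, ny = 320L, nz = 64L, a0 = 1,
                       n_cells = 400L, R0 = 8, lambda = 2,
                       gamma = 0.08, mu = 300, kappa_cc = 0.1, kappa_cw = 0.05,
                       omega_cw = 0.0025, omega_cc = NULL, Omega = 0.4,
                       xi = 1, alpha = 0.1, J = 0.2, Dr = 0.005,
                       dt = 0.25, n_steps = 29000L, seed = 1L,
                       n_relax = 100L, snapshot_every = 50L, jitter = 0,
                       overlap_threshold = NULL, analyze_stress = TRUE,
                       l_dir = R0, l_stress = max(R0 / 4, 2 * a0),
                       remove_extruded = FALSE) {
  if (is.null(omega_cc)) omega_cc <- Omega * omega_cw
  lattice <- lattice_spec(nx, ny, nz, a0)
  energy <- energy_params(gamma = gamma, lambda = lambda, mu = mu, R0 = R0,
                          kappa_cc = kappa_cc, kappa_cw = kappa_cw,
                          omega_cw = omega_cw, omega_cc = omega_cc)
  dynamics <- dynamics_params(xi = xi, alpha = alpha, J = J, Dr = Dr, dt = dt,
                              n_steps = n_steps, R0 = R0, seed = seed)
  cfg <- structure(list(lattice = lattice, energy = energy, dynamics = dynamics,
                        n_cells = as.integer(n_cells), R0 = R0,
                        n_relax = as.integer(n_relax),
                        snapshot_every = as.integer(snapshot_every),
                        jitter = jitter, overlap_threshold = overlap_threshold,
                        analyze_stress = isTRUE(analyze_stress),
                        l_dir = l_dir, l_stress = l_stress,
                        remove_extruded = isTRUE(remove_extruded)),
                   class = "run_config")
  validate_config(cfg)
}

validate_config <- function(config) {
  if (!inherits(config, "run_config")) stop("config must be a run_config object")
  stopifnot(config$n_cells >= 1, config$R0 >= 4 * config$lattice$a0,
            config$n_relax >= 0, config$snapshot_every >= 0)
  if (config$l_stress < 2 * config$lattice$a0)
    stop("l_stress must be >= 2 * a0")
  Om <- adhesion_ratio(config$energy)
  if (is.finite(Om) && !any(abs(Om - c(0.2, 0.4, 0.6)) < 1e-12))
    message(sprintf("note: Omega = %g is outside the canonical sweep {0.2, 0.4, 0.6}", Om))
  if (!any(abs(config$energy$omega_cw - c(0.0015, 0.002, 0.0025)) < 1e-12))
    message(sprintf("note: omega_cw = %g is outside the canonical sweep {0.0015, 0.002, 0.0025}",
                    config$energy$omega_cw))
  config
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf("<run_config> %dx%dx%d lattice, %d cells (R0=%g), %d steps, Omega=%.3g\n",
              x$lattice$nx, x$lattice$ny, x$lattice$nz, x$n_cells, x$R0,
              x$dynamics$n_steps, adhesion_ratio(x$energy)))
  invisible(x)
}

# flatten a run_config to the scalar key set
config_to_keys <- function(config) {
  list(nx = config$lattice$nx, ny = config$lattice$ny, nz = config$lattice$nz,
       a0 = config$lattice$a0, n_cells = config$n_cells, R0 = config$R0,
       lambda = config$energy$lambda, gamma = config$energy$gamma,
       mu = config$energy$mu, kappa_cc = config$energy$kappa_cc,
       kappa_cw = config$energy$kappa_cw, omega_cc = config$energy$omega_cc,
       omega_cw = config$energy$omega_cw,
       xi = config$dynamics$xi, alpha = config$dynamics$alpha,
       J = config$dynamics$J, Dr = config$dynamics$Dr,
       dt = config$dynamics$dt, n_steps = config$dynamics$n_steps,
       seed = config$dynamics$seed, n_relax = config$n_relax,
       snapshot_every = config$snapshot_every, jitter = config$jitter,
       overlap_threshold = config$overlap_threshold,
       analyze_stress = config$analyze_stress, l_dir = config$l_dir,
       l_stress = config$l_stress, remove_extruded = config$remove_extruded)
}

#' Write a run configuration to a plain-text file
#'
#' @param config A [run_config()].
#' @param path Output path (YAML key-value text).
#' @return The path, invisibly.
#' @export
write_config <- function(config, path) {
  keys <- config_to_keys(config)
  keys <- keys[!vapply(keys, is.null, logical(1))]
  yaml::write_yaml(keys, path)
  invisible(path)
}

#' Load a run configuration from a plain-text file
#'
#' Unknown keys are rejected; missing keys take the documented defaults.
#' Out-of-range values raise an error naming the key; parameter values
#' outside the canonical sweep are accepted with a notice.
#'
#' @param path Path to a YAML key-value file.
#' @return A validated [run_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  keys <- yaml::read_yaml(path)
  unknown <- setdiff(names(keys), .config_keys)
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in c("xi", "dt", "gamma", "mu", "R0"))
    if (!is.null(keys[[k]]) && keys[[k]] <= 0)
      stop("config error: key '", k, "' must be positive")
  if (!is.null(keys$alpha) && keys$alpha < 0)
    stop("config error: key 'alpha' must be non-negative")
  do.call(run_config, keys)
}

#' Built-in scenarios
#'
#' Seed-deterministic fixture configurations exercising the model's canonical
#' behaviors:
#' * `passive_hex_relax`: 12 passive cells started from a jittered square
#'   lattice; relaxes toward a hexagonal packing (modal coordination 6).
#' * `two_cell_adhesion`: an overlapping pair with tunable adhesion ratio.
#' * `small_active_monolayer`: a reduced active monolayer with the production
#'   parameter ratios.
#' * `production_scale`: the full production configuration (320 x 320 x 64, 400
#'   cells, 29,000 steps).
#'
#' @param name Scenario name.
#' @param seed Integer seed.
#' @param ... Overrides passed to [run_config()].
#' @return A list of class `scenario` with `name`, `config` and the initial
#'   `state`.
#' @export
make_scenario <- function(name = c("passive_hex_relax", "two_cell_adhesion",
                                   "small_active_monolayer", "production_scale"),
                          seed = 1L, ...) {
  name <- match.arg(name)
  ov <- list(...)
  base <- switch(name,
    passive_hex_relax = list(nx = 48L, ny = 42L, nz = 24L, n_cells = 12L,
                             R0 = 6, alpha = 0, J = 0, Dr = 0,
                             n_steps = 2000L, n_relax = 150L, jitter = 1.5,
                             snapshot_every = 0L, analyze_stress = FALSE,
                             l_dir = 6, l_stress = 2, seed = seed),
    two_cell_adhesion = list(nx = 48L, ny = 44L, nz = 24L, n_cells = 2L,
                             R0 = 6, alpha = 0, J = 0, Dr = 0,
                             n_steps = 500L, n_relax = 150L,
                             snapshot_every = 0L, analyze_stress = FALSE,
                             l_dir = 6, l_stress = 2, seed = seed),
    small_active_monolayer = list(nx = 78L, ny = 78L, nz = 24L, n_cells = 36L,
                                  R0 = 6, n_steps = 2000L, n_relax = 100L,
                                  jitter = 1, snapshot_every = 50L,
                                  l_dir = 6, l_stress = 2, seed = seed),
    production_scale = list(nx = 320L, ny = 320L, nz = 64L, n_cells = 400L,
                       R0 = 8, n_steps = 29000L, n_relax = 200L,
                       snapshot_every = 100L, seed = seed))
  base[names(ov)] <- ov
  config <- suppressMessages(do.call(run_config, base))
  set.seed(seed)
  state <- if (name == "two_cell_adhesion") {
    two_cell_state(config)
  } else {
    initialize_monolayer(config$lattice, config$n_cells, config$R0,
                         lambda = config$energy$lambda, jitter = config$jitter)
  }
  structure(list(name = name, config = config, state = state),
            class = "scenario")
}

# overlapping pair along x at 1.8 R0 center distance
two_cell_state <- function(config) {
  lat <- config$lattice
  lam <- config$energy$lambda
  sub <- make_substrate(lat, interface_width = lam)
  z0 <- sub$z_surface + config$R0
  ctr <- c(lat$Lx / 2, lat$Ly / 2, z0)
  d <- config$R0  # tangent pair; adhesion decides whether contact grows
  cells <- list(
    new_cell_field(1L, lat, ctr - c(d, 0, 0), config$R0, lam, theta = 0),
    new_cell_field(2L, lat, ctr + c(d, 0, 0), config$R0, lam, theta = pi))
  for (i in 1:2) cells[[i]]$com <- center_of_mass(cells[[i]], lat)
  structure(list(lattice = lat, cells = cells, substrate = sub,
                 R0 = config$R0, lambda = lam, step = 0L, time = 0,
                 rng_state = NULL),
            class = "monolayer_state")
}

# documented key-derivation: per-run seeds from a master seed
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) + 9973 * as.numeric(index)) %% 2147483647L) + 1L
}

#' Enumerate (and optionally execute) a parameter sweep
#'
#' Runs the cross product of cell-substrate adhesion strengths and adhesion
#' ratios over several realizations, with per-run seeds derived from the
#' master seed by a fixed linear scheme so that analysis re-runs never
#' perturb simulation randomness. Completed runs (existing output files) are
#' skipped idempotently.
#'
#' @param base_config A [run_config()] template.
#' @param omega_cw_values Cell-substrate adhesion strengths.
#' @param Omega_values Adhesion ratios.
#' @param n_realizations Realizations per case.
#' @param seed Master seed.
#' @param out_dir Output directory (required when `execute = TRUE`).
#' @param execute Run the simulations (default FALSE: enumerate only).
#' @return The manifest data.frame: run id, parameters, derived seed, config
#'   hash, output path, done flag.
#' @export
run_sweep <- function(base_config, omega_cw_values = c(0.0015, 0.002, 0.0025),
                      Omega_values = c(0.2, 0.4, 0.6), n_realizations = 4,
                      seed = 1L, out_dir = NULL, execute = FALSE) {
  grid <- expand.grid(realization = seq_len(n_realizations),
                      Omega = Omega_values, omega_cw = omega_cw_values)
  if (!nrow(grid)) stop("empty sweep")
  keys <- config_to_keys(base_config)
  rows <- lapply(seq_len(nrow(grid)), function(r) {
    k <- keys
    k$omega_cw <- grid$omega_cw[r]
    k$omega_cc <- grid$Omega[r] * grid$omega_cw[r]
    k$seed <- derive_seed(seed, r)
    cfg <- suppressMessages(do.call(run_config, k))
    tf <- tempfile(fileext = ".yml"); write_config(cfg, tf)
    h <- unname(tools::md5sum(tf)); unlink(tf)
    out_path <- if (is.null(out_dir)) NA_character_ else
      file.path(out_dir, sprintf("run_%03d.rds", r))
    data.frame(run_id = r, omega_cw = grid$omega_cw[r], Omega = grid$Omega[r],
               realization = grid$realization[r], seed = k$seed,
               config_hash = h, out_path = out_path,
               done = !is.na(out_path) && file.exists(out_path))
  })
  manifest <- do.call(rbind, rows)
  if (execute) {
    if (is.null(out_dir)) stop("out_dir required to execute a sweep")
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (r in seq_len(nrow(manifest))) {
      if (manifest$done[r]) next
      k <- keys
      k$omega_cw <- manifest$omega_cw[r]
      k$omega_cc <- manifest$Omega[r] * manifest$omega_cw[r]
      k$seed <- manifest$seed[r]
      cfg <- suppressMessages(do.call(run_config, k))
      traj <- run_simulation(cfg)
      saveRDS(traj, manifest$out_path[r])
      manifest$done[r] <- TRUE
    }
  }
  manifest
}

.schema_version <- 1L

write_schema_csv <- function(df, path) {
  con <- file(path, "w")
  writeLines(sprintf("# extrudesim_schema=%d", .schema_version), con)
  utils::write.csv(df, con, row.names = FALSE)
  close(con)
  invisible(path)
}

read_schema_csv <- function(path) {
  first <- readLines(path, n = 1)
  if (!grepl("^# extrudesim_schema=", first))
    stop("not an extrudesim table (missing schema stamp): ", path)
  utils::read.csv(path, comment.char = "#")
}

#' Export trajectory tables
#'
#' Writes the cell tracks, extrusion events, defect tracks and per-frame
#' adjacency as schema-stamped CSV files that [read_tracks()] loads back
#' losslessly (to write/read precision).
#'
#' @param traj An `mpf_trajectory`.
#' @param dir Output directory (created if needed).
#' @param tracks Optional [track_defects()] result.
#' @return Named character vector of the files written.
#' @export
export_tracks <- function(traj, dir, tracks = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  n <- dim(traj$com)[2]
  cells <- do.call(rbind, lapply(seq_along(traj$steps), function(r)
    data.frame(step = traj$steps[r], cell_id = seq_len(n),
               x = traj$com[r, , 1], y = traj$com[r, , 2],
               z = traj$com[r, , 3], theta = traj$theta[r, ])))
  files["cells"] <- write_schema_csv(cells, file.path(dir, "cells.csv"))
  files["events"] <- write_schema_csv(traj$events, file.path(dir, "events.csv"))
  if (!is.null(tracks))
    files["defects"] <- write_schema_csv(tracks$points,
                                         file.path(dir, "defects.csv"))
  if (length(traj$frames)) {
    adj <- do.call(rbind, lapply(traj$frames, function(fr) {
      if (!nrow(fr$edges)) return(NULL)
      cbind(step = fr$step, fr$edges)
    }))
    if (is.null(adj))
      adj <- data.frame(step = integer(0), i = integer(0), j = integer(0),
                        w = numeric(0))
    files["adjacency"] <- write_schema_csv(adj, file.path(dir, "adjacency.csv"))
  }
  files
}

#' Read exported trajectory tables
#'
#' @param dir Directory written by [export_tracks()].
#' @return List of data.frames (those present): `cells`, `events`, `defects`,
#'   `adjacency`.
#' @export
read_tracks <- function(dir) {
  out <- list()
  for (nm in c("cells", "events", "defects", "adjacency")) {
    p <- file.path(dir, paste0(nm, ".csv"))
    if (file.exists(p)) out[[nm]] <- read_schema_csv(p)
  }
  out
}

#' Write 3D scalar fields as a legacy-ASCII VTK structured-points file
#'
#' For visualization of volumetric output (e.g. the global phase field or
#' stress maps) in ParaView and friends.
#'
#' @param fields Named list of 3D arrays of identical dims.
#' @param path Output path.
#' @param spacing Grid spacing (scalar or length 3).
#' @param origin Grid origin.
#' @return The path, invisibly.
#' @export
write_vtk_grid <- function(fields, path, spacing = 1, origin = c(0, 0, 0)) {
  stopifnot(length(fields) >= 1, !is.null(names(fields)))
  d <- dim(fields[[1]])
  if (length(spacing) == 1) spacing <- rep(spacing, 3)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               sprintf("extrudesim volume (schema %d)", .schema_version),
               "ASCII", "DATASET STRUCTURED_POINTS",
               sprintf("DIMENSIONS %d %d %d", d[1], d[2], d[3]),
               sprintf("ORIGIN %g %g %g", origin[1], origin[2], origin[3]),
               sprintf("SPACING %g %g %g", spacing[1], spacing[2], spacing[3]),
               sprintf("POINT_DATA %d", prod(d))), con)
  for (nm in names(fields)) {
    stopifnot(identical(dim(fields[[nm]]), d))
    writeLines(c(sprintf("SCALARS %s double 1", nm), "LOOKUP_TABLE default"), con)
    writeLines(paste(format(as.vector(fields[[nm]]), digits = 9, trim = TRUE),
                     collapse = "\n"), con)
  }
  invisible(path)
}

#' Save / load a monolayer state checkpoint
#'
#' One file per snapshot carrying the per-cell subdomain arrays and offsets,
#' polarity angles, centers of mass, step counter and RNG state; the
#' substrate profile is stored once with the state.
#'
#' @param state A `monolayer_state`.
#' @param path Checkpoint path.
#' @return `save_checkpoint` the path invisibly; `load_checkpoint` the state.
#' @export
save_checkpoint <- function(state, path) {
  state$rng_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  saveRDS(state, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  state <- readRDS(path)
  if (!inherits(state, "monolayer_state")) stop("not a monolayer checkpoint: ", path)
  if (!is.null(state$rng_state))
    assign(".Random.seed", state$rng_state, envir = globalenv())
  state
}
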