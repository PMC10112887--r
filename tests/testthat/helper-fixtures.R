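# Shared fixtures.  Everything is built in code at test time; the heavier
# relaxed states are cached per session so several test files can reuse them.

.fixture_env <- new.env(parent = emptyenv())

fixture_cached <- function(key, builder) {
  if (is.null(.fixture_env[[key]])) .fixture_env[[key]] <- builder()
  .fixture_env[[key]]
}

# a bare state from explicit cell centers (no relaxation)
make_state <- function(lattice, centers, R0, lambda = 2, thetas = NULL,
                       substrate = NULL) {
  if (is.null(substrate)) substrate <- make_substrate(lattice, interface_width = lambda)
  if (is.null(thetas)) thetas <- rep(0, nrow(centers))
  cells <- lapply(seq_len(nrow(centers)), function(i) {
    cl <- extrudesim:::new_cell_field(i, lattice, centers[i, ], R0, lambda,
                                      thetas[i])
    cl$com <- center_of_mass(cl, lattice)
    cl
  })
  structure(list(lattice = lattice, cells = cells, substrate = substrate,
                 R0 = R0, lambda = lambda, step = 0L, time = 0),
            class = "monolayer_state")
}

relax_fixture <- function(state, ep, n, dt = 0.25) {
  dp <- dynamics_params(alpha = 0, J = 0, Dr = 0, dt = dt, n_steps = 0L,
                        R0 = state$R0)
  extrudesim:::relax_state(state, ep, dp, n)
}

# small two-cell fixture on a 16^3 box used by the variation oracle
fixture_two_cell_16 <- function() {
  lat <- lattice_spec(16, 16, 16)
  ep <- energy_params(R0 = 5, lambda = 2, omega_cw = 0.0025)
  st <- make_state(lat, rbind(c(6, 8, 8), c(11, 8, 8)), R0 = 5)
  list(lat = lat, ep = ep, st = st)
}

# relaxed single droplet resting on the substrate
fixture_droplet <- function() {
  fixture_cached("droplet", function() {
    lat <- lattice_spec(40, 40, 24)
    ep <- energy_params(R0 = 6, lambda = 2)
    st <- initialize_monolayer(lat, 1, 6, seed = 1, lambda = 2)
    st <- relax_fixture(st, ep, 800)
    list(lat = lat, ep = ep, st = st)
  })
}

# relaxed, wall-free, mirror-symmetric overlapping pair (periodic box)
fixture_free_pair <- function() {
  fixture_cached("free_pair", function() {
    lat <- lattice_spec(48, 36, 36)
    ep <- energy_params(R0 = 6, lambda = 2, kappa_cw = 1e-12, omega_cw = 0,
                        omega_cc = 0.001)
    st <- make_state(lat, rbind(c(19, 18, 18), c(29, 18, 18)), R0 = 6)
    st <- relax_fixture(st, ep, 150)
    list(lat = lat, ep = ep, st = st)
  })
}

# relaxed tangent pair on the substrate
fixture_wall_pair <- function() {
  fixture_cached("wall_pair", function() {
    sc <- make_scenario("two_cell_adhesion", seed = 1)
    ep <- sc$config$energy
    st <- relax_fixture(sc$state, ep, 250)
    list(lat = sc$config$lattice, ep = ep, st = st, config = sc$config)
  })
}

# an analytic +-1/2 director pattern sampled on a cell grid
analytic_defect_field <- function(charge = 0.5, lattice = lattice_spec(64, 64, 16),
                                  n_side = 10, l_dir = 6) {
  ctr <- c(lattice$Lx / 2, lattice$Ly / 2)
  gx <- seq(4, lattice$Lx - 4, length.out = n_side)
  gy <- seq(4, lattice$Ly - 4, length.out = n_side)
  pos <- as.matrix(expand.grid(x = gx, y = gy))
  phi_p <- atan2(pos[, 2] - ctr[2], pos[, 1] - ctr[1])
  ang <- (charge * phi_p) %% pi
  list(orientations = ang, positions = pos, center = ctr, lattice = lattice,
       l_dir = l_dir)
}

# passive hexagonal relaxation scenario, run to its end state (shared by the
# packing and acceptance tests; takes ~1.5 min once per session)
fixture_hex <- function(seed = 2) {
  fixture_cached("hex", function() {
    sc <- make_scenario("passive_hex_relax", seed = seed)
    traj <- run_simulation(sc$config, state = sc$state)
    list(config = sc$config, traj = traj)
  })
}

# a short active monolayer segment with analysis frames
fixture_active_segment <- function(seed = 3) {
  fixture_cached("active_segment", function() {
    sc <- make_scenario("small_active_monolayer", seed = seed,
                        n_steps = 400L, snapshot_every = 50L)
    traj <- run_simulation(sc$config, state = sc$state)
    list(config = sc$config, traj = traj)
  })
}
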