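test_that("traction density integrates back to the cell tractions", {
  pr <- fixture_wall_pair()
  td <- traction_density(pr$st, pr$ep)
  f <- extrudesim:::monolayer_forces(pr$st, pr$ep)
  # sum phi_i * T / S over the support recovers t_i (same quadrature)
  gd <- extrudesim:::gdim(pr$lat)
  S <- extrudesim:::energy_cache(pr$st)$S
  for (i in 1:2) {
    cell <- pr$st$cells[[i]]
    w <- extrudesim:::field_on_lattice(cell, pr$lat)
    ratio <- array(0, gd)
    nz <- abs(S) > 1e-12  # fields can undershoot slightly below zero
    for (comp in 1:3) {
      Tc <- list(td$Tx, td$Ty, td$Tz)[[comp]]
      ratio[nz] <- w[nz] * Tc[nz] / S[nz]
      expect_lt(abs(sum(ratio[nz]) - f$tractions[i, comp]),
                1e-6 * max(1, abs(f$tractions[i, comp])))
    }
  }
  # relaxed isolated droplet: traction density everywhere small
  fx <- fixture_droplet()
  td1 <- traction_density(fx$st, fx$ep)
  expect_lt(max(abs(td1$Tx), abs(td1$Ty)), 0.02)
  # mirror pair: Tx anti-symmetric across the contact plane
  frp <- fixture_free_pair()
  td2 <- traction_density(frp$st, frp$ep)
  mid <- 25  # 1-based column on the mirror plane (centers at 0-based 19, 29)
  expect_lt(max(abs(td2$Tx[mid, , ])), 1e-8 * max(abs(td2$Tx)))
  left <- td2$Tx[(mid - 1):(mid - 11), , , drop = FALSE]
  right <- td2$Tx[(mid + 1):(mid + 11), , , drop = FALSE]
  expect_lt(max(abs(left + right)), 1e-7 * max(abs(td2$Tx)))
})

test_that("coarse-grained stress matches a hand-evaluated sum and is symmetric", {
  lat <- lattice_spec(8, 8, 8)
  gd <- c(8L, 8L, 8L)
  Tx <- array(0, gd); Ty <- array(0, gd); Tz <- array(0, gd)
  # three hand-placed traction vectors inside the first 4^3 block
  pts <- rbind(c(1, 1, 1, 2, 0, 0),   # x,y,z (1-based), T vector
               c(2, 3, 1, 0, -1, 0.5),
               c(4, 2, 3, 1, 1, 1))
  for (r in seq_len(nrow(pts))) {
    Tx[pts[r, 1], pts[r, 2], pts[r, 3]] <- pts[r, 4]
    Ty[pts[r, 1], pts[r, 2], pts[r, 3]] <- pts[r, 5]
    Tz[pts[r, 1], pts[r, 2], pts[r, 3]] <- pts[r, 6]
  }
  sf <- coarse_grained_stress(list(Tx = Tx, Ty = Ty, Tz = Tz), lat, l_stress = 4)
  # brute-force oracle for block (1,1,1)
  x0 <- c((4 - 1) / 2, (4 - 1) / 2, (4 - 1) / 2)
  acc <- matrix(0, 3, 3)
  for (r in seq_len(nrow(pts))) {
    xm <- pts[r, 1:3] - 1
    e <- x0 - xm
    if (sqrt(sum(e^2)) < 1e-9) next
    e <- e / sqrt(sum(e^2))
    Tv <- pts[r, 4:6]
    acc <- acc + (outer(Tv, e) + outer(e, Tv)) / 2
  }
  acc <- acc / 4^3
  expect_equal(sf$xx[1, 1, 1], acc[1, 1])
  expect_equal(sf$yy[1, 1, 1], acc[2, 2])
  expect_equal(sf$zz[1, 1, 1], acc[3, 3])
  expect_equal(sf$xy[1, 1, 1], acc[1, 2])
  expect_equal(sf$xz[1, 1, 1], acc[1, 3])
  expect_equal(sf$yz[1, 1, 1], acc[2, 3])
  # zero input -> zero tensor
  sf0 <- coarse_grained_stress(list(Tx = Tx * 0, Ty = Ty * 0, Tz = Tz * 0), lat, 4)
  expect_true(all(unlist(sf0[c("xx", "yy", "zz", "xy", "xz", "yz")]) == 0))
})

test_that("isotropic and shear maps follow the trace and normalization conventions", {
  lat <- lattice_spec(8, 8, 8)
  sf <- list(xx = array(3, c(2, 2, 2)), yy = array(3, c(2, 2, 2)),
             zz = array(3, c(2, 2, 2)), xy = array(0, c(2, 2, 2)),
             xz = array(0, c(2, 2, 2)), yz = array(0, c(2, 2, 2)),
             b = 4L, cdim = c(2L, 2L, 2L))
  m <- isotropic_and_shear_maps(sf)
  expect_true(all(m$iso == 3) && all(m$xz == 0))
  sf$xx[] <- 2; sf$yy[] <- -1; sf$zz[] <- -1; sf$xz[] <- 2
  m2 <- isotropic_and_shear_maps(sf)
  expect_true(all(m2$iso == 0))
  expect_true(all(m2$xz == 2))
  expect_equal(max(abs(m2$xz_norm)), 1)
  # 2D trace option
  m2d <- isotropic_and_shear_maps(sf, trace = "2d")
  expect_true(all(m2d$iso == 0.5))
  # all-zero field normalizes to zero by convention
  sf$xx[] <- 0; sf$yy[] <- 0; sf$zz[] <- 0; sf$xz[] <- 0
  m0 <- isotropic_and_shear_maps(sf)
  expect_true(all(m0$iso_norm == 0) && all(m0$xz_norm == 0))
})

test_that("stress on a passive relaxed packing is far below the active level", {
  # mean |sigma_iso| over the cell bodies: the passive relaxed hexagonal
  # packing vs an actively driven monolayer (activity generates the stress)
  hx <- fixture_hex()
  region_iso <- function(st, ep, l_stress = 2) {
    sf <- coarse_grained_stress(traction_density(st, ep), st$lattice, l_stress)
    maps <- isotropic_and_shear_maps(sf)
    maps$iso <- abs(maps$iso); maps$xz <- abs(maps$xz)
    extrudesim:::stress_region_means(st, sf, maps)$iso_union
  }
  iso_p <- region_iso(hx$traj$final_state, hx$config$energy)
  ac <- fixture_active_segment()
  iso_a <- region_iso(ac$traj$final_state, ac$config$energy)
  expect_lt(iso_p, 0.05 * iso_a)
})

test_that("per-event stress series normalizes by the union mean and truncates", {
  cfg <- suppressMessages(run_config(nx = 64, ny = 64, nz = 16, n_cells = 4, R0 = 8,
                    n_steps = 0, snapshot_every = 0))
  tau0 <- 160; dt <- 0.25
  mkframe <- function(step, iso_cell, iso_union)
    list(step = step, iso_cell_mean = iso_cell, xz_cell_mean = iso_cell,
         iso_union_mean = iso_union, xz_union_mean = iso_union)
  frames <- lapply(seq(0, 1600, 160), function(s) mkframe(s, c(NA, 2, 1, 1), 1))
  traj <- structure(list(config = cfg, R0 = 8, dt = dt, tau0 = tau0,
                         steps = 0:1600, frames = frames,
                         events = data.frame(cell_id = 2L, step = 1600L,
                                             t_norm = 1600 * dt / tau0)),
                    class = "mpf_trajectory")
  ser <- cell_stress_series(traj)
  expect_true(all(ser$iso_ratio == 2))
  expect_false(any(ser$truncated))
  # spatially uniform stress: ratio identically 1
  traj1 <- traj
  traj1$frames <- lapply(frames, function(f) {
    f$iso_cell_mean <- c(1, 1, 1, 1); f$iso_union_mean <- 1; f })
  expect_true(all(cell_stress_series(traj1)$iso_ratio == 1))
  # detached cell truncates with a flag
  traj2 <- traj
  traj2$events$cell_id <- 1L
  expect_true(all(cell_stress_series(traj2)$truncated))
})

test_that("defect-frame averaging rotates into the comet frame and normalizes", {
  cfg <- suppressMessages(run_config(nx = 64, ny = 64, nz = 16, n_cells = 4, R0 = 8,
                    n_steps = 0, snapshot_every = 0, l_stress = 2))
  lat <- cfg$lattice
  # basal map with structure: sigma = -cos(polar angle about the core) decaying
  core <- c(32, 32)
  n <- 32  # coarse map 32x32 over a 64-box (b = 2)
  xs <- (seq_len(n) - 0.5) * 2
  mkmap <- function(psi) {
    m <- matrix(0, n, n)
    for (j in seq_len(n)) for (i in seq_len(n)) {
      dx <- xs[i] - core[1]; dy <- xs[j] - core[2]
      r <- sqrt(dx^2 + dy^2)
      a <- atan2(dy, dx) - psi
      m[i, j] <- -cos(a) * exp(-r / 10)
    }
    m
  }
  base <- list(config = cfg, R0 = 8, dt = 0.25, tau0 = 160, steps = 0:10)
  traj <- structure(c(base, list(frames = list(
    list(step = 0, sigma_iso_basal = mkmap(0))))), class = "mpf_trajectory")
  tracks <- list(points = data.frame(track_id = 1L, charge = 0.5, frame = 1,
                                     step = 0, x = core[1], y = core[2], psi = 0))
  av <- defect_frame_average(traj, tracks, L = 12)
  # compressive (negative) ahead (+x), tensile behind (-x) after normalization
  mid <- ceiling(length(av$ys) / 2)
  expect_lt(av$map[length(av$xs), mid], -0.5)
  expect_gt(av$map[1, mid], 0.5)
  expect_equal(max(abs(av$map)), 1)
  # uniform field: flat map = 1
  trajU <- structure(c(base, list(frames = list(
    list(step = 0, sigma_iso_basal = matrix(2, n, n))))), class = "mpf_trajectory")
  avU <- defect_frame_average(trajU, tracks, L = 12)
  expect_true(all(abs(avU$map - 1) < 1e-12))
  # two tracks with psi differing by 90 deg on the same anisotropic field agree
  traj2 <- structure(c(base, list(frames = list(
    list(step = 0, sigma_iso_basal = mkmap(0)),
    list(step = 1, sigma_iso_basal = mkmap(pi / 2))))), class = "mpf_trajectory")
  traj2$steps <- 0:1
  tA <- list(points = data.frame(track_id = 1L, charge = 0.5, frame = 1, step = 0,
                                 x = core[1], y = core[2], psi = 0))
  tB <- list(points = data.frame(track_id = 2L, charge = 0.5, frame = 2, step = 1,
                                 x = core[1], y = core[2], psi = pi / 2))
  avA <- defect_frame_average(traj2, tA, L = 12)
  avB <- defect_frame_average(traj2, tB, L = 12)
  expect_equal(avA$map, avB$map, tolerance = 0.05)
})
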