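test_that("footprint orientation matches the analytic moment tensor of an ellipse", {
  mk_ellipse <- function(a, b, angle, n = 101) {
    xs <- seq(-25, 25, length.out = n)
    g <- expand.grid(x = xs, y = xs)
    ca <- cos(angle); sa <- sin(angle)
    u <- ca * g$x + sa * g$y
    v <- -sa * g$x + ca * g$y
    matrix(as.numeric((u / a)^2 + (v / b)^2 <= 1), n, n)
  }
  # major axis along x
  o1 <- cell_orientation(mk_ellipse(15, 7, 0), a0 = 0.5)
  expect_lt(abs(o1$angle %% pi), 0.02)
  expect_gt(o1$anisotropy, 0.3)
  # perfect disc: anisotropy ~ 0, flagged unreliable
  o2 <- cell_orientation(mk_ellipse(10, 10, 0), a0 = 0.5)
  expect_lt(o2$anisotropy, 1e-3)
  # rotated by 40 degrees: angle recovered within 1 degree
  o3 <- cell_orientation(mk_ellipse(15, 7, 40 * pi / 180), a0 = 0.5)
  expect_lt(abs(o3$angle - 40 * pi / 180), pi / 180)
  expect_error(cell_orientation(matrix(0, 5, 5)), "empty")
})

test_that("basal projection extracts footprints and masks detached cells", {
  fx <- fixture_droplet()
  bp <- basal_projection(fx$st)
  fp <- bp$footprints[[1]]
  expect_false(fp$empty)
  # footprint of a spread droplet: a disc of roughly R0 scale
  area <- sum(fp$vals >= 0.5)
  r_eff <- sqrt(area / pi)
  expect_gt(r_eff, 0.5 * fx$st$R0)
  expect_lt(r_eff, 1.5 * fx$st$R0)
  # a detached copy high above the substrate has an empty footprint
  st2 <- make_state(fx$lat, rbind(c(20, 20, 18)), R0 = 5)
  bp2 <- basal_projection(st2)
  expect_true(bp2$footprints[[1]]$empty)
  # translation moves the footprint identically
  stA <- make_state(fx$lat, rbind(c(14, 20, 10)), R0 = 5)
  stB <- make_state(fx$lat, rbind(c(22, 20, 10)), R0 = 5)
  oA <- extrudesim:::footprint_orientations(basal_projection(stA), fx$lat)
  oB <- extrudesim:::footprint_orientations(basal_projection(stB), fx$lat)
  expect_equal(oB$x - oA$x, 8, tolerance = 1e-6)
  expect_equal(oB$area, oA$area)
})

test_that("coarse-grained director reproduces uniform and canonical defect patterns", {
  lat <- lattice_spec(64, 64, 16)
  set.seed(3)
  pos <- cbind(runif(40, 0, 64), runif(40, 0, 64))
  # uniform orientation beta
  beta <- 0.8
  df <- coarse_grain_director(rep(beta, 40), pos, l_dir = 6, lattice = lat)
  expect_true(all(abs(extrudesim:::wrap_nematic(df$angle[df$mask] - beta)) < 1e-8))
  expect_true(all(df$S[df$mask] > 0.99))
  # two orthogonal populations at equal weight cancel: order ~ 0 at the node
  p2 <- rbind(c(32, 32), c(32, 32), c(32, 32), c(32, 32))
  df2 <- coarse_grain_director(c(0, 0, pi / 2, pi / 2), p2, l_dir = 6,
                               lattice = lat)
  ctr_node <- c(which.min(abs(df2$xs - 32)), which.min(abs(df2$ys - 32)))
  expect_lt(df2$S[ctr_node[1], ctr_node[2]], 1e-10)
  # unreliable cells are dropped before averaging
  expect_error(coarse_grain_director(c(0, 1, 2, 3), p2, 6, lat,
                                     anisotropy = rep(0.001, 4)), "at least 3")
  expect_error(coarse_grain_director(c(0, 1), p2[1:2, ], 6, lat), "at least 3")
})

test_that("defect detection recovers charge and position of analytic half-integer fields", {
  for (chg in c(0.5, -0.5)) {
    fld <- analytic_defect_field(chg, n_side = 14)
    df <- coarse_grain_director(fld$orientations, fld$positions, fld$l_dir,
                                fld$lattice, spacing = 3)
    det <- detect_defects(df)
    det <- det[order(periodic_distance(cbind(det$x, det$y),
                                       matrix(fld$center, nrow(det), 2,
                                              byrow = TRUE), fld$lattice)), ]
    expect_gte(nrow(det), 1)
    expect_equal(det$charge[1], chg)
    expect_lt(periodic_distance(c(det$x[1], det$y[1]), fld$center, fld$lattice),
              2 * 3)  # within a couple of plaquettes
    # the non-periodic analytic pattern closes its charge at the domain seam:
    # all other detections sit on the boundary
    others <- det[-1, , drop = FALSE]
    if (nrow(others)) {
      on_seam <- others$x < 4 | others$x > 60 | others$y < 4 | others$y > 60
      expect_true(all(on_seam))
    }
    if (chg > 0) {
      # comet axis of the analytic +1/2 pattern points along -x here;
      # just require a finite recorded orientation
      expect_true(is.finite(det$psi[1]))
    }
  }
  # smooth defect-free field: no detections, total winding zero on all plaquettes
  lat <- lattice_spec(64, 64, 16)
  set.seed(5)
  pos <- as.matrix(expand.grid(x = seq(2, 62, by = 6), y = seq(2, 62, by = 6)))
  ang <- (0.3 + 0.02 * sin(2 * pi * pos[, 1] / 64) +
          0.02 * cos(2 * pi * pos[, 2] / 64)) %% pi
  df0 <- coarse_grain_director(ang, pos, l_dir = 8, lattice = lat)
  det0 <- detect_defects(df0)
  expect_equal(nrow(det0), 0)
})

test_that("defect tracking links, starts and ends tracks correctly", {
  lat <- lattice_spec(64, 64, 16)
  mkdet <- function(...) {
    rows <- list(...)
    if (!length(rows)) return(data.frame(charge = numeric(0), x = numeric(0),
                                         y = numeric(0), psi = numeric(0)))
    do.call(rbind, lapply(rows, function(r)
      data.frame(charge = r[1], x = r[2], y = r[3], psi = NA_real_)))
  }
  # single stationary defect over 10 frames
  dets <- replicate(10, mkdet(c(0.5, 20, 20)), simplify = FALSE)
  tr <- track_defects(dets, lat, gate = 8)
  expect_equal(nrow(tr$tracks), 1)
  expect_equal(tr$tracks$lifetime, 10)
  # two well-separated defects: two tracks, no id switches
  dets2 <- lapply(1:8, function(f) mkdet(c(0.5, 10 + f, 10), c(-0.5, 50, 50 - f)))
  tr2 <- track_defects(dets2, lat, gate = 8)
  expect_equal(nrow(tr2$tracks), 2)
  expect_equal(sort(tr2$tracks$charge), c(-0.5, 0.5))
  expect_true(all(table(tr2$points$track_id) == 8))
  # a pair annihilating at frame k: both tracks end at k
  k <- 5
  dets3 <- lapply(1:8, function(f) {
    if (f <= k) mkdet(c(0.5, 30 - f, 30), c(-0.5, 34 + f, 30)) else mkdet()
  })
  tr3 <- track_defects(dets3, lat, gate = 8)
  expect_equal(nrow(tr3$tracks), 2)
  expect_true(all(tr3$tracks$death == k))
})

test_that("neighbor graph: disjoint cells share no edge, touching cells do, robust to threshold", {
  lat <- lattice_spec(64, 48, 24)
  ep <- energy_params(R0 = 6, lambda = 2)
  # two disjoint cells
  far <- make_state(lat, rbind(c(12, 24, 10), c(44, 24, 10)), R0 = 6)
  gfar <- neighbor_graph(far)
  expect_equal(nrow(gfar$edges), 0)
  expect_equal(unname(gfar$z), c(0L, 0L))
  # touching pair: edge present for thresholds across two decades
  pairfx <- fixture_wall_pair()
  w_direct <- extrudesim:::cpp_pair_overlap(
    pairfx$st$cells[[1]]$phi, dim(pairfx$st$cells[[1]]$phi), pairfx$st$cells[[1]]$offset,
    pairfx$st$cells[[2]]$phi, dim(pairfx$st$cells[[2]]$phi), pairfx$st$cells[[2]]$offset,
    extrudesim:::gdim(pairfx$lat))
  expect_gt(w_direct, 0)
  for (thr in c(w_direct * 1e-3, w_direct * 1e-1)) {
    g <- neighbor_graph(pairfx$st, overlap_threshold = thr)
    expect_equal(nrow(g$edges), 1)
    expect_equal(g$edges$w, w_direct, tolerance = 1e-12)
  }
  g0 <- neighbor_graph(pairfx$st, overlap_threshold = w_direct * 2)
  expect_equal(nrow(g0$edges), 0)
})

test_that("Lewis-law table gives the canonical predictions and exact empirical ratios", {
  pred <- lewis_law_predictions(c(5, 6))
  expect_equal(pred$linear, c(0.75, 1))
  expect_equal(pred$quadratic, c(25 / 36, 1))
  # all-equal areas: empirical ratio 1 in every class
  z <- c(5, 5, 6, 6, 6, 7)
  st <- lewis_law_stats(z, rep(3.3, 6))
  expect_equal(st$area_ratio, rep(1, 3))
  expect_equal(st$linear, (st$z - 2) / 4)
  expect_equal(st$quadratic, (st$z / 6)^2)
  expect_error(lewis_law_stats(rep(6, 5), rep(1, 5)), "2 distinct")
})

test_that("minimum extrusion-defect distance uses the window, charges separately, periodic metric", {
  lat <- lattice_spec(64, 64, 16)
  cfg <- suppressMessages(run_config(nx = 64, ny = 64, nz = 16, n_cells = 4, R0 = 8,
                    n_steps = 0, snapshot_every = 0))
  R0 <- 8; dt <- 0.25; tau0 <- 1 * 8 / 0.05
  traj <- structure(list(
    config = cfg, R0 = R0, dt = dt, tau0 = tau0,
    steps = 0:100,
    com = array(rep(c(20, 20, 10), each = 101 * 4), c(101, 4, 3)),
    events = data.frame(cell_id = 2L, step = 50L, t_norm = 50 * dt / tau0,
                        x = 20, y = 20, z = 16)),
    class = "mpf_trajectory")
  # one static +1/2 defect at in-plane distance 12 -> dmin = 1.5 R0 / R0
  pts <- data.frame(track_id = 1L, charge = 0.5, frame = 1:101, step = 0:100,
                    x = 32, y = 20, psi = 0)
  tracks <- list(points = pts)
  md <- min_distance_series(traj, tracks)
  expect_equal(md$dmin_plus, 12 / R0)
  expect_true(is.na(md$dmin_minus))  # no -1/2 defects: missing, not zero
  # approach-recede: minimum at closest approach within the window only
  xs <- c(seq(40, 24, length.out = 51), seq(24, 40, length.out = 50))
  pts2 <- data.frame(track_id = 1L, charge = 0.5, frame = 1:101, step = 0:100,
                     x = xs, y = 20, psi = 0)
  md2 <- min_distance_series(traj, list(points = pts2))
  # brute force over all (frame, defect) pairs inside the window
  tn <- (0:100) * dt / tau0
  inw <- tn >= traj$events$t_norm - 5.625 & tn <= traj$events$t_norm + 0.625
  brute <- min(abs(xs[inw] - 20)) / R0
  expect_equal(md2$dmin_plus, brute)
  # rigid translation of everything leaves dmin unchanged
  traj3 <- traj
  traj3$com[, , 1] <- (traj3$com[, , 1] + 31) %% 64
  pts3 <- pts; pts3$x <- (pts3$x + 31) %% 64
  md3 <- min_distance_series(traj3, list(points = pts3),
                             events = transform(traj$events, x = (x + 31) %% 64))
  expect_equal(md3$dmin_plus, md$dmin_plus)
})

test_that("coordination history averages over the stated window and flags clipping", {
  cfg <- suppressMessages(run_config(nx = 64, ny = 64, nz = 16, n_cells = 4, R0 = 8,
                    n_steps = 0, snapshot_every = 0))
  tau0 <- 160; dt <- 0.25
  mkframe <- function(step, z2) list(step = step, z = stats::setNames(c(6, z2, 6, 6), 1:4))
  frames <- lapply(seq(0, 3200, by = 160), function(s)
    mkframe(s, if (s < 1600) 6 else 5))
  traj <- structure(list(config = cfg, R0 = 8, dt = dt, tau0 = tau0,
                         steps = 0:3200, frames = frames,
                         events = data.frame(cell_id = 2L, step = 3200L,
                                             t_norm = 3200 * dt / tau0)),
                    class = "mpf_trajectory")
  ch <- coordination_history(traj)
  # window [-2.5, 0.3125] tau0 = steps [1600, 3200]: frames at z = 5 only;
  # the forward part of the window extends past the last frame -> flagged
  expect_equal(ch$zbar, 5)
  expect_true(ch$clipped)
  # constant z = 5 everywhere
  traj5 <- traj
  traj5$frames <- lapply(traj$frames, function(f) { f$z[] <- 5; f })
  expect_equal(coordination_history(traj5)$zbar, 5)
  # equal-weight average over a (6, 6, 5, 5) window
  traj6 <- traj
  traj6$frames <- lapply(seq_along(traj$frames), function(i) {
    f <- traj$frames[[i]]; f$z[2] <- if (i <= 11) 6 else 5; f
  })
  ev_step <- 2720L  # window [980, 2820] covers frames 7..18 (steps 960..2720)
  traj6$events <- data.frame(cell_id = 2L, step = ev_step,
                             t_norm = ev_step * dt / tau0)
  ch6 <- coordination_history(traj6)
  # window [1120, 2920] covers frames 8..19: four at z = 6, eight at z = 5
  expect_equal(ch6$zbar, (4 * 6 + 8 * 5) / 12)
  # window clipped at trajectory start
  traj7 <- traj
  traj7$events <- data.frame(cell_id = 2L, step = 160L, t_norm = 160 * dt / tau0)
  ch7 <- coordination_history(traj7)
  expect_true(ch7$clipped)
  expect_gt(ch7$n_frames, 0)
})
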