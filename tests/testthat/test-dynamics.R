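test_that("cell velocity implements the over-damped force balance", {
  dp <- dynamics_params(alpha = 1, xi = 1, R0 = 8)
  expect_equal(cell_velocity(c(0, 0, 0), 0, dp), c(1, 0, 0))
  dp0 <- dynamics_params(alpha = 0, xi = 1, R0 = 8)
  t_i <- c(0.3, -0.2, 0.1)
  expect_equal(cell_velocity(t_i, 1.2, dp0), t_i)
  dp2 <- dynamics_params(alpha = 0, xi = 2, R0 = 8)
  expect_equal(cell_velocity(c(0, 0, 2), 0.4, dp2), c(0, 0, 1))
  # tau0 derived, never stored independently
  dp3 <- dynamics_params(alpha = 0.05, xi = 2, R0 = 8)
  expect_equal(dp3$tau0, 2 * 8 / 0.05)
})

test_that("tractions vanish in equilibrium and obey action-reaction", {
  fx <- fixture_droplet()
  t1 <- interaction_traction(fx$st, fx$ep, 1L)
  # in-plane components vanish by symmetry; the vertical residual decays
  # slowly with relaxation (substrate wetting film) but stays small
  expect_lt(max(abs(t1[1:2])), 1e-8)
  expect_lt(sqrt(sum(t1^2)), 0.1)

  pr <- fixture_free_pair()
  f <- extrudesim:::monolayer_forces(pr$st, pr$ep)
  tr <- f$tractions
  # mirror symmetry: equal magnitude, opposite x, matching y/z
  expect_equal(tr[1, 1], -tr[2, 1], tolerance = 1e-8)
  expect_equal(tr[1, 2], tr[2, 2], tolerance = 1e-8)
  # sum over the pair vanishes relative to the largest traction
  scale <- max(abs(tr))
  expect_lt(max(abs(colSums(tr))) / scale, 1e-6)
  # direct-summation oracle: sum_i t_i = integral S grad(pi)
  f2 <- extrudesim:::monolayer_forces(pr$st, pr$ep, keep_fields = TRUE)
  direct <- c(sum(f2$cache$S * f2$grad_pi$gx),
              sum(f2$cache$S * f2$grad_pi$gy),
              sum(f2$cache$S * f2$grad_pi$gz))
  expect_lt(max(abs(direct - colSums(tr))), 1e-8 * max(scale, 1e-8))
})

test_that("field advance: dt = 0 identity, translation under imposed velocity, CFL guard", {
  fx <- fixture_droplet()
  dp0 <- dynamics_params(alpha = 0, J = 0, Dr = 0, dt = 0, n_steps = 0, R0 = 6)
  expect_identical(advance_fields(fx$st, fx$ep, dp0), fx$st)

  # uniform imposed velocity with relaxation off: first-order translation
  st <- fx$st
  dp <- dynamics_params(alpha = 0, J = 0, Dr = 0, dt = 0.25, n_steps = 0, R0 = 6)
  v <- c(0.4, 0, 0)
  n_steps <- 40  # translate by 4 grid units
  f0 <- extrudesim:::monolayer_forces(st, fx$ep)
  for (s in 1:n_steps) {
    f <- f0
    f$velocities[1, ] <- v
    f$dFs[[1]][] <- 0  # relaxation switched off
    st <- advance_fields(st, fx$ep, dp, forces = f)
  }
  expect_equal(extrudesim:::wrap_delta(st$cells[[1]]$com[1] - fx$st$cells[[1]]$com[1],
                                       fx$lat$Lx),
               v[1] * n_steps * dp$dt, tolerance = 0.05)
  expect_equal(st$cells[[1]]$com[2:3], fx$st$cells[[1]]$com[2:3], tolerance = 0.05)

  # CFL violation raises a stability error
  fbad <- extrudesim:::monolayer_forces(fx$st, fx$ep)
  fbad$velocities[1, ] <- c(8, 0, 0)
  expect_error(advance_fields(fx$st, fx$ep, dp, forces = fbad), "stability")
})

test_that("passive dynamics is a discrete gradient flow (energy non-increasing)", {
  pr <- fixture_wall_pair()
  st <- pr$st
  dp <- dynamics_params(alpha = 0, J = 0, Dr = 0, dt = 0.25, n_steps = 0, R0 = 6)
  e_prev <- free_energy(st, pr$ep)$total
  for (s in 1:200) {
    st <- advance_fields(st, pr$ep, dp)
    e <- free_energy(st, pr$ep)$total
    expect_lte(e, e_prev + 1e-9 * abs(e_prev))
    e_prev <- e
  }
})

test_that("an isolated active cell travels along its polarity at ~ alpha/xi", {
  fx <- fixture_droplet()
  st <- fx$st
  st$cells[[1]]$theta <- pi / 4
  dp <- dynamics_params(alpha = 0.05, xi = 1, J = 0, Dr = 0, dt = 0.25,
                        n_steps = 0, R0 = 6)
  for (s in 1:300) st <- advance_fields(st, fx$ep, dp)  # spin-up
  c0 <- st$cells[[1]]$com
  n <- 200
  for (s in 1:n) st <- advance_fields(st, fx$ep, dp)
  d <- c(extrudesim:::wrap_delta(st$cells[[1]]$com[1] - c0[1], fx$lat$Lx),
         extrudesim:::wrap_delta(st$cells[[1]]$com[2] - c0[2], fx$lat$Ly))
  speed <- sqrt(sum(d^2)) / (n * dp$dt)
  expect_lt(abs(speed - 0.05) / 0.05, 0.1)
  expect_equal(atan2(d[2], d[1]), pi / 4, tolerance = 0.05)
})

test_that("CIL polarity update aligns, ties break toward +pi, and diffuses correctly", {
  lat <- lattice_spec(16, 16, 16)
  st <- make_state(lat, rbind(c(8, 8, 8)), R0 = 5)
  dp <- dynamics_params(alpha = 0, J = 0.5, Dr = 0, dt = 0.1, n_steps = 0, R0 = 5)

  # traction parallel to polarity: no change
  st$cells[[1]]$theta <- 0.7
  st$tractions <- matrix(c(cos(0.7), sin(0.7), 0), 1)
  expect_equal(update_polarity(st, dp)$cells[[1]]$theta, 0.7)

  # anti-parallel: deviation is +pi by the tie-break; angle decreases by J|t|pi dt
  st$tractions <- matrix(c(-cos(0.7), -sin(0.7), 0), 1)
  th1 <- update_polarity(st, dp)$cells[[1]]$theta
  expect_equal(th1, 0.7 - 0.1 * 0.5 * 1 * pi)

  # traction ahead of polarity rotates the polarity toward it
  st$tractions <- matrix(c(cos(1.0), sin(1.0), 0), 1)
  th2 <- update_polarity(st, dp)$cells[[1]]$theta
  expect_gt(th2, 0.7); expect_lt(th2, 1.0)

  # pure rotational diffusion: Var(dtheta) ~ 2 Dr dt over many cells
  n <- 10000
  lat2 <- lattice_spec(512, 512, 16)
  centers <- as.matrix(expand.grid(x = seq(5, 507, length.out = 100),
                                   y = seq(5, 507, length.out = 100)))
  st2 <- list(lattice = lat2,
              cells = lapply(seq_len(n), function(i)
                list(id = i, theta = 0, removed = FALSE)),
              tractions = matrix(0, n, 3))
  class(st2) <- "monolayer_state"
  dpD <- dynamics_params(alpha = 0, J = 0, Dr = 0.05, dt = 0.2, n_steps = 0, R0 = 5)
  set.seed(99)
  out <- update_polarity(st2, dpD)
  dth <- vapply(out$cells, `[[`, numeric(1), "theta")
  expect_lt(abs(var(dth) - 2 * 0.05 * 0.2) / (2 * 0.05 * 0.2), 0.05)
})

test_that("extrusion detection follows the R0/2 relative-height criterion exactly", {
  # brute-force oracle on hand-built tracks
  oracle <- function(z, R0) {
    ext <- rep(FALSE, ncol(z)); ev <- NULL
    for (f in seq_len(nrow(z))) {
      ref <- median(z[f, !ext])
      for (i in seq_len(ncol(z)))
        if (!ext[i] && z[f, i] - ref > R0 / 2) {
          ext[i] <- TRUE
          ev <- rbind(ev, c(i, f))
        }
    }
    ev
  }
  R0 <- 8
  # one cell rises linearly, crossing R0/2 relative height at frame 17
  n_f <- 30; n_c <- 9
  z <- matrix(10, n_f, n_c)
  z[, 5] <- 10 + (seq_len(n_f) - 1) * (R0 / 2) / 16  # crosses > R0/2 at frame 18
  ev <- detect_extrusions(z, R0)
  orc <- oracle(z, R0)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$cell_id, orc[1, 1])
  expect_equal(ev$t_e, orc[1, 2])
  expect_equal(ev$t_e, 18)

  # all equal heights: no events
  expect_equal(nrow(detect_extrusions(matrix(10, 10, 6), R0)), 0)

  # two cells crossing at different frames: two ordered events
  z2 <- matrix(10, 20, 8)
  z2[8:20, 2] <- 15
  z2[14:20, 7] <- 15
  ev2 <- detect_extrusions(z2, R0)
  orc2 <- oracle(z2, R0)
  expect_equal(as.matrix(ev2[, c("cell_id", "t_e")]), orc2,
               ignore_attr = TRUE)
  expect_true(all(diff(ev2$t_e) >= 0))
})

test_that("run_simulation is seed-deterministic and honors n_steps = 0", {
  cfg <- suppressMessages(run_config(nx = 48, ny = 44, nz = 24, n_cells = 2,
                    R0 = 6, n_steps = 30, n_relax = 30, seed = 5,
                    snapshot_every = 15, analyze_stress = TRUE,
                    l_dir = 6, l_stress = 2, alpha = 0.05, Dr = 0.02))
  t1 <- run_simulation(cfg)
  t2 <- run_simulation(cfg)
  expect_identical(t1$com, t2$com)
  expect_identical(t1$theta, t2$theta)
  expect_identical(t1$events, t2$events)
  expect_identical(t1$final_state$cells[[1]]$phi, t2$final_state$cells[[1]]$phi)

  cfg0 <- suppressMessages(run_config(nx = 48, ny = 44, nz = 24, n_cells = 2,
                     R0 = 6, n_steps = 0, n_relax = 5, seed = 5,
                     snapshot_every = 0, l_stress = 2))
  t0 <- run_simulation(cfg0)
  expect_length(t0$steps, 1)
  expect_equal(nrow(t0$events), 0)
})
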