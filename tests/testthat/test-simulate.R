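# helpers to build tiny custom configurations
one_neuron_config <- function(variant = "nondelayed_nonnoisy") {
  noisy <- endsWith(variant, "_noisy")
  delayed <- startsWith(variant, "delayed")
  network_config(
    params = fhn_params(r = 10, b = 1, c = 0.001),
    ees = ees_drive(A = 0.1, f = 0.129),
    disturbances = ionic_disturbance(0, 0.2),
    coupling = coupling_matrix(matrix(0, 1, 1)),
    delays = if (delayed) delay_pair(0.2, 0.2) else delay_pair(0, 0),
    noise = if (noisy) noise_spec(0.01) else NULL,
    drive_ic = c(0, 0.1), variant = variant)
}

test_that("drive network vector field matches its closed form", {
  sc <- fhn_scenario("nondelayed_nonnoisy")
  cfg <- sc$config
  Aw <- 0.1 / (2 * pi * 0.129)
  # zero state at t = 0: only the EES term survives in the membrane block
  d <- drive_rhs(rep(0, 10), 0, cfg)
  expect_equal(d[1:5], rep(Aw, 5))
  expect_equal(d[6:10], rep(0, 5))
  # recovery block is b*x - c*w
  st <- c(rep(0.3, 5), rep(2, 5))
  d2 <- drive_rhs(st, 0, cfg)
  expect_equal(d2[6:10], cfg$params$b * 0.3 - cfg$params$c * 2)
  # equal membrane potentials: coupling contributes exactly nothing
  cfg0 <- cfg
  cfg0$coupling <- coupling_matrix(matrix(0, 5, 5))
  expect_equal(drive_rhs(st, 1.3, cfg), drive_rhs(st, 1.3, cfg0))
})

test_that("slave vector field equals the drive's at zero control", {
  sc <- fhn_scenario("nondelayed_nonnoisy")
  cfg <- sc$config
  st <- c(0.1, -0.2, 0.3, 0, 0.05, 0.4, 0.1, 0, -0.1, 0.2)
  expect_equal(slave_rhs(st, 2.7, cfg), drive_rhs(st, 2.7, cfg))
  # control acts on the membrane equations only
  u <- c(1, -2, 3, 0.5, -0.25)
  with_u <- slave_rhs(st, 2.7, cfg, u = u)
  without <- slave_rhs(st, 2.7, cfg)
  expect_equal(with_u[6:10], without[6:10])
  expect_equal(with_u[1:5], without[1:5] - u)
})

test_that("common noise cancels from the drive/slave difference", {
  cfg <- fhn_scenario("nondelayed_noisy")$config
  st <- c(0.2, 0.1, -0.3, 0.4, 0, 0.1, 0.2, 0.3, 0.4, 0.5)
  set.seed(99)
  for (k in 1:25) {
    z <- rnorm(5)
    expect_equal(slave_rhs(st, 1.1, cfg, noise_sample = z) -
                   drive_rhs(st, 1.1, cfg, noise_sample = z),
                 rep(0, 10))
  }
  expect_error(drive_rhs(st, 0, cfg), "noise sample")
})

test_that("non-delayed control law matches its worked values", {
  cfg <- one_neuron_config()
  sch <- controller_schedule("nondelayed", t_on = 0, gain_columns = c(1, 1))
  # zero errors give zero control
  expect_identical(control_nondelayed(0, 0, 12.3, cfg, sch), 0)
  # e_x = 1, sin(wt) = 0 at t = 0, g = 0: u = 2 (b + c) = 2.002
  expect_equal(control_nondelayed(1, 0, 0, cfg, sch), 2.002)
  # e_y = 1, cos(wt) = 0 a quarter period in: u = -2 (-b - c) = 2.002
  tq <- (pi / 2) / cfg$ees$omega
  expect_equal(control_nondelayed(0, 1, tq, cfg, sch), 2.002)
  expect_error(control_nondelayed(0, 0, 0, one_neuron_config("delayed_nonnoisy"), sch),
               "delayed")
})

test_that("delayed control law matches its worked values", {
  W <- matrix(c(0, 0.001, 0.001, 0), 2, 2)
  cfg <- network_config(
    params = fhn_params(r = rep(10, 2), b = 1, c = 0.001),
    ees = ees_drive(0.1, 0.129),
    disturbances = ionic_disturbance(rep(0, 2), 0.2),
    coupling = coupling_from_offdiagonal(W),
    delays = delay_pair(0.2, 0.2),
    drive_ic = rep(0, 4), variant = "delayed_nonnoisy")
  sch <- controller_schedule("delayed", t_on = 0, gain_columns = c(2, 2))
  expect_identical(control_delayed(c(0, 0), c(0, 0), cfg, sch), c(0, 0))
  # g11 = 0.001 (column 2 of row 1), b - c = 0.999
  expect_equal(control_delayed(c(1, 0), c(0, 0), cfg, sch),
               c(-0.000999, 0))
  # b = c makes the law vanish identically
  cfg_bc <- cfg
  cfg_bc$params <- fhn_params(r = rep(10, 2), b = 0.5, c = 0.5)
  expect_equal(control_delayed(c(1, 2), c(3, 4), cfg_bc, sch), c(0, 0))
  expect_error(control_delayed(0, 0, one_neuron_config(), sch), "delayed")
})

test_that("lagged error state follows its definition", {
  d0 <- function(t) rep(1, 2)
  s0 <- function(t) rep(0, 2)
  e <- lag_error(d0, s0, 5, delay_pair(0, 0))
  expect_equal(e$ex, 0.5)
  expect_equal(e$ey, 0.5)
  # constants: lags are irrelevant
  da <- function(t) rep(0.7, 4)
  sb <- function(t) rep(0.1, 4)
  e2 <- lag_error(da, sb, 3, delay_pair(0.4, 0.2))
  expect_equal(e2$ex, c(0.3, 0.3))
  # linear trajectories pick up the lag difference
  lin <- function(t) rep(t, 2)
  e3 <- lag_error(lin, lin, 10, delay_pair(0.4, 0.2))
  expect_equal(e3$ex, -0.1)
  expect_equal(e3$ey, -0.1)
})

test_that("fixed-step integrators hit their textbook orders", {
  f <- function(s, t) -s
  one <- step_rk4(f, 1, 0, 0.1)
  # one RK4 step of dx/dt = -x is the 4th-order Taylor truncation of e^-h
  h <- 0.1
  expect_equal(one, 1 - h + h^2 / 2 - h^3 / 6 + h^4 / 24, tolerance = 1e-15)
  expect_equal(one, exp(-0.1), tolerance = 1e-6)
  expect_lt(abs(one - exp(-0.1)), 1e-7)
  # zero field leaves the state untouched
  expect_identical(step_rk4(function(s, t) 0 * s, c(1, 2), 0, 0.1), c(1, 2))
  # Euler-Maruyama with no increment is the explicit Euler step
  expect_identical(step_em(f, 1, 0, 0.1), 1 + 0.1 * (-1))
  expect_identical(step_em(f, 1, 0, 0.1, increments = 0, index = 1),
                   step_em(f, 1, 0, 0.1))
  set.seed(1)
  expect_identical(noise_increment(5, 0, 0.005), rep(0, 5))
})

test_that("run_simulation validates schedule/variant combinations", {
  sc <- fhn_scenario("nondelayed_nonnoisy")
  scd <- fhn_scenario("delayed_nonnoisy")
  expect_error(run_simulation(sc$config, scd$schedule, t_end = 1),
               "delayed variant")
  expect_error(run_simulation(scd$config, sc$schedule, t_end = 1),
               "delayed")
  expect_error(run_simulation(sc$config, sc$schedule, t_end = 100),
               "t_on")
  scn <- fhn_scenario("nondelayed_noisy")
  expect_error(run_simulation(scn$config, controller_schedule("none"),
                              t_end = 1, method = "rk4"),
               "Euler-Maruyama")
})

test_that("controller activation is respected on the grid", {
  sc <- fhn_scenario("nondelayed_nonnoisy")
  sched <- controller_schedule("nondelayed", t_on = 1)
  tr <- run_simulation(sc$config, sched, t_end = 3, dt = 0.005)
  before <- tr$times < 1
  expect_true(all(tr$control[before, ] == 0))
  expect_true(any(tr$control[!before, ] != 0))
  expect_identical(tr$controller_active, tr$times >= 1)
})

test_that("stored errors equal their recomputation from the states", {
  tr <- reference_run("nondelayed_nonnoisy", controlled = FALSE, t_end = 5)
  expect_equal(tr$errors, (tr$drive - tr$slave) / 2, tolerance = 1e-15)
  trd <- cached("delayed-short", {
    sc <- fhn_scenario("delayed_nonnoisy")
    run_simulation(sc$config, controller_schedule("none"), t_end = 5)
  })
  dl <- state_lookup(trd, "drive")
  sl <- state_lookup(trd, "slave")
  for (t in c(0, 0.5, 1.25, 3, 5)) {
    k <- which(abs(trd$times - t) < 1e-9)
    e <- lag_error(dl, sl, t, trd$config$delays)
    expect_equal(unname(trd$errors[k, ]), c(e$ex, e$ey), tolerance = 1e-12)
  }
})

test_that("runs are reproducible from the seed", {
  sc <- fhn_scenario("nondelayed_noisy")
  a <- run_simulation(sc$config, controller_schedule("none"), t_end = 3,
                      seed = 5)
  b <- run_simulation(sc$config, controller_schedule("none"), t_end = 3,
                      seed = 5)
  expect_identical(a$drive, b$drive)
  expect_identical(a$slave, b$slave)
})

test_that("numerical blow-up aborts with a divergence condition", {
  sc <- fhn_scenario("nondelayed_nonnoisy")
  cfg <- sc$config
  cfg$drive_ic[1] <- 5          # large membrane excursion
  expect_error(
    run_simulation(cfg, controller_schedule("none"), t_end = 5, dt = 1),
    class = "fhn_divergence")
})

test_that("the integrator agrees with an independent adaptive solver", {
  skip_if_not_installed("deSolve")
  sc <- fhn_scenario("nondelayed_nonnoisy")
  cfg <- sc$config
  tr <- run_simulation(cfg, controller_schedule("none"), t_end = 2,
                       dt = 0.005)
  joint0 <- c(cfg$drive_ic, cfg$slave_ic + c(rep(1e-3, 5), rep(0, 5)))
  f <- function(t, s, p) {
    list(c(drive_rhs(s[1:10], t, cfg), slave_rhs(s[11:20], t, cfg)))
  }
  sol <- deSolve::ode(joint0, tr$times, f, NULL, method = "lsoda",
                      rtol = 1e-11, atol = 1e-13)
  expect_lt(max(abs(sol[, 2:21] - cbind(tr$drive, tr$slave))), 1e-6)
})
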