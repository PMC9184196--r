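test_that("the Lyapunov candidate is a positive definite quadratic form", {
  expect_identical(lyapunov_V(rep(0, 5), rep(0, 5)), 0)
  e1 <- c(1, 0, 0, 0, 0)
  expect_equal(lyapunov_V(e1, rep(0, 5)), 0.5)
  v <- lyapunov_V(c(0.3, -0.2), c(0.1, 0.4))
  expect_equal(lyapunov_V(2 * c(0.3, -0.2), 2 * c(0.1, 0.4)), 4 * v)
  set.seed(11)
  for (k in 1:1000) {
    ex <- rnorm(5, sd = 10^runif(1, -8, 2))
    ey <- rnorm(5, sd = 10^runif(1, -8, 2))
    if (all(ex == 0) && all(ey == 0)) next
    expect_gt(lyapunov_V(ex, ey), 0)
  }
})

test_that("the finite-difference decay series matches known derivatives", {
  # constant errors: V is constant, vdot vanishes
  tt <- seq(0, 1, by = 0.01)
  Ec <- matrix(0.3, length(tt), 4)
  vd <- vdot_series(fake_traj(tt, Ec))
  expect_lt(max(abs(vd$vdot)), 1e-12)
  # V(t) = exp(-t) via a single error component e = sqrt(2 exp(-t))
  E1 <- cbind(sqrt(2 * exp(-tt)), 0, 0, 0)
  vd1 <- vdot_series(fake_traj(tt, E1))
  expect_lt(max(abs(vd1$vdot - (-exp(-vd1$time)))), 1e-4)
  expect_length(vd1$vdot, length(tt) - 2L)
  expect_error(vdot_series(fake_traj(c(0, 1), matrix(0, 2, 4))), "3 points")
})

test_that("leading principal minors match hand computations and the
           triangular cumulative-product identity", {
  expect_equal(leading_principal_minors(diag(3)), c(1, 1, 1))
  expect_equal(leading_principal_minors(matrix(c(2, 1, 1, 2), 2)), c(2, 3))
  expect_equal(leading_principal_minors(matrix(c(1, 2, 2, 1), 2)), c(1, -3))
  expect_error(leading_principal_minors(matrix(0, 2, 3)), "square")
  set.seed(21)
  for (k in 1:20) {
    m <- sample(2:7, 1)
    L <- matrix(rnorm(m * m), m)
    L[upper.tri(L)] <- 0
    expect_equal(leading_principal_minors(L), cumprod(diag(L)),
                 tolerance = 1e-10)
  }
})

test_that("minors and symmetric-part eigenvalue verdicts agree on
           symmetric matrices", {
  v <- pd_verdict(diag(4))
  expect_true(v$pd_by_minors)
  expect_true(v$pd_by_eigen_symmetric_part)
  v2 <- pd_verdict(matrix(c(1, 2, 2, 1), 2))
  expect_false(v2$pd_by_minors)
  expect_false(v2$pd_by_eigen_symmetric_part)
  set.seed(31)
  for (k in 1:50) {
    m <- sample(2:8, 1)
    B <- matrix(rnorm(m * m), m)
    S <- if (k %% 2 == 0) crossprod(B) + 0.1 * diag(m) else (B + t(B)) / 2
    v <- pd_verdict(S)
    expect_identical(v$pd_by_minors, v$pd_by_eigen_symmetric_part)
  }
})

test_that("non-delayed stability matrix assembles as specified", {
  # r = 1, zero coupling, zero EES, vanishing b and c: top-left -> I/2
  cfg <- network_config(
    params = fhn_params(r = rep(1, 3), b = 1e-12, c = 1e-12),
    ees = ees_drive(0, 0.129),
    disturbances = ionic_disturbance(rep(0, 3), 1),
    coupling = coupling_matrix(matrix(0, 3, 3)),
    drive_ic = rep(0, 6))
  sch <- controller_schedule("nondelayed", t_on = 0)
  P <- build_P_nondelayed(0, cfg, sch)
  expect_equal(P[1:3, 1:3], 0.5 * diag(3), tolerance = 1e-9)
  expect_equal(P[1:3, 4:6], diag(3), tolerance = 1e-9)
  # bottom blocks are exactly -b I and c I
  sc <- fhn_scenario("nondelayed_nonnoisy")
  P2 <- build_P_nondelayed(7.3, sc$config, sc$schedule, neuron_index = 2)
  expect_equal(P2[6:10, 1:5], -1.001 * diag(5))
  expect_equal(P2[6:10, 6:10], 0.002 * diag(5))
  # 1/f-periodic in t
  P3 <- build_P_nondelayed(7.3 + 1 / 0.129, sc$config, sc$schedule,
                           neuron_index = 2)
  expect_equal(P2, P3, tolerance = 1e-12)
  expect_error(build_P_nondelayed(0, fhn_scenario("delayed_nonnoisy")$config,
                                  sc$schedule), "non-delayed")
})

test_that("delayed stability matrix assembles as specified", {
  scd <- fhn_scenario("delayed_nonnoisy")
  cfg <- scd$config
  sch <- scd$schedule
  n <- cfg$n
  # b = c kills the gain terms; off-diagonal upper block reduces to I
  cfg_bc <- cfg
  cfg_bc$params <- fhn_params(r = 10, b = 0.5, c = 0.5)
  P <- build_P_delayed(cfg_bc, sch, q1 = 0, q2 = 0)
  expect_equal(P[1:n, (n + 1):(2 * n)], diag(n))
  # q1 enters linearly through the top-left diagonal
  P0 <- build_P_delayed(cfg, sch, q1 = 1, q2 = 2)
  P1 <- build_P_delayed(cfg, sch, q1 = 1.5, q2 = 2)
  r <- cfg$params$r[1]
  expect_equal(P1[1:n, 1:n] - P0[1:n, 1:n],
               -((1 + r) / 2) * 0.5 * diag(n), tolerance = 1e-12)
  expect_error(build_P_delayed(fhn_scenario("nondelayed_nonnoisy")$config,
                               sch, q1 = 1, q2 = 1), "delayed")
})

test_that("trajectory bounds are exact for constants and monotone under
           extension", {
  tt <- seq(0, 1, by = 0.1)
  mk <- function(xc, yc) {
    fake_traj(tt, matrix(0, length(tt), 2),
              drive = cbind(rep(xc, length(tt)), 0),
              slave = cbind(rep(yc, length(tt)), 0))
  }
  q <- estimate_bounds_q(mk(0.5, 0.3))
  expect_equal(q$q1, 0.8)
  q2 <- estimate_bounds_q(mk(1, 1))
  expect_equal(q2$q2, 3)
  qm <- estimate_bounds_q(mk(0.5, 0.3), margin = 0.1)
  expect_equal(qm$q1, 1.1 * 0.8)
  expect_equal(qm$q2, 1.1 * q$q2)
  # appending states never decreases the bounds
  set.seed(41)
  for (k in 1:10) {
    x <- rnorm(50); y <- rnorm(50)
    short <- fake_traj(seq_len(30) * 0.1, matrix(0, 30, 2),
                       drive = cbind(x[1:30], 0), slave = cbind(y[1:30], 0))
    long <- fake_traj(seq_len(50) * 0.1, matrix(0, 50, 2),
                      drive = cbind(x, 0), slave = cbind(y, 0))
    qs <- estimate_bounds_q(short); ql <- estimate_bounds_q(long)
    expect_gte(ql$q1, qs$q1)
    expect_gte(ql$q2, qs$q2)
  }
})

test_that("the period sweep reports a finite verdict", {
  sc <- fhn_scenario("nondelayed_nonnoisy")
  rep <- pd_sweep_over_period(sc$config, sc$schedule, n_samples = 16)
  expect_s3_class(rep, "stability_report")
  expect_true(is.finite(rep$min_eig_over_sweep))
  expect_identical(rep$t_evaluated, "sweep")
  expect_length(rep$minors, 10L)
  expect_equal(nrow(rep$samples), 16L)
  # a drive without stimulation is time-independent: samples collapse
  cfg0 <- sc$config
  cfg0$ees <- ees_drive(0, 0.129)
  rep0 <- pd_sweep_over_period(cfg0, sc$schedule, n_samples = 8)
  expect_equal(nrow(rep0$samples), 1L)
})

test_that("delayed stability pipeline produces positive bounds", {
  trd <- cached("delayed-short", {
    sc <- fhn_scenario("delayed_nonnoisy")
    run_simulation(sc$config, controller_schedule("none"), t_end = 5)
  })
  rep <- stability_report_delayed(trd, margin = 0.05)
  expect_gt(rep$q1, 0)
  expect_gt(rep$q2, 0)
  expect_type(rep$pd_by_minors, "logical")
  expect_type(rep$pd_by_eigen_symmetric_part, "logical")
  path <- tempfile(fileext = ".json")
  write_stability(rep, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$q1, rep$q1)
  expect_equal(length(back$minors), 10L)
  unlink(path)
})
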