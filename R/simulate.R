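## Core dynamics, control laws, fixed-step integrators and the run driver.

#' Adaptive control law for the non-delayed variants
#'
#' The per-neuron control signal built from the instantaneous
#' half-difference errors,
#' \deqn{u_i = 2 e_{x,i}\,(g_{i1} + (A/\omega)\sin(\omega t) + b_i + c_i)
#'        - 2 e_{y,i}\,(g_{i2} - (A/\omega)\cos(\omega t) - b_i - c_i),}
#' where `g_i1`, `g_i2` are read from the coupling-matrix columns selected
#' by `schedule$gain_columns` (row `i`), and `b_i`, `c_i` are the recovery
#' parameters of neuron `i`.
#'
#' [run_simulation()] applies this signal *as* the slave membrane input
#' (slave membrane derivative `+= u`); with that placement the closed-loop
#' error dynamics are asymptotically stable, whereas the opposite sign
#' destabilizes them (see the package vignette for the sign bookkeeping).
#'
#' @param ex,ey Length-`n` membrane and recovery error vectors
#'   (`(drive - slave)/2`).
#' @param t Current time.
#' @param config An [network_config()] for a non-delayed variant.
#' @param schedule A [controller_schedule()] with `law = "nondelayed"`.
#' @return Length-`n` numeric control vector (zero when the errors vanish).
#' @export
control_nondelayed <- function(ex, ey, t, config, schedule) {
  if (startsWith(config$variant, "delayed"))
    stop("the non-delayed control law does not apply to delayed variants")
  p <- config$params
  G <- config$coupling$G
  gc <- schedule$gain_columns
  if (any(gc > config$n)) stop("gain_columns out of range")
  Aw <- ees_amp_factor(config$ees)
  w <- config$ees$omega
  2 * ex * (G[, gc[1L]] + Aw * sin(w * t) + p$b + p$c) -
    2 * ey * (G[, gc[2L]] - Aw * cos(w * t) - p$b - p$c)
}

#' Lag-error feedback law for the delayed variants
#'
#' The per-neuron control signal built from the lagged half-difference
#' errors of [lag_error()],
#' \deqn{u_i = -g_{i1} (b_i - c_i)\, e^{\tau}_{x,i}
#'             - (b_i - c_i)\, e^{\tau}_{y,i}.}
#' It vanishes when the lagged errors vanish and also when `b_i = c_i`.
#'
#' [run_simulation()] applies the *negative* of this signal to the slave
#' membrane equation (slave membrane derivative `+= -u`); that placement is
#' the one whose Lyapunov balance stabilizes the delayed error dynamics
#' (the opposite sign destabilizes them; see the vignette).
#'
#' @param ex_lag,ey_lag Length-`n` lagged membrane and recovery error
#'   vectors.
#' @param config An [network_config()] for a delayed variant.
#' @param schedule A [controller_schedule()] with `law = "delayed"`.
#' @return Length-`n` numeric control vector.
#' @export
control_delayed <- function(ex_lag, ey_lag, config, schedule) {
  if (!startsWith(config$variant, "delayed"))
    stop("the delayed control law requires a delayed variant")
  p <- config$params
  G <- config$coupling$G
  gc <- schedule$gain_columns
  if (any(gc > config$n)) stop("gain_columns out of range")
  -G[, gc[1L]] * (p$b - p$c) * ex_lag - (p$b - p$c) * ey_lag
}

## A/omega with the convention that a zero-amplitude drive contributes 0
## even when f = 0 (so "no stimulation" configurations are representable).
ees_amp_factor <- function(ees) {
  if (ees$A == 0) return(0)
  if (ees$f == 0) stop("invalid EES drive: frequency f must be nonzero")
  ees$A / ees$omega
}

#' Lagged synchronization error state
#'
#' The half-difference error evaluated at (possibly) lagged time arguments,
#' `e_x = (x(t - tau1) - y(t - tau2)) / 2` per membrane component and
#' likewise `e_y` for the recovery components.  With `tau1 = tau2 = 0` this
#' reduces to the instantaneous error `(drive - slave)/2`.
#'
#' @param drive_lookup,slave_lookup Functions of one time argument returning
#'   the length-`2n` network state `c(membrane, recovery)` at that time (see
#'   [state_lookup()]).
#' @param t Evaluation time.
#' @param delays A [delay_pair()].
#' @return A list with components `ex` and `ey` (length-`n` each).
#' @export
lag_error <- function(drive_lookup, slave_lookup, t, delays) {
  xd <- drive_lookup(t - delays$tau1)
  ys <- slave_lookup(t - delays$tau2)
  n <- length(xd) %/% 2L
  list(ex = (xd[seq_len(n)] - ys[seq_len(n)]) / 2,
       ey = (xd[n + seq_len(n)] - ys[n + seq_len(n)]) / 2)
}

#' Drive-network right-hand side
#'
#' Reference implementation of the drive network's vector field.  For
#' neuron `i`, the membrane derivative is
#' `cubic_term(x_i, r_i) - x2_i + (G %*% x_lagged)_i + I(t) + d_i(t)`
#' (plus the noise rate `xi_i` for noisy variants) and the recovery
#' derivative is `b_i x_i - c_i x2_i`.  The drive network is unactuated.
#'
#' @param state Length-`2n` state `c(membrane, recovery)`.
#' @param t Time.
#' @param config An [network_config()].
#' @param hist For delayed variants, a function of one time argument
#'   returning the drive state at that time (the coupling uses the membrane
#'   block of `hist(t - tau1)`); required iff the variant is delayed.
#' @param noise_sample Length-`n` noise rate `xi` added to the membrane
#'   derivatives; required iff the variant is noisy.
#' @return Length-`2n` derivative vector.
#' @export
drive_rhs <- function(state, t, config, hist = NULL, noise_sample = NULL) {
  .network_rhs(state, t, config, hist, noise_sample,
               params = config$params, tau = config$delays$tau1,
               control = NULL)
}

#' Slave-network right-hand side
#'
#' Identical in structure to [drive_rhs()] with the slave's states, lag
#' `tau2` and (optionally mismatched) parameters, plus the control input:
#' the membrane equation receives `-u`, where `u = u_drive - u_slave` is the
#' control difference appearing in the error dynamics (the drive is
#' unactuated, so the physically applied slave input is `-u`).  The recovery
#' equations are unaffected by `u`.  For noisy variants `noise_sample` must
#' be the *same* realization as the drive's (common noise).
#'
#' @inheritParams drive_rhs
#' @param hist Function returning the *slave* state at a lagged time.
#' @param u Length-`n` control difference (default zero).
#' @return Length-`2n` derivative vector.
#' @export
slave_rhs <- function(state, t, config, hist = NULL, noise_sample = NULL,
                      u = NULL) {
  p <- config$slave_params %||% config$params
  if (is.null(u)) u <- numeric(config$n)
  .network_rhs(state, t, config, hist, noise_sample,
               params = p, tau = config$delays$tau2,
               control = -u)
}

.network_rhs <- function(state, t, config, hist, noise_sample,
                         params, tau, control) {
  n <- config$n
  delayed <- startsWith(config$variant, "delayed")
  noisy <- endsWith(config$variant, "_noisy")
  if (delayed && is.null(hist))
    stop("delayed variant: a history lookup function is required")
  if (noisy && is.null(noise_sample))
    stop("noisy variant: a noise sample is required")
  xm <- state[seq_len(n)]
  xr <- state[n + seq_len(n)]
  xl <- if (delayed) hist(t - tau)[seq_len(n)] else xm
  Aw <- ees_amp_factor(config$ees)
  I <- Aw * cos(config$ees$omega * t)
  dd <- disturbance_value(config$disturbances, t)
  dm <- cubic_term(xm, params$r) - xr +
    as.vector(config$coupling$G %*% xl) + I + dd
  if (noisy) dm <- dm + noise_sample
  if (!is.null(control)) dm <- dm + control
  c(dm, params$b * xm - params$c * xr)
}

## ---- fixed-step integrators -------------------------------------------

#' One classical Runge-Kutta (RK4) step
#'
#' @param f Vector field, called as `f(state, t)`.
#' @param state Current state.
#' @param t Current time.
#' @param dt Step size (positive).
#' @return The state advanced by `dt`.
#' @examples
#' step_rk4(function(s, t) -s, 1, 0, 0.1)  # ~ exp(-0.1)
#' @export
step_rk4 <- function(f, state, t, dt) {
  stopifnot(dt > 0)
  k1 <- f(state, t)
  k2 <- f(state + dt / 2 * k1, t + dt / 2)
  k3 <- f(state + dt / 2 * k2, t + dt / 2)
  k4 <- f(state + dt * k3, t + dt)
  state + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
}

#' One Euler-Maruyama step with additive noise
#'
#' Advances by an explicit Euler step and then adds the supplied noise
#' increments to the components in `index`.  With zero (or no) increments
#' this is exactly the explicit Euler step.
#'
#' @inheritParams step_rk4
#' @param increments Additive noise increments (already scaled, e.g. by
#'   [noise_increment()]), or `NULL`.
#' @param index Indices of the state components receiving the increments.
#' @export
step_em <- function(f, state, t, dt, increments = NULL, index = NULL) {
  stopifnot(dt > 0)
  state <- state + dt * f(state, t)
  if (!is.null(increments)) {
    if (is.null(index)) index <- seq_along(increments)
    state[index] <- state[index] + increments
  }
  state
}

#' Gaussian noise increments for one Euler-Maruyama step
#'
#' Draws `n` increments with standard deviation `sqrt(2 * D * dt)`, the
#' discretization of zero-mean white noise with autocorrelation
#' `2 D delta(t - t')`.
#'
#' @param n Number of increments.
#' @param D Noise intensity (non-negative).
#' @param dt Step size.
#' @return Length-`n` numeric vector.
#' @export
noise_increment <- function(n, D, dt) {
  sqrt(2 * D * dt) * stats::rnorm(n)
}

## ---- trajectory lookup -------------------------------------------------

#' Interpolating state lookup on a simulated trajectory
#'
#' Returns a function of one time argument giving the (linearly
#' interpolated) state of the requested network; times at or before the
#' start return the initial state (the constant pre-history used for
#' delayed runs).  Lookups at grid points are exact.
#'
#' @param traj An `"fhn_trajectory"` from [run_simulation()].
#' @param network `"drive"` or `"slave"`.
#' @return A function `function(t)` returning a length-`2n` state.
#' @export
state_lookup <- function(traj, network = c("drive", "slave")) {
  network <- match.arg(network)
  H <- traj[[network]]
  t0 <- traj$times[1L]
  dt <- traj$dt
  nr <- nrow(H)
  function(t) {
    pos <- (t - t0) / dt
    if (pos <= 0) return(H[1L, ])
    if (pos >= nr - 1L) return(H[nr, ])
    i0 <- floor(pos)
    fr <- pos - i0
    if (fr < 1e-12) return(H[i0 + 1L, ])
    (1 - fr) * H[i0 + 1L, ] + fr * H[i0 + 2L, ]
  }
}

## ---- main driver -------------------------------------------------------

#' Simulate a drive/slave FHN network pair
#'
#' Integrates the joint drive/slave system on a uniform grid with step
#' `dt`.  Deterministic variants use the classical 4th-order Runge-Kutta
#' scheme; noisy variants use Euler-Maruyama with additive membrane
#' increments of standard deviation `sqrt(2 D dt)`, with one common
#' realization injected into both networks when `noise$common` is `TRUE`.
#' Delayed variants keep the full past on the step grid and look lagged
#' states up by linear interpolation (exact when the delays are integer
#' multiples of `dt`; the pre-history for `t < 0` is the constant initial
#' condition).
#'
#' The controller is inactive for `t < schedule$t_on`.  When active, the
#' slave membrane equations receive `+u` for the non-delayed law and `-u`
#' for the delayed law, where `u` is the respective law's control signal
#' ([control_nondelayed()], [control_delayed()]); these are the
#' placements under which each law's Lyapunov balance is stabilizing.  The
#' recorded `control` column is the *applied* slave membrane input.
#'
#' The stored `errors` are the instantaneous half-differences for
#' non-delayed variants and the lagged errors of [lag_error()] for delayed
#' variants.
#'
#' @param config An [network_config()].
#' @param schedule A [controller_schedule()]; defaults to no control.
#' @param t_end Final time (the grid is `seq(0, t_end, by = dt)`).
#' @param dt Step size (default 0.005).
#' @param seed Optional integer seed; required for reproducible noisy runs
#'   and recorded in the result.
#' @param method `"auto"` (RK4 for deterministic, Euler-Maruyama for noisy
#'   variants), `"rk4"`, or `"euler"`.  Noisy variants require `"euler"`.
#' @return An object of class `"fhn_trajectory"`: a list with `times`
#'   (length `T`), `drive`, `slave` (`T x 2n` state matrices), `control`
#'   (`T x n` applied slave input), `errors` (`T x 2n`, membrane then
#'   recovery), `controller_active` (logical), and the run metadata
#'   (`config`, `schedule`, `dt`, `seed`, `method`).
#' @examples
#' sc <- fhn_scenario("nondelayed_nonnoisy")
#' tr <- run_simulation(sc$config, sc$schedule, t_end = 2)
#' range(tr$errors)
#' @export
run_simulation <- function(config, schedule = controller_schedule("none"),
                           t_end, dt = 0.005, seed = NULL,
                           method = c("auto", "rk4", "euler")) {
  stopifnot(inherits(config, "fhn_network_config"),
            inherits(schedule, "controller_schedule"))
  method <- match.arg(method)
  if (!is.numeric(t_end) || t_end <= 0) stop("'t_end' must be positive")
  if (!is.numeric(dt) || dt <= 0) stop("'dt' must be positive")
  delayed <- startsWith(config$variant, "delayed")
  noisy <- endsWith(config$variant, "_noisy")
  law <- schedule$law
  if (law == "nondelayed" && delayed)
    stop("law 'nondelayed' cannot be scheduled for a delayed variant")
  if (law == "delayed" && !delayed)
    stop("law 'delayed' requires a delayed variant")
  if (law != "none" && t_end <= schedule$t_on)
    stop("controlled run: 't_end' must exceed the activation time t_on")
  if (method == "auto") method <- if (noisy) "euler" else "rk4"
  if (noisy && method == "rk4")
    stop("noisy variants use the Euler-Maruyama scheme (method = 'euler')")
  if (!is.null(seed)) set.seed(seed)

  n <- config$n
  p <- config$params
  sp <- config$slave_params %||% p
  r_d <- p$r; b_d <- p$b; c_d <- p$c
  r_s <- sp$r; b_s <- sp$b; c_s <- sp$c
  G <- config$coupling$G
  Aw <- ees_amp_factor(config$ees)
  w <- config$ees$omega
  amp <- config$disturbances$amplitude
  drt <- config$disturbances$rate
  tau1 <- config$delays$tau1
  tau2 <- config$delays$tau2
  gc <- schedule$gain_columns
  if (any(gc > n)) stop("gain_columns out of range")
  g1 <- G[, gc[1L]]; g2 <- G[, gc[2L]]
  t_on <- schedule$t_on
  D <- if (noisy) config$noise$D else 0
  common <- if (noisy) config$noise$common else TRUE
  eps <- config$slave_ic_perturbation

  im <- seq_len(n); ir <- n + im; jm <- 2L * n + im; jr <- 3L * n + im
  s0 <- c(config$drive_ic,
          config$slave_ic + c(rep(eps, n), rep(0, n)))
  nst <- as.integer(round(t_end / dt))
  H <- matrix(0, nst + 1L, 4L * n)
  H[1L, ] <- s0
  ctrl <- matrix(0, nst + 1L, n)
  zeros <- numeric(n)

  lookup <- function(tq) {
    pos <- tq / dt
    if (pos <= 0) return(s0)
    i0 <- floor(pos)
    fr <- pos - i0
    if (fr < 1e-12) return(H[i0 + 1L, ])
    (1 - fr) * H[i0 + 1L, ] + fr * H[i0 + 2L, ]
  }

  ## applied slave membrane input at a (stage) time
  applied_input <- function(s, t) {
    if (law == "none" || t < t_on) return(zeros)
    if (law == "nondelayed") {
      ex <- (s[im] - s[jm]) / 2
      ey <- (s[ir] - s[jr]) / 2
      2 * ex * (g1 + Aw * sin(w * t) + b_d + c_d) -
        2 * ey * (g2 - Aw * cos(w * t) - b_d - c_d)
    } else {
      hx <- lookup(t - tau1)
      hy <- lookup(t - tau2)
      exT <- (hx[im] - hy[jm]) / 2
      eyT <- (hx[ir] - hy[jr]) / 2
      -(-g1 * (b_d - c_d) * exT - (b_d - c_d) * eyT)
    }
  }

  rhs <- function(s, t) {
    xm <- s[im]; xr <- s[ir]; ym <- s[jm]; yr <- s[jr]
    if (delayed) {
      xl <- lookup(t - tau1)[im]
      yl <- lookup(t - tau2)[jm]
    } else {
      xl <- xm; yl <- ym
    }
    I <- Aw * cos(w * t)
    dd <- amp * sin(drt * t)
    ua <- applied_input(s, t)
    c(cubic_term(xm, r_d) - xr + as.vector(G %*% xl) + I + dd,
      b_d * xm - c_d * xr,
      cubic_term(ym, r_s) - yr + as.vector(G %*% yl) + I + dd + ua,
      b_s * ym - c_s * yr)
  }

  sig <- sqrt(2 * D * dt)
  s <- s0
  ctrl[1L, ] <- applied_input(s, 0)
  for (k in seq_len(nst)) {
    t <- (k - 1L) * dt
    if (method == "rk4") {
      k1 <- rhs(s, t)
      k2 <- rhs(s + dt / 2 * k1, t + dt / 2)
      k3 <- rhs(s + dt / 2 * k2, t + dt / 2)
      k4 <- rhs(s + dt * k3, t + dt)
      s <- s + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    } else {
      s <- s + dt * rhs(s, t)
      if (noisy) {
        if (common) {
          z <- sig * stats::rnorm(n)
          s[im] <- s[im] + z
          s[jm] <- s[jm] + z
        } else {
          s[im] <- s[im] + sig * stats::rnorm(n)
          s[jm] <- s[jm] + sig * stats::rnorm(n)
        }
      }
    }
    if (anyNA(s) || any(!is.finite(s)) || max(abs(s)) > 1e6) {
      cond <- structure(
        class = c("fhn_divergence", "error", "condition"),
        list(message = sprintf(
          "simulation diverged (|state| > 1e6 or non-finite) at t = %.4f",
          k * dt), call = sys.call(-1L)))
      stop(cond)
    }
    H[k + 1L, ] <- s
    ctrl[k + 1L, ] <- applied_input(s, k * dt)
  }

  times <- seq(0, by = dt, length.out = nst + 1L)
  drive <- H[, c(im, ir), drop = FALSE]
  slave <- H[, c(jm, jr), drop = FALSE]
  errors <- if (!delayed) {
    (drive - slave) / 2
  } else {
    hx <- .lagged_states(H, s0, dt, tau1)
    hy <- .lagged_states(H, s0, dt, tau2)
    cbind((hx[, im, drop = FALSE] - hy[, jm, drop = FALSE]) / 2,
          (hx[, ir, drop = FALSE] - hy[, jr, drop = FALSE]) / 2)
  }
  structure(list(times = times, drive = drive, slave = slave,
                 control = ctrl, errors = errors,
                 controller_active = law != "none" & times >= t_on,
                 config = config, schedule = schedule,
                 dt = dt, seed = seed, method = method),
            class = "fhn_trajectory")
}

## rows of H linearly interpolated at t_k - tau, constant pre-history
.lagged_states <- function(H, s0, dt, tau) {
  nr <- nrow(H)
  pos <- (seq_len(nr) - 1L) - tau / dt
  i0 <- floor(pos)
  fr <- pos - i0
  out <- matrix(s0, nr, ncol(H), byrow = TRUE)
  ok <- pos >= 0
  if (any(ok)) {
    lo <- H[pmax(i0[ok], 0L) + 1L, , drop = FALSE]
    hi <- H[pmin(i0[ok] + 1L, nr - 1L) + 1L, , drop = FALSE]
    out[ok, ] <- (1 - fr[ok]) * lo + fr[ok] * hi
  }
  out
}

#' @export
print.fhn_trajectory <- function(x, ...) {
  n <- x$config$n
  cat("FHN drive/slave trajectory\n")
  cat("  variant:", x$config$variant, " law:", x$schedule$law,
      " t_on:", x$schedule$t_on, "\n")
  cat("  grid:   ", length(x$times), "points, dt =", x$dt,
      ", t in [", x$times[1L], ",", x$times[length(x$times)], "]\n")
  cat("  scheme: ", x$method,
      if (!is.null(x$seed)) paste0(" (seed ", x$seed, ")"), "\n")
  cat("  final max |error|:", format(max(abs(x$errors[nrow(x$errors), ]))),
      "\n")
  invisible(x)
}
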