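## The reduced synchronization-error system, used as an independent
## validation path for the direct two-network simulation.

#' Right-hand side of the reduced error system
#'
#' The error dynamics written directly in the half-difference variables
#' (for a single shared cubic steepness `r`):
#' \deqn{\dot e_x = -\tfrac12 r\, c_d + \tfrac12 (1+r)\, s_d
#'       - e_x - e_y + G e_x + u, \qquad
#'       \dot e_y = b e_x - c e_y,}
#' where `c_d = x^3 - y^3` and `s_d = x^2 - y^2` are the cubic and square
#' state differences supplied from the network trajectories, and `u` is the
#' control difference `u_drive - u_slave`.
#'
#' @param ex,ey Length-`n` error vectors.
#' @param t Time (unused by the autonomous part; kept for signature
#'   uniformity).
#' @param shared_r The single cubic steepness of the reduction.
#' @param b,c Length-`n` (or scalar) recovery parameters.
#' @param G `n x n` coupling matrix.
#' @param u Length-`n` control difference.
#' @param cd,sd Length-`n` cubic and square state differences.
#' @return A list with components `ex` and `ey` holding the derivatives.
#' @seealso [integrate_error_path()]
#' @export
error_system_rhs <- function(ex, ey, t, shared_r, b, c, G, u, cd, sd) {
  list(ex = -0.5 * shared_r * cd + 0.5 * (1 + shared_r) * sd -
         ex - ey + as.vector(G %*% ex) + u,
       ey = b * ex - c * ey)
}

#' Integrate the reduced error system along a simulated trajectory
#'
#' Re-derives the synchronization errors by integrating the reduced error
#' system with `c_d`, `s_d` and the matched control taken from a completed
#' two-network simulation, providing an independent consistency check of
#' the direct error trajectory (the two paths must agree up to integration
#' error).
#'
#' The reduction assumes one shared cubic steepness; with `strict = TRUE`
#' (default) heterogeneous `r` in the configuration is an error.  The
#' matched control is `u = -applied/2`, where `applied` is the recorded
#' slave membrane input (the drive is unactuated, so the control
#' *difference* per error equation is minus half the applied input).
#' For delayed variants the lagged differences are used.
#'
#' @param traj An `"fhn_trajectory"` from [run_simulation()].
#' @param shared_r Cubic steepness of the reduction; defaults to the first
#'   neuron's `r`.
#' @param strict Error out when the configuration's `r` are heterogeneous.
#' @return A `T x 2n` matrix of re-derived errors (membrane block first),
#'   on the same time grid as `traj`.
#' @export
integrate_error_path <- function(traj, shared_r = NULL, strict = TRUE) {
  cfg <- traj$config
  n <- cfg$n
  if (is.null(shared_r)) shared_r <- cfg$params$r[1L]
  if (strict && any(cfg$params$r != shared_r))
    stop("heterogeneous 'r' in config; the reduced error system assumes ",
         "a single shared r (set strict = FALSE to force)")
  b <- cfg$params$b
  c <- cfg$params$c
  G <- cfg$coupling$G
  dt <- traj$dt
  nt <- length(traj$times)
  delayed <- startsWith(cfg$variant, "delayed")
  im <- seq_len(n)

  if (delayed) {
    H <- cbind(traj$drive, traj$slave)
    s0 <- H[1L, ]
    x <- .lagged_states(H, s0, dt, cfg$delays$tau1)[, im, drop = FALSE]
    y <- .lagged_states(H, s0, dt,
                        cfg$delays$tau2)[, 2L * n + im, drop = FALSE]
  } else {
    x <- traj$drive[, im, drop = FALSE]
    y <- traj$slave[, im, drop = FALSE]
  }
  cd <- x^3 - y^3
  sd_ <- x^2 - y^2
  u <- -traj$control / 2

  interp <- function(M, pos) {
    ## linear interpolation of grid series at fractional row position
    i0 <- floor(pos)
    fr <- pos - i0
    lo <- M[min(i0, nt - 1L) + 1L, ]
    if (fr < 1e-12) return(lo)
    hi <- M[min(i0 + 1L, nt - 1L) + 1L, ]
    (1 - fr) * lo + fr * hi
  }

  E <- matrix(0, nt, 2L * n)
  ex <- traj$errors[1L, im]
  ey <- traj$errors[1L, n + im]
  E[1L, ] <- c(ex, ey)
  f <- function(e, pos) {
    d <- error_system_rhs(e[im], e[n + im], t = pos * dt,
                          shared_r = shared_r, b = b, c = c, G = G,
                          u = interp(u, pos), cd = interp(cd, pos),
                          sd = interp(sd_, pos))
    c(d$ex, d$ey)
  }
  e <- c(ex, ey)
  for (k in seq_len(nt - 1L)) {
    pos <- k - 1L
    k1 <- f(e, pos)
    k2 <- f(e + dt / 2 * k1, pos + 0.5)
    k3 <- f(e + dt / 2 * k2, pos + 0.5)
    k4 <- f(e + dt * k3, pos + 1)
    e <- e + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    E[k + 1L, ] <- e
  }
  E
}
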