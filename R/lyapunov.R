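## Numerical Lyapunov machinery: the quadratic candidate, its observed
## decay, the block stability matrices and positive-definiteness tests.

#' Quadratic Lyapunov candidate
#'
#' `V = (||e_x||^2 + ||e_y||^2) / 2`, the quadratic form whose decay along
#' trajectories certifies synchronization.  `V` is positive definite and
#' homogeneous of degree two.
#'
#' @param ex,ey Error vectors (membrane and recovery blocks).
#' @return A single non-negative number.
#' @export
lyapunov_V <- function(ex, ey) {
  0.5 * (sum(ex^2) + sum(ey^2))
}

#' Lyapunov candidate along a trajectory
#'
#' @param traj An `"fhn_trajectory"`.
#' @return Numeric vector `V(t)` on the trajectory's grid.
#' @export
lyapunov_series <- function(traj) {
  0.5 * rowSums(traj$errors^2)
}

#' Observed decay rate of the Lyapunov candidate
#'
#' Centered finite differences of `V` along the trajectory:
#' `(V[k+1] - V[k-1]) / (2 dt)` at the interior grid points.
#'
#' @param traj An `"fhn_trajectory"` with at least three grid points.
#' @return A data frame with columns `time` and `vdot` (length `T - 2`).
#' @export
vdot_series <- function(traj) {
  V <- lyapunov_series(traj)
  nt <- length(V)
  if (nt < 3L) stop("trajectory must have at least 3 points")
  i <- 2L:(nt - 1L)
  data.frame(time = traj$times[i],
             vdot = (V[i + 1L] - V[i - 1L]) / (2 * traj$dt))
}

#' Leading principal minors
#'
#' Determinants of the top-left `k x k` submatrices, `k = 1, ..., m`.  All
#' positive is Sylvester's criterion for positive definiteness of a
#' *symmetric* matrix; for a triangular matrix the minors are the
#' cumulative products of the diagonal.
#'
#' @param M A square numeric matrix.
#' @return Numeric vector of length `nrow(M)`.
#' @examples
#' leading_principal_minors(matrix(c(2, 1, 1, 2), 2))  # 2, 3
#' @export
leading_principal_minors <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("matrix must be square")
  vapply(seq_len(nrow(M)),
         function(k) det(M[seq_len(k), seq_len(k), drop = FALSE]),
         numeric(1L))
}

#' Positive-definiteness verdicts
#'
#' Two tests reported side by side: `pd_by_minors` applies Sylvester's
#' leading-principal-minors criterion to `M` exactly as given (the
#' criterion is conclusive only for symmetric matrices, but the stability
#' matrices assembled here are not symmetric, so this is the "as-printed"
#' verdict); `pd_by_eigen_symmetric_part` checks that all eigenvalues of
#' `(M + t(M)) / 2` are positive, which is necessary and sufficient for
#' `x' M x > 0` for all nonzero `x` and is the mathematically binding test.
#' For symmetric `M` the two verdicts coincide.
#'
#' @param M A square numeric matrix.
#' @return A list with logical fields `pd_by_minors` and
#'   `pd_by_eigen_symmetric_part`, plus `minors` and `min_eig_sym`.
#' @export
pd_verdict <- function(M) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("matrix must be square")
  minors <- leading_principal_minors(M)
  ev <- eigen((M + t(M)) / 2, symmetric = TRUE, only.values = TRUE)$values
  list(pd_by_minors = all(minors > 0),
       pd_by_eigen_symmetric_part = all(ev > 0),
       minors = minors,
       min_eig_sym = min(ev))
}

#' Stability block matrix, non-delayed configuration
#'
#' Assembles the time-dependent `2n x 2n` block matrix whose positive
#' definiteness makes the bound `Vdot <= -E P E'` negative for the
#' non-delayed error system under the non-delayed control law.  With
#' `I` the `n x n` identity and scalars broadcast onto identity blocks:
#' top-left
#' `(r/2 - (1+r)/2) I + I - 2G - (2 g_i1 + 2(A/w) sin(wt) + 2 b_i + 2 c_i) I`,
#' top-right `I + (2 g_i2 - 2(A/w) cos(wt) - 2 b_i - 2 c_i) I`,
#' bottom-left `-b_i I`, bottom-right `c_i I`.
#'
#' The first two scalar terms derive from the trajectory bounds on the
#' square and cubic state differences; the plain form above omits the
#' bound factors, and supplying `q = c(q1, q2)` (see
#' [estimate_bounds_q()]) produces the bound-consistent variant
#' `((r/2) q2 - ((1+r)/2) q1) I + ...` instead.
#'
#' @param t Evaluation time (the matrix is `1/f`-periodic in `t`).
#' @param config A non-delayed [network_config()].
#' @param schedule A [controller_schedule()] supplying `gain_columns`.
#' @param shared_r Single cubic steepness of the reduction; defaults to the
#'   first neuron's `r` (use `max(config$params$r)` for a conservative
#'   variant).
#' @param neuron_index Which neuron's row supplies the gains `g_i1`,
#'   `g_i2` and the scalars `b_i`, `c_i`.
#' @param q Optional `c(q1, q2)` trajectory bounds for the bound-consistent
#'   variant.
#' @return A `2n x 2n` numeric matrix.
#' @export
build_P_nondelayed <- function(t, config, schedule, shared_r = NULL,
                               neuron_index = 1L, q = NULL) {
  if (startsWith(config$variant, "delayed"))
    stop("build_P_nondelayed() requires a non-delayed configuration")
  n <- config$n
  stopifnot(neuron_index >= 1L, neuron_index <= n)
  r <- shared_r %||% config$params$r[1L]
  bi <- config$params$b[neuron_index]
  ci <- config$params$c[neuron_index]
  gc <- schedule$gain_columns
  gi1 <- config$coupling$G[neuron_index, gc[1L]]
  gi2 <- config$coupling$G[neuron_index, gc[2L]]
  Aw <- ees_amp_factor(config$ees)
  w <- config$ees$omega
  I <- diag(n)
  lead <- if (is.null(q)) {
    r / 2 - (1 + r) / 2
  } else {
    (r / 2) * q[2L] - ((1 + r) / 2) * q[1L]
  }
  TL <- (lead + 1 - 2 * gi1 - 2 * Aw * sin(w * t) - 2 * bi - 2 * ci) * I -
    2 * config$coupling$G
  TR <- (1 + 2 * gi2 - 2 * Aw * cos(w * t) - 2 * bi - 2 * ci) * I
  rbind(cbind(TL, TR),
        cbind(-bi * I, ci * I))
}

#' Stability block matrix, delayed configuration
#'
#' The time-independent `2n x 2n` block matrix of the delayed error system
#' under the delayed control law, with trajectory bounds `q1` (on
#' `|x| + |y|`) and `q2` (on the cubic-difference factor
#' `x^2 + |x||y| + y^2`): top-left
#' `((r/2) q2 - ((1+r)/2) q1) I + I - G + (g_i1 b_i - g_i1 c_i) I`,
#' top-right `I + (b_i - c_i) I`, bottom-left `-b_i I`, bottom-right
#' `c_i I`.
#'
#' @param config A delayed [network_config()].
#' @param schedule A [controller_schedule()] supplying `gain_columns`.
#' @param shared_r Single cubic steepness; defaults to the first neuron's.
#' @param q1,q2 Non-negative trajectory bounds (see [estimate_bounds_q()]).
#' @param neuron_index Which neuron's row supplies `g_i1`, `b_i`, `c_i`.
#' @return A `2n x 2n` numeric matrix.
#' @export
build_P_delayed <- function(config, schedule, shared_r = NULL,
                            q1, q2, neuron_index = 1L) {
  if (!startsWith(config$variant, "delayed"))
    stop("build_P_delayed() requires a delayed configuration")
  stopifnot(q1 >= 0, q2 >= 0)
  n <- config$n
  stopifnot(neuron_index >= 1L, neuron_index <= n)
  r <- shared_r %||% config$params$r[1L]
  bi <- config$params$b[neuron_index]
  ci <- config$params$c[neuron_index]
  gc <- schedule$gain_columns
  gi1 <- config$coupling$G[neuron_index, gc[1L]]
  I <- diag(n)
  TL <- ((r / 2) * q2 - ((1 + r) / 2) * q1 + 1 + gi1 * bi - gi1 * ci) * I -
    config$coupling$G
  TR <- (1 + bi - ci) * I
  rbind(cbind(TL, TR),
        cbind(-bi * I, ci * I))
}

#' Trajectory bounds for the stability matrices
#'
#' Estimates the bounds used by the delayed stability matrix from a
#' simulated run: `q1 = (1 + margin) * max_i (max_t |x_i| + max_t |y_i|)`
#' over the drive (`x`) and slave (`y`) membrane potentials, and
#' `q2 = (1 + margin) * max_{i,t} (x^2 + |x||y| + y^2)`, the factor
#' bounding `|x^3 - y^3| / |x - y|`.
#'
#' Both bounds are monotone under extension of the trajectory: appending
#' states can only increase them.
#'
#' @param traj An `"fhn_trajectory"`.
#' @param margin Non-negative safety margin (both bounds are scaled by
#'   `1 + margin`).
#' @return A list with fields `q1` and `q2`.
#' @export
estimate_bounds_q <- function(traj, margin = 0) {
  stopifnot(margin >= 0)
  n <- traj$config$n
  if (nrow(traj$drive) == 0L) stop("empty trajectory")
  x <- traj$drive[, seq_len(n), drop = FALSE]
  y <- traj$slave[, seq_len(n), drop = FALSE]
  q1 <- max(apply(abs(x), 2L, max) + apply(abs(y), 2L, max))
  q2 <- max(x^2 + abs(x) * abs(y) + y^2)
  list(q1 = (1 + margin) * q1, q2 = (1 + margin) * q2)
}

#' Sweep the non-delayed stability matrix over one EES period
#'
#' Evaluates [build_P_nondelayed()] on `n_samples` times spanning one
#' stimulation period `1/f` and reports, per sample, the minors verdict
#' and the minimum eigenvalue of the symmetric part.  The reported `P`,
#' `minors` and verdicts belong to the worst sample (minimal symmetric-part
#' eigenvalue).  The verdicts are reported, not asserted: whether this
#' matrix is in fact positive definite for realistic parameters is an open
#' property of the construction.
#'
#' @inheritParams build_P_nondelayed
#' @param n_samples Number of samples over one period (at least 1; with
#'   `A = 0` the matrix is time-independent and all samples coincide).
#' @return A `"stability_report"`: list with `P`, `minors`,
#'   `pd_by_minors`, `pd_by_eigen_symmetric_part`, `q1`, `q2` (`NA` here),
#'   `t_evaluated = "sweep"`, `min_eig_over_sweep` and a per-sample data
#'   frame `samples`.
#' @export
pd_sweep_over_period <- function(config, schedule, shared_r = NULL,
                                 n_samples = 64L, neuron_index = 1L,
                                 q = NULL) {
  if (startsWith(config$variant, "delayed"))
    stop("pd_sweep_over_period() requires a non-delayed configuration")
  stopifnot(n_samples >= 1L)
  f <- config$ees$f
  times <- if (config$ees$A == 0 || f == 0) {
    0
  } else {
    seq(0, 1 / abs(f), length.out = n_samples + 1L)[seq_len(n_samples)]
  }
  res <- lapply(times, function(t) {
    P <- build_P_nondelayed(t, config, schedule, shared_r = shared_r,
                            neuron_index = neuron_index, q = q)
    v <- pd_verdict(P)
    list(P = P, v = v, t = t)
  })
  eigs <- vapply(res, function(z) z$v$min_eig_sym, numeric(1L))
  worst <- which.min(eigs)
  samples <- data.frame(
    t = vapply(res, `[[`, numeric(1L), "t"),
    min_eig_sym = eigs,
    minors_all_positive = vapply(res, function(z) z$v$pd_by_minors,
                                 logical(1L)))
  new_stability_report(
    P = res[[worst]]$P,
    minors = res[[worst]]$v$minors,
    pd_by_minors = all(samples$minors_all_positive),
    pd_by_eigen_symmetric_part = all(eigs > 0),
    q1 = NA_real_, q2 = NA_real_,
    t_evaluated = "sweep",
    min_eig_over_sweep = min(eigs),
    samples = samples)
}

#' Stability report for a delayed run
#'
#' The full pipeline for a delayed configuration: estimate the trajectory
#' bounds from a simulated run, assemble the delayed stability matrix and
#' test it for positive definiteness.
#'
#' @param traj An `"fhn_trajectory"` of a delayed variant.
#' @param margin Safety margin for [estimate_bounds_q()].
#' @param neuron_index,shared_r Passed to [build_P_delayed()].
#' @return A `"stability_report"` (see [pd_sweep_over_period()]), with
#'   `t_evaluated = NA` (the delayed matrix is time-independent).
#' @export
stability_report_delayed <- function(traj, margin = 0, neuron_index = 1L,
                                     shared_r = NULL) {
  q <- estimate_bounds_q(traj, margin = margin)
  P <- build_P_delayed(traj$config, traj$schedule, shared_r = shared_r,
                       q1 = q$q1, q2 = q$q2, neuron_index = neuron_index)
  v <- pd_verdict(P)
  new_stability_report(
    P = P, minors = v$minors,
    pd_by_minors = v$pd_by_minors,
    pd_by_eigen_symmetric_part = v$pd_by_eigen_symmetric_part,
    q1 = q$q1, q2 = q$q2,
    t_evaluated = NA_real_,
    min_eig_over_sweep = v$min_eig_sym,
    samples = NULL)
}

new_stability_report <- function(P, minors, pd_by_minors,
                                 pd_by_eigen_symmetric_part, q1, q2,
                                 t_evaluated, min_eig_over_sweep,
                                 samples) {
  structure(list(P = P, minors = minors, pd_by_minors = pd_by_minors,
                 pd_by_eigen_symmetric_part = pd_by_eigen_symmetric_part,
                 q1 = q1, q2 = q2, t_evaluated = t_evaluated,
                 min_eig_over_sweep = min_eig_over_sweep,
                 samples = samples),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat("Stability report (", nrow(x$P), "x", ncol(x$P), " block matrix)\n",
      sep = "")
  cat("  PD by leading principal minors:  ", x$pd_by_minors, "\n")
  cat("  PD by symmetric-part eigenvalues:", x$pd_by_eigen_symmetric_part,
      "\n")
  cat("  min symmetric-part eigenvalue:   ",
      format(x$min_eig_over_sweep), "\n")
  if (!is.na(x$q1)) cat("  q1 =", format(x$q1), " q2 =", format(x$q2), "\n")
  invisible(x)
}

#' Serialize a stability report to JSON
#'
#' @param report A `"stability_report"`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_stability <- function(report, path) {
  out <- list(
    P = unname(apply(report$P, 1L, function(r) as.numeric(r),
                     simplify = FALSE)),
    minors = report$minors,
    pd_by_minors = report$pd_by_minors,
    pd_by_eigen_symmetric_part = report$pd_by_eigen_symmetric_part,
    q1 = report$q1, q2 = report$q2,
    t_evaluated = report$t_evaluated,
    min_eig_over_sweep = report$min_eig_over_sweep)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
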