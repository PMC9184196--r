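## Synchronization metrics, convergence detection and trajectory export.

#' Synchronization error norm over time
#'
#' Per-time norm over all `2n` error components of a trajectory: the
#' maximum absolute component (`"max"`) or the Euclidean norm (`"l2"`).
#'
#' @param traj An `"fhn_trajectory"`.
#' @param norm `"max"` or `"l2"`.
#' @return Numeric vector on the trajectory's time grid.
#' @export
sync_error_norm <- function(traj, norm = c("max", "l2")) {
  norm <- match.arg(norm)
  E <- traj$errors
  if (norm == "max") {
    do.call(pmax, c(as.data.frame(abs(E)), list(na.rm = FALSE)))
  } else {
    sqrt(rowSums(E^2))
  }
}

#' Detect synchronization convergence
#'
#' Finds the first time `t >= t_on` from which the max-norm error stays
#' below `tol` all the way to the end of the run, requiring at least `hold`
#' time units of sustained sub-tolerance behaviour.  This operationalizes
#' "the errors converged to zero" with an explicit tolerance and holding
#' time.
#'
#' @param traj An `"fhn_trajectory"`.
#' @param tol Positive tolerance (default `1e-3`).
#' @param hold Required holding duration in time units (default `10`).
#' @return A list of class `"fhn_convergence"` with fields `converged`,
#'   `t_converge` (`NA` when never), `sup_error_after` (supremum of the
#'   max-norm error from `t_converge` to the end; `NA` when not
#'   converged), `tol`, `hold` and `t_on`.
#' @export
convergence_time <- function(traj, tol = 1e-3, hold = 10) {
  stopifnot(tol > 0, hold >= 0)
  times <- traj$times
  t_on <- if (traj$schedule$law == "none") times[1L] else traj$schedule$t_on
  t_end <- times[length(times)]
  if (t_on + hold > t_end)
    stop("holding duration extends beyond the simulated horizon")
  nrm <- sync_error_norm(traj, "max")
  below <- nrm < tol
  eligible <- times >= t_on
  ## first index from which 'below' holds through the end of the run
  idx <- which(eligible & below)
  t_converge <- NA_real_
  if (length(idx)) {
    ## find the start of the terminal all-below run
    last_bad <- which(eligible & !below)
    start <- if (length(last_bad)) max(last_bad) + 1L else min(which(eligible))
    if (start <= length(times) && all(below[start:length(below)])) {
      if (t_end - times[start] >= hold) t_converge <- times[start]
    }
  }
  converged <- !is.na(t_converge)
  sup_after <- if (converged)
    max(nrm[times >= t_converge]) else NA_real_
  structure(list(converged = converged, t_converge = t_converge,
                 sup_error_after = sup_after, tol = tol, hold = hold,
                 t_on = t_on),
            class = "fhn_convergence")
}

#' @export
print.fhn_convergence <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "converged: yes  (t_converge = %.3f, sup error after = %.3g, tol = %g)\n",
      x$t_converge, x$sup_error_after, x$tol))
  } else {
    cat(sprintf("converged: no   (tol = %g, hold = %g)\n", x$tol, x$hold))
  }
  invisible(x)
}

#' Drive/slave phase-plane pairs
#'
#' The paired series `(drive value, slave value)` of one neuron's membrane
#' or recovery state.  When the networks are synchronized the points
#' collapse onto the identity diagonal.
#'
#' @param traj An `"fhn_trajectory"`.
#' @param neuron Neuron index in `1..n`.
#' @param block `"membrane"` or `"recovery"`.
#' @return A data frame with columns `time`, `drive`, `slave`.
#' @export
phase_plane_pairs <- function(traj, neuron,
                              block = c("membrane", "recovery")) {
  block <- match.arg(block)
  n <- traj$config$n
  if (neuron < 1L || neuron > n) stop("'neuron' out of range 1..", n)
  col <- if (block == "membrane") neuron else n + neuron
  data.frame(time = traj$times,
             drive = traj$drive[, col],
             slave = traj$slave[, col])
}

#' Export / re-import a simulated run
#'
#' Writes a long-format CSV of the trajectory (columns `time`, `network`,
#' `neuron`, `state`, `value`, with `network` one of `drive`, `slave`,
#' `error`, `control`), a JSON metadata file (configuration, schedule,
#' seed, step size, scheme) and, optionally, a JSON stability report.
#' Values are printed with 17 significant digits, so re-reading reproduces
#' the series exactly.
#'
#' @param traj An `"fhn_trajectory"`.
#' @param path Existing destination directory.
#' @param stability Optional `"stability_report"` to include.
#' @param thin Keep every `thin`-th time point (default all).
#' @return Invisibly, the named character vector of files written.
#' @export
export_run <- function(traj, path, stability = NULL, thin = 1L) {
  if (!dir.exists(path))
    stop("destination directory does not exist: ", path)
  thin <- as.integer(thin)
  stopifnot(thin >= 1L)
  keep <- seq(1L, length(traj$times), by = thin)
  n <- traj$config$n
  states <- c(rep("membrane", n), rep("recovery", n))
  neurons <- rep(seq_len(n), 2L)
  t <- traj$times[keep]

  block_df <- function(M, network, states, neurons) {
    data.frame(
      time = rep(t, times = ncol(M)),
      network = network,
      neuron = rep(neurons, each = length(t)),
      state = rep(states, each = length(t)),
      value = as.vector(M[keep, , drop = FALSE]))
  }
  long <- rbind(
    block_df(traj$drive, "drive", states, neurons),
    block_df(traj$slave, "slave", states, neurons),
    block_df(traj$errors, "error", states, neurons),
    block_df(traj$control, "control", rep("input", n), seq_len(n)))
  long$value <- sprintf("%.17g", long$value)
  traj_file <- file.path(path, "trajectory.csv")
  utils::write.csv(long, traj_file, row.names = FALSE, quote = FALSE)

  cfg <- traj$config
  meta <- list(
    variant = cfg$variant, n = n,
    r = cfg$params$r, b = cfg$params$b, c = cfg$params$c,
    ees_A = cfg$ees$A, ees_f = cfg$ees$f,
    dist_amplitude = cfg$disturbances$amplitude,
    dist_rate = cfg$disturbances$rate,
    coupling = unname(apply(cfg$coupling$G, 1L, as.numeric,
                            simplify = FALSE)),
    tau1 = cfg$delays$tau1, tau2 = cfg$delays$tau2,
    noise_D = if (is.null(cfg$noise)) NULL else cfg$noise$D,
    noise_common = if (is.null(cfg$noise)) NULL else cfg$noise$common,
    drive_ic = cfg$drive_ic, slave_ic = cfg$slave_ic,
    slave_ic_perturbation = cfg$slave_ic_perturbation,
    law = traj$schedule$law, t_on = traj$schedule$t_on,
    gain_columns = traj$schedule$gain_columns,
    dt = traj$dt, seed = traj$seed, method = traj$method,
    t_end = traj$times[length(traj$times)], thin = thin)
  meta_file <- file.path(path, "metadata.json")
  jsonlite::write_json(Filter(Negate(is.null), meta), meta_file,
                       auto_unbox = TRUE, digits = NA)
  files <- c(trajectory = traj_file, metadata = meta_file)
  if (!is.null(stability)) {
    stab_file <- file.path(path, "stability.json")
    write_stability(stability, stab_file)
    files <- c(files, stability = stab_file)
  }
  invisible(files)
}

#' @param path Directory previously written by [export_run()].
#' @rdname export_run
#' @return `read_run()` returns a list with elements `trajectory` (long
#'   data frame with numeric `value`) and `metadata`.
#' @export
read_run <- function(path) {
  traj_file <- file.path(path, "trajectory.csv")
  meta_file <- file.path(path, "metadata.json")
  if (!file.exists(traj_file)) stop("no trajectory.csv under ", path)
  long <- utils::read.csv(traj_file, stringsAsFactors = FALSE)
  long$value <- as.numeric(long$value)
  meta <- jsonlite::read_json(meta_file, simplifyVector = TRUE)
  list(trajectory = long, metadata = meta)
}
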