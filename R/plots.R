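## Error time-series and phase-plane figures (base graphics).

#' Plot per-neuron synchronization errors
#'
#' One panel per neuron showing the error time series of the chosen block,
#' with an optional uncontrolled run overlaid and a vertical marker at the
#' controller activation time.  Controlled runs are drawn in red, the
#' uncontrolled companion in blue.
#'
#' @param traj An `"fhn_trajectory"` (typically the controlled run).
#' @param uncontrolled Optional second `"fhn_trajectory"` to overlay.
#' @param block `"membrane"` or `"recovery"`.
#' @param file Optional PNG path; when given the figure is written there,
#'   otherwise the current device is used.
#' @return Invisibly, a list with `panels` (number of panels drawn) and
#'   `t_on` (marker position, `NA` when uncontrolled).
#' @export
plot_errors <- function(traj, uncontrolled = NULL,
                        block = c("membrane", "recovery"), file = NULL) {
  block <- match.arg(block)
  if (length(traj$times) == 0L) stop("empty trajectory")
  n <- traj$config$n
  cols <- if (block == "membrane") seq_len(n) else n + seq_len(n)
  t_on <- if (traj$schedule$law == "none") NA_real_ else traj$schedule$t_on
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 180 * n)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(n, 1L), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  for (i in seq_len(n)) {
    ci <- cols[i]
    ylim <- range(traj$errors[, ci],
                  if (!is.null(uncontrolled)) uncontrolled$errors[, ci])
    graphics::plot(traj$times, traj$errors[, ci], type = "l", col = "red",
                   xlab = "t", ylab = sprintf("e[%s %d]", block, i),
                   ylim = ylim,
                   main = sprintf("%s error, neuron %d", block, i))
    if (!is.null(uncontrolled))
      graphics::lines(uncontrolled$times, uncontrolled$errors[, ci],
                      col = "blue")
    if (!is.na(t_on)) graphics::abline(v = t_on, lty = 2, col = "grey40")
  }
  invisible(list(panels = n, t_on = t_on))
}

#' Plot drive-slave phase planes
#'
#' One panel per neuron plotting the slave state against the drive state
#' of the chosen block; synchronized segments collapse onto the identity
#' diagonal (drawn dashed).
#'
#' @inheritParams plot_errors
#' @return Invisibly, a list with `panels`.
#' @export
plot_phase <- function(traj, uncontrolled = NULL,
                       block = c("membrane", "recovery"), file = NULL) {
  block <- match.arg(block)
  if (length(traj$times) == 0L) stop("empty trajectory")
  n <- traj$config$n
  if (!is.null(file)) {
    grDevices::png(file, width = 600, height = 200 * n)
    on.exit(grDevices::dev.off())
  }
  op <- graphics::par(mfrow = c(n, 1L), mar = c(4, 4, 1.5, 1))
  on.exit(graphics::par(op), add = TRUE, after = FALSE)
  for (i in seq_len(n)) {
    pp <- phase_plane_pairs(traj, i, block)
    graphics::plot(pp$drive, pp$slave, type = "l", col = "red",
                   xlab = sprintf("drive %s %d", block, i),
                   ylab = sprintf("slave %s %d", block, i),
                   main = sprintf("phase plane, %s neuron %d", block, i))
    if (!is.null(uncontrolled)) {
      pu <- phase_plane_pairs(uncontrolled, i, block)
      graphics::lines(pu$drive, pu$slave, col = "blue")
    }
    graphics::abline(0, 1, lty = 2, col = "grey40")
  }
  invisible(list(panels = n))
}
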