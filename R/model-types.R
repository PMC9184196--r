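#' Per-neuron FitzHugh-Nagumo parameters
#'
#' Bundles the three positive parameters of each neuron: the cubic steepness
#' `r` (the membrane nonlinearity is `x(x-1)(1-rx)`), the recovery gain `b`
#' and the recovery decay `c` (the recovery variable obeys
#' `dx2/dt = b*x1 - c*x2`).
#'
#' @param r,b,c Numeric vectors of positive values, recycled to a common
#'   length (one entry per neuron).
#' @return A data frame of class `"fhn_params"` with columns `r`, `b`, `c`.
#' @examples
#' fhn_params(r = c(10, 10.2), b = 1, c = 0.001)
#' @export
fhn_params <- function(r, b, c) {
  n <- max(length(r), length(b), length(c))
  r <- rep_len(as.numeric(r), n)
  b <- rep_len(as.numeric(b), n)
  c <- rep_len(as.numeric(c), n)
  if (!all(is.finite(r)) || any(r <= 0)) stop("'r' must be finite and positive")
  if (!all(is.finite(b)) || any(b <= 0)) stop("'b' must be finite and positive")
  if (!all(is.finite(c)) || any(c <= 0)) stop("'c' must be finite and positive")
  structure(data.frame(r = r, b = b, c = c),
            class = c("fhn_params", "data.frame"))
}

#' Cubic FHN membrane nonlinearity
#'
#' Evaluates `x * (x - 1) * (1 - r * x)`, the excitable nonlinearity of the
#' membrane equation.  Its roots are exactly `0`, `1` and `1/r`.
#'
#' @param x Membrane potential (vectorized).
#' @param r Cubic steepness parameter (positive; vectorized).
#' @return `x (x - 1) (1 - r x)`, elementwise.
#' @examples
#' cubic_term(0.5, 10)  # 1
#' @export
cubic_term <- function(x, r) {
  x * (x - 1) * (1 - r * x)
}

#' External electrical stimulation (EES) drive
#'
#' The EES current applied identically to every neuron of both networks:
#' `I(t) = (A / omega) * cos(omega * t)` with `omega = 2 * pi * f`.  The
#' angular frequency is always derived from `f` and never stored
#' independently, so the amplitude factor `A/omega` and the phase can never
#' disagree.
#'
#' @param A Stimulation amplitude.
#' @param f Stimulation frequency (model units).
#' @return An object of class `"ees_drive"` with fields `A`, `f` and the
#'   derived `omega`.
#' @seealso [ees_current()]
#' @export
ees_drive <- function(A, f) {
  stopifnot(is.numeric(A), length(A) == 1L, is.finite(A),
            is.numeric(f), length(f) == 1L, is.finite(f))
  structure(list(A = as.numeric(A), f = as.numeric(f),
                 omega = 2 * pi * as.numeric(f)),
            class = "ees_drive")
}

#' Evaluate the EES current
#'
#' @param ees An [ees_drive()] object.
#' @param t Time (vectorized).
#' @return `(A/omega) * cos(omega * t)`; bounded by `A/omega` in absolute
#'   value and periodic with period `1/f`.
#' @examples
#' ees_current(ees_drive(A = 0.1, f = 0.129), 0)
#' @export
ees_current <- function(ees, t) {
  stopifnot(inherits(ees, "ees_drive"))
  if (ees$f == 0) stop("invalid EES drive: frequency f must be nonzero")
  (ees$A / ees$omega) * cos(ees$omega * t)
}

#' Ionic gate disturbance
#'
#' A bounded deterministic disturbance `d(t) = amplitude * sin(rate * t)`
#' acting on the membrane equation of each neuron (identically in the drive
#' and slave networks, so it cancels from the synchronization error).
#'
#' @param amplitude,rate Numeric vectors, recycled to a common length (one
#'   entry per neuron).
#' @return A data frame of class `"ionic_disturbance"` with columns
#'   `amplitude` and `rate`.
#' @export
ionic_disturbance <- function(amplitude, rate) {
  n <- max(length(amplitude), length(rate))
  amplitude <- rep_len(as.numeric(amplitude), n)
  rate <- rep_len(as.numeric(rate), n)
  if (!all(is.finite(amplitude)) || !all(is.finite(rate)))
    stop("'amplitude' and 'rate' must be finite")
  structure(data.frame(amplitude = amplitude, rate = rate),
            class = c("ionic_disturbance", "data.frame"))
}

#' Evaluate an ionic disturbance at one time
#'
#' @param d An [ionic_disturbance()] object.
#' @param t A single time.
#' @return Numeric vector (one value per neuron): `amplitude * sin(rate*t)`.
#' @export
disturbance_value <- function(d, t) {
  stopifnot(inherits(d, "ionic_disturbance"), length(t) == 1L)
  d$amplitude * sin(d$rate * t)
}

#' Additive Gaussian membrane noise specification
#'
#' Zero-mean Gaussian white noise of intensity `D` (autocorrelation
#' `2 D delta(t - t')`) on the membrane equations.  By default the *same*
#' realization is injected into the drive and the slave network
#' (`common = TRUE`), matching the shared-noise-source model; the noise term
#' then cancels exactly from the error dynamics.
#'
#' @param D Non-negative noise intensity.
#' @param common Logical; inject one common realization into both networks
#'   (default) or independent realizations.
#' @param seed Optional integer recorded with the specification; the seed
#'   actually used for a run is the one given to [run_simulation()].
#' @return An object of class `"noise_spec"`.
#' @export
noise_spec <- function(D = 0.01, common = TRUE, seed = NULL) {
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D), D >= 0,
            is.logical(common), length(common) == 1L)
  structure(list(D = as.numeric(D), common = common, seed = seed),
            class = "noise_spec")
}

#' Gap-junction transmission delays
#'
#' Delay `tau1` applies to the coupling term of the drive network
#' (`x_j(t - tau1)`), `tau2` to that of the slave network.  `(0, 0)` selects
#' the non-delayed model.
#'
#' @param tau1,tau2 Non-negative delays.
#' @return An object of class `"delay_pair"`.
#' @export
delay_pair <- function(tau1 = 0, tau2 = 0) {
  stopifnot(is.numeric(tau1), length(tau1) == 1L, is.finite(tau1), tau1 >= 0,
            is.numeric(tau2), length(tau2) == 1L, is.finite(tau2), tau2 >= 0)
  structure(list(tau1 = as.numeric(tau1), tau2 = as.numeric(tau2)),
            class = "delay_pair")
}

.fhn_variants <- c("nondelayed_nonnoisy", "nondelayed_noisy",
                   "delayed_nonnoisy", "delayed_noisy")

#' Full drive/slave network configuration
#'
#' Collects everything that defines one drive/slave experiment: per-neuron
#' parameters, the EES drive, per-neuron ionic disturbances, the gap-junction
#' coupling matrix, the delay pair, an optional noise specification and the
#' initial conditions of both networks.
#'
#' The state vector of each network is laid out as
#' `c(membrane[1..n], recovery[1..n])` (length `2n`).
#'
#' `slave_ic_perturbation` adds a deterministic offset `eps` to every slave
#' *membrane* initial condition at run time.  The reference experiments print
#' identical drive and slave initial conditions, for which the uncontrolled
#' non-delayed error is identically zero; a small `eps` (default `1e-3`)
#' breaks this degeneracy so that the transverse (de)synchronization dynamics
#' become observable.  `eps = 0` reproduces the printed initial conditions
#' exactly.
#'
#' @param params An [fhn_params()] data frame (drive network; also used for
#'   the slave unless `slave_params` is given).
#' @param ees An [ees_drive()] object (identical for every neuron of both
#'   networks).
#' @param disturbances An [ionic_disturbance()] data frame.
#' @param coupling A [coupling_matrix()].
#' @param delays A [delay_pair()]; defaults to no delay.
#' @param noise A [noise_spec()] or `NULL` for the noise-free variants.
#' @param drive_ic,slave_ic Length-`2n` initial state vectors; `slave_ic`
#'   defaults to `drive_ic`.
#' @param slave_ic_perturbation Non-negative scalar `eps` added to each slave
#'   membrane initial condition at run time.
#' @param variant One of `"nondelayed_nonnoisy"`, `"nondelayed_noisy"`,
#'   `"delayed_nonnoisy"`, `"delayed_noisy"`; inferred from `delays` and
#'   `noise` when omitted and checked for consistency when given.
#' @param slave_params Optional [fhn_params()] for a parameter-mismatched
#'   slave network; the default (`NULL`) shares `params`.
#' @return An object of class `"fhn_network_config"`.
#' @export
network_config <- function(params, ees, disturbances, coupling,
                           delays = delay_pair(0, 0), noise = NULL,
                           drive_ic, slave_ic = drive_ic,
                           slave_ic_perturbation = 1e-3,
                           variant = NULL, slave_params = NULL) {
  stopifnot(inherits(params, "fhn_params"), inherits(ees, "ees_drive"),
            inherits(disturbances, "ionic_disturbance"),
            inherits(coupling, "coupling_matrix"),
            inherits(delays, "delay_pair"))
  if (!is.null(noise)) stopifnot(inherits(noise, "noise_spec"))
  n <- coupling$n
  if (nrow(params) != n)
    stop("'params' must have one row per neuron (n = ", n, ")")
  if (nrow(disturbances) != n)
    stop("'disturbances' must have one row per neuron (n = ", n, ")")
  if (!is.null(slave_params)) {
    stopifnot(inherits(slave_params, "fhn_params"))
    if (nrow(slave_params) != n)
      stop("'slave_params' must have one row per neuron (n = ", n, ")")
  }
  drive_ic <- as.numeric(drive_ic)
  slave_ic <- as.numeric(slave_ic)
  if (length(drive_ic) != 2 * n || length(slave_ic) != 2 * n)
    stop("initial conditions must have length 2n = ", 2 * n)
  stopifnot(is.numeric(slave_ic_perturbation),
            length(slave_ic_perturbation) == 1L,
            slave_ic_perturbation >= 0)
  delayed <- delays$tau1 > 0 || delays$tau2 > 0
  inferred <- paste0(if (delayed) "delayed" else "nondelayed", "_",
                     if (is.null(noise)) "nonnoisy" else "noisy")
  if (is.null(variant)) {
    variant <- inferred
  } else {
    variant <- match.arg(variant, .fhn_variants)
    if (variant != inferred)
      stop("variant '", variant, "' is inconsistent with the delay/noise ",
           "fields (which imply '", inferred, "')")
  }
  structure(list(n = n, params = params, ees = ees,
                 disturbances = disturbances, coupling = coupling,
                 delays = delays, noise = noise,
                 drive_ic = drive_ic, slave_ic = slave_ic,
                 slave_ic_perturbation = as.numeric(slave_ic_perturbation),
                 variant = variant, slave_params = slave_params),
            class = "fhn_network_config")
}

#' @export
print.fhn_network_config <- function(x, ...) {
  cat("FHN drive/slave network configuration\n")
  cat("  neurons:     ", x$n, "\n")
  cat("  variant:     ", x$variant, "\n")
  cat("  EES:          A =", x$ees$A, ", f =", x$ees$f, "\n")
  cat("  delays:       tau1 =", x$delays$tau1, ", tau2 =", x$delays$tau2, "\n")
  if (!is.null(x$noise))
    cat("  noise:        D =", x$noise$D,
        if (x$noise$common) "(common)" else "(independent)", "\n")
  cat("  slave IC eps:", x$slave_ic_perturbation, "\n")
  invisible(x)
}

#' Controller schedule
#'
#' Which control law acts on the slave network and from when.  `law` is one
#' of `"none"`, `"nondelayed"` (the adaptive law for the non-delayed
#' variants, built from the instantaneous errors) or `"delayed"` (the
#' lag-error feedback law for the delayed variants).  The controller is off
#' for `t < t_on` and active afterwards.
#'
#' @param law Control law tag.
#' @param t_on Activation time (non-negative).
#' @param gain_columns Integer pair: the columns of the coupling matrix that
#'   supply the per-neuron gains `g_i1` and `g_i2` of the control laws.
#' @return An object of class `"controller_schedule"`.
#' @export
controller_schedule <- function(law = c("none", "nondelayed", "delayed"),
                                t_on = 0, gain_columns = c(1L, 2L)) {
  law <- match.arg(law)
  stopifnot(is.numeric(t_on), length(t_on) == 1L, is.finite(t_on), t_on >= 0)
  gain_columns <- as.integer(gain_columns)
  stopifnot(length(gain_columns) == 2L, all(gain_columns >= 1L))
  structure(list(law = law, t_on = as.numeric(t_on),
                 gain_columns = gain_columns),
            class = "controller_schedule")
}
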