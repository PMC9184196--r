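#' Packaged five-neuron reference scenarios
#'
#' Builds the configuration and controller schedule of the four reference
#' drive/slave experiments on five coupled neurons: the variants without or
#' with gap-junction delays, each without or with common additive membrane
#' noise.
#'
#' The per-neuron parameters are `r = (10, 10.2, 10.4, 10.6, 10.8)`,
#' `b = (1, 1.001, 1.002, 1.003, 1.004)`, `c = (0.001, ..., 0.005)`; the
#' ionic disturbances are `d_i(t) = (0.001 i) sin(0.2 t)`; the EES drive has
#' `A = 0.1`, `f = 0.129`; the coupling matrix is [reference_coupling()].
#' Drive and slave initial conditions are identical (membranes
#' `(0, 0.05, 0.05, 0, 0.05)`, recovery `(0.1, 0.2, 0.2, 0.1, 0.2)`); the
#' slave membranes are additionally offset by `slave_ic_perturbation` at run
#' time (see [network_config()]).  The controller activates at `t = 150` for
#' the non-delayed variants and `t = 110` for the delayed ones.
#'
#' Quantities the reference experiments leave unspecified get package
#' defaults: noise intensity `D = 0.01` and equal gap-junction delays
#' `tau1 = tau2 = 0.2`.  Equal delays are deliberate: with distinct
#' per-network delays the EES, disturbance and coupling histories of the two
#' networks can never be brought into agreement, which leaves a persistent
#' forcing of order `A * |tau1 - tau2|` in the lag-error dynamics and puts
#' exact synchronization out of reach of any bounded feedback (see the
#' package vignette).  Distinct delays remain fully supported through the
#' `tau1` / `tau2` arguments.
#'
#' @param variant One of `"nondelayed_nonnoisy"`, `"nondelayed_noisy"`,
#'   `"delayed_nonnoisy"`, `"delayed_noisy"`.
#' @param slave_ic_perturbation Offset `eps` added to the slave membrane
#'   initial conditions at run time (default `1e-3`).
#' @param tau1,tau2 Gap-junction delays for the delayed variants (defaults
#'   `0.2` and `0.2`); ignored for the non-delayed variants.
#' @param noise_D Noise intensity for the noisy variants (default `0.01`);
#'   ignored otherwise.
#' @param t_on Controller activation time; defaults to 150 (non-delayed) or
#'   110 (delayed).
#' @param gain_columns Columns of the coupling matrix supplying the control
#'   gains `g_i1`, `g_i2` (default `c(1, 2)`).
#' @return A list of class `"fhn_scenario"` with elements `config`
#'   ([network_config()]), `schedule` ([controller_schedule()]), `variant`
#'   and `t_end` (the recommended horizon: 300 non-delayed, 250 delayed).
#' @examples
#' sc <- fhn_scenario("nondelayed_nonnoisy")
#' sc$config$params$r[3]   # 10.4
#' sc$schedule$t_on        # 150
#' @export
fhn_scenario <- function(variant = c("nondelayed_nonnoisy", "nondelayed_noisy",
                                     "delayed_nonnoisy", "delayed_noisy"),
                         slave_ic_perturbation = 1e-3,
                         tau1 = 0.2, tau2 = 0.2, noise_D = 0.01,
                         t_on = NULL, gain_columns = c(1L, 2L)) {
  variant <- match.arg(variant)
  delayed <- startsWith(variant, "delayed")
  noisy <- endsWith(variant, "_noisy")
  params <- fhn_params(r = c(10, 10.2, 10.4, 10.6, 10.8),
                       b = c(1, 1.001, 1.002, 1.003, 1.004),
                       c = c(0.001, 0.002, 0.003, 0.004, 0.005))
  dist <- ionic_disturbance(amplitude = c(0.001, 0.002, 0.003, 0.004, 0.005),
                            rate = 0.2)
  ees <- ees_drive(A = 0.1, f = 0.129)
  ic <- c(0, 0.05, 0.05, 0, 0.05,      # membranes
          0.1, 0.2, 0.2, 0.1, 0.2)     # recovery variables
  delays <- if (delayed) delay_pair(tau1, tau2) else delay_pair(0, 0)
  noise <- if (noisy) noise_spec(D = noise_D, common = TRUE) else NULL
  cfg <- network_config(params = params, ees = ees, disturbances = dist,
                        coupling = reference_coupling(), delays = delays,
                        noise = noise, drive_ic = ic, slave_ic = ic,
                        slave_ic_perturbation = slave_ic_perturbation,
                        variant = variant)
  if (is.null(t_on)) t_on <- if (delayed) 110 else 150
  sched <- controller_schedule(law = if (delayed) "delayed" else "nondelayed",
                               t_on = t_on, gain_columns = gain_columns)
  structure(list(config = cfg, schedule = sched, variant = variant,
                 t_end = if (delayed) 250 else 300),
            class = "fhn_scenario")
}

#' @export
print.fhn_scenario <- function(x, ...) {
  cat("FHN reference scenario '", x$variant, "'\n", sep = "")
  cat("  law = ", x$schedule$law, ", t_on = ", x$schedule$t_on,
      ", recommended t_end = ", x$t_end, "\n", sep = "")
  print(x$config)
  invisible(x)
}

## ---- YAML (de)serialization -------------------------------------------

#' Write / read a scenario as a YAML configuration file
#'
#' The file is a flat key/value document mirroring the [network_config()]
#' and [controller_schedule()] fields (the coupling matrix is stored as a
#' list of rows).  The four reference scenarios ship as packaged fixtures
#' under `system.file("extdata", package = "fhnsync")`.
#'
#' @param scenario An `"fhn_scenario"` object (or a list with elements
#'   `config` and `schedule`).
#' @param path File path.
#' @return `write_scenario()` returns `path` invisibly; `read_scenario()`
#'   returns an `"fhn_scenario"` object.
#' @export
write_scenario <- function(scenario, path) {
  cfg <- scenario$config
  sch <- scenario$schedule
  doc <- list(
    variant = cfg$variant,
    n = cfg$n,
    r = cfg$params$r, b = cfg$params$b, c = cfg$params$c,
    ees_A = cfg$ees$A, ees_f = cfg$ees$f,
    dist_amplitude = cfg$disturbances$amplitude,
    dist_rate = cfg$disturbances$rate,
    coupling = lapply(seq_len(cfg$n), function(i) cfg$coupling$G[i, ]),
    tau1 = cfg$delays$tau1, tau2 = cfg$delays$tau2,
    noise_D = if (is.null(cfg$noise)) NULL else cfg$noise$D,
    noise_common = if (is.null(cfg$noise)) NULL else cfg$noise$common,
    drive_ic = cfg$drive_ic, slave_ic = cfg$slave_ic,
    slave_ic_perturbation = cfg$slave_ic_perturbation,
    law = sch$law, t_on = sch$t_on,
    gain_columns = sch$gain_columns,
    t_end = scenario$t_end)
  if (!is.null(cfg$slave_params)) {
    doc$slave_r <- cfg$slave_params$r
    doc$slave_b <- cfg$slave_params$b
    doc$slave_c <- cfg$slave_params$c
  }
  doc <- Filter(Negate(is.null), doc)
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path) {
  doc <- yaml::read_yaml(path)
  need <- c("n", "r", "b", "c", "ees_A", "ees_f", "dist_amplitude",
            "dist_rate", "coupling", "drive_ic", "law", "t_on")
  missing <- setdiff(need, names(doc))
  if (length(missing))
    stop("configuration file is missing keys: ",
         paste(missing, collapse = ", "))
  G <- do.call(rbind, lapply(doc$coupling, as.numeric))
  noise <- if (!is.null(doc$noise_D))
    noise_spec(D = doc$noise_D, common = isTRUE(doc$noise_common)) else NULL
  slave_params <- if (!is.null(doc$slave_r))
    fhn_params(doc$slave_r, doc$slave_b, doc$slave_c) else NULL
  cfg <- network_config(
    params = fhn_params(doc$r, doc$b, doc$c),
    ees = ees_drive(doc$ees_A, doc$ees_f),
    disturbances = ionic_disturbance(doc$dist_amplitude, doc$dist_rate),
    coupling = coupling_matrix(G, validate = TRUE, tol = 5e-7),
    delays = delay_pair(doc$tau1 %||% 0, doc$tau2 %||% 0),
    noise = noise,
    drive_ic = doc$drive_ic,
    slave_ic = doc$slave_ic %||% doc$drive_ic,
    slave_ic_perturbation = doc$slave_ic_perturbation %||% 1e-3,
    variant = doc$variant,
    slave_params = slave_params)
  sched <- controller_schedule(law = doc$law, t_on = doc$t_on,
                               gain_columns = doc$gain_columns %||% c(1L, 2L))
  structure(list(config = cfg, schedule = sched, variant = cfg$variant,
                 t_end = doc$t_end %||%
                   (if (startsWith(cfg$variant, "delayed")) 250 else 300)),
            class = "fhn_scenario")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
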