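# Shared fixtures: reference-scenario runs are expensive, so they are
# computed once per test session and reused across files.

`%||%` <- function(a, b) if (is.null(a)) b else a

.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) assign(key, force(expr), envir = .sim_cache)
  get(key, envir = .sim_cache)
}

# A controlled or uncontrolled run of one packaged reference variant.
reference_run <- function(variant, controlled = TRUE, seed = 1L,
                          eps = 1e-3, t_end = NULL, dt = 0.005) {
  key <- paste(variant, controlled, seed, eps, t_end %||% "default", dt,
               sep = "|")
  cached(key, {
    sc <- fhn_scenario(variant, slave_ic_perturbation = eps)
    sched <- if (controlled) sc$schedule else controller_schedule("none")
    run_simulation(sc$config, sched, t_end = t_end %||% sc$t_end,
                   dt = dt, seed = seed)
  })
}

# Minimal synthetic trajectory for metric-level tests (no simulation).
fake_traj <- function(times, errors, drive = NULL, slave = NULL,
                      law = "none", t_on = 0) {
  n <- ncol(errors) %/% 2L
  if (is.null(drive)) drive <- matrix(0, length(times), 2L * n)
  if (is.null(slave)) slave <- matrix(0, length(times), 2L * n)
  sc <- fhn_scenario("nondelayed_nonnoisy")
  cfg <- sc$config
  cfg$n <- n  # metric functions only use n and the matrices
  structure(list(times = times, drive = drive, slave = slave,
                 control = matrix(0, length(times), n),
                 errors = errors,
                 controller_active = law != "none" & times >= t_on,
                 config = cfg,
                 schedule = controller_schedule(law, t_on = t_on),
                 dt = if (length(times) > 1L) times[2L] - times[1L] else 1,
                 seed = NULL, method = "rk4"),
            class = "fhn_trajectory")
}
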