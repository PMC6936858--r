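#' Sinusoidal driver specification
#'
#' Weak extrinsic drivers added to the pyramidal membrane potential of the
#' targeted nodes: `c_ext * sin(2 pi f_ext t + phase)`.  By convention the
#' first target carries phase 0 and the phase offset of a pair probe is
#' applied to the second target.
#'
#' @param targets Integer node indices receiving a driver.
#' @param f_ext Driver frequency (Hz).
#' @param c_ext Driver amplitude (mV).
#' @param phases Per-target phases (rad), recycled to `length(targets)` and
#'   wrapped modulo 2 pi.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(targets = integer(0), f_ext = 11, c_ext = 0.5,
                          phases = 0) {
  stopifnot(c_ext >= 0, f_ext > 0)
  targets <- as.integer(targets)
  if (anyDuplicated(targets)) stop("duplicate stimulation targets")
  phases <- rep_len(phases, length(targets)) %% (2 * pi)
  structure(list(targets = targets, f_ext = f_ext, c_ext = c_ext,
                 phases = phases), class = "stimulus_spec")
}

#' Background-noise specification
#'
#' Sub-cortical background input modeled as a rate drawn independently and
#' uniformly in `[low, high]` for every node on a fixed noise grid (see
#' [sim_config()]), held constant between draws.
#'
#' @param low,high Uniform bounds (1/s).
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(low = 120, high = 320) {
  stopifnot(low >= 0, high >= low)
  structure(list(low = low, high = high), class = "noise_spec")
}

#' Integration settings
#'
#' @param dt RK4 integration step (s); 1 ms default.
#' @param duration Total simulated time (s), including the transient.
#' @param transient Initial stretch discarded from the output (s).
#' @param seed Integer RNG seed, or NULL to use the current RNG state.
#' @param noise_dt Grid on which noise is redrawn (s).  Kept at 1 ms by
#'   default independently of `dt`, so the stochastic input process does not
#'   change when the integration step does (step-size comparisons stay
#'   meaningful).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt = 1e-3, duration = 60, transient = 10, seed = NULL,
                       noise_dt = 1e-3) {
  stopifnot(dt > 0, duration > 0, transient >= 0, transient < duration,
            noise_dt >= dt)
  structure(list(dt = dt, duration = duration, transient = transient,
                 seed = seed, noise_dt = noise_dt), class = "sim_config")
}

new_timeseries <- function(V, dt, t0, labels, drivers = NULL) {
  colnames(V) <- labels
  structure(list(V = V, dt = dt, t0 = t0, labels = labels, drivers = drivers),
            class = "jr_timeseries")
}

#' @export
print.jr_timeseries <- function(x, ...) {
  cat(sprintf("jr_timeseries: %d nodes x %d steps (dt = %g s, %.1f s)\n",
              ncol(x$V), nrow(x$V), x$dt, nrow(x$V) * x$dt))
  invisible(x)
}

#' Driver potential at a given time
#'
#' @param t Time (s); vectorized.
#' @param spec A [stimulus_spec()].
#' @param target_index Node index; returns 0 for non-targets.
#' @return Potential (mV).
#' @export
driver_signal <- function(t, spec, target_index) {
  k <- match(target_index, spec$targets)
  if (is.na(k)) return(rep(0, length(t)))
  spec$c_ext * sin(2 * pi * spec$f_ext * t + spec$phases[k])
}

#' Initial delay-history buffer
#'
#' The integrator needs the pyramidal potential of every node up to the
#' maximum delay in the past.  History is initialized at the rest state
#' (all six node states zero, hence zero potential); this is deterministic
#' and independent of the noise seed.
#'
#' @param connectome A [connectome()].
#' @param coupling A [global_coupling()].
#' @param cfg A [sim_config()].
#' @return Zero matrix of dimension (max delay in steps) x n; 0-row matrix
#'   for an edgeless network.
#' @export
history_init <- function(connectome, coupling = global_coupling(),
                         cfg = sim_config()) {
  d <- delays_in_steps(connectome$L, coupling$v, cfg$dt,
                       mask = connectome$C > 0)
  matrix(0, max(d, 0L), connectome$n)
}

#' Simulate a delay-coupled Jansen-Rit network
#'
#' Integrates `n` Jansen-Rit nodes coupled through their pyramidal
#' populations with RK4 at fixed step `cfg$dt`.  Node `j` receives the
#' network rate `u_net_j(t) = c_net * sum_m C[m, j] *
#' sigmoid(V_pyr_m(t - delay_mj))`, a background-noise rate redrawn on the
#' `cfg$noise_dt` grid, and optionally a sinusoidal driver added to its
#' pyramidal membrane potential.  Delayed terms and noise are held constant
#' across the four RK4 stages; delays are rounded to full steps with a
#' 1-step floor; history starts at rest.  Bit-reproducible for a fixed
#' `cfg$seed`.
#'
#' @param connectome A [connectome()].
#' @param coupling A [global_coupling()].
#' @param stim A [stimulus_spec()] or NULL (no drivers).
#' @param noise A [noise_spec()] or NULL (no noise).
#' @param cfg A [sim_config()].
#' @param params A [jr_params()].
#' @param store_drivers If TRUE, the driver waveforms over the kept steps
#'   are stored in the result (used to treat the stimulus as a virtual node
#'   in coherence analyses).
#' @return A `jr_timeseries`: matrix `V` (kept step x node) of pyramidal
#'   potentials `V_pyr = v_e2p - v_i2p + v_stim` (mV), step `dt`, start time
#'   `t0`, and optionally `drivers`.
#' @examples
#' con <- make_motif("bi_2node", total_distance = 100)
#' ts <- simulate(con, cfg = sim_config(duration = 2, transient = 1, seed = 1),
#'                noise = noise_spec())
#' dim(ts$V)
#' @export
simulate <- function(connectome, coupling = global_coupling(), stim = NULL,
                     noise = NULL, cfg = sim_config(), params = jr_params(),
                     store_drivers = FALSE) {
  n <- connectome$n
  dt <- cfg$dt
  n_steps <- round(cfg$duration / dt)
  n_trans <- round(cfg$transient / dt)
  delays <- delays_in_steps(connectome$L, coupling$v, dt,
                            mask = connectome$C > 0)
  if (is.null(stim)) stim <- stimulus_spec()
  noise_every <- if (is.null(noise)) 0L else max(1L, as.integer(round(cfg$noise_dt / dt)))
  nl <- if (is.null(noise)) 0 else noise$low
  nh <- if (is.null(noise)) 0 else noise$high
  par <- unlist(params[c("He", "Hi", "tau_e", "tau_i", "c1", "c2", "c3", "c4",
                         "e0", "r", "V0")])
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  V <- .simulate_jr_cpp(connectome$C, delays, coupling$c_net, par,
                        stim$targets - 1L, stim$f_ext, stim$c_ext,
                        stim$phases, nl, nh, noise_every,
                        dt, n_steps, n_trans)
  drivers <- NULL
  if (store_drivers && length(stim$targets)) {
    tt <- (seq_len(n_steps - n_trans) + n_trans) * dt
    drivers <- vapply(seq_along(stim$targets), function(q)
      stim$c_ext * sin(2 * pi * stim$f_ext * tt + stim$phases[q]),
      numeric(length(tt)))
    colnames(drivers) <- paste0("driver_", connectome$labels[stim$targets])
  }
  new_timeseries(V, dt = dt, t0 = cfg$transient + dt,
                 labels = connectome$labels, drivers = drivers)
}
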