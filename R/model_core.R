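#' Jansen-Rit node parameters
#'
#' Constructs the physiological parameter set of a single Jansen-Rit neural
#' mass, a mean-field model of a cortical column with a pyramidal cell
#' population coupled to an excitatory and an inhibitory interneuron
#' population.  The defaults are the standard parametrization that places a
#' noise-driven node in the alpha regime (~10 Hz).
#'
#' @param He,Hi Average synaptic gain of excitatory / inhibitory synapses (mV).
#' @param tau_e,tau_i Lumped synaptic time constants (s).
#' @param c1 Average number of synaptic contacts from pyramidal cells to
#'   excitatory interneurons; `c2`, `c3`, `c4` default to the usual fixed
#'   ratios `0.8*c1`, `0.25*c1`, `0.25*c1`.
#' @param c2,c3,c4 Remaining contact counts (dimensionless).
#' @param e0 Half of the maximum population firing rate (1/s); the sigmoid
#'   saturates at `2*e0`.
#' @param r Sigmoid steepness (1/mV).
#' @param V0 Membrane potential of half-maximal firing (mV).
#' @return An object of class `jr_params` (named list).
#' @examples
#' p <- jr_params()
#' sigmoid(p$V0, p)  # half-max firing rate, 2.5 1/s
#' @export
jr_params <- function(He = 3.25, Hi = 22, tau_e = 0.01, tau_i = 0.02,
                      c1 = 135, c2 = 0.8 * c1, c3 = 0.25 * c1, c4 = 0.25 * c1,
                      e0 = 2.5, r = 0.56, V0 = 6) {
  p <- list(He = He, Hi = Hi, tau_e = tau_e, tau_i = tau_i,
            c1 = c1, c2 = c2, c3 = c3, c4 = c4, e0 = e0, r = r, V0 = V0)
  if (!all(vapply(p, function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x > 0,
                  logical(1))))
    stop("all Jansen-Rit parameters must be finite, strictly positive scalars")
  structure(p, class = "jr_params")
}

#' @export
print.jr_params <- function(x, ...) {
  cat("Jansen-Rit parameters:\n")
  cat(sprintf("  He = %g mV, Hi = %g mV, tau_e = %g s, tau_i = %g s\n",
              x$He, x$Hi, x$tau_e, x$tau_i))
  cat(sprintf("  c1..c4 = %g, %g, %g, %g\n", x$c1, x$c2, x$c3, x$c4))
  cat(sprintf("  e0 = %g 1/s, r = %g 1/mV, V0 = %g mV\n", x$e0, x$r, x$V0))
  invisible(x)
}

#' Potential-to-rate sigmoid
#'
#' Transforms an average membrane potential into an average population firing
#' rate: `sigma(V) = 2 e0 / (1 + exp(r (V0 - V)))`.  Total, strictly
#' increasing, bounded in `(0, 2 e0)`.
#'
#' @param V Membrane potential (mV); vectorized.
#' @param params A [jr_params()] object.
#' @return Firing rate(s) in 1/s.
#' @export
sigmoid <- function(V, params = jr_params()) {
  2 * params$e0 / (1 + exp(params$r * (params$V0 - V)))
}

#' Second-order synapse kinetics
#'
#' A post-synaptic potential follows the critically damped second-order
#' system `dv = i`, `di = (H/tau) u - (2/tau) i - v/tau^2`, whose impulse
#' response is the alpha kernel `h(t) = (H/tau) t exp(-t/tau)` and whose
#' equilibrium under constant input `u` is `v* = H tau u`.
#'
#' @param v,i Current PSP (mV) and synaptic current (mV/s).
#' @param u Pre-synaptic input rate (1/s).
#' @param H Synaptic gain (mV).
#' @param tau Synaptic time constant (s).
#' @return Numeric vector `c(dv, di)`.
#' @export
synapse_derivatives <- function(v, i, u, H, tau) {
  if (tau <= 0 || H <= 0) stop("H and tau must be strictly positive")
  c(i, (H / tau) * u - (2 / tau) * i - v / tau^2)
}

#' Full Jansen-Rit node derivative
#'
#' Composes the three synapses of a node.  The pyramidal population fires at
#' `sigmoid(v_e2p - v_i2p + v_stim)` and drives the synapse onto the
#' interneurons; the excitatory feedback `c2 sigmoid(c1 v_p2i)` plus the
#' background-noise rate `u_noise` plus the network rate `u_net` drive the
#' excitatory input synapse; the inhibitory feedback `c4 sigmoid(c3 v_p2i)`
#' drives the inhibitory input synapse.
#'
#' @param state Numeric length-6 vector
#'   `(v_p2i, i_p2i, v_e2p, i_e2p, v_i2p, i_i2p)`.
#' @param u_noise,u_net Non-negative input rates (1/s).
#' @param v_stim Extrinsic driver potential added to the pyramidal membrane
#'   potential (mV).
#' @param params A [jr_params()] object.
#' @return Length-6 derivative vector, same layout as `state`.
#' @export
node_derivatives <- function(state, u_noise = 0, u_net = 0, v_stim = 0,
                             params = jr_params()) {
  if (length(state) != 6 || !all(is.finite(state)))
    stop("state must be 6 finite scalars")
  if (u_noise < 0 || u_net < 0) stop("input rates must be non-negative")
  p <- params
  m_pyr <- sigmoid(state[3] - state[5] + v_stim, p)
  m_exc <- p$c2 * sigmoid(p$c1 * state[1], p)
  m_inh <- p$c4 * sigmoid(p$c3 * state[1], p)
  c(synapse_derivatives(state[1], state[2], m_pyr, p$He, p$tau_e),
    synapse_derivatives(state[3], state[4], m_exc + u_noise + u_net, p$He, p$tau_e),
    synapse_derivatives(state[5], state[6], m_inh, p$Hi, p$tau_i))
}

#' Pure-R reference network integrator
#'
#' A slow, straightforward RK4 integrator over [node_derivatives()] with the
#' same delay and noise conventions as the compiled core ([simulate()]):
#' delayed terms and noise held constant across RK4 stages, noise redrawn on
#' the `noise_dt` grid, history initialized at rest.  Used as an independent
#' cross-check of the compiled integrator and for linear-regime tests via
#' `rate_fun` (e.g. a zero function turns the model into uncoupled stable
#' linear synapses).
#'
#' @param connectome A [connectome()] object.
#' @param coupling A [global_coupling()] object.
#' @param stim A [stimulus_spec()] or NULL.
#' @param noise A [noise_spec()] or NULL (no noise).
#' @param cfg A [sim_config()].
#' @param params A [jr_params()] object.
#' @param rate_fun Optional replacement for the sigmoid (test hook), a
#'   function of `(V, params)`.
#' @return A `jr_timeseries` object, as from [simulate()].
#' @keywords internal
#' @export
simulate_reference <- function(connectome, coupling = global_coupling(),
                               stim = NULL, noise = NULL, cfg = sim_config(),
                               params = jr_params(), rate_fun = NULL) {
  sig <- if (is.null(rate_fun)) sigmoid else rate_fun
  n <- connectome$n
  dt <- cfg$dt
  n_steps <- round(cfg$duration / dt)
  n_trans <- round(cfg$transient / dt)
  delays <- delays_in_steps(connectome$L, coupling$v, dt, mask = connectome$C > 0)
  max_del <- max(delays, 0L)
  Hh <- max_del + 1L
  hist <- matrix(0, Hh, n)
  x <- matrix(0, 6, n)
  noise_every <- if (is.null(noise)) 0L else max(1L, round(cfg$noise_dt / dt))
  u_noise <- rep(0, n)
  targets <- if (is.null(stim)) integer(0) else stim$targets
  out <- matrix(NA_real_, n_steps - n_trans, n)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  vstim_at <- function(tt) {
    v <- rep(0, n)
    if (length(targets))
      v[targets] <- stim$c_ext * sin(2 * pi * stim$f_ext * tt + stim$phases)
    v
  }
  edges <- which(connectome$C > 0, arr.ind = TRUE)  # (source, target)
  for (s in seq_len(n_steps) - 1L) {
    t0 <- s * dt
    vs <- vstim_at(t0)
    hist[s %% Hh + 1L, ] <- x[3, ] - x[5, ] + vs
    if (noise_every > 0 && s %% noise_every == 0)
      u_noise <- stats::runif(n, noise$low, noise$high)
    u_net <- rep(0, n)
    for (k in seq_len(nrow(edges))) {
      m <- edges[k, 1]; j <- edges[k, 2]
      d <- delays[m, j]
      Vd <- if (s - d < 0) 0 else hist[(s - d) %% Hh + 1L, m]
      u_net[j] <- u_net[j] + connectome$C[m, j] * sig(Vd, params)
    }
    u_net <- coupling$c_net * u_net
    vs_h <- vstim_at(t0 + dt / 2)
    vs_1 <- vstim_at(t0 + dt)
    for (j in seq_len(n)) {
      f <- function(state, v_stim) {
        p <- params
        m_pyr <- sig(state[3] - state[5] + v_stim, p)
        m_exc <- p$c2 * sig(p$c1 * state[1], p)
        m_inh <- p$c4 * sig(p$c3 * state[1], p)
        c(state[2],
          (p$He / p$tau_e) * m_pyr - (2 / p$tau_e) * state[2] - state[1] / p$tau_e^2,
          state[4],
          (p$He / p$tau_e) * (m_exc + u_noise[j] + u_net[j]) - (2 / p$tau_e) * state[4] - state[3] / p$tau_e^2,
          state[6],
          (p$Hi / p$tau_i) * m_inh - (2 / p$tau_i) * state[6] - state[5] / p$tau_i^2)
      }
      k1 <- f(x[, j], vs[j])
      k2 <- f(x[, j] + dt / 2 * k1, vs_h[j])
      k3 <- f(x[, j] + dt / 2 * k2, vs_h[j])
      k4 <- f(x[, j] + dt * k3, vs_1[j])
      x[, j] <- x[, j] + dt / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    if (s >= n_trans)
      out[s - n_trans + 1L, ] <- x[3, ] - x[5, ] + vstim_at(t0 + dt)
  }
  new_timeseries(out, dt = dt, t0 = cfg$transient + dt,
                 labels = connectome$labels)
}
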