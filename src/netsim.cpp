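#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Delay-coupled Jansen-Rit network integrator (fixed-step RK4).
//
// Per node the state is six scalars, two per post-synaptic potential:
//   x0 = v_p2i, x1 = i_p2i   pyramidal -> interneuron excitatory synapse
//   x2 = v_e2p, x3 = i_e2p   excitatory input synapse onto pyramidal cells
//   x4 = v_i2p, x5 = i_i2p   inhibitory input synapse onto pyramidal cells
// The recorded observable is V_pyr = v_e2p - v_i2p + v_stim; the same
// quantity drives the pyramidal output sigmoid and, through the history
// buffer, the delayed network coupling.
//
// Delayed terms and the background-noise rate are held constant across the
// four RK4 stages of a step; the sinusoidal driver is evaluated at stage
// times (it is a known analytic signal).  Noise is drawn on its own fixed
// grid (noise_dt) so the stochastic process is defined independently of the
// integration step, which makes step-size comparisons meaningful.

struct JRPar {
  double He, Hi, taue, taui, c1, c2, c3, c4, e0, r, V0;
};

static inline double sigm(double V, const JRPar &p) {
  return 2.0 * p.e0 / (1.0 + std::exp(p.r * (p.V0 - V)));
}

// dv = i ; di = (H/tau) u - (2/tau) i - v/tau^2
static inline void node_deriv(const double *x, double u_noise, double u_net,
                              double v_stim, const JRPar &p, double *dx) {
  double Vp = x[2] - x[4] + v_stim;
  double m_pyr = sigm(Vp, p);                  // pyramidal output rate
  double m_exc = p.c2 * sigm(p.c1 * x[0], p);  // excitatory feedback
  double m_inh = p.c4 * sigm(p.c3 * x[0], p);  // inhibitory feedback
  // p2i synapse (excitatory kinetics)
  dx[0] = x[1];
  dx[1] = (p.He / p.taue) * m_pyr - (2.0 / p.taue) * x[1] - x[0] / (p.taue * p.taue);
  // e2p synapse: feedback + noise + network input
  double u_e = m_exc + u_noise + u_net;
  dx[2] = x[3];
  dx[3] = (p.He / p.taue) * u_e - (2.0 / p.taue) * x[3] - x[2] / (p.taue * p.taue);
  // i2p synapse (inhibitory kinetics)
  dx[4] = x[5];
  dx[5] = (p.Hi / p.taui) * m_inh - (2.0 / p.taui) * x[5] - x[4] / (p.taui * p.taui);
}

// [[Rcpp::export(name = ".simulate_jr_cpp")]]
NumericMatrix simulate_jr_cpp(const NumericMatrix &C,       // source x target weights
                              const IntegerMatrix &delays,  // delay in steps, 0 = no edge
                              double c_net,
                              const NumericVector &par,     // He,Hi,taue,taui,c1..c4,e0,r,V0
                              const IntegerVector &stim_targets,  // 0-based
                              double f_ext, double c_ext,
                              const NumericVector &stim_phases,
                              double noise_low, double noise_high, int noise_every,
                              double dt, int n_steps, int n_transient) {
  const int n = C.nrow();
  JRPar p;
  p.He = par[0]; p.Hi = par[1]; p.taue = par[2]; p.taui = par[3];
  p.c1 = par[4]; p.c2 = par[5]; p.c3 = par[6]; p.c4 = par[7];
  p.e0 = par[8]; p.r = par[9]; p.V0 = par[10];

  // edge list with per-edge delay
  std::vector<int> e_src, e_dst, e_del;
  std::vector<double> e_w;
  int max_del = 0;
  for (int j = 0; j < n; ++j)
    for (int m = 0; m < n; ++m)
      if (C(m, j) > 0.0 && m != j) {
        e_src.push_back(m); e_dst.push_back(j);
        e_w.push_back(C(m, j));
        int d = delays(m, j);
        if (d < 1) stop("existing edge with delay < 1 step");
        e_del.push_back(d);
        if (d > max_del) max_del = d;
      }
  const int n_edges = (int)e_src.size();
  const int H = max_del + 1;  // ring buffer length

  std::vector<double> x(6 * n, 0.0);           // state, rest init
  std::vector<double> hist((size_t)H * n, 0.0); // V_pyr history, rest init
  std::vector<double> u_noise(n, 0.0), u_net(n, 0.0), v_stim(n, 0.0);
  std::vector<double> k1(6), k2(6), k3(6), k4(6), xs(6);

  const int n_stim = stim_targets.size();
  const double two_pi_f = 2.0 * M_PI * f_ext;

  const int n_keep = n_steps - n_transient;
  NumericMatrix out(n_keep, n);

  for (int s = 0; s < n_steps; ++s) {
    const double t = s * dt;

    // driver potentials at step start
    for (int q = 0; q < n_stim; ++q)
      v_stim[stim_targets[q]] = c_ext * std::sin(two_pi_f * t + stim_phases[q]);

    // write current V_pyr (incl. stimulation) into the ring buffer
    const int row = s % H;
    for (int j = 0; j < n; ++j)
      hist[(size_t)row * n + j] = x[6 * j + 2] - x[6 * j + 4] + v_stim[j];

    // background noise, redrawn on its own grid
    if (noise_every > 0 && s % noise_every == 0)
      for (int j = 0; j < n; ++j)
        u_noise[j] = noise_low + unif_rand() * (noise_high - noise_low);

    // delayed network input, held across the four stages
    std::fill(u_net.begin(), u_net.end(), 0.0);
    for (int e = 0; e < n_edges; ++e) {
      int past = s - e_del[e];
      double Vd = (past < 0) ? 0.0 : hist[(size_t)(past % H) * n + e_src[e]];
      u_net[e_dst[e]] += e_w[e] * sigm(Vd, p);
    }
    for (int j = 0; j < n; ++j) u_net[j] *= c_net;

    // RK4, drivers evaluated at stage times
    for (int j = 0; j < n; ++j) {
      double *xj = &x[6 * j];
      double vs0 = v_stim[j], vs_h = vs0, vs_1 = vs0;
      bool stim_j = false;
      for (int q = 0; q < n_stim; ++q) if (stim_targets[q] == j) stim_j = true;
      if (stim_j) {
        double ph = 0.0;
        for (int q = 0; q < n_stim; ++q)
          if (stim_targets[q] == j) ph = stim_phases[q];
        vs_h = c_ext * std::sin(two_pi_f * (t + 0.5 * dt) + ph);
        vs_1 = c_ext * std::sin(two_pi_f * (t + dt) + ph);
      }
      node_deriv(xj, u_noise[j], u_net[j], vs0, p, k1.data());
      for (int d = 0; d < 6; ++d) xs[d] = xj[d] + 0.5 * dt * k1[d];
      node_deriv(xs.data(), u_noise[j], u_net[j], vs_h, p, k2.data());
      for (int d = 0; d < 6; ++d) xs[d] = xj[d] + 0.5 * dt * k2[d];
      node_deriv(xs.data(), u_noise[j], u_net[j], vs_h, p, k3.data());
      for (int d = 0; d < 6; ++d) xs[d] = xj[d] + dt * k3[d];
      node_deriv(xs.data(), u_noise[j], u_net[j], vs_1, p, k4.data());
      for (int d = 0; d < 6; ++d)
        xj[d] += dt / 6.0 * (k1[d] + 2.0 * k2[d] + 2.0 * k3[d] + k4[d]);
    }

    // record V_pyr at the end of the step (state at t + dt)
    if (s >= n_transient) {
      const double t1 = t + dt;
      for (int q = 0; q < n_stim; ++q)
        v_stim[stim_targets[q]] = c_ext * std::sin(two_pi_f * t1 + stim_phases[q]);
      for (int j = 0; j < n; ++j) {
        double Vp = x[6 * j + 2] - x[6 * j + 4] + v_stim[j];
        if (!std::isfinite(Vp))
          stop("simulation diverged at step %d (t = %.3f s), node %d",
               s + 1, t1, j + 1);
        out(s - n_transient, j) = Vp;
      }
    }
  }
  return out;
}
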