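---
title: "Probing communication pathways in delay-coupled neural mass networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing communication pathways in delay-coupled neural mass networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pathprobe)
```

## The scientific question

Most pairs of brain regions are connected by several anatomical routes.
If inter-areal communication works through coherence — a signal arriving
at the excitable phase of its target succeeds, one arriving off-phase
fails — then the *phase relationship* between two regions, together with
the conduction delays of the routes between them, should decide which
route actually carries their interaction.  `pathprobe` implements a
perturbational protocol for studying this in silico: drive two network
nodes with weak sinusoids at a common frequency, sweep the phase offset
between the two drivers, and watch how the coherence between the nodes
and along each candidate pathway responds.

## The node model

Each network node is a Jansen-Rit neural mass: a pyramidal population
reciprocally coupled to an excitatory and an inhibitory interneuron
population.  Every synapse turns a pre-synaptic firing rate $u(t)$ into a
post-synaptic potential through critically damped second-order kinetics

$$\dot v = i,\qquad
  \dot i = \frac{H}{\tau}\,u - \frac{2}{\tau}\,i - \frac{v}{\tau^2},$$

whose impulse response is the alpha kernel $h(t) = (H/\tau)\,t\,e^{-t/\tau}$
and whose fixed point under constant input is $v^\* = H\tau u$
(`synapse_derivatives()`).  Potentials map back to rates through the
sigmoid

$$\sigma(V) = \frac{2e_0}{1 + e^{r(V_0 - V)}},$$

with half-max rate $e_0$ at $V = V_0$ (`sigmoid()`).  The default
parameters (`jr_params()`) are the standard alpha-regime set: $H_e =
3.25$ mV, $H_i = 22$ mV, $\tau_e = 10$ ms, $\tau_i = 20$ ms, $c_1 = 135$,
$c_2 = 0.8c_1$, $c_3 = c_4 = 0.25c_1$, $e_0 = 2.5\,\mathrm{s^{-1}}$,
$r = 0.56\,\mathrm{mV^{-1}}$, $V_0 = 6$ mV.  A single node driven by
background noise oscillates at $\approx 10$–11 Hz; the package's own
acceptance check measures 10.75 Hz.

The observable is the pyramidal membrane potential
$V_\mathrm{pyr} = v_{e2p} - v_{i2p} + v_\mathrm{stim}$, the EEG-like
quantity.  The extrinsic driver enters additively on the pyramidal
membrane potential — inside the pyramidal output sigmoid and in the
recorded signal — because it models input that affects the excitability
of the same population that also receives network input.

## Network coupling and integration

Nodes are coupled pyramidal-to-pyramidal through a structural matrix $C$
(`C[m, j]`: strength from source $m$ to target $j$; incoming weights
normalized to 1 per target) and fiber lengths $L$ (mm) converted into
discrete delays $d_{mj} = \mathrm{round}((L_{mj}/1000)/v/\Delta t)$
steps, floored at one step.  Node $j$ receives the delayed rate

$$u^{\mathrm{net}}_j(t) = c_\mathrm{net}\sum_m C_{mj}\,
  \sigma\!\big(V_{\mathrm{pyr},m}(t - d_{mj}\Delta t)\big)$$

on its excitatory input synapse, alongside uniform background noise
($120$–$320\,\mathrm{s^{-1}}$ per node, redrawn on a fixed 1 ms grid) and
the driver.  The defaults $c_\mathrm{net} = 14$, $v = 2.6$ m/s are the values at
which this kind of connectome model best reproduces resting-state EEG
coherence; `fc_fit()` re-derives such values by grid search against any
reference functional-connectivity matrix.

Integration is classical RK4 at $\Delta t = 1$ ms (`simulate()`, compiled
core).  Numerical conventions, all deliberate:

* **Delayed terms are frozen within a step**: the delayed rates are read
  once from the history ring buffer at the step start and reused by all
  four RK4 stages.  The smallest delay (one step) still exceeds the
  stage spacing, and this is the standard treatment for fixed-step
  delayed systems on a grid.
* **Noise is frozen within its own grid cell**: one uniform draw per node
  per `noise_dt` (default 1 ms), held constant in between.  Tying the
  noise process to its own grid rather than to the integration step makes
  the stochastic input *identical* across step sizes, so step-halving
  comparisons compare integrators, not noise realizations.
* **History starts at rest** (all states and buffered potentials zero),
  and a configurable transient (default 10 s) is discarded.
* Delays are rounded to the nearest step, not interpolated; the
  step-size robustness test quantifies the consequences.

A pure-R reference integrator (`simulate_reference()`) reproduces the
compiled core bit-for-bit on test fixtures and accepts a replacement rate
function, which the tests use to verify that the linear synaptic skeleton
is stable (everything decays to rest when the sigmoid is zeroed).

## The probing protocol

`pair_probe()` stimulates a pair of nodes with two sinusoids at
$f_\mathrm{ext} = 11$ Hz (the frequency at which a single driver
penetrates the connectome model deepest) and amplitude
$c_\mathrm{ext} = 0.5$ mV (weak relative to the 1–10 mV intrinsic
fluctuations; toy-motif analyses use 0.1 mV), at 16 equally spaced phase
offsets $\Delta\varphi \in [0, 2\pi)$.  The first target always carries
phase 0; $\Delta\varphi$ is applied to the second.  The noise seed is
held fixed across offsets so the offset is the only experimental factor.
Even two *uncoupled* co-driven nodes show high coherence (the trivial
coherence of common drive), but that coherence is flat in
$\Delta\varphi$; only interaction through the network produces
phase-offset structure.  Hence all metrics are ranges over offsets.

## The analysis chain

Each simulation is band-pass filtered at $10 \pm 2$ Hz with a zero-phase
Hamming-windowed-sinc FIR filter (odd tap count, group delay compensated
exactly; edge transients of `max(1 s, 3×group delay)` trimmed), Hilbert
transformed, and reduced to instantaneous phases (`bandpass_analytic()`).
"Coherence" is the phase-locking value
$\mathrm{coh}(i,j) = |\langle e^{\mathrm{i}(\varphi_i - \varphi_j)}\rangle_t|$:
bounded in $[0,1]$, amplitude-invariant, invariant to a fixed lag.  The
band-pass–Hilbert–coherence wording of the protocol is compatible with
either this or an amplitude-weighted coherency; the phase-locking form
was chosen for boundedness and amplitude invariance, and the weighted
variant stays available behind `weighted = TRUE` for sensitivity checks.
Spectra use Welch's averaged periodogram (Hann windows, 4 s segments,
50% overlap; `welch_psd()`, `psd_peak()`), and network synchrony the
Kuramoto order parameter (`kuramoto_order()`).

## The four metrics

With $\mathrm{coh}(k_i, k_j, \Delta\varphi)$ the pair coherence at offset
$\Delta\varphi$:

* **PSF** (pathway synchronization facilitation, `psf()`):
  $\max_{\Delta\varphi} \mathrm{coh} - \min_{\Delta\varphi} \mathrm{coh}$
  for the stimulated pair.  High PSF means the phase relationship matters
  for the pair's interaction.
* **PA** (pathway activation, `pa()`): for a pathway $k_1..k_n$,
  $\prod_{i=1}^{n-1}\mathrm{coh}(k_i, k_{i+1}, \Delta\varphi)$ — a failed
  segment annihilates the route, and long routes are penalized.
  Variants: `pa_min()` (bottleneck only) and `pa_weighted()` (scaled by
  mean structural strength along the route).
* **PPS** (pathway phase selectivity, `pps()`): max − min of a pathway's
  PA curve.
* **PSI** (pathway switching index, `psi()`):
  $\max_{\Delta\varphi}(\mathrm{PA}_1 - \mathrm{PA}_2)\cdot
   \max_{\Delta\varphi}(\mathrm{PA}_2 - \mathrm{PA}_1)$ between the
  strongest pathway and the strongest pathway edge-disjoint from it;
  positive iff each route dominates at some offset.  `psi_normalized()`
  takes $\mathrm{sign}\cdot\sqrt{|\cdot|}$ back to coherence scale.

"Strongest" means highest offset-averaged PA (arithmetic mean); ties
break lexicographically on the node sequence.  "No overlapping segments"
means edge-disjoint — shared interior nodes are allowed.  Pathways are
enumerated on the undirected support of $C$ (preprocessed support is
near-symmetric; a `directed` flag retains the directed view), capped by
default at 6 edges for graph statistics and 4 edges (5 nodes) for PA
evaluation — the two caps the protocol states, kept as separate
parameters.  Pairs then fall into three classes (`classify_pairs()`):
*flat* (strongest path PPS below 0.1), *selective* (phase-selective, no
switching), *switching* (PSI > 0).  The 0.1 threshold is this package's
choice of a boundary for "very small selectivity"; it sits well below
typical selective-path PPS values (median ~0.3, upper range ~0.7 on the
test suite's synthetic connectomes) and
well above the PSF of uncoupled control pairs (< 0.05).

## The synthetic connectome

Diffusion-imaging connectivity matrices of the kind this model consumes
(e.g. a 33-region single-hemisphere parcellation) are generally not
redistributable, so `synth_connectome()` generates stand-ins:
Bernoulli directed edges (default density 0.3, matching the sparsity of
a thresholded single-hemisphere parcellation), log-normal raw weights
(sparse, heavy-tailed, like tract-count matrices), symmetric uniform
distances in 10–160 mm (the span of intra-hemispheric average tract
lengths), a random spanning tree for connectedness, then the same
preprocessing as real data: normalize incoming weights to 1, zero
entries below 0.1, renormalize (`preprocess_sc()`; the
normalize–threshold–renormalize order follows the stated preprocessing
sequence).  What it does **not** emulate: spatial embedding (distance is
independent of topology), hemispheric community structure, and the
empirical weight–distance anticorrelation.  A green pipeline test on a
synthetic connectome therefore establishes that the machinery produces
the qualitative phenomenology (all three pair classes exist; PSF
declines with network distance), not quantitative values measured on any
particular empirical connectome, which are tied to that connectome's
matrices.

## Numerical choices and degenerate inputs

* Integer delays; minimum 1 step so the integrator never needs
  same-step neighbor states.
* A target losing all inputs at thresholding stays all-zero with a
  warning rather than erroring: real parcellations can produce isolated
  regions.
* Coherence of constant-phase series is exactly 1; `psd_peak()` reports
  a prominence (peak over median band power) so peakless spectra can be
  flagged instead of trusted.
* Flat PA or coherence curves make the phase-alignment argmax
  ill-defined; the first argmax is used and the result flagged.
* Wrapped phase differences live in $(-\pi, \pi]$, with $-\pi$ mapped to
  $+\pi$.

## Known limitations

* **Pointwise trajectories are not step-size reproducible.**  The
  delay-coupled noisy network is weakly chaotic: halving $\Delta t$
  (with matched noise and delay-commensurate distances) keeps
  functional-connectivity matrices correlated at 0.91–0.99, but raw
  50 s trajectories decorrelate to 0.6–0.9 — and $\Delta t = 0.5$ ms vs
  0.25 ms behaves identically, so this is sensitivity to any
  perturbation, not integrator inaccuracy.  Statistical quantities (FC,
  spectra, the four metrics) are the reproducible level; the package's
  step-size acceptance test asserts both levels and the trajectory-level
  assertion documents this limit.
* One long run per offset (no trial averaging) is the default; repeats
  are a config away but multiply runtime.
* Discrete single-valued delays per edge; distributed-delay profiles are
  out of scope.
* The background-noise process is conventionally described either as
  Gaussian around $220\,\mathrm{s^{-1}}$ or as uniform on
  120–320 $\mathrm{s^{-1}}$; the uniform i.i.d. version is implemented
  (one draw per node per millisecond), and only its bounds are exposed.

## A minimal session

```{r example, eval = FALSE}
con <- synth_connectome(n = 10, density = 0.3, seed = 5)
pr  <- pair_probe(con, pair = c(1, 2),
                  cfg = sim_config(duration = 70, transient = 10, seed = 11))
m   <- pair_metrics(pr, con)
m$psf    # phase-offset range of the pair coherence
m$psi    # switching index between the top two disjoint routes
```
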