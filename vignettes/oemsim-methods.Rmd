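---
title: "Model and methods: spiking odorant encoding from antenna to calyx"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model and methods: spiking odorant encoding from antenna to calyx}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`oemsim` simulates the first three stages of the *Drosophila* early olfactory
system — the antenna, the antennal lobe (AL) and the mushroom-body calyx — as
a cascade of kinetic divisive-normalization circuits driving Connor-Stevens
spiking neurons.  Its purpose is to study how the circuit separates an
odorant's *identity* (its per-receptor binding and dissociation rates, the
"semantics") from its *concentration waveform* (the "syntax"), and how the
identity ends up represented as a concentration-invariant sequence of first
spikes across the Kenyon-cell (KC) population.

This vignette documents the model equations as implemented, the parameter
choices that matter and why they were made, the synthetic odorant generator,
numerical decisions, and the limits of what the simulations show.

## The odorant object

An odorant is a vector of binding rates $b_r$ (1/(ppm·s)) and dissociation
rates $d_r$ (1/s) over the $R$ receptor types, stored as an
`affinity_tensor` with dimensions odorant × receptor × OSN.  The affinity
$a_r = b_r/d_r$ (1/ppm) determines the steady-state binding.  The
concentration waveform $u_o(t)$ (ppm) is carried separately; a stimulus is a
rectangular step by default.  Mixtures are sets of such components with one
waveform each (`make_mixture()`).

## Antenna: odorant transduction

Each OSN expresses one receptor type and transduces all mixture components:

1. **Peri-receptor filtering.** $v = \mathrm{Re}[(h*u) + \gamma\, (h * u')]$
   with $h(t) = \tau_h^{-1} e^{-t/\tau_h}$ (unit DC gain, $\tau_h$ = 10 ms,
   $\gamma$ = 0.1 s).  The derivative path produces the physiological onset
   transient; the rectifier keeps $v \ge 0$ at offset.
2. **Competitive (syntopic) binding.**  Components compete for the same free
   receptor pool:
   $\dot x_{1,o} = b_o v_o (1 - \sum_p x_{1,p}) - d_o x_{1,o}$.
   The steady state is the competitive equilibrium
   $x^*_{1,o} = a_o v_o / (\sum_p a_p v_p + 1)$, and at a fixed component
   ratio the mixture binds in total exactly like a pure odorant with the
   concentration-weighted *effective affinity*
   $a_\mathrm{eff} = \sum_o a_o v_o / \sum_o v_o$.
3. **Co-receptor channel with calcium feedback.**
   $\dot x_2 = \alpha_2 X (1-x_2) - \beta_2 x_2 - \kappa x_2^{2/3} x_3^{2/3}$,
   $\dot x_3 = \alpha_3 x_2 - \beta_3 x_3$, where $X = \sum_o x_{1,o}$.
   The $x_3$ pathway is a slow divisive adaptation.
4. **Transduction current.**  Hill form
   $I = \bar I\, x_2^{\rho} / (x_2^{\rho} + c^{\rho})$, used in its
   steady-state form by default (the current kinetics are much faster than
   the gating kinetics); the dynamic ODE is available for comparison.
5. **Spike generation.** The Noisy Connor-Stevens point neuron (below).

The co-receptor and current constants ($\alpha_2 = 5$, $\beta_2 = 2$,
$\kappa = 10$, $\alpha_3 = 2.5$, $\beta_3 = 1$ s$^{-1}$; $\rho = 1$,
$c = 0.5$, $\bar I = 60\ \mu$A/cm²) are operating-point choices determined by
parameter sweeping, with one target: across 50–200 ppm the responding
channels should traverse the *non-saturated* part of the cascade, so that
OSN rates remain visibly concentration dependent (a prerequisite for any
claim that downstream stages remove that dependence).  All constants are
overridable per run.

## The spike generator

All spiking populations use the standard Connor-Stevens point neuron (Na, K,
transient A-current, leak; $C_m = 1\ \mu$F/cm²), a Type-I neuron with
rheobase $\approx 8.1\ \mu$A/cm², continuous f–I curve, and first-spike
latency strictly decreasing in drive — the property that makes a first-spike
code read out the drive ranking.  Noise enters as additive white current
noise with Euler–Maruyama integration; the noise variance smooths the f–I
curve around the rheobase.  All characterizations in the package run with
noise 0 and are bit-reproducible given the seeds.  Spikes are detected as
upward crossings of 0 mV with a 2 ms lockout.

## Antennal lobe

Each receptor type defines one glomerular channel:

* **OSN axon terminal (feedback DNP).**  A vesicle state is incremented by
  each OSN spike ($x \mathrel{+}= \alpha(1-x)$), decays at $\beta$, and is
  divisively decremented by each spike of the global presynaptic local
  neuron (Pre-LN): $x \mathrel{-}= \kappa x$.  Under Poisson rates
  $\lambda$ (OSN) and $\mu$ (Pre-LN) the mean has the divisive form
  $\alpha\lambda / (\alpha\lambda + \beta + \kappa\mu)$ — because the
  per-event updates are linear in $x$, this fixed point is exact in
  expectation, and the event-driven simulation matches it to a few percent.
* **Pre-LN.**  One Connor-Stevens neuron driven by graded synapses from all
  axon terminals; its spikes feed back into every channel, implementing
  spatial normalization across glomeruli (it engages when several channels
  are active, e.g. for broadly tuned odorants and mixtures).
* **Post-eLN / Post-iLN.**  Onset and offset local neurons.  The
  implementation estimates the channel's instantaneous OSN rate with a fast
  (50 ms) and a slow (250 ms) exponential filter and drives the onset
  neuron with $\mathrm{Re}[s_\mathrm{fast}-s_\mathrm{slow}]$ and the offset
  neuron with the mirrored rectification; each contacts the projection
  neuron (PN) through an excitatory resp. inhibitory conductance synapse.
  This rectified-rate-difference form was chosen as the simplest circuit
  with the stated onset/offset function; it is a declared design choice.
* **PN.**  One Connor-Stevens neuron per channel summing the axon-terminal,
  Post-eLN and Post-iLN synaptic currents, plus a constant sub-rheobase bias
  (`pn_bias` = 7 µA/cm²) modeling the high intrinsic excitability of PNs.
  Without the bias, weak channels are clipped by the spiking threshold and
  *recruited* abruptly as concentration rises, which inflates rather than
  reduces the concentration dependence of the population response.

Conductance synapses follow $\dot x = \alpha\,\mathrm{drive}\,(1-x) -
\beta x$ with current $g\,x\,(E - V)$ (excitatory $E = 0$ mV, inhibitory
$E = -80$ mV).  The axon-terminal and PN-synapse gains are set so that PN
rates track OSN rates with a compressed but non-zero concentration slope:
normalization at the AL is deliberately partial, as in the physiology, with
the calyx removing the remainder.

## Calyx

* **Wiring.**  Each of `M` KCs draws exactly `Q` distinct PNs uniformly at
  random (`sample_pn_kc_graph()`); `Q = 6` matches the average claw count,
  `M` defaults to 500 (the rank-curve results are scale free; the
  anatomical 2,000 is available by configuration).
* **KC dendrite (feedback DNP).**  PN spikes increment the dendritic state
  ($\alpha_1 = 0.1$ per spike), which decays at $\beta_1 = 4$ s$^{-1}$ and
  is divisively suppressed by the APL state through
  $\kappa_1 x\, x^\mathrm{APL}$ with $\kappa_1 = 120$ s$^{-1}$.
* **APL.**  A single kinetic state incremented by every KC spike
  ($5\times10^{-4}$ per spike) and decaying at 10 s$^{-1}$.  This is a
  *high-gain, slow* feedback configuration: the APL state stays small, so
  its relative sensitivity to total KC activity is near-maximal, and the
  loop behaves like integral gain control, pinning the marginal KC class at
  the firing onset at every concentration.
* **KC spike generator.**  Driven by $\bar I^K x$ with
  $\bar I^K = 14\ \mu$A/cm², placing the firing onset at $x \approx 0.58$ —
  slightly *above* the dendritic activity threshold of 0.5.  With the onset
  exactly at 0.5 the feedback loop parks the marginal KC class on a knife
  edge at the threshold, and on some wirings the 50 ppm response oscillates
  around it; the offset guarantees that every KC counted active is reliably
  spiking, so the first-spike sequence contains every active KC.
* **Initial-condition jitter.**  Each KC's initial membrane voltage receives
  a seeded uniform ±2 mV offset.  With deterministic neurons and few
  responding PNs, KCs wired to the same responding channels would otherwise
  be *identical* and fire in lockstep; the jitter desynchronizes them (as
  heterogeneous initial conditions do in vivo) without adding ongoing noise.
  Runs remain reproducible for a fixed seed.

PN–KC and KC–APL synaptic dynamics are intentionally omitted; spikes act
directly on the kinetic states.

## Synthetic odorants

The generator (`synth_affinity_profile()`) emulates the two tuning regimes
seen across real odorants:

* **sparse-k** — `k` dominant receptors with comparable affinities drawn
  log-uniform in [0.007, 0.016] per ppm, over a geometrically decaying,
  jittered "shoulder" (ratio 0.15 to the dominant mean, decay 0.4 per rank,
  log-normal jitter).  The shoulder reproduces the descending continuum of
  measured affinity rank profiles; the background is rescaled if necessary
  so the `k` dominants jointly carry 85% of the summed affinity (hence
  exactly `k` receptors carry at least 80%).  The dominant magnitudes put
  $a\,u$ near the half-saturation of the binding equilibrium across
  50–200 ppm, where concentration sensitivity is maximal; substantially
  larger values saturate binding and flatten every stage's concentration
  response.
* **broad** — all receptors log-uniform in [10⁻⁴, 10⁻²] per ppm, yielding
  graded responses across many channels and a smooth KC input rank curve
  without a cliff.

What passing tests on these fixtures do **not** show: real affinity vectors
have correlated structure across odorants and receptors, real OSN
populations are noisy and heterogeneous within a type, and real
concentration dynamics are turbulent rather than rectangular.  The fixtures
isolate the circuit mechanisms — competitive binding, divisive
normalization, expansion coding, APL gain control — under controlled
conditions; they do not calibrate the model against physiology.

## Readouts

For each run the package reports steady OSN/PN rates (mean over a trailing
window of the odor step — the last 0.3–0.5 s, after the onset transient and
adaptation have settled), the aggregate PN drive per KC ("KC dendritic
input"), the steady dendritic output `x_kcd_steady`, rank curves of both,
the active set (`x > 0.5`), the first-spike sequence of the active KCs
(aligned to stimulus onset) and its cumulative inter-spike-interval curve.

Two sequences are compared by (i) the Jaccard overlap of their active sets
and (ii) the normalized Kendall distance between the first-spike time
rankings restricted to shared KCs, with simultaneous spikes assigned average
ranks.  Ranking by spike time (rather than list position) matters because
deterministic KC classes can fire simultaneously, and positional ranks would
inherit an arbitrary identity tie-break.  The rank-curve "gap" statistic is
the largest adjacent drop divided by the curve's total range, which stays
well defined on tie-plateau curves (a median-based denominator degenerates
to zero there).

## Numerical choices

* One shared clock; `dt` defaults to 10 µs (engine) with 20 µs used by the
  test-suite protocols; the Connor-Stevens Euler step is stability-limited
  at 20 µs, and deterministic spike times shift by under 1% when `dt` is
  halved.
* Spike trains act on kinetic states as impulsive per-event updates
  (`x += α(1−x)` per spike, exact exponential decay between events within
  the grid), preserving the event semantics without `dt`-dependent delta
  scaling.
* The competitive-binding step is one backward-Euler step of the coupled
  linear system; the total bound fraction has a closed form, so the
  implicit step is explicit to compute, unconditionally stable, exactly
  bounded in [0, 1], and has the exact competitive equilibrium as its fixed
  point.  Explicit Euler fails the bound during the onset transient at high
  concentration.  Other kinetic states use explicit Euler with
  invariant-tolerance checks (violations beyond 10⁻⁹ raise errors rather
  than being silently clipped).
* Two independent RNG streams: wiring (`seeds$graph`) versus noise and
  initial-condition jitter (`seeds$noise`), so wiring-fixed noise studies
  and noise-fixed wiring studies are both possible.
* The reference stimulus protocol is 0.3 s silence, a 1.0 s odor step and a
  0.2 s tail; the characterization suites use a compressed 0.1/0.6/0.1 s
  protocol at `dt` = 20 µs with `M` = 500 KCs, which reproduces the same
  steady-state statistics at a fraction of the cost.  Problem sizes per
  experiment: 23 receptors/channels, 500 KCs, 4 concentration levels,
  5 wirings.

## Known limitations

* Multiglomerular PNs, the lateral horn, mushroom-body output neurons, KC
  subtypes and plasticity are out of scope, as are odorant masking,
  binding facilitation/suppression and ephaptic coupling.
* With deterministic neurons and a handful of responding channels the KC
  population decomposes into equivalence classes of identical drive; the
  first-spike code is correspondingly quantized.  Initial-voltage jitter
  spreads the within-class timing but not the drive itself.
* The Post-eLN/Post-iLN equations are a functional stand-in with the stated
  onset/offset behavior, not a fitted circuit.
* Affinity magnitudes are declared operating-point choices; nothing here is
  fitted to recordings.
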