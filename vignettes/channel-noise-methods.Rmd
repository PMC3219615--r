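---
title: "Channel noise in Hodgkin-Huxley membranes: models, approximations, and how this package validates them"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel noise in Hodgkin-Huxley membranes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hhnoise)
```

## The problem

A patch of excitable membrane carries finitely many voltage-gated ion
channels. Each channel wanders stochastically among its conformational
states with voltage-dependent rates, and the fraction of channels in the
conducting configuration sets the ionic conductance in the current-balance
equation

$$C_m \frac{dV}{dt} = \bar g_{Na}\, y_{Na} (E_{Na} - V)
  + \bar g_K\, y_K (E_K - V) + g_L (E_L - V) + I(t).$$

With $N \to \infty$ channels the conducting fractions converge to the
deterministic Hodgkin-Huxley expressions $y_{Na} = m^3 h$, $y_K = n^4$,
where each gating variable obeys
$\dot x = \alpha_x(V)(1 - x) - \beta_x(V)\,x$. At physiological channel
counts (thousands per patch) the fluctuations — *channel noise* — are large
enough to trigger spontaneous action potentials and to randomize spike
timing, so a stochastic description is required.

The exact description is a continuous-time Markov chain over channel
configurations: 8 states for the classical Na channel (0-3 open $m$-gates
$\times$ open/closed $h$-gate, conducting state $(3,1)$) and 5 states for
the K channel (0-4 open $n$-gates, conducting state 4). This package
simulates that chain exactly with a Gillespie-type algorithm, and
implements, side by side, the four stochastic-differential-equation
approximations that the literature has proposed in its place:

1. **Current noise** — deterministic gating plus a white-noise current
   $\xi(t)$ of intensity $\sigma_I$ in the voltage equation. Empirical: no
   first-principles value for $\sigma_I$ exists, so the package calibrates
   it against a target mean interspike interval.
2. **Subunit noise** — Langevin terms on the gating variables, with noise
   variance $(\alpha_x(1-x) + \beta_x x)/N$ per step (for $m,h$: the Na
   channel count; for $n$: the K channel count), gates clipped to
   $[0, 1]$. Also the independent-copies variant
   ($y_{Na} = m_1 m_2 m_3 h$, $y_K = n_1 n_2 n_3 n_4$ with independent
   SDE solutions per slot).
3. **Voltage-clamp conductance noise (OU bank)** — the conducting fraction
   is the deterministic value plus a sum of Ornstein-Uhlenbeck processes
   whose timescales and stationary variances reproduce, at fixed voltage,
   the exact binomial variance and exponential-mixture autocovariance of
   the Markov chain: for K, $\tau_k = \tau_n / k$ and
   $v_k = \binom{4}{k} n_\infty^{2(4-k)} (n_\infty(1-n_\infty))^k / N_K$,
   $k = 1..4$; for Na the analogous 7 components over
   $(i, j) \ne (0, 0)$. The total variance telescopes exactly to the
   binomial $p_\infty(1 - p_\infty)/N$.
4. **System-size conductance noise** — the Fox-Lu expansion of the master
   equation: the channel-state fraction vector is split as
   $x = \bar x + \tilde x$, where $\bar x$ solves the deterministic part
   $\dot{\bar x} = A(V)\bar x$ (generated exactly by the multinomial
   combination of the gating variables) and the zero-mean fluctuation
   obeys the linear SDE
   $d\tilde x = A(V) \tilde x\,dt + S\,dW$ with $S S^\top = D(V, \bar x)$,
   the diffusion matrix assembled from one-way probability fluxes.
   The conducting component of $\tilde x$ is added to $m^3 h$ (or $n^4$)
   in the voltage equation.

The benchmark statistics are closed-form: along any fixed voltage path the
open-channel fraction of the exact model is asymptotically binomial with
mean $m(t)^3 h(t)$ (resp. $n(t)^4$) and variance $p(t)(1-p(t))/N$, where
the gating variables solve the deterministic equations along the path
(`binomial_moments_along_path()`).

## Parameters and their defaults

| Parameter | Default | Units | Meaning |
|---|---|---|---|
| $C_m$ | 1 | uF/cm^2 | membrane capacitance |
| $\bar g_{Na}, \bar g_K, g_L$ | 120, 36, 0.3 | mS/cm^2 | maximal conductances |
| $E_{Na}, E_K, E_L$ | 50, -77, -54.387 | mV | reversal potentials |
| area | 100 | um^2 | patch size |
| $\rho_{Na}, \rho_K$ | 60, 18 | channels/um^2 | channel densities |
| $N_{Na}, N_K$ | 6,000, 1,800 | — | channel counts (round(density x area)) |
| dt | 0.01 | ms | forward-Euler / Euler-Maruyama step |
| spike threshold | -20 | mV | upward-crossing detector |
| dead time | 2 | ms | minimum spike separation |

The rate functions are the community-standard shifted Hodgkin-Huxley
forms (resting potential near -65 mV); the removable singularities of
$\alpha_m$ at -40 mV and $\alpha_n$ at -55 mV are evaluated by a series
branch within $10^{-7}$ mV. The default patch (6,000 Na / 1,800 K
channels) is the reference condition for every comparison in the test
suite; at that size the membrane fires spontaneously with no applied
current.

Spike detection at -20 mV with a 2 ms dead time is insensitive to the
threshold within roughly +-10 mV for full-height action potentials; both
values are arguments of `detect_spikes()`.

## Numerical choices

**Fixed-step forward Euler everywhere.** The deterministic model, the
voltage update of every stochastic model, and the Euler-Maruyama SDE
steppers share one update rule (gating/channels advance first with rates
frozen at the current voltage, then the voltage advances on the updated
conducting fractions). Consequence: setting the noise amplitude to zero
(infinite $N$, or $\sigma_I = 0$) reproduces the deterministic trajectory
*bit for bit*, which the test suite asserts. The price is first-order
accuracy: the spiking period converges at $O(dt)$ (error $\approx 7\,dt$
at $dt = 0.01$ ms), which the tests verify as a convergence *rate* rather
than a fixed constant.

**Hybrid Gillespie coupling.** In the free-running Markov-chain neuron,
channel transition rates are frozen over each voltage step of length
$dt$; within the step the chain is simulated exactly (exponential waiting
times, categorical event choice). The freezing error vanishes as
$dt \to 0$; in voltage clamp the simulation is exact.

**Matrix square roots.** $D$ is evaluated at the *deterministic* state
$\bar x$ (never the stochastic one), which keeps it positive semidefinite
by construction. The symmetric eigendecomposition root is used rather
than Cholesky because $D$ is singular — the all-ones vector spans its
null space (probability conservation) — and the symmetric root keeps that
vector in the null space of $S$ structurally, so $\mathbf{1}^\top \tilde x$
is conserved to rounding ($< 10^{-8}$ over $10^4$ steps). Eigenvalues
below $-10^{-9} \times$ the trace scale raise an error; small negative
rounding residuals are clamped to zero. The root is refreshed every step.

**Boundaries.** Subunit gates are clipped to $[0,1]$ after every step
(excursions are $O(N^{-1/2})$; clipping is simpler than reflection and
the square-root argument is evaluated at the clipped state, so it is
never negative). The conductance-noise models permit transiently negative
instantaneous open fractions — the fluctuation statistics are Gaussian by
construction — but the total conductance is floored at zero inside the
voltage equation to prevent reversal-potential pathologies. Replay
(clamped-statistics) kernels do *not* floor, so ensemble moments are
exactly those of the Gaussian models.

**Euler-Maruyama stationary bias.** The discrete stationary covariance of
a linear SDE solves $A\Sigma + \Sigma A^\top + D + dt\,A \Sigma A^\top = 0$,
an $O(dt)$ bias that reaches 4-8% on the fast Na ($m$-gate) components at
$dt = 0.01$ ms. Validations that resolve stationary covariances at the
percent level therefore integrate finer: the clamp-covariance comparisons
sample at $dt = 0.001$-$0.002$ ms, and `replay_ensemble(substeps = 2)`
lets the system-size model integrate at half the path step while
reporting on the original grid.

**Lyapunov oracle.** The stationary covariance of the fluctuation SDE in
clamp is obtained independently by solving $A\Sigma + \Sigma A^\top + D = 0$
through the SVD pseudo-inverse of the Kronecker system; the generator's
zero mode (along the stationary distribution) is fixed by requiring
$\mathbf{1}^\top \Sigma \mathbf{1} = 0$. The result coincides to
$10^{-12}$ with the closed-form multinomial covariance
$(\mathrm{diag}(\bar x) - \bar x \bar x^\top)/N$, and the simulated
covariance matches it component-wise within Monte-Carlo error.

**Random numbers.** Every stochastic kernel takes an explicit integer
seed; replicate ensembles derive independent sub-streams by a splitmix64
hash of (root seed, replicate index), so results are reproducible and
replicates are exchangeable. Normals come from Box-Muller, exponentials
from inverse-CDF uniforms on a 64-bit Mersenne Twister.

## Study conditions and problem sizes

The package's validation protocols mirror two canonical comparisons, at
the default 6,000/1,800-channel patch:

* **Replayed trajectory.** A spontaneous-spike voltage path
  (`spontaneous_spike_path()`: 120 ms of subthreshold wandering, a
  channel-noise-induced spike, 40 ms of tail, at $I = 0$) is generated by
  the Markov chain and then replayed through every model with the voltage
  equation disabled; per-time mean and variance of the conducting
  fractions across replicates are compared with the binomial closed form.
  The test suite uses 1,000 replicates for the Markov chain and 1,500 for
  the SDE models; the first 30 ms are discarded as burn-in (fluctuation
  relaxation times are a few ms at rest, with $\tau_h \approx 8.5$ ms the
  slowest). The expected signatures: the system-size model's variance
  tracks the closed form at $\ge 95\%$ of points through the spike; the
  subunit model's variance is far below it subthreshold ($\sim 2\%$ of
  the binomial value for Na — the linearized ratio is
  $\approx 9 m_\infty^2 h_\infty$, tiny at rest) and overshoots for K
  during the spike (the linearized K ratio $16 n^2(1-n)/(1-n^4)$ reaches
  2-3.5 at depolarized voltages); the OU bank — quasistationary by
  construction — misses the variance transient during the rapid spike.
* **DC-drive ISI statistics.** At $I = 7$ uA/cm^2 (suprathreshold: the
  deterministic model fires repetitively) each model runs until 500
  spikes are collected; ISI mean and CV (population-SD convention) carry
  standard errors over batches of 50 intervals. The system-size model is
  expected to match the Markov chain within Monte-Carlo error; the
  subunit model produces significantly longer mean intervals (its Na
  conductance noise is far too weak) and a significantly different CV.
  For the current-noise model, $\sigma_I$ is calibrated once — for the
  membrane area, by bisection against the Markov chain's mean ISI — and
  its CV discrepancy is then assessed across two drive levels (7 and 10
  uA/cm^2) with that single $\sigma_I$, because at the calibration drive
  itself a white-noise current can mimic the ISI distribution closely.
  The CV-discrepancy ranking uses 1,200 spikes per estimate so that
  estimation error sits well below the $\approx 0.08$ CV gap being
  ranked.

Two further structural checks: one Euler-Maruyama step of the combined
channel-state SDE equals the sum of the decomposed deterministic and
fluctuation steps to $10^{-12}$ (exactness of the split, by linearity),
and at $N = 10^6$ channels the stochastic voltage traces collapse onto
the deterministic one. For the latter, note a metric subtlety: the
pointwise sup-norm over a window containing a spike amplifies the
$O(N^{-1/2})$ spike-phase jitter by the $\sim$400 mV/ms upstroke slope,
so a 2 mV tolerance sits near the median of the seed distribution even
though subthreshold agreement is 0.1-0.3 mV; the deterministic limit is
demonstrated more robustly by the $1/\sqrt{N}$ scaling of the stationary
fluctuations, which the suite also verifies.

## What the synthetic conditions do and do not show

All inputs here are model-generated: the package emulates an isopotential
patch with exactly the classical kinetic schemes, spatially unresolved
channels, no temperature dependence, and white calibration-free noise
only where the models define it. Passing tests therefore certify the
numerical fidelity of each approximation *to the Markov-chain ideal* at
the stated conditions — not that any of these models captures a real
membrane, whose channels have richer (possibly non-Markov) kinetics,
inhomogeneous densities, and spatial structure. The generic
`kinetic_scheme()` machinery accepts arbitrary connected state graphs
with user-supplied rate functions, so non-subunit schemes can be
simulated in clamp and replay; the OU bank and the hard-coded SDE neuron
kernels apply to the classical subunit-factorizable schemes only.

## Design decisions worth knowing about

* **Shared-noise OU variant** (`ou_shared`): implemented as the
  equal-increment special case — one Wiener increment per channel type
  driving all bank components with amplitudes $\sqrt{2 v_i/\tau_i}$. The
  induced component correlations raise the clamp variance above the
  binomial value (by the closed-form factor
  $\sum_{ij} s_i s_j \tau_i \tau_j/(\tau_i + \tau_j) \big/ \sum_i v_i$,
  about 3.4 for K at -50 mV); the variant is validated against that
  closed form. Amplitude reweighting to restore the binomial variance
  under shared noise would need coefficients this package does not
  derive.
* **OU deterministic baseline out of clamp** is the gating-ODE track
  $m^3 h$ (not the instantaneous $m_\infty^3 h_\infty$), so the model
  reduces correctly in clamp and stays causal when $V$ moves.
* **Calibration** (`calibrate_current_noise()`) bisects on $\sigma_I$
  assuming the mean ISI decreases with noise intensity — true in the
  noise-driven and near-threshold regimes it is meant for; far above
  threshold the response is non-monotone and shallow, and the routine
  reports a bracketing failure rather than forcing an answer.
* **Markov replay initialization** draws exact multinomial samples from
  the stationary occupancy at the path's initial voltage; the OU bank
  starts from its stationary component variances; subunit and
  system-size replays start at the deterministic state and rely on the
  burn-in window.

## Known limitations

* Single compartment only; no cable structure, no Q10/temperature
  scaling, no alternate published parameter sets.
* First-order (Euler/Euler-Maruyama) integration throughout — chosen for
  the exact zero-noise reduction — so percent-level stationary statistics
  require the finer steps discussed above.
* The independent-copies and shared-noise variants are provided for
  comparison, not endorsement; both misrepresent the channel-level
  statistics by construction.
* The Gillespie neuron freezes rates over one voltage step; for extremely
  stiff stimuli reduce `dt` (the hybrid error is $O(dt)$).
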