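# hhnoise

Stochastic Hodgkin-Huxley simulators with exact and approximate channel
noise.

A patch of excitable membrane carries finitely many voltage-gated
channels, and their random open/close transitions — *channel noise* —
make conductances fluctuate, trigger spontaneous action potentials, and
randomize spike timing. The exact description is a continuous-time Markov
chain over channel configurations (8 states for the classical Na channel,
5 for K) coupled to the current-balance equation

    C_m dV/dt = g_Na y_Na (E_Na - V) + g_K y_K (E_K - V) + g_L (E_L - V) + I(t)

where `y_Na`, `y_K` are the conducting-state fractions (deterministically
`m^3 h` and `n^4`). This package is for computational neuroscientists and
biophysicists who need that gold-standard model and its common
stochastic-differential-equation approximations *side by side*, with the
closed-form statistics to judge them:

* **`markov`** — exact Gillespie-type simulation of the channel-state
  Markov chain, in voltage clamp or coupled to the evolving membrane
  potential.
* **`current`** — white-noise current of intensity `sigma_I` added to the
  voltage equation (with a calibration routine that matches a target mean
  interspike interval).
* **`subunit`** — Langevin terms on the gating variables m, h, n with
  state-dependent variance `(alpha(1-x) + beta x)/N`; also the
  independent-subunit-copies variant (**`subunit_independent`**).
* **`ou` / `ou_shared`** — voltage-clamp conductance noise: deterministic
  open fractions plus a bank of Ornstein-Uhlenbeck processes (4 components
  for K, 7 for Na) whose total stationary variance equals the binomial
  `p(1-p)/N` exactly.
* **`ssa`** — the system-size (Fox-Lu) conductance model: zero-mean
  channel-state fluctuation vectors driven by a linear SDE with generator
  drift `A(V)` and matrix-square-root diffusion `S S' = D`, added to the
  deterministic conducting fractions.

Benchmarks included: time-resolved binomial moments of the open-channel
fractions along any fixed voltage path, replayed-trajectory ensemble
statistics, spike detection, ISI mean/CV with batch standard errors, and
first-spike-time histograms.

## Worked example

```r
library(hhnoise)
p <- membrane_params()   # 100 um^2 patch: 6,000 Na and 1,800 K channels
p
#> Hodgkin-Huxley membrane parameters
#>   C_m = 1 uF/cm^2; g_Na/g_K/g_L = 120/36/0.3 mS/cm^2
#>   E_Na/E_K/E_L = 50/-77/-54.387 mV
#>   area = 100 um^2; N_Na = 6000, N_K = 1800 channels

# spontaneous activity of the exact Markov-chain model, no applied current
tr <- simulate_neuron("markov", p, I = 0, T = 1000, seed = 42)
detect_spikes(tr)
#> spike_train: 7 spikes (threshold -20 mV, dead time 2 ms)
```

Seven channel-noise-induced spikes in one second with *zero* applied
current — the signature of a finite-size membrane (the deterministic model
sits silently at rest). Now compare ISI statistics of the system-size SDE
approximation with the exact model under a DC drive:

```r
trains_mc <- list(); trains_ssa <- list()
for (k in 1:3) {
  trains_mc[[k]]  <- detect_spikes(simulate_neuron("markov", p, I = 10, T = 2000, seed = k))
  trains_ssa[[k]] <- detect_spikes(simulate_neuron("ssa",    p, I = 10, T = 2000, seed = k))
}
isi_stats(trains_mc)
#> ISI statistics (386 intervals, 7 batches)
#>   mean = 15.457 ms (SE 0.246); CV = 0.2676 (SE 0.0270)
isi_stats(trains_ssa)
#> ISI statistics (380 intervals, 7 batches)
#>   mean = 15.738 ms (SE 0.240); CV = 0.2721 (SE 0.0306)
```

Mean and CV agree within one standard error — the system-size model is
the approximation that reproduces the Markov chain's spiking statistics.
In voltage clamp the exact model's open fraction is binomial, and the
simulation recovers it:

```r
occ <- simulate_markov_clamped(hh_k_scheme(), N = 1800, V = -40, T = 2000, seed = 7)
y <- occ$open_frac[occ$time_ms > 200]
s <- hh_steady_state(-40)
round(c(mean_sim = mean(y), mean_binom = s$n^4,
        var_sim = var(y), var_binom = s$n^4 * (1 - s$n^4) / 1800), 6)
#>   mean_sim mean_binom    var_sim  var_binom
#>   0.211713   0.212047   0.000085   0.000093
```

Other entry points: `replay_ensemble()` (ensemble statistics of any model
along a recorded voltage path), `binomial_moments_along_path()` (the
closed-form reference), `spontaneous_spike_path()` (canned
spontaneous-spike protocol), `calibrate_current_noise()`,
`build_ou_bank()`, `ssa_matrices()` / `lyapunov_covariance()`, and
`run_experiment()` / `run_comparison()` for config-driven batch runs with
manifests. See the vignette in `vignettes/channel-noise-methods.Rmd` for
the models, their assumptions, and every numerical choice.

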