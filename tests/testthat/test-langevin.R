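# The three simple SDE noise models: current noise, subunit noise (and its
# independent-copies variant), and the voltage-clamp OU conductance bank.

test_that("every SDE stepper with noise disabled reproduces the
           deterministic Euler trajectory bit-for-bit", {
  p <- fix_params()
  det <- simulate_deterministic(p, I = 7, T = 40)
  inf_args <- list(N_Na = Inf, N_K = Inf)
  for (m in c("subunit", "subunit_independent", "ou", "ou_shared", "ssa")) {
    tr <- do.call(simulate_neuron,
                  c(list(m, p, I = 7, T = 40, seed = 99), inf_args))
    expect_identical(tr$V_mV, det$V_mV, label = m)
  }
  trc <- simulate_neuron("current", p, I = 7, T = 40, seed = 99, sigma_I = 0)
  expect_identical(trc$V_mV, det$V_mV)
})

test_that("clamped subunit gate variance matches m_inf(1-m_inf)/N across
           the voltage range", {
  for (V in c(-80, -60, -40, -20, 0)) {
    s <- hh_steady_state(V)
    r <- hhnoise:::cpp_subunit_replay_ensemble(rep(V, 6001), 0.01, 400, 50 + V,
                                               1 / 6000, 1 / 1800,
                                               s$m, s$h, s$n, FALSE)
    stat <- r$var_m[3001:6001]
    v_th <- s$m * (1 - s$m) / 6000
    # conservative band: sampling error of a variance across 400 reps
    expect_lt(abs(mean(stat) - v_th), 3 * v_th * sqrt(2 / 399),
              label = sprintf("V = %g", V))
  }
})

test_that("subunit open-fraction variance falls far below the binomial law
           at rest", {
  V <- -65
  s <- hh_steady_state(V)
  p <- s$m^3 * s$h
  es <- replay_ensemble("subunit", rep(V, 4001), reps = 800, seed = 23,
                        dt = 0.01, N_Na = 6000, N_K = 1800)
  i <- es$time_ms > 20
  binom <- p * (1 - p) / 6000
  # significantly below: more than 3 SE under the closed form at most points
  expect_gt(mean((es$var_open_Na < binom - 3 * es$se_var_open_Na)[i]), 0.9)
  expect_lt(mean(es$var_open_Na[i]) / binom, 0.5)
})

test_that("independent-copies variant reduces to the aggregate model
           without noise and misses the binomial variance with it", {
  p <- fix_params()
  det <- simulate_deterministic(p, I = 7, T = 30)
  tr <- simulate_neuron("subunit_independent", p, I = 7, T = 30, seed = 1,
                        N_Na = Inf, N_K = Inf)
  expect_identical(tr$open_frac_Na, det$open_frac_Na)
  V <- -40
  s <- hh_steady_state(V)
  pna <- s$m^3 * s$h
  es <- replay_ensemble("subunit_independent", rep(V, 4001), reps = 800,
                        seed = 29, dt = 0.01, N_Na = 6000, N_K = 1800)
  i <- es$time_ms > 20
  binom <- pna * (1 - pna) / 6000
  expect_gt(mean((abs(es$var_open_Na - binom) > 3 * es$se_var_open_Na)[i]),
            0.9)
})

test_that("OU-bank total stationary variances collapse to the binomial
           values algebraically", {
  set.seed(31)
  for (i in 1:300) {
    V <- runif(1, -100, 40); N <- sample(50:20000, 1)
    bk <- build_ou_bank("K", V, N)
    pk <- attr(bk, "p_inf")
    expect_lt(abs(sum(bk$v) - pk * (1 - pk) / N), 1e-12 / N * 10)
    bn <- build_ou_bank("Na", V, N)
    pn <- attr(bn, "p_inf")
    expect_lt(abs(sum(bn$v) - pn * (1 - pn) / N), 1e-12 / N * 10)
  }
  expect_equal(nrow(build_ou_bank("Na", -60, 100)), 7L)
  expect_equal(nrow(build_ou_bank("K", -60, 100)), 4L)
  expect_error(build_ou_bank(two_state_scheme(1, 1), -60, 100),
               "factorization")
})

test_that("OU-bank implied autocovariance matches the clamped Markov
           chain", {
  V <- -40; N <- 1800
  b <- build_ou_bank("K", V, N)
  occ <- simulate_markov_clamped(hh_k_scheme(), N, V, T = 20000,
                                 record_dt = 0.05, seed = 8)
  y <- occ$open_frac[occ$time_ms > 100]
  taun <- hh_rates(V)$tau_n
  nb <- 10
  seg <- rep(seq_len(nb), each = floor(length(y) / nb))[seq_along(y)]
  for (lag_ms in c(0, taun, 2 * taun)) {
    L <- round(lag_ms / 0.05)
    acv_seg <- vapply(seq_len(nb), function(s) {
      ys <- y[seg == s]
      n <- length(ys) - L
      cov(ys[1:n], ys[(1 + L):(L + n)])
    }, 0.0)
    th <- sum(b$v * exp(-lag_ms / b$tau))
    expect_lt(abs(mean(acv_seg) - th), 3 * sd(acv_seg) / sqrt(nb),
              label = sprintf("lag %.2f ms", lag_ms))
  }
})

test_that("OU conductance fluctuations have the binomial stationary
           variance in clamp and vanish with the noise", {
  V <- -50
  s <- hh_steady_state(V)
  pk <- s$n^4
  es <- replay_ensemble("ou", rep(V, 4001), reps = 800, seed = 37,
                        dt = 0.01, N_Na = 6000, N_K = 1800)
  i <- es$time_ms > 10
  binom <- pk * (1 - pk) / 1800
  expect_gt(mean((abs(es$var_open_K - binom) < 3 * es$se_var_open_K)[i]),
            0.9)
  # v_i = 0 (infinite N) => no fluctuation at all
  es0 <- replay_ensemble("ou", rep(V, 101), reps = 2, seed = 37, dt = 0.01,
                         N_Na = Inf, N_K = Inf)
  expect_true(all(es0$var_open_K == 0))
})

test_that("shared-noise OU variant has the clamp variance its component
           correlations imply", {
  # a single Wiener increment driving all components correlates them; the
  # stationary total variance is sum_ij s_i s_j tau_i tau_j/(tau_i+tau_j)
  # with s_i = sqrt(2 v_i / tau_i), which exceeds the independent-noise
  # (binomial) value
  V <- -50
  b <- build_ou_bank("K", V, 1800)
  s_i <- sqrt(2 * b$v / b$tau)
  Cth <- sum(outer(s_i, s_i) * outer(b$tau, b$tau) /
               outer(b$tau, b$tau, "+"))
  es <- replay_ensemble("ou_shared", rep(V, 4001), reps = 800, seed = 41,
                        dt = 0.01, N_Na = 6000, N_K = 1800)
  i <- es$time_ms > 15
  expect_gt(Cth, sum(b$v))                        # correlations add variance
  # simulated variance relaxes onto the analytic shared-noise value
  expect_lt(abs(mean(es$var_open_K[i]) - Cth), 3 * Cth * sqrt(2 / 799))
})

test_that("current-noise calibration: degenerate target, self-consistency,
           and monotone response in the fluctuation-driven regime", {
  p <- fix_params()
  det <- simulate_deterministic(p, I = 10, T = 400)
  target0 <- mean(diff(detect_spikes(det)$times))
  # deterministic model already at target -> sigma ~ 0 accepted
  cal0 <- calibrate_current_noise(p, I_DC = 10, target_mean_isi = target0,
                                  tol = 0.5, seed = 61,
                                  sigma_range = c(0, 8), n_spikes = 150)
  expect_equal(cal0$sigma_I, 0)
  # subthreshold drive (noise-induced firing): doubling sigma shortens the
  # mean ISI beyond Monte-Carlo noise
  s1 <- isi_stats(hhnoise:::collect_spike_trains("current", p, I = 3,
                                                 dt = 0.01, seed = 71,
                                                 n_spikes = 200,
                                                 sigma_I = 2))
  s2 <- isi_stats(hhnoise:::collect_spike_trains("current", p, I = 3,
                                                 dt = 0.01, seed = 72,
                                                 n_spikes = 200,
                                                 sigma_I = 4))
  expect_gt(s1$mean_isi - s2$mean_isi, 3 * se2(s1$se_mean, s2$se_mean))
  # closed loop: re-simulating at the calibrated intensity hits the target
  cal <- calibrate_current_noise(p, I_DC = 7, target_mean_isi = 19,
                                 tol = 0.5, seed = 63,
                                 sigma_range = c(0.5, 8), n_spikes = 250)
  re <- hhnoise:::collect_mean_isi(function(T, s)
    simulate_neuron("current", p, I = 7, T = T, seed = s,
                    sigma_I = cal$sigma_I),
    n_spikes = 400, seed = 64)
  expect_lt(abs(re - 19), 1.0)
  # an unreachable target reports a calibration failure
  expect_error(calibrate_current_noise(p, I_DC = 10, target_mean_isi = 60,
                                       tol = 0.2, seed = 65,
                                       sigma_range = c(1, 2),
                                       n_spikes = 100),
               "calibration failure")
})
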