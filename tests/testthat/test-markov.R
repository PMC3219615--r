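# Exact Gillespie channel kinetics: clamp statistics, dwell times,
# determinism, conservation, and the hybrid neuron.

test_that("zero rates freeze the occupancy", {
  sc <- two_state_scheme(0, 0)
  occ <- simulate_markov_clamped(sc, N = 50, V = -65, T = 20,
                                 record_dt = 0.5, seed = 1,
                                 init = c(30L, 20L))
  expect_true(all(occ$closed == 30))
  expect_true(all(occ$open == 20))
})

test_that("clamped K-channel open fraction matches the binomial mean and
           variance", {
  V <- -40; N <- 1800
  s <- hh_steady_state(V)
  p <- s$n^4
  occ <- simulate_markov_clamped(hh_k_scheme(), N, V, T = 5000,
                                 record_dt = 0.5, seed = 11)
  y <- occ$open_frac[occ$time_ms > 250]
  # batch means over 250 ms stretches (>> correlation time ~ tau_n)
  nb <- 19
  batch <- rep(seq_len(nb), each = floor(length(y) / nb))[seq_along(y)]
  bm <- tapply(y, batch, mean)
  bv <- tapply(y, batch, var)
  expect_lt(abs(mean(y) - p), 3 * sd(bm) / sqrt(nb))
  expect_lt(abs(mean(bv) - p * (1 - p) / N), 3 * sd(bv) / sqrt(nb))
})

test_that("dwell times in a two-state channel are exponential with the
           analytic rate", {
  alpha <- 0.5; beta <- 0.25
  sc <- two_state_scheme(alpha, beta)
  ev <- markov_events(sc, c(1L, 0L), V = -65, T = 1e5, seed = 4,
                      max_events = 20001)
  dw <- diff(ev$time_ms)
  from <- ev$from[-1]          # state occupied during each dwell
  ks_open <- ks.test(dw[from == "open"], "pexp", beta)
  ks_closed <- ks.test(dw[from == "closed"], "pexp", alpha)
  expect_gt(ks_open$p.value, 0.05)
  expect_gt(ks_closed$p.value, 0.05)
  expect_gt(sum(from == "open"), 5000)
})

test_that("identical configuration and seed reproduce the event sequence;
           different seeds diverge", {
  occ1 <- simulate_markov_clamped(hh_k_scheme(), 200, -50, T = 100, seed = 7)
  occ2 <- simulate_markov_clamped(hh_k_scheme(), 200, -50, T = 100, seed = 7)
  occ3 <- simulate_markov_clamped(hh_k_scheme(), 200, -50, T = 100, seed = 8)
  expect_identical(occ1, occ2)
  expect_false(identical(occ1, occ3))
  p <- fix_params()
  tr1 <- simulate_neuron("markov", p, I = 5, T = 50, seed = 13)
  tr2 <- simulate_neuron("markov", p, I = 5, T = 50, seed = 13)
  expect_identical(tr1$V_mV, tr2$V_mV)
})

test_that("channel counts are conserved at every recorded sample", {
  occ <- simulate_markov_clamped(hh_na_scheme(), 500, -30, T = 200,
                                 record_dt = 0.5, seed = 5)
  sums <- rowSums(occ[, hh_na_scheme()$states])
  expect_true(all(sums == 500))
  p <- membrane_params(area = 10)  # 600 Na / 180 K channels
  tr <- simulate_neuron("markov", p, I = 8, T = 50, seed = 6,
                        record_states = TRUE)
  expect_true(all(rowSums(attr(tr, "occupancy_Na")) == p$N_Na))
  expect_true(all(rowSums(attr(tr, "occupancy_K")) == p$N_K))
})

test_that("clamped open-count variance is binomial, not Poisson, at high
           open probability", {
  V <- 20; N <- 1800                     # n_inf^4 ~ 0.66
  s <- hh_steady_state(V)
  p <- s$n^4
  occ <- simulate_markov_clamped(hh_k_scheme(), N, V, T = 4000,
                                 record_dt = 0.5, seed = 15)
  y <- occ$open_frac[occ$time_ms > 100]
  nb <- 15
  batch <- rep(seq_len(nb), each = floor(length(y) / nb))[seq_along(y)]
  bv <- tapply(y, batch, var)
  se <- sd(bv) / sqrt(nb)
  expect_lt(abs(mean(bv) - p * (1 - p) / N), 3 * se)     # binomial
  expect_gt(abs(mean(bv) - p / N), 3 * se)               # not Poisson
})

test_that("the hybrid Markov neuron fires spontaneously at zero applied
           current with 6,000 Na / 1,800 K channels", {
  p <- fix_params()
  n_spikes <- sum(vapply(1:3, function(k) {
    tr <- simulate_neuron("markov", p, I = 0, T = 1200, seed = 30 + k)
    length(detect_spikes(tr)$times)
  }, 0L))
  expect_gt(n_spikes, 0)
})

test_that("replaying with duplicated replicate seeds gives zero ensemble
           variance", {
  path <- rep(-55, 501)
  es <- replay_ensemble("markov", path, seed = NULL, dt = 0.01,
                        params = membrane_params(area = 10),
                        rep_seeds = c(42, 42))
  expect_true(all(es$var_open_Na == 0))
  expect_true(all(es$var_open_K == 0))
})

test_that("clamped replay variance settles on the binomial closed form", {
  V <- -45; N_Na <- 6000; N_K <- 1800
  es <- replay_ensemble("markov", rep(V, 801), reps = 600, seed = 17,
                        dt = 0.01, N_Na = N_Na, N_K = N_K)
  s <- hh_steady_state(V)
  pNa <- s$m^3 * s$h; pK <- s$n^4
  i <- es$time_ms > 2            # stationary init; tiny settling margin
  dev_na <- abs(es$var_open_Na - pNa * (1 - pNa) / N_Na)
  dev_k <- abs(es$var_open_K - pK * (1 - pK) / N_K)
  expect_gt(mean((dev_na < 3 * es$se_var_open_Na)[i]), 0.95)
  expect_gt(mean((dev_k < 3 * es$se_var_open_K)[i]), 0.95)
})
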