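# Closed-form moments, spike detection, ISI statistics, spike-time
# histograms.

test_that("binomial moments on a clamped path are constant at the
           stationary values and vanish as N grows", {
  V <- -35
  s <- hh_steady_state(V)
  mom <- binomial_moments_along_path(rep(V, 501), N_Na = 6000, N_K = 1800,
                                     dt = 0.01)
  pna <- s$m^3 * s$h; pk <- s$n^4
  expect_lt(max(abs(mom$mean_open_Na - pna)), 1e-10)
  expect_lt(max(abs(mom$var_open_Na - pna * (1 - pna) / 6000)), 1e-12)
  expect_lt(max(abs(mom$var_open_K - pk * (1 - pk) / 1800)), 1e-12)
  mom_inf <- binomial_moments_along_path(rep(V, 11), N_Na = Inf, N_K = Inf,
                                         dt = 0.01)
  expect_true(all(mom_inf$var_open_Na == 0))
  expect_true(all(mom_inf$var_open_K == 0))
  # variances never exceed the binomial ceiling 1/(4N)
  mom2 <- fig1_moments()
  expect_true(all(mom2$var_open_Na <= 1 / (4 * 6000) + 1e-15))
  expect_true(all(mom2$mean_open_Na >= 0 & mom2$mean_open_Na <= 1))
})

test_that("spike detection: empty trains, sawtooth periodicity, dead time,
           interpolation", {
  t <- seq(0, 100, by = 0.01)
  flat <- data.frame(time_ms = t, V_mV = rep(-70, length(t)))
  expect_length(detect_spikes(flat)$times, 0)
  # sawtooth crossing -20 mV once per 10 ms period
  saw <- data.frame(time_ms = t, V_mV = -80 + 70 * ((t %% 10) / 10))
  st <- detect_spikes(saw, threshold = -20, dead_time = 2)
  expect_equal(length(st$times), 10)
  expect_lt(max(abs(diff(st$times) - 10)), 1e-6)
  # crossings within the dead time are discarded
  chat <- data.frame(time_ms = c(0, 1, 1.2, 1.4, 1.6, 10),
                     V_mV = c(-70, 0, -30, 0, -70, -70))
  st2 <- detect_spikes(chat, dead_time = 2)
  expect_equal(length(st2$times), 1)
  # deterministic suprathreshold spiking settles onto a limit cycle whose
  # period is constant to within one time step
  tr <- simulate_deterministic(fix_params(), I = 12, T = 120)
  isis <- diff(detect_spikes(tr)$times)
  isis <- isis[-(1:2)]                    # discard the onset transient
  expect_lt(max(isis) - min(isis), 0.011)
})

test_that("ISI statistics: exact small cases and the exponential oracle", {
  expect_equal(isi_stats(rep(7.5, 100))$cv, 0)
  s <- isi_stats(rep(c(10, 20), 50))
  expect_equal(s$mean_isi, 15)
  expect_equal(s$cv, 5 / 15, tolerance = 1e-12)
  expect_error(isi_stats(c(1, 2, 3), spikes_per_batch = 50),
               "insufficient")
  # 1e4 exponential ISIs at rate 0.1/ms: mean 10, CV 1
  set.seed(73)
  isis <- rexp(1e4, 0.1)
  s2 <- isi_stats(isis, spikes_per_batch = 500)
  expect_lt(abs(s2$mean_isi - 10), 3 * s2$se_mean)
  expect_lt(abs(s2$cv - 1), 3 * s2$se_cv)
  # pooling spike trains equals pooling their ISIs
  tr1 <- structure(list(times = c(0, 10, 20)), class = "spike_train")
  tr2 <- structure(list(times = c(5, 25)), class = "spike_train")
  s3 <- isi_stats(list(tr1, tr2), spikes_per_batch = 3)
  expect_equal(s3$n_isi, 3L)
  expect_equal(s3$mean_isi, mean(c(10, 10, 20)))
})

test_that("spike-time histogram conserves counts and localizes a
           deterministic response", {
  mk <- function(t) structure(list(times = t), class = "spike_train")
  trains <- c(replicate(30, mk(12.34), simplify = FALSE),
              replicate(10, mk(numeric(0)), simplify = FALSE))
  h <- spike_time_histogram(trains, bin = 0.15, window = c(10, 15))
  expect_equal(sum(h$mean_count), 30)
  expect_equal(sum(h$mean_count > 0), 1)
  expect_equal(h$bin_left_ms[h$mean_count > 0], 12.25, tolerance = 1e-9)
  # empty input
  h0 <- spike_time_histogram(list(mk(numeric(0))), bin = 0.15,
                             window = c(0, 5))
  expect_true(all(h0$mean_count == 0))
  # deterministic step response: all mass in the bin of the first spike
  p <- fix_params()
  tr <- simulate_deterministic(p, I = function(t) if (t >= 5) 12 else 0,
                               T = 30)
  st <- detect_spikes(tr)
  h1 <- spike_time_histogram(replicate(20, st, simplify = FALSE),
                             bin = 0.15, window = c(5, 30))
  expect_equal(sum(h1$mean_count), 20)
  expect_equal(sum(h1$mean_count > 0), 1)
  expect_true(st$times[1] >= h1$bin_left_ms[h1$mean_count > 0] &&
              st$times[1] < h1$bin_left_ms[h1$mean_count > 0] + 0.15)
})

test_that("variance-tracking error on the replayed path ranks the
           system-size model best", {
  mom <- fig1_moments()
  w <- fig1_windows()
  es_ssa <- fig1_replay("ssa", 400)
  es_sub <- fig1_replay("subunit", 400)
  es_ou <- fig1_replay("ou", 400)
  ise <- function(es) {
    mean(((es$var_open_Na - mom$var_open_Na)^2 +
            (es$var_open_K - mom$var_open_K)^2)[w$analysis])
  }
  e_ssa <- ise(es_ssa); e_sub <- ise(es_sub); e_ou <- ise(es_ou)
  expect_lt(e_ssa * 2, e_ou)
  expect_lt(e_ssa * 2, e_sub)
})
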