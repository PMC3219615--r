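# Rate functions, kinetic schemes, generator structure, and the
# deterministic reference model.

test_that("rate functions are positive, finite, and handle the removable
           singularities analytically", {
  V <- seq(-120, 80, by = 0.5)
  r <- hh_rates(V)
  rates <- r[, c("alpha_m", "beta_m", "alpha_h", "beta_h", "alpha_n",
                 "beta_n")]
  expect_true(all(is.finite(as.matrix(rates))))
  expect_true(all(as.matrix(rates) > 0))
  # series-limit values at the singular voltages
  expect_equal(hh_rates(-40)$alpha_m, 1.0, tolerance = 1e-10)
  expect_equal(hh_rates(-55)$alpha_n, 0.1, tolerance = 1e-10)
  # continuity across the series branch
  expect_equal(hh_rates(-40 + 1e-8)$alpha_m, hh_rates(-40 - 1e-8)$alpha_m,
               tolerance = 1e-8)
  # steady states in (0,1), time constants positive
  expect_true(all(r$m_inf > 0 & r$m_inf < 1))
  expect_true(all(r$tau_m > 0 & r$tau_h > 0 & r$tau_n > 0))
  expect_error(hh_rates(NaN), "finite")
})

test_that("independent re-evaluation of the rate formulas reproduces the
           package values at rest", {
  # plain-R transcription of the decided formulas, kept separate from the
  # package implementation
  am <- function(V) 0.1 * (V + 40) / (1 - exp(-(V + 40) / 10))
  bm <- function(V) 4 * exp(-(V + 65) / 18)
  ah <- function(V) 0.07 * exp(-(V + 65) / 20)
  bh <- function(V) 1 / (1 + exp(-(V + 35) / 10))
  an <- function(V) 0.01 * (V + 55) / (1 - exp(-(V + 55) / 10))
  bn <- function(V) 0.125 * exp(-(V + 65) / 80)
  V <- -65
  s <- hh_steady_state(V)
  expect_equal(s$m, am(V) / (am(V) + bm(V)), tolerance = 1e-12)
  expect_equal(s$h, ah(V) / (ah(V) + bh(V)), tolerance = 1e-12)
  expect_equal(s$n, an(V) / (an(V) + bn(V)), tolerance = 1e-12)
  # x_inf is the fixed point of dx/dt = alpha (1-x) - beta x
  for (V in c(-80, -52.3, -30, 0)) {
    r <- hh_rates(V)
    expect_equal(r$alpha_m * (1 - r$m_inf) - r$beta_m * r$m_inf, 0,
                 tolerance = 1e-14)
  }
})

test_that("generator columns sum to zero and the K scheme carries the
           combinatorial rates", {
  set.seed(101)
  for (V in runif(50, -120, 80)) {
    Ana <- build_generator(hh_na_scheme(), V)
    Ak <- build_generator(hh_k_scheme(), V)
    expect_lt(max(abs(colSums(Ana))), 1e-12)
    expect_lt(max(abs(colSums(Ak))), 1e-12)
  }
  V <- -48.7
  r <- hh_rates(V)
  Ak <- build_generator(hh_k_scheme(), V)
  for (k in 0:3) {
    expect_equal(Ak[k + 2, k + 1], (4 - k) * r$alpha_n)
    expect_equal(Ak[k + 1, k + 2], (k + 1) * r$beta_n)
  }
})

test_that("stationary null vector of the generator equals the multinomial
           gating map at steady state", {
  for (V in c(-80, -65, -40, -10)) {
    s <- hh_steady_state(V)
    for (sch in list(hh_na_scheme(), hh_k_scheme())) {
      stat <- stationary_statevec(sch, V)
      expect_lt(max(abs(stat - gating_to_statevec(s, sch))), 1e-10)
    }
  }
})

test_that("gating_to_statevec lies on the simplex with the right conducting
           entries", {
  sna <- hh_na_scheme(); sk <- hh_k_scheme()
  # all subunits open -> indicator of the conducting state
  x <- gating_to_statevec(list(m = 1, h = 1), sna)
  expect_equal(unname(x), c(rep(0, 7), 1))
  set.seed(7)
  for (i in 1:25) {
    g <- list(m = runif(1), h = runif(1), n = runif(1))
    xna <- gating_to_statevec(g, sna)
    xk <- gating_to_statevec(g, sk)
    expect_equal(sum(xna), 1, tolerance = 1e-14)
    expect_equal(sum(xk), 1, tolerance = 1e-14)
    expect_equal(unname(xna["m3h1"]), g$m^3 * g$h)
    expect_equal(unname(xk["n4"]), g$n^4)
  }
  expect_error(gating_to_statevec(list(m = .5, h = .5),
                                  two_state_scheme(1, 1)),
               "factorization")
})

test_that("the multinomial gating map solves the linear channel-state ODE
           along a voltage path", {
  skip_if_not_installed("deSolve")
  sna <- hh_na_scheme()
  Vfun <- function(t) -65 + 30 * sin(t / 3)  # smooth voltage excursion
  s0 <- hh_steady_state(Vfun(0))
  # gating route: integrate (m,h) accurately, then map
  gode <- function(t, y, parms) {
    r <- hh_rates(Vfun(t))
    list(c(r$alpha_m * (1 - y[1]) - r$beta_m * y[1],
           r$alpha_h * (1 - y[2]) - r$beta_h * y[2]))
  }
  # direct route: the 8-state linear system dx/dt = A(V) x
  xode <- function(t, x, parms) {
    list(as.vector(build_generator(sna, Vfun(t)) %*% x))
  }
  times <- seq(0, 12, by = 0.5)
  g <- deSolve::ode(c(s0$m, s0$h), times, gode, NULL,
                    rtol = 1e-10, atol = 1e-12)
  x <- deSolve::ode(unname(gating_to_statevec(s0, sna)), times, xode, NULL,
                    rtol = 1e-10, atol = 1e-12)
  for (i in seq_along(times)) {
    mapped <- gating_to_statevec(list(m = g[i, 2], h = g[i, 3]), sna)
    expect_lt(max(abs(mapped - x[i, -1])), 1e-8)
  }
})

test_that("deterministic model holds the resting fixed point and relaxes
           a small perturbation without spiking", {
  p <- fix_params()
  rest <- resting_state(p)
  tr <- simulate_deterministic(p, I = 0, T = 100)
  expect_lt(max(abs(tr$V_mV - rest$V)), 1e-6)
  # +1 mV perturbation decays back to rest, no spike
  init <- rest; init$V <- rest$V + 1
  tr2 <- simulate_deterministic(p, I = 0, T = 100, init = init)
  expect_length(detect_spikes(tr2)$times, 0)
  expect_lt(abs(tr2$V_mV[nrow(tr2)] - rest$V), 0.1)
})

test_that("deterministic spiking converges at first order under time-step
           refinement", {
  p <- fix_params()
  period <- function(dt) {
    tr <- simulate_deterministic(p, I = 10, T = 100, dt = dt)
    mean(diff(detect_spikes(tr)$times))
  }
  p1 <- period(0.01); p2 <- period(0.005); p3 <- period(0.001)
  # refinement from dt = 0.01 to dt/10 moves the period by < 0.1 ms
  expect_lt(abs(p1 - p3), 0.1)
  # error vs the fine reference roughly halves when dt halves
  ratio <- abs(p1 - p3) / abs(p2 - p3)
  expect_gt(ratio, 1.4)
  expect_lt(ratio, 3.0)
  # divergence guard names the step
  expect_error(simulate_deterministic(p, I = 1e5, T = 5), "diverged")
})

test_that("membrane parameter validation and channel-count derivation", {
  p <- membrane_params()
  expect_equal(p$N_Na, 6000L)
  expect_equal(p$N_K, 1800L)
  expect_equal(membrane_params(area = 10)$N_Na, 600L)
  expect_error(membrane_params(C_m = 0), "C_m")
  expect_error(membrane_params(E_Na = -80), "E_Na")
  expect_error(membrane_params(g_K = -1), "conductances")
})

test_that("scheme constructors validate structure and serialize to JSON", {
  expect_error(kinetic_scheme(c("a", "b"), "a",
                              data.frame(from = "a", to = "a", rate = 1)),
               "self-transitions")
  expect_error(kinetic_scheme(c("a", "b", "c"), "a",
                              data.frame(from = "a", to = "b", rate = 1)),
               "connected")
  f <- tempfile(fileext = ".json")
  s <- hh_na_scheme()
  scheme_to_json(s, f)
  s2 <- scheme_from_json(f)
  expect_equal(s2$states, s$states)
  expect_equal(s2$open_states, s$open_states)
  expect_equal(build_generator(s2, -40), build_generator(s, -40))
  unlink(f)
})
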