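test_that("impedance factor has the correct passive limits", {
  m <- passive_model(area = 1000, g = 3, e = -65)   # R = 333.3 MOhm
  R <- 1000 / 3
  z <- quasi_active_impedance(m, -65, default_freq_grid(1e-5, 1e5))
  # very fast noise is fully filtered; very slow noise sees the DC resistance
  expect_lt(impedance_factor(m, -65, 1e-3, z = z), 0.05 * R)
  expect_equal(impedance_factor(m, -65, 1e5, z = z), R, tolerance = 0.02)
  # active membrane: z(tau) is non-monotone, reflecting the resonance
  mh <- hh_model(1000)
  zt <- impedance_factor(mh, -65, c(0.01, 1, 5, 1000))
  expect_gt(max(zt[2:3]), zt[1])
  expect_gt(max(zt[2:3]), zt[4])
})

test_that("OU generator is an exact AR(1) with the requested moments", {
  spec <- ou_spec(tau = 5, sigma_i = 10)
  x <- generate_ou(spec, dt = 0.5, t_max = 5e4, seed = 1)   # 1e4 tau
  n_eff <- length(x) / (2 * 5 / 0.5)          # effective sample count
  se_var <- 100 * sqrt(2 / n_eff)
  expect_lt(abs(var(x) - 100), 3 * se_var)
  # lag-tau autocorrelation ~ exp(-1)
  k <- 5 / 0.5
  r <- cor(x[-(1:k)], head(x, -k))
  expect_equal(r, exp(-1), tolerance = 0.1)
  # no discretization bias: coarse and fine dt give the same lag-tau decay
  xf <- generate_ou(spec, dt = 0.05, t_max = 5e4, seed = 2)
  rf <- cor(xf[-(1:100)], head(xf, -100))
  expect_equal(rf, exp(-1), tolerance = 0.1)
  # degenerate cases
  expect_identical(generate_ou(ou_spec(5, sigma_i = 0), 0.1, 10, 1),
                   numeric(100))
  expect_identical(generate_ou(spec, 0.5, 100, 7),
                   generate_ou(spec, 0.5, 100, 7))
  # sigma_v + z_tau parameterisation
  s2 <- ou_spec(tau = 1, sigma_v = 0.5, z_tau = 125)
  expect_equal(s2$sigma_i, 1000 * 0.5 / 125)
  expect_error(ou_spec(tau = 1, sigma_v = 0.5), "z_tau")
})

test_that("impedance calibration fixes the subthreshold voltage variance across tau", {
  m <- hh_model(1000)
  v0 <- resting_state(m)$v_rest
  z <- quasi_active_impedance(m, v0, default_freq_grid(1e-5, 1e5))
  target <- 0.3                               # mV, well below threshold
  for (tau in c(0.1, 1, 10, 100)) {
    zt <- impedance_factor(m, v0, tau, z = z)
    iext <- generate_ou(ou_spec(tau, sigma_i = 1000 * target / zt),
                        dt = 0.005, t_max = 8000, seed = 21)
    tr <- integrate_deterministic(m, i_ext = iext, dt = 0.005, t_max = 8000,
                                  v0 = v0, thin = 10L)
    expect_equal(sd(tr$v[tr$t > 500]), target, tolerance = 0.1,
                 info = paste("tau =", tau))
  }
})

test_that("channel surrogates carry the binomial variance and dominant correlation time", {
  m <- hh_model(1000)
  v0 <- -65
  sk <- channel_surrogate(m$populations$hh_k, m, v0)
  expect_equal(sk$tau_eff, ORACLE$tau_n / 4, tolerance = 1e-6)
  expect_equal(sk$variance,
               binomial_noise(m$populations$hh_k, 1000, v0)$sigma_i^2,
               tolerance = 1e-10)
  sna <- channel_surrogate(m$populations$hh_na, m, v0)
  # near-degenerate pair: tau_m tau_h/(tau_m + 3 tau_h), virtually tau_m/3
  expect_equal(sna$tau_eff,
               ORACLE$tau_m * ORACLE$tau_h / (ORACLE$tau_m + 3 * ORACLE$tau_h),
               tolerance = 1e-6)
  expect_equal(sna$tau_eff, ORACLE$tau_m / 3, tolerance = 0.01)
})

test_that("surrogate injections preserve the K-over-Na ordering and the Na underestimate", {
  a <- 50
  m <- hh_model(a)
  v0 <- resting_state(m)$v_rest
  rate_sur <- function(nm) {
    sur <- channel_surrogate(m$populations[[nm]], m, v0)
    iext <- generate_ou(sur$spec, dt = 0.005, t_max = 15200, seed = 33)
    tr <- integrate_deterministic(m, i_ext = iext, dt = 0.005,
                                  t_max = 15200, v0 = v0, thin = 1000L)
    sum(tr$spikes > 200) / 15
  }
  r_k <- rate_sur("hh_k")
  r_na <- rate_sur("hh_na")
  expect_gt(r_k, r_na)
  # K-only stochastic reference (Na deterministic)
  r_k_stoch <- spontaneous_rate(hh_model(a, na_mode = "deterministic"),
                                t_total = 15200, seed = 34)$rate
  r_na_stoch <- spontaneous_rate(hh_model(a, k_mode = "deterministic"),
                                 t_total = 15200, seed = 35)$rate
  # K surrogate tracks the stochastic K rate within an order of magnitude
  expect_gt(r_k, r_k_stoch / 10)
  expect_lt(r_k, r_k_stoch * 10)
  # the Gaussian Na surrogate underestimates Na-driven spiking
  expect_lt(r_na, r_na_stoch)
})

test_that("slow-noise limit reduces to the f-I curve average", {
  m <- hh_model(1000)
  fi <- fI_curve(m, seq(0, 200, by = 20), t_max = 1200, discard = 400)
  # concentrated far below rheobase: silent
  expect_equal(slow_noise_rate(m, mean_i = 20, sd_i = 5, fi = fi), 0,
               tolerance = 1e-6)
  # degenerate (zero-width) distribution returns the f-I value
  i0 <- 160
  f_at <- fi$rate[fi$current == i0]
  expect_equal(slow_noise_rate(m, mean_i = i0, sd_i = 0, fi = fi), f_at)
  # an uncovered distribution errors
  expect_error(slow_noise_rate(m, mean_i = 300, sd_i = 50, fi = fi),
               "cover")
})
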