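test_that("binomial noise model gives the expected moments and limits", {
  pk <- population("hh_k", 18)
  bn <- binomial_noise(pk, 1000, -65)
  expect_equal(bn$n_channels, 18000)
  expect_equal(bn$mean_open, 18000 * ORACLE$p_k, tolerance = 1e-6)
  # zero driving force kills the current noise
  expect_equal(binomial_noise(pk, 1000, -77)$sigma_i, 0)
  # p in {0, 1} gives zero variance
  s1 <- channel_scheme("always", subunit_spec("x", 1,
    rate_pair(function(v) rep(1, length(v)),
              function(v) rep(0, length(v)))), gamma = 20, e_rev = 0)
  expect_equal(binomial_noise(population(s1, 10), 100, -65)$var_open, 0)
})

test_that("Na/K current-noise sd ratio at rest matches direct evaluation", {
  m <- hh_model(1000)
  r <- binomial_noise(m$populations$hh_na, 1000, -65)$sigma_i /
       binomial_noise(m$populations$hh_k, 1000, -65)$sigma_i
  expect_equal(r, ORACLE$sigma_ratio_na_k, tolerance = 1e-6)
  # the ratio is area-independent
  r2 <- binomial_noise(m$populations$hh_na, 123, -65)$sigma_i /
        binomial_noise(m$populations$hh_k, 123, -65)$sigma_i
  expect_equal(r, r2, tolerance = 1e-12)
})

test_that("current spectra have the published multi-Lorentzian structure", {
  m <- hh_model(1000)
  sk <- current_psd(m$populations$hh_k, 1000, -65)
  expect_equal(nrow(sk$terms), 4)
  # corner frequencies are k/(2 pi tau_n), k = 1..4
  fc_ref <- (1:4) / (2 * pi * ORACLE$tau_n) * 1000
  expect_equal(sort(sk$terms$f_c), sort(fc_ref), tolerance = 1e-6)
  sna <- current_psd(m$populations$hh_na, 1000, -65)
  expect_equal(nrow(sna$terms), 7)
  # dominant corners: ~116 Hz for K+, ~2 kHz for Na+
  expect_equal(attr(sk, "dominant_f_c"), 4 / (2 * pi * ORACLE$tau_n) * 1000,
               tolerance = 1e-6)
  expect_equal(attr(sna, "dominant_f_c"), 2035, tolerance = 0.01)
  # spectra are non-increasing in f
  f <- default_freq_grid()
  expect_true(all(diff(lorentzian_eval(sk, f)) <= 0))
})

test_that("Lorentzian closed-form integral equals the binomial variance across schemes and voltages", {
  for (nm in c("hh_k", "hh_na", "ca1_na", "ca1_kdr", "ca1_ka")) {
    p <- population(nm, 10)
    for (v in c(-80, -65, -50, -40)) {
      s <- current_psd(p, 500, v)
      bn <- binomial_noise(p, 500, v)
      expect_equal(lorentzian_variance(s), bn$sigma_i^2,
                   tolerance = 1e-10, info = paste(nm, v))
    }
  }
})

test_that("quasi-active impedance matches the RC closed form for a passive membrane", {
  m <- passive_model(area = 1000, g = 3, e = -65)   # R = 333.3 MOhm, C = 10 pF
  f <- c(1, 10, 100, 1000, 10000)
  z <- quasi_active_impedance(m, -65, f)
  R <- 1000 / 3; C_nF <- 10e-3                       # MOhm, nF (so RC in ms)
  ref <- R / sqrt(1 + (2 * pi * f / 1000 * R * C_nF)^2)
  expect_equal(Mod(z$z), ref, tolerance = 1e-9)
})

test_that("active impedance shows a subthreshold resonance and capacitive rolloff", {
  z <- quasi_active_impedance(hh_model(1000), -65)
  mz <- Mod(z$z)
  pk <- which.max(mz)
  expect_gt(z$freqs[pk], 20)
  expect_lt(z$freqs[pk], 200)
  expect_gt(mz[pk], mz[1])              # resonant peak above the DC value
  # capacitive asymptote |Z| -> 1/(2 pi f C) at high f
  hi <- z$freqs >= 2e4
  ref <- 1000 / (2 * pi * z$freqs[hi] / 1000 * 10)   # MOhm, C = 10 pF
  expect_equal(Mod(z$z[hi]), ref, tolerance = 0.02)
})

test_that("sine-injection impedance agrees with the linearization within 2%", {
  m <- hh_model(1000)
  f <- c(10, 30, 100, 300, 1000, 5000)
  za <- quasi_active_impedance(m, -65, f)
  v0 <- resting_state(m)$v_rest
  ze <- empirical_impedance(m, v0, f, amplitude = 1)
  expect_equal(Mod(ze$z), Mod(za$z), tolerance = 0.02)
  # passive membrane: both equal the RC closed form
  mp <- passive_model(area = 1000, g = 3, e = -65)
  zp <- empirical_impedance(mp, -65, c(10, 100, 1000), amplitude = 1)
  R <- 1000 / 3
  ref <- R / sqrt(1 + (2 * pi * c(10, 100, 1000) / 1000 * R * 0.01)^2)
  expect_equal(Mod(zp$z), ref, tolerance = 0.01)
})

test_that("empirical impedance rejects amplitudes that drive a nonlinear response", {
  m <- hh_model(100)
  expect_error(empirical_impedance(m, resting_state(m)$v_rest, 100,
                                   amplitude = 5), "amplitude|2 mV")
})

test_that("generalized Ohm's law: unit impedance passes the current spectrum through", {
  s <- current_psd(population("hh_k", 18), 1000, -65)
  f <- default_freq_grid()
  z1 <- impedance_spectrum(f, rep(complex(real = 1), length(f)))  # 1 MOhm
  sv <- voltage_psd(s, z1)
  # 1 MOhm converts pA to uV, i.e. 1e-6 mV^2 per pA^2
  expect_equal(sv$power, lorentzian_eval(s, f) * 1e-6, tolerance = 1e-12)
  # grid mismatch is an error
  s2 <- list(freqs = f[-1], power = lorentzian_eval(s, f[-1]))
  expect_error(voltage_psd(s2, z1), "grid")
})

test_that("voltage variance integration matches the single-Lorentzian closed form", {
  a <- 2.5; fc <- 50
  s <- lorentzian_sum(a, fc)
  f <- default_freq_grid()
  zc <- impedance_spectrum(f, rep(complex(real = 200), length(f)))  # 200 MOhm
  v <- voltage_variance(voltage_psd(s, zc))
  expect_equal(v, a * fc * pi / 2 * 0.2^2, tolerance = 1e-3)
  # a non-decaying spectrum is rejected
  flat <- structure(list(freqs = f, power = rep(1, length(f))),
                    class = "cn_psd")
  expect_error(voltage_variance(flat), "not decayed")
})

test_that("membrane filtering attenuates fast Na+ noise more than slow K+ noise", {
  m <- hh_model(1000)
  z <- quasi_active_impedance(m, -65)
  r_na <- filter_ratio(m$populations$hh_na, m, -65, z = z)
  r_k <- filter_ratio(m$populations$hh_k, m, -65, z = z)
  expect_gt(r_k, r_na)
  # r is monotone non-increasing in the source corner frequency through a
  # passive (non-resonant) membrane
  mp <- passive_model()
  zp <- quasi_active_impedance(mp, -65)
  rr <- vapply(c(10, 100, 1000, 10000), function(fc) {
    s <- lorentzian_sum(1 / fc, fc)     # unit-variance-ish single Lorentzian
    1000 * sqrt(voltage_variance(voltage_psd(s, zp))) /
      sqrt(lorentzian_variance(s))
  }, numeric(1))
  expect_true(all(diff(rr) < 0))
})

test_that("noise report decomposes the five factors consistently", {
  m <- hh_model(1000)
  nr <- noise_report(m, -65)
  expect_equal(nr$population, c("hh_na", "hh_k"))
  expect_equal(nr$driving_force_mv, c(-115, 12))
  expect_equal(nr$gamma_ps, c(20, 20))
  expect_equal(sum(nr$var_share), 1)
  bn <- binomial_noise(m$populations$hh_na, 1000, -65)
  expect_equal(nr$sigma_i_pa[1], bn$sigma_i, tolerance = 1e-10)
  expect_equal(nr$r_mohm, 1000 * nr$sigma_v_mv / nr$sigma_i_pa,
               tolerance = 1e-12)
})

test_that("theory predicts the free-running voltage variance at large areas but not below", {
  m1 <- hh_model(1000)
  th1 <- sum(noise_report(m1, resting_state(m1)$v_rest)$var_v_mv2)
  tr1 <- simulate_stochastic(m1, t_max = 3000, seed = 10, thin = 4L)
  ratio1 <- var(tr1$v[tr1$t > 300]) / th1
  expect_equal(ratio1, 1, tolerance = 0.3)
  # at small areas spontaneous spikes inflate the measured variance far
  # beyond the subthreshold theory
  m2 <- hh_model(100)
  th2 <- sum(noise_report(m2, resting_state(m2)$v_rest)$var_v_mv2)
  tr2 <- simulate_stochastic(m2, t_max = 3000, seed = 10, thin = 4L)
  ratio2 <- var(tr2$v[tr2$t > 300]) / th2
  expect_gt(ratio2, ratio1 * 2)
})
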