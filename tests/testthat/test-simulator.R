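test_that("resting state solves the current balance", {
  # standard squid-axon configuration rests at about -65 mV
  rs <- resting_state(hh_model(1000))
  expect_equal(rs$v_rest, -65, tolerance = 0.01)  # within ~0.5 mV
  expect_named(rs$gating, c("hh_na", "hh_k"))
  # leak-only membrane rests exactly at the leak reversal
  expect_equal(resting_state(passive_model(e = -62))$v_rest, -62,
               tolerance = 1e-6)
  # CA1 configuration: leak densities are solved to rest at -65 mV
  expect_equal(resting_state(ca1_model(1000))$v_rest, -65, tolerance = 1e-6)
  # no root in the search window errors
  expect_error(resting_state(passive_model(e = -30)), "no resting state")
})

test_that("deterministic integration is stable at rest and spikes under step current", {
  m <- hh_model(1000)
  tr <- integrate_deterministic(m, t_max = 100)
  expect_lt(max(abs(tr$v - resting_state(m)$v_rest)), 0.01)
  expect_length(tr$spikes, 0)
  # suprathreshold DC step drives repetitive spiking
  tr2 <- integrate_deterministic(m, i_ext = 100, t_max = 500, thin = 10L)
  expect_gt(length(tr2$spikes), 5)
  # interspike intervals are regular once settled (tonic type-II firing)
  isi <- diff(tr2$spikes)
  isi <- tail(isi, 5)
  expect_lt(max(isi) - min(isi), 0.1 * mean(isi))
})

test_that("passive membrane relaxes exponentially with tau = C/g", {
  m <- passive_model(area = 1000, g = 3, e = -65)  # R = 333 MOhm, C = 10 pF
  tr <- integrate_deterministic(m, t_max = 20, v0 = -55)
  tau_ms <- (1000 * 0.01) / (3 * 1000 / 1000)      # C_pF / g_nS
  expect_equal(tr$v, -65 + 10 * exp(-tr$t / tau_ms), tolerance = 1e-3)
})

test_that("charge bookkeeping holds along a deterministic trajectory", {
  m <- hh_model(1000)
  tr <- integrate_deterministic(m, i_ext = 80, t_max = 30, dt = 0.001)
  C <- 10                                 # pF at 1000 um^2, 1 uF/cm^2
  g_l <- 3; e_l <- -55                    # nS, mV
  dv <- diff(tr$v) / tr$dt
  i_leak <- g_l * (tr$v - e_l)
  i_net <- -(rowSums(tr$currents) + i_leak) + tr$injected
  # compare C dV/dt with the net current midway between samples
  mid <- (i_net[-1] + i_net[-length(i_net)]) / 2
  expect_lt(max(abs(C * dv - mid)) / max(abs(mid)), 0.02)
})

test_that("identical seeds give bit-identical stochastic runs", {
  m <- hh_model(100)
  a <- simulate_stochastic(m, t_max = 200, seed = 4, thin = 5L)
  b <- simulate_stochastic(m, t_max = 200, seed = 4, thin = 5L)
  expect_identical(a$v, b$v)
  expect_identical(a$currents, b$currents)
  expect_identical(a$spikes, b$spikes)
  c <- simulate_stochastic(m, t_max = 200, seed = 5, thin = 5L)
  expect_false(identical(a$v, c$v))
})

test_that("stochastic trajectories converge to the deterministic limit with area", {
  rms <- vapply(c(1e3, 1e4, 1e5), function(a) {
    m <- hh_model(a)
    v0 <- resting_state(m)$v_rest
    st <- simulate_stochastic(m, t_max = 200, seed = 7, v0 = v0, thin = 10L)
    de <- integrate_deterministic(m, t_max = 200, v0 = v0, thin = 10L)
    sqrt(mean((st$v - de$v)^2))
  }, numeric(1))
  expect_true(all(diff(rms) < 0))
  expect_lt(rms[3], 0.1)
})

test_that("voltage clamp reproduces binomial open-count statistics", {
  m <- hh_model(1000)
  vc <- voltage_clamp(m, -65, t_max = 4000, seed = 8, thin = 10L)
  expect_true(all(vc$v == -65))
  bn <- binomial_noise(m$populations$hh_k, 1000, -65)
  counts <- vc$gating[, "hh_k"]
  # mean open count ~ N p (~183); allow 4 s.e. of the autocorrelated series
  expect_equal(mean(counts), bn$mean_open, tolerance = 0.05)
  expect_equal(var(counts), bn$var_open, tolerance = 0.2)
  # chi-squared of decorrelated samples against the binomial law
  thin_ms <- 30                                  # >> 4 tau_n
  sub <- counts[seq(1, length(counts), by = thin_ms / vc$dt)]
  lo <- qbinom(0.005, bn$n_channels, bn$p_open)
  hi <- qbinom(0.995, bn$n_channels, bn$p_open)
  br <- c(-Inf, seq(lo, hi, length.out = 8), Inf)
  obs <- table(cut(sub, br))
  pr <- diff(pbinom(c(-Inf, seq(lo, hi, length.out = 8), Inf),
                    bn$n_channels, bn$p_open))
  expect_gt(suppressWarnings(
    chisq.test(as.numeric(obs), p = pr / sum(pr))$p.value), 0.01)
})

test_that("clamping at a population's reversal removes its current", {
  m <- hh_model(500)
  vc <- voltage_clamp(m, -77, t_max = 100, seed = 2)
  expect_true(all(vc$currents[, "hh_k"] == 0))
  expect_false(all(vc$currents[, "hh_na"] == 0))
})

test_that("fully deterministic model with no input never spikes; f-I starts at zero", {
  m <- hh_model(1000, na_mode = "deterministic", k_mode = "deterministic")
  r <- spontaneous_rate(m, t_total = 1000, seed = 1)
  expect_identical(r$rate, 0)
  fi <- fI_curve(hh_model(1000), currents = 0, t_max = 600, discard = 200)
  expect_equal(fi$rate, 0)
})

test_that("spike counts are insensitive to threshold within the spike upswing range", {
  m <- hh_model(1000)
  tr <- integrate_deterministic(m, i_ext = 100, t_max = 300, thin = 10L)
  n <- vapply(c(-30, -20, 0), function(th)
    length(detect_spikes(tr, threshold = th)$times), numeric(1))
  expect_true(all(n == n[1]))
  expect_gt(n[1], 0)
})

test_that("timestep validity check rejects oversized dt", {
  expect_error(simulate_stochastic(hh_model(100), t_max = 10, seed = 1,
                                   dt = 0.2), "dt")
})
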