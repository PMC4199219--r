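# Colored (Ornstein-Uhlenbeck) current-noise surrogates: impedance-calibrated
# amplitude so the subthreshold voltage variance is fixed across correlation
# times, injection into deterministic models, and Gaussian surrogates for
# specific channel populations.

#' Impedance factor z(tau)
#'
#' Converts a target voltage-noise s.d. into the OU current s.d. that
#' produces it through the membrane filter:
#' `z^2(tau) = integral S_u(f) |Z(f)|^2 df` with the unit-variance OU
#' spectrum `S_u(f) = 4 tau_s / (1 + (2 pi f tau_s)^2)` (so that
#' `integral S_u df = 1`).  A current with s.d. `sigma_I = sigma_V / z(tau)`
#' (unit care: `sigma_I [pA] = 1000 * sigma_V [mV] / z [MOhm]`) then yields
#' subthreshold voltage s.d. `sigma_V`.
#'
#' @inheritParams quasi_active_impedance
#' @param tau noise correlation time (ms), vectorised.
#' @param z optional precomputed [impedance_spectrum()]; must extend to low
#'   enough frequency for the largest `tau` (the default grid spans
#'   1e-5 to 1e5 Hz).
#' @return `z(tau)` in MOhm.
#' @export
impedance_factor <- function(model, v0, tau, z = NULL) {
  if (is.null(z))
    z <- quasi_active_impedance(model, v0,
                                default_freq_grid(fmin = 1e-5, fmax = 1e5))
  f <- z$freqs
  zg <- (Mod(z$z) / 1000)^2          # GOhm^2, so pA -> mV
  vapply(tau, function(tt) {
    tau_s <- tt / 1000
    su <- 4 * tau_s / (1 + (2 * pi * f * tau_s)^2)
    g <- su * zg
    core <- sum(diff(f) * (head(g, -1) + tail(g, -1)) / 2)
    headpart <- g[1] * f[1]          # flat extension below the grid
    sqrt(core + headpart) * 1000     # GOhm -> MOhm
  }, numeric(1))
}

#' OU noise specification
#'
#' Exponentially correlated Gaussian current noise with correlation time
#' `tau` (ms).  The amplitude is given either directly as a current s.d.
#' `sigma_i` (pA) or as a target voltage s.d. `sigma_v` (mV) together with
#' the impedance factor `z_tau` (MOhm), in which case
#' `sigma_i = 1000 * sigma_v / z_tau`.
#'
#' @param tau correlation time (ms), > 0.
#' @param sigma_i current s.d. (pA).
#' @param sigma_v target voltage s.d. (mV).
#' @param z_tau impedance factor (MOhm), see [impedance_factor()].
#' @return An object of class `cn_ou_spec`.
#' @export
ou_spec <- function(tau, sigma_i = NULL, sigma_v = NULL, z_tau = NULL) {
  stopifnot(tau > 0)
  if (is.null(sigma_i)) {
    if (is.null(sigma_v) || is.null(z_tau))
      stop("give either sigma_i, or sigma_v together with z_tau")
    sigma_i <- 1000 * sigma_v / z_tau
  }
  stopifnot(sigma_i >= 0)
  structure(list(tau = tau, sigma_i = sigma_i, sigma_v = sigma_v,
                 z_tau = z_tau), class = "cn_ou_spec")
}

#' Generate an OU current series
#'
#' Stationary Gaussian series with autocovariance `sigma^2 exp(-|t|/tau)`,
#' generated by the exact discrete-time AR(1) recursion with decay
#' `exp(-dt/tau)` and innovation s.d. `sigma * sqrt(1 - exp(-2 dt/tau))`,
#' so the lag-k autocorrelation is exactly `exp(-k dt / tau)` at any `dt`.
#'
#' @param spec an [ou_spec()].
#' @param dt sample interval (ms).
#' @param t_max duration (ms).
#' @param seed integer seed.
#' @return Numeric vector of `round(t_max/dt)` current samples (pA).
#' @export
generate_ou <- function(spec, dt, t_max, seed) {
  stopifnot(inherits(spec, "cn_ou_spec"), dt > 0)
  n <- round(t_max / dt)
  if (spec$sigma_i == 0) return(numeric(n))
  rho <- exp(-dt / spec$tau)
  innov_sd <- spec$sigma_i * sqrt(1 - rho^2)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  x1 <- rnorm(1, 0, spec$sigma_i)
  eps <- rnorm(n - 1, 0, innov_sd)
  c(x1, as.numeric(stats::filter(eps, rho, method = "recursive",
                                 init = x1)))
}

#' Spontaneous rate under injected OU noise vs correlation time
#'
#' Injects OU current noise into the deterministic model across a range of
#' correlation times.  In calibrated mode the current s.d. is set to
#' `sigma_I = 1000 sigma_V / z(tau)` so the subthreshold voltage variance is
#' the same at every `tau`; in uncalibrated mode a fixed current s.d. is
#' used, which lets the induced voltage variance (and hence the rate) vary
#' strongly with `tau`.
#'
#' @param model a [membrane_model()]; integrated deterministically.
#' @param sigma_v target voltage s.d. (mV), used when `calibrate = TRUE`;
#'   the default 8 mV puts the calibrated rate at `tau = 1` ms in the tens
#'   of Hz for the standard squid-axon model at 1000 um^2.
#' @param taus noise correlation times (ms).
#' @param t_total simulated time per trial (ms), excluding `burn_in`.
#' @param seed master seed; each (tau, trial) uses an offset stream.
#' @param calibrate if `FALSE`, use `sigma_i_fixed` at every tau.
#' @param sigma_i_fixed current s.d. (pA) for the uncalibrated variant;
#'   defaults to the calibrated value at `tau = 1` ms.
#' @param dt integration timestep (ms); the OU update itself is exact at any
#'   dt, and dt is additionally capped at `tau/10` down to `dt_min`.
#' @param dt_min lower bound on the timestep (ms).
#' @param burn_in discarded initial period per trial (ms).
#' @param min_corr_times slow noise is sampled over independent trials until
#'   the accumulated duration covers at least this many correlation times
#'   (capped at `max_trials` trials), so rate estimates at very slow tau are
#'   not dominated by a handful of noise excursions.
#' @param max_trials upper bound on trials per tau.
#' @param threshold,refractory spike detection rule.
#' @return Data frame with columns `tau`, `z_mohm`, `sigma_i`, `rate` (Hz),
#'   `se`, `n_spikes`, `duration_s`.
#' @export
rate_vs_tau <- function(model, sigma_v = 8, taus, t_total = 10000, seed = 1,
                        calibrate = TRUE, sigma_i_fixed = NULL,
                        dt = 0.005, dt_min = 0.001, burn_in = 200,
                        min_corr_times = 50, max_trials = 50,
                        threshold = -20, refractory = 2) {
  v0 <- resting_state(model)$v_rest
  zimp <- quasi_active_impedance(model, v0,
                                 default_freq_grid(fmin = 1e-5, fmax = 1e5))
  zt <- impedance_factor(model, v0, taus, z = zimp)
  if (!calibrate && is.null(sigma_i_fixed))
    sigma_i_fixed <- 1000 * sigma_v / impedance_factor(model, v0, 1, z = zimp)
  res <- lapply(seq_along(taus), function(k) {
    tau <- taus[k]
    sig_i <- if (calibrate) 1000 * sigma_v / zt[k] else sigma_i_fixed
    dtk <- max(dt_min, min(dt, tau / 10))
    n_tr <- min(max_trials, max(1, ceiling(min_corr_times * tau / t_total)))
    n <- 0
    for (j in seq_len(n_tr)) {
      tk <- t_total + burn_in
      iext <- generate_ou(ou_spec(tau, sigma_i = sig_i), dtk, tk,
                          seed = seed + 977 * k + 500009 * j)
      tr <- integrate_deterministic(model, i_ext = iext, dt = dtk,
                                    t_max = tk, v0 = v0, thin = 1000L,
                                    threshold = threshold,
                                    refractory = refractory)
      n <- n + sum(tr$spikes > burn_in)
    }
    dur_s <- n_tr * t_total / 1000
    data.frame(tau = tau, z_mohm = zt[k], sigma_i = sig_i,
               rate = n / dur_s, se = sqrt(n) / dur_s, n_spikes = n,
               duration_s = dur_s)
  })
  do.call(rbind, res)
}

#' Gaussian surrogate for a channel population's noise
#'
#' Reduces a population's channel noise to a single OU process: variance from
#' the binomial steady-state model, `N i^2 p_o (1 - p_o)` (pA^2), and
#' effective correlation time `tau_eff = 1 / sum_j (mult_j / tau_j)` -- the
#' decay time of the all-subunit-flip covariance term, which dominates near
#' rest (`tau_n / 4` for the squid K+ scheme; for the Na+ scheme the
#' near-degenerate pair `tau_m tau_h / (tau_m + 3 tau_h) ~ tau_m / 3`).
#' The single-time-constant reduction is known to underestimate Na+-driven
#' spiking at small areas; see the package vignette.
#'
#' @inheritParams binomial_noise
#' @param model the [membrane_model()] supplying the area.
#' @param v0 operating voltage (mV).
#' @return List with `variance` (pA^2), `sigma_i` (pA), `tau_eff` (ms) and
#'   the matching [ou_spec()].
#' @export
channel_surrogate <- function(pop, model, v0) {
  bn <- binomial_noise(pop, model$area, v0)
  tau <- .scheme_tau(pop$scheme, v0)
  mult <- .scheme_mult(pop$scheme)
  tau_eff <- 1 / sum(mult / tau)
  list(variance = bn$sigma_i^2, sigma_i = bn$sigma_i, tau_eff = tau_eff,
       spec = ou_spec(tau_eff, sigma_i = bn$sigma_i))
}

#' Spontaneous rate in the slow-noise limit
#'
#' For noise much slower than all membrane and gating time constants the
#' dynamics decouple and the spontaneous rate is
#' `integral P(I) f(I) dI`, with `P` the stationary current distribution and
#' `f` the deterministic f-I curve.
#'
#' @param model a [membrane_model()].
#' @param mean_i,sd_i Gaussian current distribution parameters (pA).
#' @param fi optional precomputed data frame from [fI_curve()]; it must
#'   cover `mean_i +/- 4 sd_i`, else it is computed on that range.
#' @param n_grid number of f-I grid points when computing `fi`.
#' @param ... passed to [fI_curve()].
#' @return Rate (Hz).
#' @export
slow_noise_rate <- function(model, mean_i, sd_i, fi = NULL, n_grid = 25,
                            ...) {
  lo <- mean_i - 4 * sd_i; hi <- mean_i + 4 * sd_i
  if (is.null(fi)) {
    fi <- fI_curve(model, seq(lo, hi, length.out = n_grid), ...)
  } else if (min(fi$current) > lo || max(fi$current) < hi) {
    stop("provided f-I curve does not cover the 4-sigma current range")
  }
  f_fun <- approxfun(fi$current, fi$rate, rule = 2)
  if (sd_i == 0) return(f_fun(mean_i))
  integrate(function(I) stats::dnorm(I, mean_i, sd_i) * f_fun(I),
            lo, hi, subdivisions = 500L)$value
}
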