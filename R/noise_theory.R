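# Analytic noise layer: binomial steady-state channel noise, multi-Lorentzian
# current-noise power spectra from the kinetic scheme, quasi-active and
# sine-injection impedance, voltage-noise spectra and variances, and the
# per-population filtering ratio r = sigma_V / sigma_I.
#
# Spectral-density convention: one-sided, S(0) = 4 N i^2 p (1 - p) tau for a
# two-state channel, so that integral_0^inf S(f) df equals the variance.

#' Default logarithmic frequency grid
#'
#' Hertz grid used for impedance and voltage-noise calculations: logarithmic
#' from 0.1 Hz to 100 kHz at 60 points per decade.
#'
#' @param fmin,fmax grid limits (Hz).
#' @param per_decade grid density.
#' @return Numeric vector of frequencies (Hz).
#' @export
default_freq_grid <- function(fmin = 0.1, fmax = 1e5, per_decade = 60) {
  10 ^ seq(log10(fmin), log10(fmax), by = 1 / per_decade)
}

#' Binomial steady-state channel noise
#'
#' At a fixed voltage each channel is open independently with probability
#' `p_o`, so the open count over `N` channels is binomial: mean `N p_o`,
#' variance `N p_o (1 - p_o)`, and the current noise standard deviation is
#' `|gamma (V - E)| * sqrt(N p_o (1 - p_o))`.
#'
#' @param pop a [population()].
#' @param area membrane area (um^2).
#' @param v membrane voltage (mV).
#' @return List with `n_channels`, `p_open`, `mean_open`, `var_open`,
#'   `i_single` (pA, signed, outward positive) and `sigma_i` (pA).
#' @examples
#' binomial_noise(population("hh_k", 18), area = 1000, v = -65)
#' @export
binomial_noise <- function(pop, area, v) {
  stopifnot(inherits(pop, "cn_population"))
  n <- .n_channels(pop, area)
  p <- open_probability(pop$scheme, v)
  i1 <- pop$scheme$gamma / 1000 * (v - pop$scheme$e_rev)  # pA
  list(n_channels = n, p_open = p, mean_open = n * p,
       var_open = n * p * (1 - p), i_single = i1,
       sigma_i = abs(i1) * sqrt(n * p * (1 - p)))
}

# ---- Lorentzian sums -------------------------------------------------------

#' Lorentzian-sum power spectrum
#'
#' Container for an analytic spectrum `S(f) = sum_k a_k / (1 + (f/f_c_k)^2)`
#' with zero-frequency densities `a_k` (units^2/Hz) and corner frequencies
#' `f_c_k` (Hz).
#'
#' @param a zero-frequency spectral densities per term.
#' @param f_c corner frequencies (Hz), > 0.
#' @param units character label for the source units (e.g. `"pA"`).
#' @return An object of class `cn_lorentzians`.
#' @export
lorentzian_sum <- function(a, f_c, units = "pA") {
  stopifnot(length(a) == length(f_c), all(a >= 0), all(f_c > 0))
  structure(list(terms = data.frame(a = a, f_c = f_c), units = units),
            class = "cn_lorentzians")
}

#' @export
print.cn_lorentzians <- function(x, ...) {
  cat(sprintf("<Lorentzian sum> %d term(s), total variance %.4g %s^2\n",
              nrow(x$terms), lorentzian_variance(x), x$units))
  print(x$terms, ...)
  invisible(x)
}

#' Evaluate a Lorentzian sum on a frequency grid
#'
#' @param ls a [lorentzian_sum()].
#' @param freqs frequencies (Hz).
#' @return Spectral density at `freqs`.
#' @export
lorentzian_eval <- function(ls, freqs) {
  stopifnot(inherits(ls, "cn_lorentzians"))
  out <- numeric(length(freqs))
  for (k in seq_len(nrow(ls$terms)))
    out <- out + ls$terms$a[k] / (1 + (freqs / ls$terms$f_c[k])^2)
  out
}

#' Closed-form integral of a Lorentzian sum over f >= 0
#'
#' Each term integrates to `a_k * f_c_k * pi / 2`; the total equals the
#' process variance under the one-sided convention.
#'
#' @inheritParams lorentzian_eval
#' @return Variance (source units squared).
#' @export
lorentzian_variance <- function(ls) {
  stopifnot(inherits(ls, "cn_lorentzians"))
  sum(ls$terms$a * ls$terms$f_c) * pi / 2
}

#' Analytic current-noise power spectrum of a channel population
#'
#' Expands the autocovariance of the open-channel indicator of an
#' independent-subunit scheme into a sum of decaying exponentials via the
#' multinomial expansion of
#' `prod_j (x_j + (1 - x_j) exp(-t/tau_j))^mult_j - p_o`,
#' and converts each exponential into a one-sided Lorentzian scaled by
#' `4 N i^2`.  For the squid-axon K+ scheme (`n^4`) this yields exactly 4
#' terms with corner frequencies `k/(2 pi tau_n)`, k = 1..4; for the Na+
#' scheme (`m^3 h`) exactly 7 terms.
#'
#' @inheritParams binomial_noise
#' @return A [lorentzian_sum()] in pA^2/Hz, with attribute `"dominant_f_c"`:
#'   the corner of the all-subunit-flip term `sum_j mult_j / tau_j / (2 pi)`,
#'   which dominates the spectrum near rest where on-probabilities are low.
#' @examples
#' s <- current_psd(population("hh_k", 18), area = 1000, v = -65)
#' attr(s, "dominant_f_c")  # ~116 Hz
#' @export
current_psd <- function(pop, area, v) {
  stopifnot(inherits(pop, "cn_population"))
  sch <- pop$scheme
  mult <- .scheme_mult(sch)
  x <- .scheme_xinf(sch, v)
  tau <- .scheme_tau(sch, v)             # ms
  n <- .n_channels(pop, area)
  i1 <- sch$gamma / 1000 * (v - sch$e_rev)
  p_o <- prod(x ^ mult)

  ks <- as.matrix(expand.grid(lapply(mult, function(m) 0:m),
                              KEEP.OUT.ATTRS = FALSE))
  ks <- ks[rowSums(ks) > 0, , drop = FALSE]
  coef <- apply(ks, 1, function(k)
    p_o * prod(choose(mult, k) * x ^ (mult - k) * (1 - x) ^ k))
  tau_term_s <- 1 / (ks %*% (1 / tau)) / 1000        # decay time, s
  a <- 4 * n * i1^2 * coef * as.numeric(tau_term_s)  # pA^2/Hz
  f_c <- 1 / (2 * pi * as.numeric(tau_term_s))
  ls <- lorentzian_sum(a, f_c, units = "pA")
  attr(ls, "dominant_f_c") <- sum(mult / tau) / (2 * pi) * 1000
  ls
}

# ---- impedance -------------------------------------------------------------

#' Impedance spectrum container
#'
#' @param freqs frequency grid (Hz).
#' @param z complex impedance (MOhm) at each frequency.
#' @return An object of class `cn_impedance`.
#' @export
impedance_spectrum <- function(freqs, z) {
  stopifnot(length(freqs) == length(z), all(freqs >= 0))
  structure(list(freqs = freqs, z = z), class = "cn_impedance")
}

#' @export
print.cn_impedance <- function(x, ...) {
  pk <- which.max(Mod(x$z))
  cat(sprintf(
    "<impedance> %d frequencies [%.3g, %.3g] Hz; |Z| peak %.4g MOhm at %.4g Hz\n",
    length(x$freqs), min(x$freqs), max(x$freqs), Mod(x$z[pk]), x$freqs[pk]))
  invisible(x)
}

# d x_inf / dV by central difference
.dxinf_dv <- function(rates, v, eps = 1e-4) {
  (steady_state(rates, v + eps) - steady_state(rates, v - eps)) / (2 * eps)
}

#' Quasi-active (linearized) membrane impedance
#'
#' Linearizes the full voltage/gating dynamics around an operating point `v0`
#' and returns the small-signal transfer function `Z(f) = dV/dI`.  The
#' admittance collects the capacitive term, the leaks, each population's
#' open-channel conductance, and one first-order gating term per subunit
#' type: the gating perturbation responds as
#' `dx_j = (dx_j_inf/dV) dV / (1 + i 2 pi f tau_j)`, which for
#' delayed-rectifier-like subunits behaves as a phenomenological inductance
#' and produces a subthreshold resonance.
#'
#' @param model a [membrane_model()].
#' @param v0 operating voltage (mV); should be an equilibrium of the
#'   deterministic model.
#' @param freqs frequency grid (Hz).
#' @return An [impedance_spectrum()] in MOhm.
#' @examples
#' z <- quasi_active_impedance(hh_model(1000), -65)
#' @export
quasi_active_impedance <- function(model, v0, freqs = default_freq_grid()) {
  stopifnot(inherits(model, "cn_model"))
  w <- 2 * pi * freqs / 1000                  # rad/ms
  lk <- .leak_terms(model)
  Y <- 1i * w * .capacitance_pf(model) + lk$gl    # nS
  for (p in model$populations) {
    sch <- p$scheme
    mult <- .scheme_mult(sch)
    x <- .scheme_xinf(sch, v0)
    tau <- .scheme_tau(sch, v0)
    gbar <- sch$gamma / 1000 * p$density * model$area
    Y <- Y + gbar * prod(x ^ mult)
    for (j in seq_along(mult)) {
      dpo_dxj <- mult[j] * x[j] ^ (mult[j] - 1) *
        prod(x[-j] ^ mult[-j])
      dxj <- .dxinf_dv(sch$subunits[[j]]$rates, v0)
      Y <- Y + gbar * dpo_dxj * (v0 - sch$e_rev) * dxj / (1 + 1i * w * tau[j])
    }
  }
  if (any(Mod(Y) < 1e-9))
    stop("quasi-active admittance vanishes at some frequency (divergent ",
         "impedance); use empirical_impedance() instead")
  impedance_spectrum(freqs, 1000 / Y)          # nS -> MOhm
}

#' Empirical impedance by sine-wave current injection
#'
#' Measures `|Z(f)|` and phase of the deterministic model by injecting a
#' small sine current at each frequency and projecting the steady-state
#' voltage response onto the in-phase and quadrature components.  Mirrors the
#' experimental procedure and serves as an independent cross-check of
#' [quasi_active_impedance()] (and as the fallback when the linearization
#' diverges).
#'
#' @inheritParams quasi_active_impedance
#' @param amplitude sine amplitude (pA); the voltage response must stay
#'   within +/- 2 mV of `v0`.
#' @param n_cycles measured cycles per frequency (after an equal transient
#'   discard, at least one membrane time constant).
#' @param dt integration timestep (ms).
#' @return An [impedance_spectrum()] in MOhm.
#' @export
empirical_impedance <- function(model, v0, freqs, amplitude = 1,
                                n_cycles = 8, dt = 0.005) {
  stopifnot(inherits(model, "cn_model"))
  z <- complex(length(freqs))
  for (k in seq_along(freqs)) {
    f_khz <- freqs[k] / 1000                 # cycles per ms
    period <- 1 / f_khz
    settle <- max(50, 3 * period)
    t_max <- settle + n_cycles * period
    dtk <- min(dt, period / 64)
    tr <- integrate_deterministic(
      model, i_ext = function(t) amplitude * sin(2 * pi * f_khz * t),
      dt = dtk, t_max = t_max, v0 = v0)
    keep <- tr$t > settle
    tt <- tr$t[keep]
    dv <- tr$v[keep] - mean(tr$v[keep])
    if (max(abs(tr$v[keep] - v0)) > 2)
      stop("voltage response exceeds +/-2 mV around v0; ",
           "reduce the injection amplitude")
    s <- sin(2 * pi * f_khz * tt); cc <- cos(2 * pi * f_khz * tt)
    # quadrature projection of the response onto the injected sinusoid
    re <- 2 * mean(dv * s); im <- 2 * mean(dv * cc)
    fund <- sqrt(re^2 + im^2)
    # nonlinearity guard: second-harmonic content
    s2 <- sin(4 * pi * f_khz * tt); c2 <- cos(4 * pi * f_khz * tt)
    h2 <- sqrt((2 * mean(dv * s2))^2 + (2 * mean(dv * c2))^2)
    if (h2^2 > 0.05 * fund^2)
      stop("nonlinear response (2nd harmonic > 5% of fundamental); ",
           "reduce the injection amplitude")
    z[k] <- complex(real = re, imaginary = im) / amplitude * 1000  # MOhm
  }
  impedance_spectrum(freqs, z)
}

# ---- voltage noise ---------------------------------------------------------

#' Voltage-noise spectrum through the generalized Ohm's law
#'
#' `S_V(f) = S_I(f) |Z(f)|^2`: the current-noise spectrum of a source
#' filtered by the membrane impedance.
#'
#' @param s_i a [lorentzian_sum()] current spectrum (pA^2/Hz) or a list with
#'   elements `freqs`/`power` on the impedance grid.
#' @param z an [impedance_spectrum()] (MOhm).
#' @return List of class `cn_psd` with `freqs` (Hz) and `power` (mV^2/Hz).
#' @export
voltage_psd <- function(s_i, z) {
  stopifnot(inherits(z, "cn_impedance"))
  if (inherits(s_i, "cn_lorentzians")) {
    si <- lorentzian_eval(s_i, z$freqs)
  } else {
    if (!isTRUE(all.equal(s_i$freqs, z$freqs)))
      stop("frequency grids of S_I and Z differ")
    si <- s_i$power
  }
  structure(list(freqs = z$freqs, power = si * (Mod(z$z) / 1000)^2),
            class = "cn_psd")
}

#' Integrate a sampled voltage-noise spectrum
#'
#' Trapezoidal integral over the stored grid plus analytic corrections: a
#' flat extension below the lowest frequency and a `1/f^2` tail above the
#' highest.  Errors if the spectrum has not decayed by the end of the grid
#' (last-decade contribution above 1%).
#'
#' @param s_v a `cn_psd` from [voltage_psd()].
#' @return Variance (mV^2).
#' @export
voltage_variance <- function(s_v) {
  f <- s_v$freqs; p <- s_v$power
  core <- sum(diff(f) * (head(p, -1) + tail(p, -1)) / 2)
  headpart <- p[1] * f[1]
  tailpart <- p[length(p)] * f[length(f)]   # integral of p_end*(f_end/f)^2
  last_decade <- f >= max(f) / 10
  ld <- sum(diff(f[last_decade]) *
            (head(p[last_decade], -1) + tail(p[last_decade], -1)) / 2)
  tot <- core + headpart + tailpart
  if (ld + tailpart > 0.01 * tot)
    stop("spectrum has not decayed at the end of the frequency grid; ",
         "extend the grid")
  tot
}

#' Membrane filtering ratio of a channel population
#'
#' The ratio `r = sigma_V / sigma_I` (in MOhm) between the voltage-noise and
#' current-noise standard deviations of one population, obtained by filtering
#' its analytic current spectrum through the membrane impedance.  Slowly
#' gating populations are filtered less by the capacitive membrane and have
#' larger `r`.
#'
#' @inheritParams binomial_noise
#' @param model the full [membrane_model()] providing the impedance.
#' @param v0 operating voltage (mV).
#' @param z optional precomputed [impedance_spectrum()].
#' @return `r` in MOhm.
#' @examples
#' \donttest{
#' m <- hh_model(1000)
#' filter_ratio(m$populations$hh_na, m, -65)  # ~44.5 MOhm
#' }
#' @export
filter_ratio <- function(pop, model, v0, z = NULL) {
  if (is.null(z)) z <- quasi_active_impedance(model, v0)
  s_i <- current_psd(pop, model$area, v0)
  sigma_v <- sqrt(voltage_variance(voltage_psd(s_i, z)))   # mV
  sigma_i <- sqrt(lorentzian_variance(s_i))                # pA
  1000 * sigma_v / sigma_i                                 # MOhm
}

#' Per-population noise decomposition report
#'
#' Tabulates, for every population of a model at a fixed voltage, the factors
#' that determine its contribution to membrane noise: open probability,
#' channel count, driving force, single-channel conductance, current-noise
#' s.d., dominant spectral corner frequency, predicted voltage-noise s.d.,
#' filtering ratio `r`, and share of the total voltage-noise variance.
#'
#' @inheritParams quasi_active_impedance
#' @return A data frame, one row per population.
#' @examples
#' \donttest{
#' noise_report(hh_model(1000), -65)
#' }
#' @export
noise_report <- function(model, v0, freqs = default_freq_grid()) {
  z <- quasi_active_impedance(model, v0, freqs)
  rows <- lapply(names(model$populations), function(nm) {
    p <- model$populations[[nm]]
    bn <- binomial_noise(p, model$area, v0)
    s_i <- current_psd(p, model$area, v0)
    var_v <- voltage_variance(voltage_psd(s_i, z))
    data.frame(population = nm,
               p_open = bn$p_open,
               n_channels = bn$n_channels,
               driving_force_mv = v0 - p$scheme$e_rev,
               gamma_ps = p$scheme$gamma,
               sigma_i_pa = bn$sigma_i,
               dominant_f_c_hz = attr(s_i, "dominant_f_c"),
               sigma_v_mv = sqrt(var_v),
               r_mohm = 1000 * sqrt(var_v) / bn$sigma_i,
               var_v_mv2 = var_v)
  })
  out <- do.call(rbind, rows)
  out$var_share <- out$var_v_mv2 / sum(out$var_v_mv2)
  out
}
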