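# Single-compartment membrane simulation: deterministic rate equations or
# discrete stochastic Markov gating per channel population.

# voltage grid for the tabulated rate functions handed to the compiled core
.VGRID_MIN <- -120
.VGRID_MAX <- 60
.VGRID_STEP <- 0.02
# range of physiologically visited voltages used for the timestep validity
# check (spike overshoot stays below ~+55 mV, undershoot above ~-80 mV)
.DT_CHECK_RANGE <- c(-80, 55)

#' Channel population
#'
#' A population of identical channels placed on the membrane at a fixed
#' density, simulated either as discrete stochastic Markov channels or in the
#' deterministic continuum (rate-equation) limit.
#'
#' @param scheme a [channel_scheme()] or a built-in scheme name (see
#'   [get_scheme()]).
#' @param density channels per um^2 (>= 0).
#' @param mode `"stochastic"` or `"deterministic"`.
#' @return An object of class `cn_population`.
#' @export
population <- function(scheme, density,
                       mode = c("stochastic", "deterministic")) {
  if (is.character(scheme)) scheme <- get_scheme(scheme)
  stopifnot(inherits(scheme, "cn_scheme"), density >= 0)
  mode <- match.arg(mode)
  structure(list(scheme = scheme, density = density, mode = mode),
            class = "cn_population")
}

#' Single-compartment membrane model
#'
#' @param area membrane area (um^2), > 0.
#' @param populations list of [population()] objects (possibly empty for a
#'   passive membrane).
#' @param leaks data frame with columns `g` (conductance density, pS/um^2)
#'   and `e` (reversal potential, mV); leak channels are always deterministic.
#' @param c_m specific membrane capacitance (uF/cm^2).
#' @return An object of class `cn_model`.
#' @seealso [hh_model()] for the standard squid-axon configuration.
#' @export
membrane_model <- function(area, populations = list(),
                           leaks = data.frame(g = 3, e = -55), c_m = 1) {
  if (inherits(populations, "cn_population"))
    populations <- list(populations)
  stopifnot(area > 0, c_m > 0,
            all(vapply(populations, inherits, TRUE, "cn_population")),
            is.data.frame(leaks), all(c("g", "e") %in% names(leaks)),
            all(leaks$g >= 0))
  names(populations) <- vapply(populations, function(p) p$scheme$name, "")
  structure(list(area = area, c_m = c_m, populations = populations,
                 leaks = leaks), class = "cn_model")
}

#' Standard squid-axon membrane model
#'
#' The classic squid-axon single-compartment configuration: Na+ channels
#' (`m^3 h`, 60 /um^2, E = +50 mV), delayed-rectifier K+ channels (`n^4`,
#' 18 /um^2, E = -77 mV), both 20 pS, a 3 pS/um^2 leak reversing at -55 mV,
#' and 1 uF/cm^2 capacitance, which rests at approximately -65 mV.
#'
#' @param area membrane area (um^2).
#' @param na_mode,k_mode gating mode per population, `"stochastic"` or
#'   `"deterministic"`.
#' @return A `cn_model`.
#' @examples
#' m <- hh_model(100)
#' resting_state(m)$v_rest
#' @export
hh_model <- function(area, na_mode = "stochastic", k_mode = "stochastic") {
  membrane_model(
    area = area,
    populations = list(population("hh_na", 60, na_mode),
                       population("hh_k", 18, k_mode)),
    leaks = data.frame(g = 3, e = -55), c_m = 1)
}

#' CA1 pyramidal-cell membrane model (approximate built-in kinetics)
#'
#' Single-compartment model with Na+ (20 /um^2), delayed-rectifier K+
#' (20 /um^2) and A-type K+ (24 /um^2) channels at 20 pS each, plus two
#' deterministic voltage-independent leaks (one Na+-permeable, E = +55 mV,
#' one K+-permeable, E = -90 mV).  The two leak densities are solved from
#' two constraints: a total leak of 2.5 pS/um^2 and a resting voltage of
#' -65 mV given the active channels' steady-state currents there.  The
#' active kinetics are approximate transcriptions; see [get_scheme()].
#'
#' @inheritParams hh_model
#' @param modes named character vector of gating modes for `na`, `kdr`, `ka`.
#' @return A `cn_model`.
#' @export
ca1_model <- function(area, modes = c(na = "stochastic", kdr = "stochastic",
                                      ka = "stochastic")) {
  pops <- list(population("ca1_na", 20, modes[["na"]]),
               population("ca1_kdr", 20, modes[["kdr"]]),
               population("ca1_ka", 24, modes[["ka"]]))
  # active steady-state current density (pA/um^2) at the target rest
  v_rest <- -65; g_leak_tot <- 2.5; e_na_leak <- 55; e_k_leak <- -90
  i_active <- sum(vapply(pops, function(p)
    p$scheme$gamma / 1000 * p$density *
      open_probability(p$scheme, v_rest) * (v_rest - p$scheme$e_rev),
    numeric(1)))
  # g_na_leak (v - e_na) + g_k_leak (v - e_k) = -i_active ;
  # g_na_leak + g_k_leak = g_leak_tot   (conductances in nS/um^2)
  g_na_leak <- (-i_active - g_leak_tot / 1000 * (v_rest - e_k_leak)) /
    ((v_rest - e_na_leak) - (v_rest - e_k_leak))
  g_k_leak <- g_leak_tot / 1000 - g_na_leak
  if (g_na_leak < 0 || g_k_leak < 0)
    stop("leak-density solution is negative; active rest currents too large")
  membrane_model(
    area = area,
    populations = pops,
    leaks = data.frame(g = 1000 * c(g_na_leak, g_k_leak),
                       e = c(e_na_leak, e_k_leak)), c_m = 1)
}

# total leak conductance (nS) and conductance-weighted reversal sum (nS mV)
.leak_terms <- function(model) {
  g <- model$leaks$g * model$area / 1000     # pS -> nS
  list(gl = sum(g), glE = sum(g * model$leaks$e))
}

.capacitance_pf <- function(model) model$c_m * model$area * 0.01

.n_channels <- function(pop, area) round(pop$density * area)

# steady-state total ionic current (pA, outward positive) at voltage v
.steady_current <- function(model, v) {
  lk <- .leak_terms(model)
  I <- lk$gl * v - lk$glE
  for (p in model$populations) {
    gbar <- p$scheme$gamma / 1000 * p$density * model$area   # nS
    I <- I + gbar * open_probability(p$scheme, v) * (v - p$scheme$e_rev)
  }
  I
}

#' Resting state of a membrane model
#'
#' Solves the steady-state current-balance equation for the resting voltage
#' nearest the physiological range and returns all gating variables at their
#' steady-state values there.
#'
#' @param model a [membrane_model()].
#' @param interval search interval (mV) for the current-balance root.
#' @return List with `v_rest` (mV) and `gating`, a per-population list of
#'   steady-state subunit on-probabilities.
#' @export
resting_state <- function(model, interval = c(-90, -40)) {
  stopifnot(inherits(model, "cn_model"))
  f <- function(v) .steady_current(model, v)
  lo <- f(interval[1]); hi <- f(interval[2])
  if (is.na(lo) || is.na(hi) || lo * hi > 0)
    stop("no resting state found in [", interval[1], ", ", interval[2],
         "] mV")
  v_rest <- uniroot(f, interval, tol = 1e-10)$root
  gating <- lapply(model$populations, function(p)
    setNames(.scheme_xinf(p$scheme, v_rest),
             vapply(p$scheme$subunits, `[[`, "", "name")))
  list(v_rest = v_rest, gating = gating)
}

# ---- core plumbing ---------------------------------------------------------

.rate_tables <- function(scheme) {
  v <- seq(.VGRID_MIN, .VGRID_MAX, by = .VGRID_STEP)
  at <- vapply(scheme$subunits, function(s) s$rates$alpha(v),
               numeric(length(v)))
  bt <- vapply(scheme$subunits, function(s) s$rates$beta(v),
               numeric(length(v)))
  list(atab = as.matrix(at), btab = as.matrix(bt), vgrid = v)
}

.max_rate <- function(model, vrange = .DT_CHECK_RANGE) {
  v <- seq(vrange[1], vrange[2], by = 0.1)
  mx <- 0
  for (p in model$populations)
    for (s in p$scheme$subunits)
      mx <- max(mx, s$rates$alpha(v), s$rates$beta(v))
  mx
}

.check_dt <- function(model, dt, limit) {
  mr <- .max_rate(model)
  if (mr * dt > limit)
    stop(sprintf(paste0("dt = %g ms too large: max transition rate %.3g/ms ",
                        "over [%g, %g] mV gives rate*dt = %.3g > %g"),
                 dt, mr, .DT_CHECK_RANGE[1], .DT_CHECK_RANGE[2],
                 mr * dt, limit))
  invisible(TRUE)
}

.iext_series <- function(i_ext, dt, nsteps) {
  if (is.function(i_ext)) return(i_ext(dt * seq_len(nsteps)))
  if (length(i_ext) == 1) return(as.numeric(i_ext))
  as.numeric(i_ext)
}

.pop_core_spec <- function(pop, model, v0, force_mode = NULL) {
  sch <- pop$scheme
  mode <- if (is.null(force_mode)) pop$mode else force_mode
  tabs <- .rate_tables(sch)
  n <- .n_channels(pop, model$area)
  if (mode == "stochastic" && n < 1)
    stop("stochastic population '", sch$name, "' has no channels (N = ", n,
         "); increase area or density")
  list(name = sch$name,
       stochastic = (mode == "stochastic"),
       mult = .scheme_mult(sch),
       n_channels = n,
       gamma_ns = sch$gamma / 1000,
       gbar_ns = sch$gamma / 1000 * pop$density * model$area,
       e_rev = sch$e_rev,
       atab = tabs$atab, btab = tabs$btab,
       init_xinf = .scheme_xinf(sch, v0))
}

.run_core <- function(model, v0, clamp, i_ext, dt, t_max, seed,
                      thin = 1L, record = TRUE, threshold = -20,
                      refractory = 2, force_mode = NULL, rate_dt_limit = 0.05) {
  stopifnot(inherits(model, "cn_model"), dt > 0, t_max > 0)
  .check_dt(model, dt, rate_dt_limit)
  nsteps <- round(t_max / dt)
  specs <- lapply(model$populations, .pop_core_spec, model = model, v0 = v0,
                  force_mode = force_mode)
  lk <- .leak_terms(model)
  G <- length(seq(.VGRID_MIN, .VGRID_MAX, by = .VGRID_STEP))
  out <- .sim_core(unname(specs), .VGRID_MIN, .VGRID_STEP, G,
                   lk$gl, lk$glE, .capacitance_pf(model),
                   v0, clamp,
                   .iext_series(i_ext, dt, nsteps), dt, nsteps,
                   as.integer(thin), as.double(seed %||% 0),
                   threshold, refractory, record)
  out$pop_names <- names(model$populations)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.as_trace <- function(out, dt, thin, model, clamp = FALSE, v_hold = NULL) {
  pn <- out$pop_names
  colnames(out$i_pop) <- pn
  colnames(out$open) <- pn
  structure(list(
    dt = dt * thin,
    t = dt * thin * seq_len(length(out$v)),
    v = if (clamp) rep(v_hold, nrow(out$i_pop)) else out$v,
    currents = out$i_pop,
    injected = out$injected,
    gating = out$open,
    spikes = out$spikes,
    area = model$area), class = "cn_trace")
}

#' @export
print.cn_trace <- function(x, ...) {
  cat(sprintf(
    "<trace> %.6g ms at dt = %g ms; %d population(s); %d spike(s)\n",
    max(x$t), x$dt, ncol(x$currents), length(x$spikes)))
  invisible(x)
}

# ---- user-facing simulation entry points -----------------------------------

#' Deterministic (continuum-limit) integration
#'
#' Integrates the coupled membrane/gating ODE system with every population in
#' deterministic rate-equation mode.  Voltage advances by exponential Euler
#' with conductances frozen per step; gating variables advance by their exact
#' per-step exponential relaxation.
#'
#' @param model a [membrane_model()].
#' @param i_ext injected current: scalar (pA), function of time (ms), or
#'   per-step numeric vector.
#' @param dt timestep (ms).
#' @param t_max duration (ms).
#' @param v0 initial voltage (mV); defaults to the resting state.
#' @param thin record every `thin`-th step.
#' @param threshold,refractory spike-detection rule (mV upward crossing, ms
#'   dead time).
#' @return A `cn_trace` with voltage, per-population currents (pA, outward
#'   positive), open fractions, injected current and detected spike times.
#' @export
integrate_deterministic <- function(model, i_ext = 0, dt = 0.005, t_max,
                                    v0 = NULL, thin = 1L, threshold = -20,
                                    refractory = 2) {
  if (is.null(v0)) v0 <- resting_state(model)$v_rest
  out <- .run_core(model, v0, clamp = FALSE, i_ext = i_ext, dt = dt,
                   t_max = t_max, seed = 0, thin = thin, record = TRUE,
                   threshold = threshold, refractory = refractory,
                   force_mode = "deterministic", rate_dt_limit = 0.1)
  .as_trace(out, dt, thin, model)
}

#' Stochastic simulation with discrete Markov channels
#'
#' Advances each stochastic population's aggregated subunit on-count state by
#' multinomially distributed transition counts each timestep; populations in
#' deterministic mode follow the continuum rate equations.  The initial
#' channel states are drawn from the product-binomial stationary law at the
#' starting voltage.  Results are reproducible given `(seed, dt)`; each
#' population consumes an independent named RNG stream so changing one
#' population's mode does not perturb the others.
#'
#' @inheritParams integrate_deterministic
#' @param seed master integer seed (required).
#' @param record if `FALSE`, do not store series (spike times are still
#'   returned), which keeps long-rate estimation memory-free.
#' @return A `cn_trace`; in stochastic mode the `gating` columns hold open
#'   channel counts.
#' @examples
#' \donttest{
#' tr <- simulate_stochastic(hh_model(100), t_max = 1000, seed = 1)
#' length(tr$spikes)
#' }
#' @export
simulate_stochastic <- function(model, i_ext = 0, dt = 0.005, t_max, seed,
                                v0 = NULL, thin = 1L, record = TRUE,
                                threshold = -20, refractory = 2) {
  stopifnot(!missing(seed))
  if (is.null(v0)) v0 <- resting_state(model)$v_rest
  out <- .run_core(model, v0, clamp = FALSE, i_ext = i_ext, dt = dt,
                   t_max = t_max, seed = seed, thin = thin, record = record,
                   threshold = threshold, refractory = refractory)
  tr <- .as_trace(out, dt, thin, model)
  tr$seed <- seed
  tr
}

#' Stochastic gating under voltage clamp
#'
#' Simulates channel gating stochastically at a fixed holding voltage; the
#' per-population current is `gamma * (v_hold - e_rev)` times the open count.
#'
#' @inheritParams simulate_stochastic
#' @param v_hold holding potential (mV).
#' @return A `cn_trace` with constant voltage.
#' @export
voltage_clamp <- function(model, v_hold, dt = 0.005, t_max, seed,
                          thin = 1L) {
  stopifnot(!missing(seed))
  out <- .run_core(model, v_hold, clamp = TRUE, i_ext = 0, dt = dt,
                   t_max = t_max, seed = seed, thin = thin, record = TRUE)
  .as_trace(out, dt, thin, model, clamp = TRUE, v_hold = v_hold)
}

#' Spontaneous firing rate
#'
#' Estimates the spontaneous spike rate of a model with zero mean external
#' input.  A burn-in is discarded to remove initialisation transients; the
#' standard error treats spike counts as Poisson, and for zero observed
#' spikes a one-sided 95% upper bound (`3/duration`) is reported.
#'
#' @inheritParams simulate_stochastic
#' @param t_total total simulated time (ms), including burn-in.
#' @param burn_in discarded initial period (ms).
#' @return List with `rate` (Hz), `se` (Hz), `n_spikes`, `duration_s` and
#'   `upper95` (Hz, informative when `n_spikes == 0`).
#' @export
spontaneous_rate <- function(model, t_total, seed, dt = 0.005,
                             threshold = -20, refractory = 2,
                             burn_in = 200) {
  stopifnot(t_total > burn_in)
  out <- .run_core(model, resting_state(model)$v_rest, clamp = FALSE,
                   i_ext = 0, dt = dt, t_max = t_total, seed = seed,
                   record = FALSE, threshold = threshold,
                   refractory = refractory)
  sp <- out$spikes[out$spikes > burn_in]
  dur_s <- (t_total - burn_in) / 1000
  n <- length(sp)
  list(rate = n / dur_s, se = sqrt(n) / dur_s, n_spikes = n,
       duration_s = dur_s, upper95 = max(n, 3) / dur_s)
}

#' Deterministic f-I curve
#'
#' Steady-state firing rate of the deterministic model as a function of
#' injected DC current, measured after discarding an initial transient.
#'
#' @inheritParams integrate_deterministic
#' @param currents injected DC levels (pA).
#' @param t_max simulated time per level (ms).
#' @param discard transient discarded before counting spikes (ms).
#' @return Data frame with columns `current` (pA) and `rate` (Hz).
#' @export
fI_curve <- function(model, currents, t_max = 2000, discard = 500,
                     dt = 0.005, threshold = -20, refractory = 2) {
  rate <- vapply(currents, function(I) {
    tr <- integrate_deterministic(model, i_ext = I, dt = dt, t_max = t_max,
                                  threshold = threshold,
                                  refractory = refractory, thin = 1000L)
    sum(tr$spikes > discard) / ((t_max - discard) / 1000)
  }, numeric(1))
  data.frame(current = currents, rate = rate)
}

#' Spontaneous rate as a function of membrane area
#'
#' Runs [spontaneous_rate()] over a set of membrane areas for a model
#' factory, e.g. `function(a) hh_model(a)`.
#'
#' @param model_fn function of area returning a `cn_model`.
#' @param areas membrane areas (um^2).
#' @param t_total,seed,... passed to [spontaneous_rate()]; each area uses
#'   seed `seed + index - 1`.
#' @return Data frame with columns `area`, `rate`, `se`, `n_spikes`.
#' @export
rate_vs_area <- function(model_fn, areas, t_total, seed, ...) {
  res <- lapply(seq_along(areas), function(i) {
    r <- spontaneous_rate(model_fn(areas[i]), t_total = t_total,
                          seed = seed + i - 1, ...)
    data.frame(area = areas[i], rate = r$rate, se = r$se,
               n_spikes = r$n_spikes)
  })
  do.call(rbind, res)
}
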