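# Kinetic layer: voltage-dependent two-state subunits, channel schemes built
# as independent products of subunits, and their aggregated Markov expansion.
#
# Unit conventions: voltage mV, rates 1/ms, single-channel conductance pS,
# reversal potential mV.

# Threshold below which the (V - vh) argument of the linear/(1 - exp) rate
# form is treated as a removable singularity and replaced by its limit.
.SINGULARITY_EPS <- 1e-7

#' Rate-function constructors
#'
#' Voltage-gated subunit transition rates in conductance-based models take a
#' small number of canonical functional forms.  These constructors return
#' vectorised functions of voltage (mV) yielding rates in 1/ms:
#'
#' \describe{
#'   \item{`rate_linexp(a, vh, k)`}{`a * (V - vh) / (1 - exp(-(V - vh)/k))`.
#'     The removable singularity at `V = vh` is evaluated by its analytic
#'     limit `a * k`.}
#'   \item{`rate_expo(a, vh, k)`}{`a * exp(-(V - vh)/k)` (pure exponential;
#'     negative `k` gives a rising exponential).}
#'   \item{`rate_logistic(a, vh, k)`}{`a / (1 + exp(-(V - vh)/k))` (sigmoid).}
#' }
#'
#' @param a rate amplitude (1/ms, or 1/(ms mV) for `rate_linexp`).
#' @param vh half-point / offset voltage (mV).
#' @param k slope factor (mV).
#' @return A function of voltage, carrying its parameters in attributes so
#'   schemes can be serialised to config files.
#' @examples
#' alpha_m <- rate_linexp(0.1, -40, 10)
#' alpha_m(-40)  # removable singularity: limit 0.1 * 10 = 1
#' @name rate_forms
NULL

.make_rate <- function(f, form, pars) {
  attr(f, "form") <- form
  attr(f, "pars") <- pars
  class(f) <- c("cn_rate_fun", "function")
  f
}

#' @rdname rate_forms
#' @export
rate_linexp <- function(a, vh, k) {
  force(a); force(vh); force(k)
  f <- function(v) {
    x <- v - vh
    out <- a * x / (1 - exp(-x / k))
    lim <- abs(x) < .SINGULARITY_EPS
    out[lim] <- a * k
    out
  }
  .make_rate(f, "linexp", c(a = a, vh = vh, k = k))
}

#' @rdname rate_forms
#' @export
rate_expo <- function(a, vh, k) {
  force(a); force(vh); force(k)
  f <- function(v) a * exp(-(v - vh) / k)
  .make_rate(f, "expo", c(a = a, vh = vh, k = k))
}

#' @rdname rate_forms
#' @export
rate_logistic <- function(a, vh, k) {
  force(a); force(vh); force(k)
  f <- function(v) a / (1 + exp(-(v - vh) / k))
  .make_rate(f, "logistic", c(a = a, vh = vh, k = k))
}

#' Forward/backward rate pair of a two-state subunit
#'
#' @param alpha,beta functions of voltage (mV) returning non-negative rates
#'   (1/ms); typically built with the [rate_forms] constructors.
#' @param check if `TRUE`, validate non-negativity and finiteness on
#'   \[-120, 60\] mV.
#' @return An object of class `cn_rate_pair`.
#' @export
rate_pair <- function(alpha, beta, check = TRUE) {
  stopifnot(is.function(alpha), is.function(beta))
  rp <- structure(list(alpha = alpha, beta = beta), class = "cn_rate_pair")
  if (check) {
    v <- seq(-120, 60, by = 0.5)
    a <- alpha(v); b <- beta(v)
    if (any(!is.finite(a)) || any(!is.finite(b)))
      stop("rate functions must be finite on [-120, 60] mV")
    if (any(a < 0) || any(b < 0))
      stop("rate functions must be non-negative on [-120, 60] mV")
  }
  rp
}

#' Hodgkin-Huxley subunit rates
#'
#' Empirical opening (`alpha`) and closing (`beta`) rates of the squid-axon
#' gating subunits at 6.3 degrees C:
#' `m` and `h` for the Na+ channel and `n` for the K+ channel.  Removable
#' singularities of the linear/(1-exp) form (`alpha_m` at -40 mV, `alpha_n`
#' at -55 mV) are evaluated by their analytic limits.
#'
#' @param subunit one of `"m"`, `"h"`, `"n"`.
#' @param v membrane voltage (mV), vectorised.
#' @return A list with numeric elements `alpha` and `beta` (1/ms).
#' @examples
#' hh_rates("n", -65)
#' @export
hh_rates <- function(subunit = c("m", "h", "n"), v) {
  subunit <- match.arg(subunit)
  rp <- .hh_rate_pair(subunit)
  list(alpha = rp$alpha(v), beta = rp$beta(v))
}

.hh_rate_pair <- function(subunit) {
  switch(subunit,
    m = rate_pair(rate_linexp(0.1, -40, 10), rate_expo(4, -65, 18),
                  check = FALSE),
    h = rate_pair(rate_expo(0.07, -65, 20), rate_logistic(1, -35, 10),
                  check = FALSE),
    n = rate_pair(rate_linexp(0.01, -55, 10), rate_expo(0.125, -65, 80),
                  check = FALSE),
    stop("unknown HH subunit: ", subunit)
  )
}

#' Steady state and time constant of a two-state subunit
#'
#' For a subunit with voltage-dependent rates `alpha` (off to on) and `beta`
#' (on to off), the steady-state on-probability is `alpha/(alpha + beta)` and
#' the relaxation time constant is `1/(alpha + beta)`.
#'
#' @param rates a [rate_pair()].
#' @param v membrane voltage (mV), vectorised.
#' @return `steady_state()`: probability in \[0, 1\]; `time_constant()`: ms.
#' @export
steady_state <- function(rates, v) {
  stopifnot(inherits(rates, "cn_rate_pair"))
  a <- rates$alpha(v); b <- rates$beta(v)
  s <- a + b
  if (any(s == 0)) stop("degenerate rates: alpha + beta = 0")
  a / s
}

#' @rdname steady_state
#' @export
time_constant <- function(rates, v) {
  stopifnot(inherits(rates, "cn_rate_pair"))
  s <- rates$alpha(v) + rates$beta(v)
  if (any(s == 0)) stop("degenerate rates: alpha + beta = 0")
  1 / s
}

#' Subunit specification
#'
#' One independent two-state subunit type of a channel, with its multiplicity
#' (number of identical copies per channel; e.g. 3 for `m`, 4 for `n`).
#'
#' @param name label, e.g. `"m"`.
#' @param multiplicity positive integer number of copies per channel.
#' @param rates a [rate_pair()].
#' @return An object of class `cn_subunit`.
#' @export
subunit_spec <- function(name, multiplicity, rates) {
  stopifnot(is.character(name), length(name) == 1,
            multiplicity >= 1, multiplicity == round(multiplicity),
            inherits(rates, "cn_rate_pair"))
  structure(list(name = name, multiplicity = as.integer(multiplicity),
                 rates = rates),
            class = "cn_subunit")
}

#' Channel kinetic scheme
#'
#' A voltage-gated channel built as an independent product of two-state
#' subunits: the channel conducts iff every subunit copy is in its on-state.
#' Single-channel current is Ohmic, `i = gamma * (V - e_rev)`.
#'
#' @param name label, e.g. `"hh_na"`.
#' @param subunits list of [subunit_spec()] objects.
#' @param gamma single-channel conductance (pS), > 0.
#' @param e_rev reversal potential (mV).
#' @return An object of class `cn_scheme`.
#' @seealso [get_scheme()] for the built-in schemes.
#' @export
channel_scheme <- function(name, subunits, gamma, e_rev) {
  if (inherits(subunits, "cn_subunit")) subunits <- list(subunits)
  stopifnot(length(subunits) >= 1,
            all(vapply(subunits, inherits, TRUE, "cn_subunit")),
            gamma > 0, is.finite(e_rev))
  structure(list(name = name, subunits = subunits,
                 gamma = gamma, e_rev = e_rev),
            class = "cn_scheme")
}

#' @export
print.cn_scheme <- function(x, ...) {
  stoich <- paste(vapply(x$subunits, function(s)
    if (s$multiplicity == 1) s$name else
      paste0(s$name, "^", s$multiplicity), ""), collapse = " ")
  cat("<channel scheme>", x$name, ":", stoich,
      sprintf("| gamma = %g pS, E_rev = %g mV\n", x$gamma, x$e_rev))
  invisible(x)
}

.scheme_mult <- function(scheme)
  vapply(scheme$subunits, `[[`, integer(1), "multiplicity")

.scheme_xinf <- function(scheme, v)
  vapply(scheme$subunits, function(s) steady_state(s$rates, v), numeric(1))

.scheme_tau <- function(scheme, v)
  vapply(scheme$subunits, function(s) time_constant(s$rates, v), numeric(1))

#' Steady-state open probability of a channel scheme
#'
#' Product over subunit types of the steady-state on-probability raised to the
#' multiplicity: for the HH Na+ channel `m_inf^3 * h_inf`, for the K+ channel
#' `n_inf^4`.
#'
#' @param scheme a [channel_scheme()].
#' @param v membrane voltage (mV), scalar or vector.
#' @return Open probability in \[0, 1\], vectorised over `v`.
#' @examples
#' open_probability(get_scheme("hh_k"), -65)   # ~0.010
#' @export
open_probability <- function(scheme, v) {
  stopifnot(inherits(scheme, "cn_scheme"))
  vapply(v, function(vi) prod(.scheme_xinf(scheme, vi) ^ .scheme_mult(scheme)),
         numeric(1))
}

#' Aggregated Markov expansion of a channel scheme at fixed voltage
#'
#' Expands the independent-subunit scheme into its aggregated Markov chain
#' whose states are tuples of on-counts per subunit type (`prod(mult + 1)`
#' states).  With `k` copies of subunit type `j` in the off state, the on-count
#' increases at rate `k_off * alpha_j` and decreases at rate `k_on * beta_j`.
#' Used by the stochastic simulator and by brute-force test oracles.
#'
#' @param scheme a [channel_scheme()].
#' @param v membrane voltage (mV), scalar.
#' @return An object of class `cn_markov` with elements `states` (matrix of
#'   on-counts, one row per state), `rate_matrix` (generator, 1/ms; rows sum
#'   to zero) and `open_state_index` (the all-on state).
#' @export
expand_markov <- function(scheme, v) {
  stopifnot(inherits(scheme, "cn_scheme"), length(v) == 1)
  mult <- .scheme_mult(scheme)
  J <- length(mult)
  states <- as.matrix(expand.grid(lapply(mult, function(m) 0:m),
                                  KEEP.OUT.ATTRS = FALSE))
  colnames(states) <- vapply(scheme$subunits, `[[`, "", "name")
  S <- nrow(states)
  a <- vapply(scheme$subunits, function(s) s$rates$alpha(v), numeric(1))
  b <- vapply(scheme$subunits, function(s) s$rates$beta(v), numeric(1))
  # column strides of the lexicographic expand.grid enumeration
  stride <- cumprod(c(1, head(mult + 1, -1)))
  Q <- matrix(0, S, S)
  for (s in seq_len(S)) {
    k <- states[s, ]
    for (j in seq_len(J)) {
      if (k[j] < mult[j]) {          # one more copy switches on
        r <- (mult[j] - k[j]) * a[j]
        Q[s, s + stride[j]] <- Q[s, s + stride[j]] + r
      }
      if (k[j] > 0) {                # one copy switches off
        r <- k[j] * b[j]
        Q[s, s - stride[j]] <- Q[s, s - stride[j]] + r
      }
    }
  }
  diag(Q) <- -rowSums(Q)
  open_idx <- which(apply(states, 1, function(k) all(k == mult)))
  structure(list(states = states, rate_matrix = Q,
                 open_state_index = open_idx, v = v, scheme = scheme),
            class = "cn_markov")
}

#' Stationary distribution of an aggregated Markov expansion
#'
#' Solves the null space of the generator transpose.  For an
#' independent-subunit scheme this equals the product of binomial laws over
#' subunit on-counts.
#'
#' @param mk a `cn_markov` from [expand_markov()].
#' @return Probability vector over the aggregated states.
#' @export
markov_stationary <- function(mk) {
  stopifnot(inherits(mk, "cn_markov"))
  Q <- mk$rate_matrix
  S <- nrow(Q)
  # solve pi Q = 0, sum(pi) = 1 as a bordered linear system
  A <- rbind(t(Q), rep(1, S))
  b <- c(rep(0, S), 1)
  pi_hat <- qr.solve(A, b)
  pi_hat[pi_hat < 0 & pi_hat > -1e-12] <- 0
  pi_hat / sum(pi_hat)
}
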