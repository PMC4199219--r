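# Built-in channel schemes and the scheme registry.

.scheme_registry <- new.env(parent = emptyenv())

#' Scheme registry
#'
#' Built-in channel schemes are registered by name and retrieved with
#' `get_scheme()`.  Available built-ins:
#'
#' \describe{
#'   \item{`"hh_na"`}{Squid-axon Na+ channel, `m^3 h`, 20 pS, E = +50 mV.}
#'   \item{`"hh_k"`}{Squid-axon delayed-rectifier K+ channel, `n^4`, 20 pS,
#'     E = -77 mV.}
#'   \item{`"ca1_na"`, `"ca1_kdr"`, `"ca1_ka"`}{Single-compartment CA1
#'     pyramidal-cell channels (Na+, delayed-rectifier K+, A-type K+).
#'     These are \emph{approximate} transcriptions: the original published
#'     rate equations use functional forms outside this package's three
#'     canonical ones, so the built-ins match the published half-activation
#'     voltages and slopes qualitatively, not the original curves point-wise.}
#' }
#'
#' @param name scheme name.
#' @param scheme a [channel_scheme()] (for `register_scheme`).
#' @return `get_scheme()` returns a `cn_scheme`; `list_schemes()` the
#'   registered names.
#' @export
get_scheme <- function(name) {
  if (!exists(name, envir = .scheme_registry, inherits = FALSE))
    stop("unknown channel scheme: '", name, "' (see list_schemes())")
  get(name, envir = .scheme_registry, inherits = FALSE)
}

#' @rdname get_scheme
#' @export
register_scheme <- function(name, scheme) {
  stopifnot(inherits(scheme, "cn_scheme"))
  assign(name, scheme, envir = .scheme_registry)
  invisible(scheme)
}

#' @rdname get_scheme
#' @export
list_schemes <- function() sort(ls(.scheme_registry))

.register_builtin_schemes <- function() {
  register_scheme("hh_na", channel_scheme(
    "hh_na",
    list(subunit_spec("m", 3, .hh_rate_pair("m")),
         subunit_spec("h", 1, .hh_rate_pair("h"))),
    gamma = 20, e_rev = 50))
  register_scheme("hh_k", channel_scheme(
    "hh_k",
    list(subunit_spec("n", 4, .hh_rate_pair("n"))),
    gamma = 20, e_rev = -77))

  # CA1 pyramidal-cell channels (approximate; see ?get_scheme).  Each gate
  # uses a complementary logistic rate pair alpha = A/(1 + exp(-(V-vh)/k)),
  # beta = A - alpha, which yields a logistic steady state with midpoint vh
  # and slope k and a voltage-independent time constant 1/A -- a bounded
  # approximation matching the published midpoints/slopes qualitatively.
  # Reversal potentials +55 / -90 mV, 20 pS single-channel conductance as in
  # the single-compartment reference configuration.
  logistic_gate <- function(A, vh, k)
    rate_pair(rate_logistic(A, vh, k), rate_logistic(A, vh, -k))
  register_scheme("ca1_na", channel_scheme(
    "ca1_na",
    list(subunit_spec("m", 3, logistic_gate(10, -30, 7)),
         subunit_spec("h", 1, logistic_gate(0.5, -45, -4))),
    gamma = 20, e_rev = 55))
  register_scheme("ca1_kdr", channel_scheme(
    "ca1_kdr",
    list(subunit_spec("n", 1, logistic_gate(0.4, 13, 9))),
    gamma = 20, e_rev = -90))
  register_scheme("ca1_ka", channel_scheme(
    "ca1_ka",
    list(subunit_spec("a", 1, logistic_gate(5, -1, 15)),
         subunit_spec("b", 1, logistic_gate(0.2, -56, -8))),
    gamma = 20, e_rev = -90))
}

.onLoad <- function(libname, pkgname) {
  .register_builtin_schemes()
}
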