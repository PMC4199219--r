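# Shared fixtures: small models and frozen oracle values.
#
# The frozen constants below were computed once from the closed-form rate
# equations with an independent script (direct evaluation / null-space
# solves), and are asserted against package output in the unit tests.

# direct evaluation of the printed rate formulas at -65 mV
ORACLE <- list(
  alpha_n = 0.01 * (-10) / (1 - exp(1)),        # 0.0581977...
  beta_n  = 0.125,
  m_inf   = 0.05293249,
  h_inf   = 0.59612075,
  n_inf   = 0.31767691,
  tau_m   = 0.23676689,
  tau_h   = 8.51601059,
  tau_n   = 5.45858525,
  p_na    = 8.840994e-05,
  p_k     = 0.010184572,
  sigma_ratio_na_k = 1.6384716   # binomial sigma_I(Na)/sigma_I(K), any area
)

passive_model <- function(area = 1000, g = 3, e = -65)
  membrane_model(area, populations = list(),
                 leaks = data.frame(g = g, e = e))

# a synthetic trace object for analysis-module tests
synth_trace <- function(t, v, currents, dt = t[2] - t[1]) {
  structure(list(dt = dt, t = t, v = v, currents = currents,
                 injected = numeric(length(t)),
                 gating = NULL, spikes = numeric(0), area = NA_real_),
            class = "cn_trace")
}
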