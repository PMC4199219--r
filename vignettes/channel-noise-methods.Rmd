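---
title: "Channel noise, membrane filtering and spontaneous spikes: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Channel noise, membrane filtering and spontaneous spikes: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(channelnoise)
```

## The problem

Voltage-gated ion channels are discrete molecules that open and close
stochastically. In a single-compartment neuron with channel densities
$\rho_x$ and area $A$, each population of $N_x = \rho_x A$ channels produces
a fluctuating current even at a fixed voltage. These fluctuations drive
membrane-voltage noise and, in small patches, spontaneous action
potentials. `channelnoise` implements both routes to quantifying this:
direct stochastic simulation of the discrete channel states, and a
small-noise analytic theory that predicts the voltage-noise spectrum and
each population's share of it from the kinetic scheme alone.

## Model and units

Channels are built as independent products of two-state subunits: a channel
with subunit multiplicities $m_j$ is open iff all
$\sum_j m_j$ subunit copies are in their on state, each copy switching
on at rate $\alpha_j(V)$ and off at rate $\beta_j(V)$. Steady state and
time constant of a subunit are $x_{j\infty} = \alpha_j/(\alpha_j+\beta_j)$
and $\tau_j = 1/(\alpha_j+\beta_j)$, and the open probability is
$p_o = \prod_j x_{j\infty}^{m_j}$. Single-channel currents are Ohmic,
$i_x = \gamma_x (V - E_x)$.

Units everywhere: mV, ms, pS, µm², pA, MΩ, Hz — chosen so published
parameter tables can be entered verbatim. The built-in `hh_model()` uses
the classic squid-axon parameters (Na⁺: $m^3h$, 60 /µm², $E$ = +50 mV;
K⁺: $n^4$, 18 /µm², $E$ = −77 mV; both 20 pS; leak 3 pS/µm² at −55 mV;
1 µF/cm²) at 6.3 °C. No temperature-scaling machinery is included: all
rate constants are used as printed at that temperature.

The three supported rate functional forms cover these kinetics exactly:
linear-over-(1−exp) (`rate_linexp`), pure exponential (`rate_expo`) and
logistic (`rate_logistic`). The removable singularities of the first form
(e.g. $\alpha_m$ at −40 mV) are evaluated by their analytic limit whenever
the argument is within $10^{-7}$ mV of the singular point, avoiding 0/0 at
exactly representable voltages.

The CA1 pyramidal-cell built-ins (`ca1_na`, `ca1_kdr`, `ca1_ka`) are
*approximate*: the original published equations use functional forms
outside the three above, so each gate is represented by a complementary
logistic rate pair (sigmoidal steady state at the published midpoint and
slope, constant time constant). Their two voltage-independent leak
densities are solved at model-construction time from two constraints —
total leak 2.5 pS/µm² and rest at −65 mV — mirroring how the reference
configuration was calibrated. Quantities that depend on the exact CA1
curves should not be read quantitatively from these built-ins; the
qualitative structure (K⁺-type channels dominating the voltage noise) is
reproduced.

## Stochastic simulation scheme

Each stochastic population is simulated on its aggregated Markov chain: the
state of one channel is its tuple of subunit on-counts
($\prod_j (m_j + 1)$ states; 8 for $m^3h$, 5 for $n^4$), and the population
state is the occupancy histogram over these states. Per timestep and state,
the number of channels taking each allowed transition is drawn
multinomially (sequential conditional binomials) with probabilities
$r\,\mathrm{d}t$, which matches the classic fixed-small-timestep scheme and
costs the same for $10^2$ or $10^6$ channels. The default
$\mathrm{d}t = 0.005$ ms is checked against the largest transition rate
over the physiologically visited voltage range (−80 to +55 mV; spike
overshoot and undershoot stay inside it) with the requirement
$r_{\max}\mathrm{d}t \le 0.05$.

The voltage advances by exponential Euler with conductances frozen per
step, which is stable through the stiff spike upswing; deterministic-mode
populations advance their gating by the exact per-step exponential
relaxation toward $x_\infty(V)$. Initial stochastic states are drawn from
the product-binomial stationary law at the starting voltage, and rate
estimation discards a 200 ms burn-in. Each population consumes its own
named RNG stream derived from the master seed, so switching one population
between stochastic and deterministic modes does not perturb the others'
realizations; identical seeds give bit-identical runs.

Spike detection is an upward crossing of −20 mV with a 2 ms refractory
period. Spikes overshoot 0 mV, so any threshold in roughly [−30, 0] mV
yields identical counts — the test suite asserts this insensitivity.

## Analytic noise theory

At fixed voltage the open count of a population is binomial, giving current
noise variance $\sigma_I^2 = N i^2 p_o (1-p_o)$. The temporal structure
follows from the autocovariance of the open-channel indicator: expanding
$\prod_j (x_{j\infty} + (1-x_{j\infty}) e^{-t/\tau_j})^{m_j} - p_o$
multinomially yields a sum of decaying exponentials, each of which
transforms into a Lorentzian. The package generates this expansion
symbolically for any product scheme rather than hard-coding particular
channels; for the squid K⁺ channel it reproduces exactly the four
Lorentzians with corners $k/(2\pi\tau_n)$, $k = 1\ldots4$, and for Na⁺ the
seven-term sum, which serve as unit-test oracles. The spectral convention
is one-sided with $S(0) = 4 N i^2 p(1-p)\tau$, so
$\int_0^\infty S(f)\,df = \sigma_I^2$ exactly (asserted to $10^{-10}$
relative error). Cross-population covariances are ignored — channels are
independent and the voltage is frozen at the operating point — which is
precisely the small-noise regime the theory targets.

Voltage noise follows from the generalized Ohm's law
$S_V(f) = S_I(f)\,|Z(f)|^2$ with $Z$ the quasi-active impedance: the
admittance collects the capacitive term, leaks, each population's resting
conductance, and one first-order term per gating variable,
$\delta x_j = (dx_{j\infty}/dV)\,\delta V/(1 + i 2\pi f \tau_j)$. The
delayed-rectifier term acts as a phenomenological inductance and produces a
subthreshold resonance (peak $|Z|$ near 66 Hz for the squid model at
1000 µm²; the resonance makes $|Z|$ non-monotone below ~100 Hz). An
independent sine-injection estimator (`empirical_impedance`) mirrors the
experimental procedure, cross-validates the linearization within 2%, and is
the fallback when a model's linearization diverges.

Variance integrals use the per-Lorentzian closed form
$a f_c \pi/2$ whenever available; sampled spectra ($S_I|Z|^2$) are
integrated trapezoidally on a logarithmic grid (0.1 Hz – 100 kHz, 60
points/decade) with a flat extension below the grid and an analytic
$1/f^2$ tail above it, and the integrator refuses spectra that have not
decayed by the end of the grid. This keeps the filtering ratios
$r_x = \sigma_{Vx}/\sigma_{Ix}$ grid-insensitive.

```{r, eval = FALSE}
noise_report(hh_model(1000), -65)
```

## Colored-noise surrogates

To connect voltage noise to spontaneous rates, channel noise is replaced by
an Ornstein–Uhlenbeck current injected into the deterministic model. The
generator is the exact discrete-time AR(1), so its lag-$k$ autocorrelation
is $e^{-k\,\mathrm{d}t/\tau}$ at any timestep. The impedance factor
$z^2(\tau) = \int S_u(f)|Z(f)|^2 df$ (with the unit-variance OU spectrum
$S_u$) converts a target voltage s.d. into the current s.d. that produces
it; the closure of this loop (measured $\sigma_V$ within 10% of target
across $\tau$ = 0.1–100 ms) is asserted in the tests. Because $z(\tau)$
requires spectral support below the corner $1/2\pi\tau$ for slow noise, it
is evaluated on an extended grid ($10^{-5}$–$10^5$ Hz).

Per-population surrogates reduce a channel's noise to variance
$N i^2 p_o(1-p_o)$ and a single effective correlation time
$\tau_{\rm eff} = 1/\sum_j m_j/\tau_j$ — the decay time of the
all-subunit-flip covariance term ($\tau_n/4$ for K⁺; for Na⁺ the
near-degenerate pair $\approx \tau_m/3$). This reduction is deliberately
coarse: it discards the slower covariance terms and all non-Gaussian
structure. In practice the surrogate preserves the K-over-Na rate ordering
and tracks the K⁺-driven rates within an order of magnitude, but
underestimates Na⁺-driven spiking badly (its current distribution is very
skewed at rest — the mean open Na⁺ count at 50 µm² is below one channel),
consistent with the known need to inflate the Na⁺ surrogate amplitude by
tens of percent to match discrete simulations. OU noise is injected as an
additive external *current*, not as conductance noise.

The `rate_vs_tau()` default target $\sigma_V$ = 8 mV was chosen once so
that (i) the calibrated rate at $\tau$ = 1 ms is in the tens of Hz and
(ii) extremely slow noise still evokes spikes. The second condition
matters: slow current ramps inactivate the Na⁺ channel and raise the
effective threshold, so with weaker noise the slow-$\tau$ rates collapse
toward zero and the calibrated-rate span across $\tau$ widens — exactly
what the slow-noise limit $\int P(I) f(I)\,dI$ over a distribution mostly
below (accommodated) rheobase predicts. At 8 mV the calibrated rates span
roughly 50 down to 9 Hz over six decades of $\tau$ (less than one order of
magnitude), while fixed-current-variance noise spans several orders.

## Spike-triggered analysis

`sta_currents()` averages each population's current over a window before
every detected spike; the change $\Delta I_x$ is measured against the
population's resting current, defined as its mean over spike-free epochs
(no spike within ±50 ms) since sufficiently long spike-free stretches always
exist in the regimes analyzed. Currents are stored outward-positive;
`dominance_fraction()` reports, per pre-spike lag, the fraction of spikes
in which the K⁺ population contributes more *depolarization* than Na⁺,
i.e. $-\Delta I_K > -\Delta I_{Na}$, with ties counted as not-exceeding.
In the fully stochastic squid model at 100 µm² this fraction exceeds 0.5
through the early pre-spike phase (~4–10 ms) and collapses to ~0 in the
final millisecond when the Na⁺ upswing takes over; with K⁺ made
deterministic the pre-spike K⁺ drop disappears and spikes ride on Na⁺
fluctuations instead.

Spectral estimation (`estimate_psd`) is a Hann-windowed averaged
periodogram with 50% overlap, scaled to the same one-sided convention as
the analytic spectra (integral = variance; Parseval asserted within 5%).
Segment lengths of 32768 samples at dt = 0.005 ms give ~6 Hz resolution,
comfortably resolving the 115 Hz K⁺ corner.

## Problem sizes used in the shipped checks

The test suite favors exact analytic assertions wherever possible and uses
deliberately modest simulation sizes elsewhere, chosen to keep sampling
error well inside the asserted tolerances: voltage-clamp spectra from 4 s
of clamp at 1000 µm²; rate-vs-area ordering from 15 s per condition at
50–200 µm² plus a 40 s point at 250 µm² for the log-linear fit; STA
properties from 15 s runs at 100 and 50 µm² (≥ 40 and ≥ 20 spikes); OU
rate curves from 10 s per correlation time, stretched to 30 correlation
times (capped at 120 s) for slow noise. Quantities printed only as figure
curves in the source analyses (rate-vs-area values, the exact OU noise
amplitude) are validated as order/monotonicity/span properties, not
point-wise.

## Known limitations

* The analytic layer is a small-noise (linear-response) theory: once
  spontaneous spikes appear (areas below ~500 µm² in the squid model) the
  measured voltage variance exceeds the prediction, and the tests assert
  this divergence rather than hiding it.
* Channel schemes are restricted to independent products of identical
  two-state subunits; arbitrary (non-product) Markov topologies are only
  representable through `expand_markov()`-style generators and are not
  accepted by the spectral layer, which errors on them.
* Single compartments only; no cable structure, no synaptic input, no
  ligand- or calcium-gated channels, no GHK (non-Ohmic) single-channel
  currents.
* The per-step multinomial scheme is O(states) per step but not an exact
  event-driven (Gillespie) simulation; its accuracy is controlled by the
  $r_{\max}\mathrm{d}t \le 0.05$ check and validated against binomial
  statistics and analytic spectra in the tests.
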