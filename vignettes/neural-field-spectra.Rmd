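---
title: "Neural field models of steady-state spectra: model, inversion, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Neural field models of steady-state spectra}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nfdcm)
```

## The generative model

`nfdcm` treats a single cortical source as a one-dimensional patch (radius
`ell`, normalized to 1) carrying three interacting populations, one per
cortical lamina: excitatory spiny stellate cells (population 1, the input
layer), inhibitory interneurons (population 2) and pyramidal cells
(population 3, the output layer). The average depolarization of each
population is a field over the patch. Synaptic dynamics are second order:
presynaptic input arriving at rate density `u` produces a postsynaptic
depolarization through a kernel with maximum response `m` and rate constant
`kappa` (time constants of 4 ms and 28 ms for excitatory and inhibitory
synapses at the defaults). Populations couple through lateral connectivity
kernels

\[
d_{ij}(x, t) = \tfrac{\alpha_{ij}}{2}\, e^{-c_{ij}|x|}\,
\delta(t - \upsilon |x|),
\]

an exponential fall-off of synaptic strength with distance together with a
delay proportional to distance: `upsilon` is the transit time per unit
patch radius, the inverse of the lateral conduction velocity. The
microcircuit has four connections: pyramidal cells drive stellate cells
(`alpha_13`) and interneurons (`alpha_23`); stellate cells excite
(`alpha_31`) and interneurons inhibit (`alpha_32`) pyramidal cells.
Depolarization maps to firing through a sigmoid with slope `r` and
inflection `eta`; the model is linearized about the working point `v = 0`,
so each kernel is multiplied by the sigmoid gain
`gamma = r e^{r eta} / (1 + e^{r eta})^2` (0.135 at the defaults).

In the spectral domain the kernel has the closed-form transfer function

\[
D_{ij}(k, \omega) = \frac{\alpha_{ij} (c_{ij} + i \upsilon \omega)}
{c_{ij}^2 - \upsilon^2 \omega^2 + 2 i \upsilon c_{ij} \omega + k^2},
\]

and the linearized system gives a 3-vector transfer function
`T(k, omega)` from input fluctuations (entering the stellate population
only) to depolarization perturbations; `transfer_vector()` computes it by a
complex linear solve and `predict_spectrum()` uses an algebraically
equivalent closed form for the pyramidal component, which is the only one
observed. Under periodic boundary conditions the patch supports standing
waves with wavenumbers `k_j = j * pi / ell`; the predicted sensor spectrum
is the lead-field-weighted modal sum

\[
g_Y(\omega) = \frac{\pi}{\ell} \sum_{j=1}^{J} L(k_j)\,
|T_3(k_j, \omega)|^2\, g_U(\omega)\, L(k_j),
\qquad L(k) = \phi_1 e^{-\phi_2 \pi^2 k^2},
\]

with `J = 32` modes by default. The neuronal input spectrum
`g_U = alpha_U + beta_U / omega` and the channel noise
`g_N = alpha_N + beta_N / omega` are free mixtures of white and pink
components; observed spectra are modeled as
`g_Y + g_N` plus Gaussian error on every frequency bin.

```{r spectra}
params <- nf_params_default()
freq <- seq(1, 60, by = 0.5)
g_field <- predict_spectrum(params, freq)
g_mass <- mass_limit_spectrum(params, freq)
```

Setting the transit time to zero collapses the patch to a point source:
every layer sees distant input instantaneously, delays no longer shape the
dynamics, and the model reduces to the classical three-population neural
mass model (`mass_limit_spectrum()`, or structurally via
`make_mass_variant()`). At the default parameters the field spectrum shows
delay-induced structure (a resonance near 30 Hz for the first mode) that
the smooth, single-peaked mass spectrum lacks; this contrast is what makes
the two models distinguishable from a single channel.

## Parameters, units and normalization

| name | meaning | default | unit |
|---|---|---|---|
| `m_e`, `m_i` | max. postsynaptic depolarization | 8, 32 | mV |
| `kappa_e`, `kappa_i` | postsynaptic rate constants | 250, 35.7 | s^-1 |
| `alpha_13..alpha_32` | kernel amplitudes | 2000, 8000, 2000, 1000 | — |
| `c_13`, `c_23`, `c_31` | kernel decay constants | 0.32 | per patch radius |
| `upsilon` | transit time (centre to boundary) | 1/60 | s |
| `r`, `eta` | sigmoid slope, inflection | 0.54, 0 | mV^-1, mV |
| `phi_1`, `phi_2` | lead-field amplitude, width | 1, 0.01 | a.u., radius^2 |
| `alpha_U`, `beta_U` | input spectrum, white/pink | 1, 1 | a.u. |
| `alpha_N`, `beta_N` | channel noise, white/pink | 2e-6, 2e-6 | a.u. |

All spatial quantities are expressed per patch radius (`ell = 1`); the
transit time is the physical radius divided by the conduction velocity
(50 mm at 3 m/s gives 16.7 ms). Configuration files accept the printed
units (rate constants in ms^-1, velocity in m/s, radius in mm) and
`load_config()` converts exactly once.

Two normalization choices deserve comment, because the conventions in the
source material are internally inconsistent and the package had to commit
to one reading:

* **Kernel decay constant.** The decay constant is taken as 0.32 *per
  normalized patch radius*, not per millimetre. Multiplying by a 50 mm
  radius (decay constant 16 per radius) would push all delay effects to
  `omega ~ c / upsilon` near 150 Hz, far above the 1-60 Hz band; the field
  and mass models would then be empirically indistinguishable at any noise
  level, model selection between them would be vacuous, and widening the
  lateral extent could never make the field spectrum mass-like. With the
  decay constant of order one, the first delay resonances fall inside the
  band and all of the qualitative spectral behavior of the model (new
  low-frequency peaks as conduction slows; mass-like spectra as the kernels
  narrow) is reproduced.
* **Lead field.** The spatial sensitivity profile of the sensor is a
  Gaussian of width `phi_2 = 0.01` (appropriate for an LFP electrode that
  sees a wide range of spatial frequencies). The package adopts the
  spectral form `L(k) = phi_1 exp(-phi_2 pi^2 k^2)` directly. Note that
  this is not the exact Fourier transform of the spatial Gaussian
  `phi_1 exp(-x^2/phi_2)` (the amplitude prefactor `sqrt(pi phi_2)` and a
  factor 4 in the exponent differ); the spectral form is taken as the
  definition and the spatial form as illustration only.

## Stability

The linearized model is only a valid generative model while the underlying
fixed point persists. `check_stability()` declares a parameter set unstable
when, for any retained mode, either

1. the determinant of the spectral system matrix nearly vanishes somewhere
   on the real frequency grid (below 1e-8 of the mode's median magnitude) —
   a resonance of the delayed system; or
2. the determinant at zero frequency is not strictly positive — the static
   criterion for the saddle-node bifurcation through which a runaway
   excitatory loop (`alpha_13 * alpha_31` too strong) destroys the fixed
   point. This criterion is exact: scaling the excitatory loop flips the
   flag precisely at the closed-form point where the static loop gain
   reaches one, which the test suite verifies by bisection.

The largest real part of the eigenvalues of each mode's delay-free state
matrix is reported as a diagnostic but deliberately does not veto: with the
sigmoid gain pinned at `v = 0` rather than at a self-consistently solved
operating point, that surrogate shows weakly positive real parts even at
the default parameters, while the steady-state spectral model remains
perfectly well defined (the saturating sigmoid, which the linearization
discards, is what bounds those loops in the full model). During inversion
any candidate step that loses stability is rejected and the previous
estimate retained.

## Variational-Laplace inversion

Every free parameter is estimated as a log-scaling of its default:
`theta_i = P_i exp(mu_i)`, which enforces positivity and makes priors
scale-free. The 19 scalings (18 for the mass variant, which drops the
transit time) carry independent Gaussian priors with mean 0 and precision
16 (prior sd 0.25, i.e. roughly 78%-128% of the default at one sd). The
sigmoid inflection `eta` is excluded (its default is 0, and the gain is
scaled through the slope `r`).

The observation error on the spectral data features is Gaussian with
covariance `Sigma = exp(-lambda) I` over frequency bins (a single
log-precision hyperparameter by default; a multi-component basis is
available through `nf_error_model()`). Real and imaginary parts of the
prediction error enter the Gibbs energy as separate quadratic forms — for
the real single-channel auto-spectra inverted here the imaginary terms are
exactly zero, and the test suite checks that the complex-path energy
coincides with a real-only computation.

The scheme is a Gauss-Newton ascent on the free energy with
Levenberg-Marquardt damping, alternated with the closed-form mean-field
update of `lambda` (moment matching of the residual variance, capped at
|lambda| = 32 so that exactly vanishing residuals cannot drive the
precision to infinity):

* Jacobians of the prediction error with respect to the log-scalings are
  central finite differences with step 1e-3 (predictions are smooth in the
  log-parameters; the step is reduced fivefold, twice if necessary, when a
  perturbed prediction crosses a resonance).
* A candidate step is accepted only if the free energy does not decrease
  (tolerance 1e-6 nats) and the candidate parameters are stable; on
  rejection the damping is multiplied by 10, on acceptance divided by 10.
* Convergence is declared after three consecutive accepted improvements
  below 1e-3 nats, or 128 iterations.
* The free energy uses the standard Laplace form
  `F = G(mu) - 1/2 ln|-ddG| + (p/2) ln 2 pi` with the Gauss-Newton
  curvature; the posterior is `N(mu, (-ddG)^{-1})`.
* Because conduction delays move resonances through the band, the marginal
  likelihood over the transit-time scaling can be multimodal. The ascent
  therefore initializes that single scaling by profiling the
  prior-penalized residual sum of squares over a 13-point grid on
  [-1.5, 1.5] before iterating; all other scalings start at their prior
  means. Without this, inversions of data generated at strongly negative
  transit-time scalings can converge to a spurious mode of opposite sign.

Model comparison uses the free energies directly: `compare_models()` ranks
posteriors fitted to the same data and flags a margin of three nats or more
over the runner-up as strong evidence. The mass variant is implemented
structurally (transit time exactly zero, one fewer free parameter) because
a log-scaled parameter can never reach zero; an alternative
shrinkage-prior route (`make_mass_variant(shrink = TRUE)`) pins the
transit-time scaling near a large negative mean with precision 1e8 for
users who prefer nested priors over nested structures.

## Spectral estimation from time series

`var_cross_spectrum()` estimates cross-spectral data features from raw
recordings by fitting a vector autoregression of order 8 (ordinary least
squares on lagged regressors via `stats::ar.ols`) and evaluating its
parametric spectrum `H(f) Sigma H(f)^* / fs` on the analysis grid. The
package-wide convention is a two-sided density per Hz; only relative
spectral shape matters for inversion, since the input and noise amplitudes
are free parameters. Series are demeaned before fitting; no windowing or
detrending beyond mean removal is applied. `preprocess()` provides the
usual acquisition chain (zero-phase Butterworth band-pass, decimation to a
target rate that must divide the input rate).

## The synthetic-data generator

`simulate_observed_spectrum()` draws observed spectra from the generative
model itself: predicted source spectrum plus channel noise plus independent
Gaussian error per bin. Its defaults define the study conditions used
throughout the tests and the acceptance script:

* frequency grid 1-60 Hz in 0.5 Hz steps (119 bins), matching the band of
  typical band-limited LFP acquisition;
* observation-error sd set to one tenth of the peak of the noiseless
  spectrum (peak signal-to-noise ratio of 10) — a deliberately modest
  level at which model selection must still work;
* all parameters at their defaults, except where an experiment scales one.

The generator emulates the second-order statistics of steady-state
recordings, not the recordings themselves: it produces spectra with exactly
independent Gaussian bin errors. Real spectral estimates (e.g. the VAR
features above) have errors that are correlated across frequencies and
asymmetric on the scale of the density; passing the recovery and
model-selection tests therefore demonstrates that the inversion machinery
works under the model's own assumptions, not that those assumptions hold
for any particular recording system. Negative bins can occur at high
frequencies under the Gaussian error and are retained (the inversion
treats data features as unconstrained reals).

Experiment sizes are chosen to keep the full suite fast while leaving the
conclusions unambiguous: transit-time recovery uses 9 scalings over
[-1, 1] at the full 119-bin grid; the replicated 2x2 model-selection
design uses ten seeds at a 1 Hz grid (60 bins), where the free-energy
margins (order 100 and 20 nats for field- and mass-generated data) dwarf
seed-to-seed variability. The sensitivity scans sweep log-scalings over
[-2.5, 2.5]; scalings that lose stability are reported as such rather than
dropped.

## Known limitations

* Inversion is implemented for single-channel auto-spectra (the model of a
  single source observed through one lead field); the cross-spectral
  containers and the complex-data energy are in place, but multi-sensor
  prediction would require a model of several lead fields.
* The transit-time posterior shrinks toward the prior at extreme true
  deviations (|scaling| = 1, i.e. four prior standard deviations), so
  credible intervals there can miss the truth — visible in the recovery
  experiment and expected of any informative prior.
* On mass-generated data the free-energy margin in favor of the mass model
  is much smaller than on field-generated data (the mass model is nested
  in the field model), and its magnitude depends on the noise level; only
  the ordering should be treated as a robust claim.
* The scan of the transit time is summarized from the baseline upward
  (slower conduction concentrates power at low frequencies); below the
  baseline the comparison is ill-posed because the near-instantaneous
  limit is an alpha-peaked mass spectrum whose power is also
  low-frequency.
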