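---
title: "Nested-well analysis of specific and nonspecific protein–DNA binding"
author: "NestedWell authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested-well analysis of specific and nonspecific protein-DNA binding}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NestedWell)
```

## The model and its assumptions

A label-free biosensor records, per probe spot, the surface mass density
$\sigma(t)$ of protein bound to immobilised DNA duplexes during analyte
injections. Spots carrying the consensus site ("specific") and spots without
it ("nonspecific") are measured in parallel under identical solution
conditions. The package analyses such paired measurements with a sequential
two-state scheme in which specific docking is always preceded by nonspecific
contact:

$$\mathrm{unbound} \;\xrightleftharpoons[k_{off,1}]{k_{on,1}c}\;
\theta_1 \;(\mathrm{nonspecific})
\;\xrightleftharpoons[k_{off,2}]{k_{on,2}}\; \theta_2 \;(\mathrm{docked})$$

The picture behind it is a conformational coordinate along which the deep,
narrow specific well sits *inside* the broad nonspecific one: a protein can
only reach (and leave) the docked state through the nonspecifically bound
state. There is deliberately no direct unbound→docked channel.

Key consequences, all implemented in closed form:

* **Equilibrium.** With $K_1 = k_{off,1}/k_{on,1}$ (nM) and
  $K_2 = k_{off,2}/k_{on,2} = \theta_1/\theta_2$ (dimensionless), total
  occupancy follows a Langmuir isotherm in the effective constant
  $K_d = K_1K_2/(1+K_2) < K_1$ (`effectiveKd`), invertible as
  $K_2 = K_d/(K_1-K_d)$ (`k2FromKd`).
* **Kinetics.** At constant $c$ the linear rate equations give a double
  exponential with times $\tau_S \le \tau_L$, the negative reciprocal
  eigenvalues of the $2\times2$ rate matrix (`relaxationSpectrum`). For
  $k_{on,2}=0$ this collapses to one exponential with rate
  $\Gamma(c) = k_{on}c + k_{off}$. The slow time always exceeds the
  single-well response time $\tau_1 = 1/(k_{on,1}c+k_{off,1})$; under fast
  inner exchange it saturates at
  $\tau_{L\infty} = 1/(k_{on,1}c + k_{off,1}K_2/(1+K_2))$ (`tauLLimit`),
  the escape time of a nonspecific pool in constant equilibrium with the
  docked one.
* **Thermodynamics.** $\Delta G = RT\ln K_2$ with
  $R = 1.987\times10^{-3}$ kcal/(mol K). Because $K_2$ is
  dissociation-like (nonspecific over specific), $\Delta G$ is *negative*
  when docking is favoured — the reverse of the common association
  convention; we keep this sign throughout to stay consistent with the
  ratio definition. The temperature dependence is modelled as
  $K_2(T) = \exp(\Delta H/RT - \Delta S/R)$, linear in $1/T$ on the log
  scale, with $\Delta H$ in kcal/mol and $\Delta S$ in cal/(mol K).

Standing assumptions: excess analyte (concentration constant within an
injection step, as in a stirred or flow cell); independent, identical probe
sites; at most one protein per probe contributing to the analysed
concentration range; no mass-transport limitation; no direct modelling of
sliding/hopping search. These match the regime the instrument data are
collected in (low nM, far from surface saturation).

## The estimation pipeline

1. **Per-step reduction** (`fitStep`, `fitAllSteps`). Each injection step is
   fitted with the single exponential
   $\sigma(t) = \sigma_{prev} + (\Sigma(c)-\sigma_{prev})(1-e^{-\Gamma(t-t_0)})$,
   time measured from the injection, chained so each step starts from the
   previous step's *fitted* plateau. The asymptote is stored absolutely so it
   feeds the isotherm directly. The initial slope is taken analytically from
   the fit, $\sigma'(c)=\Gamma\,(\Sigma-\sigma_{prev})$, not from finite
   differences — the single most effective noise-robustness choice in the
   layer.
2. **Paired isotherm** (`langmuirPairFit`). Both probes' $\Sigma(c)$ are fitted
   simultaneously with $\Sigma_\infty c/(c+K_d)$, one *shared* $\Sigma_\infty$
   and one $K_d$ per class: the maximum protein load depends on probe length,
   not on the presence of the consensus tract.
3. **Rates** (`konFromSlopes`). Binding from an empty surface obeys
   $\sigma'(c)=\Sigma_\infty k_{on}c$ exactly. In a stepwise titration the
   exact per-step slope is
   $k_{on}\Sigma_\infty K_d\,\Delta c/(c_{prev}+K_d)$ — a relation that holds
   unchanged for nested-well probes with $K_d$ read as the effective constant,
   provided the previous step equilibrated. The plain regressors `"c"` and
   `"delta_c"` are therefore biased low once $c_{prev}\sim K_d$; regressor
   `"exact"` uses the fitted per-class $K_d$ to remove that bias, and the
   pipeline uses it by default. A residual bias remains for nested probes
   because the single-exponential fit slightly underestimates the true
   (double-exponential) initial slope; in synthetic tests at the default
   parameters this bias is about 10 %, well inside the experimental
   uncertainty of $k_{on}$, and the unbiased kinetic route is the joint fit
   below. $k_{off} = K_d k_{on}$ per class.
4. **Selectivity** (`extractK2`). $K_2 = K_d^{sp}/(K_d^{ns}-K_d^{sp})$ with
   delta-method errors from the isotherm covariance. The propagation
   degenerates as $K_d^{sp}\to K_d^{ns}$, so a seeded residual bootstrap
   (`bootstrapK2`, default 500 resamples) is provided as an alternative.
5. **Joint kinetic fit** (`nwJointFit`). Both raw traces are fitted
   simultaneously against the piecewise analytic solution, parameterised as
   $(\log k_{on,1},\log K_1,\log k_{on,2},\log K_2)$ with $\Sigma_\infty$
   profiled out linearly. Initialisation comes from the stepwise/Langmuir
   estimates with a small multi-start grid over $k_{on,2}$
   ($10^{-4}\dots10^{-1}$ s$^{-1}$), since equilibrium data do not pin it
   down. The fit reports whether it sits in the fast-inner-exchange regime
   ($\tau_L$ within 5 % of $\tau_{L\infty}$), where only a lower bound on
   $k_{on,2}$ is identifiable (`kon2-lower-bound` flag); a fitted
   $K_2>100$ flags collapse to a single well.
6. **Thermodynamics** (`vantHoffFit`). Weighted regression of $\ln K_2$ on
   $1/T$; slope $=\Delta H/R$, intercept $=-\Delta S/R$, covariance
   propagated to $\Delta G(T) = \Delta H - T\Delta S$, which equals
   $RT\ln K_2^{model}(T)$ identically.

## Parameters that matter

| parameter | units | default | why |
|---|---|---|---|
| concentration ladder | nM | 0.08, 0.16, …, 40.96, 50 | doubling ladder over the experimental titration range |
| step duration | s | 3000 | near-saturates the slowest default mode; per-step asymptotes are unbiased once steps exceed ~3 τL |
| discard window | s | 10 | drops the injection/mixing transient; the instrument papers are silent, 10 s is conservative for sampled dt ≥ 1 s |
| temperature | K | 303.15 | the experiments' 30 °C |
| ionic strength | mM | 150 | the physiological reference condition |
| gas constant | kcal/(mol K) | 1.987e-3 | thermodynamic outputs in kcal/mol, ΔS in cal/(mol K) |
| kon regressor | — | pipeline: `"exact"` | removes the closed-form stepwise bias (see above); `"c"` reproduces the printed convention |
| bootstrap resamples | — | 500 | stable 95 % intervals for K2 at the default noise |

## The synthetic generator's stated world

`generateProbePair` produces paired traces from the piecewise analytic
solution with: shared $\Sigma_\infty$ (default 1000 instrument units), shared
$k_{on,1} = 1.6\times10^{-5}$ s$^{-1}$nM$^{-1}$, $K_1 = 200$ nM,
$K_2 = 0.16$, docking rate $k_{on,2} = 5\times10^{-3}$ s$^{-1}$ (chosen so the
inner well is kinetically visible — $\tau_L \approx 2500$ s at 10 nM — without
being unidentifiable), additive i.i.d. Gaussian noise (default tests use 1 %
of $\Sigma_\infty$), and the doubling ladder above. Noise is additive Gaussian
because the smooth measured traces give no reason for anything richer; drift,
injection spikes (exercised by a separate synthetic-spike fixture), spot
geometry and optical conversion are *not* simulated. The van't Hoff generator
uses $\Delta H = -12.8$ kcal/mol, $\Delta S = -38.7$ cal/(mol K) on a 6-point
grid 288.15–310.15 K (the experimental grid is not published; this span
brackets the working temperature) with lognormal multiplicative noise.

A green test on this world therefore establishes: correctness of the model
algebra (verified independently against a matrix-exponential/RK4 integration
oracle to $<10^{-8}$), correctness and calibration of the estimators under
the model's own noise assumptions, and end-to-end parameter recovery. It does
*not* establish robustness to drift, mass-transport limitation, probe
heterogeneity, analyte depletion, or optical-conversion errors — none of
which are modelled.

Every generator is a pure function of (parameters, seed); per-trace streams
are derived from (seed, spot label) so fixture sets are order-independent,
and the global RNG state is restored after generation.

## Numerical choices

* Per-step exponential fits profile the amplitude (linear for fixed rate),
  search $\log\Gamma$ over a ±2-decade bracket, then polish with damped
  Gauss–Newton to a $10^{-13}$ relative step; this is robust where `nls`
  fails on zero-residual data. Standard errors come from the Jacobian at the
  optimum.
* Steps whose rise is below 3× the noise estimate (from first differences)
  are flagged unusable instead of fitted; a flat step returns the previous
  plateau with a degenerate-rate flag.
* Eigenvalue degeneracy in the relaxation spectrum ($\tau_S=\tau_L$) is
  detected at discriminant $<10^{-10}$ relative and handled with the
  critically-damped closed form.
* The integration oracle defaults to exponential time-stepping with the
  augmented-generator matrix exponential (`Matrix::expm`), which is exact for
  a linear system and algorithmically independent of the hand-derived
  eigendecomposition it checks; a classical fixed-step RK4 (step
  $\le 0.02/\lVert A\rVert_\infty$) is available as a second opinion.
* The Langmuir and joint fits optimise log-parameters (positivity by
  construction) with Nelder–Mead at `reltol` $10^{-13\ldots14}$ plus a BFGS
  polish where smooth; saturation densities are profiled out linearly in both.
* The explicit amplitudes $B$, $\tau_S$, $\tau_L$ are derived from the
  eigen-decomposition with the empty-surface initial condition and validated
  against the oracle rather than against any published closed form.

## Known limitations

* The initial-slope $k_{on}$ estimator retains a ~10 % model-mismatch bias on
  nested probes (single-exponential layer on double-exponential truth); use
  `nwJointFit` when an unbiased $k_{on}$ matters.
* $K_2$ uncertainties from the delta method blow up as selectivity vanishes;
  the bootstrap is preferred near $K_d^{sp}\approx K_d^{ns}$.
* The ionic-strength dependence is treated purely descriptively (independent
  conditions, no counterion-release model), matching the scope of the
  underlying analysis.
* Conversion of $\Sigma_\infty$ to absolute proteins-per-probe requires an
  instrument calibration that is out of scope; all densities stay in
  instrument units.
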