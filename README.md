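# NestedWell

Quantitative analysis of specific versus nonspecific transcription-factor–DNA
binding from label-free biosensor sensorgrams.

## The problem

A transcription factor finds its consensus site on DNA through nonspecific
contacts: it binds any duplex electrostatically, slides and hops, and only then
docks onto the cognate sequence. Measuring probes **with** and **without** the
consensus site in parallel on a multi-spot biosensor gives simultaneous access
to both interaction modes, but disentangling them requires a model.

`NestedWell` implements a sequential two-state ("nested-well") kinetic scheme:

```
            kon1·c                kon2
  unbound  ───────►  nonspecific ──────►  specifically docked
           ◄───────    (θ₁)      ◄──────       (θ₂)
            koff1                 koff2
```

with the outer (nonspecific) dissociation constant `K1 = koff1/kon1` (nM) and
the dimensionless inner coefficient `K2 = koff2/kon2 = θ₁/θ₂`, the equilibrium
ratio of nonspecifically to specifically bound protein. The measured
dissociation constant of a consensus-carrying probe is

```
Kd = K1·K2/(1 + K2)        ⇔        K2 = Kd/(K1 − Kd)
```

so a paired measurement of `Kd` (specific probe) and `K1` (nonspecific
reference) yields `K2`, the free-energy gap `ΔG = RT ln K2`, and — from a
temperature series — the van't Hoff decomposition
`K2(T) = exp(ΔH/RT − ΔS/R)` into enthalpy and entropy.

Kinetically, each concentration step of a stepwise titration relaxes as a
double exponential `σ(c,t) = Σ(c)(1 − B e^(−t/τL) − (1−B) e^(−t/τS))`, whose
times are the eigenvalues of the 2×2 rate matrix; for `kon2 = 0` this
collapses to the single-well `Γ(c) = kon·c + koff`.

The package provides, per module:

* **model** — closed-form equilibrium and relaxation spectrum, the piecewise
  analytic titration solution (`nwSolve`), and an independent
  numerical-integration oracle (`odeOracle`);
* **synthetic data** — seeded generators for paired sensorgrams
  (`generateProbePair`), condition tables and `K2(T)` series, so the whole
  pipeline is testable without instrument data;
* **trace fitting** — per-injection exponential fits (`fitStep`,
  `fitAllSteps`) and the `Γ(c)` line (`gammaLineFit`);
* **inference** — paired Langmuir fit with shared saturation density
  (`langmuirPairFit`), initial-slope `kon` (`konFromSlopes`), `K2`
  extraction with delta-method or bootstrap errors, the joint kinetic fit
  (`nwJointFit`), and van't Hoff thermodynamics (`vantHoffFit`);
* **io/cli** — documented CSV/JSON formats (`readTraces`, `writeSummary`,
  …) and a subcommand interface (`nwCLI`, wrapped by
  `inst/scripts/nwbind.R`).

## Worked example

Simulate a noisy paired titration at the experimentally determined scale
(`K1 = 200` nM, `K2 = 0.16`, `kon = 1.6e-5` s⁻¹nM⁻¹, 1 % noise) and run the
full analysis:

```r
library(NestedWell)
sch  <- makeDefaultSchedule()                     # 0.08 → 50 nM, 3000 s steps
pair <- generateProbePair(K1 = 200, K2 = 0.16, kon1 = 1.6e-5, kon2 = 5e-3,
                          sigmaInf = 1000, schedule = sch, noiseSd = 10,
                          sampleDt = 10, seed = 1)
res <- analyzeProbePair(pair$specific, pair$nonspecific)
res$isotherm
#> IsothermFit (paired Langmuir, shared saturation density)
#>   Sigma_inf = 1021 +/- 28
#>   Kd specific    = 29.04 +/- 1.6 nM
#>   Kd nonspecific = 204.5 +/- 9.4 nM
#>   flags: identifiability-all-linear
res$K2
#> $K2 [1] 0.1660   $se [1] 0.0080
res$summary$dG_kcal      # -1.08 kcal/mol : free-energy gap RT ln K2
res$summary$ddG_kcal     #  1.18 kcal/mol : RT ln(Kd_ns / Kd_sp)
res$nwFit
#> NWFit (joint nested-well kinetic fit)
#>   kon1 = 1.545e-05 1/(s nM)  koff1 = 0.003037 1/s
#>   kon2 = 0.005103 1/s        koff2 = 0.0007943 1/s
#>   K1 = 196.5 nM  K2 = 0.1556  effective Kd = 26.47 nM
```

The paired isotherm recovers the generating constants within their reported
errors: the specific probe binds ~7× more strongly (`Kd ≈ 29` vs `205` nM),
yet the free-energy gap between docked and undocked bound states is only
about −1.1 kcal/mol, and `10/(1+K2) ≈ 8.6` of every 10 bound proteins are
actually docked. A temperature series decomposes that small gap:

```r
tf <- vantHoffFit(generateK2TemperatureSeries(-12.8, -38.7,
                                              relNoise = 0.05, seed = 1))
tf
#> ThermoFit (van't Hoff decomposition of K2(T))
#>   dH = -12.57 +/- 0.74 kcal/mol
#>   dS = -37.91 +/- 2.5  cal/(mol K)
#>   dG(303.15 K) = -1.08 kcal/mol over 6 temperatures
```

a textbook entropy–enthalpy compensation: a ~13 kcal/mol enthalpic gain on
docking is >90 % cancelled by the entropic cost of conformational freezing.

The same pipeline is scriptable:

```sh
Rscript inst/scripts/nwbind.R simulate --params params.json \
        --out-traces traces.csv --out-manifest manifest.json
Rscript inst/scripts/nwbind.R run-all --traces traces.csv \
        --manifest manifest.json --out summary.json --seed 1
```

## Acceptance script

`scripts/acceptance.R` recomputes, from scratch with the installed package,
the headline thermodynamic quantities of the analysis: the free-energy gap
`RT ln K2` and the docked fraction at `K2 = 0.16`, and the enthalpy and
entropy recovered by the van't Hoff regression from a noiseless synthetic
`K2(T)` series. Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Vignette

`vignettes/nested-well-analysis.Rmd` documents the model and its assumptions,
the estimators and their known biases, the synthetic-data generator's stated
world, and the numerical choices.
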