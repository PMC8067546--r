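Package: NestedWell
Title: Nested-Well Analysis of Specific and Nonspecific Protein-DNA Binding Kinetics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to disentangle specific from nonspecific transcription-factor
    binding to surface-immobilised DNA probes measured with label-free biosensors.
    Implements the nested-well sequential two-state kinetic model (closed-form
    equilibrium, double-exponential relaxation spectrum, and a numerical
    integration oracle), per-injection exponential fitting of stepwise titration
    sensorgrams, paired Langmuir isotherm fits with a shared saturation density,
    extraction of the specific-binding coefficient K2 and the kinetic rates, a
    joint kinetic fit of paired specific/nonspecific traces, and van't Hoff
    decomposition of K2(T) into enthalpy and entropy. Includes a synthetic
    sensorgram generator so the full pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'AllGenerics.R'
    'nw-model.R'
    'synthetic.R'
    'trace-fitting.R'
    'inference.R'
    'io.R'
    'pipeline.R'
    'cli.R'
    'NestedWell-package.R'
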