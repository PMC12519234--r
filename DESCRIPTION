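Package: aptfit
Title: Ligand-RNA Binding Analysis for Riboswitch Characterization
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Model fitting and simulation toolkit for the biophysical
    characterization of ligand-binding RNAs such as preQ1 riboswitch
    aptamers. Implements equilibrium fluorescence titration models (exact
    single-site quadratic isotherm with ligand depletion, cooperative Hill
    model, and a two-site binding-polynomial model), stopped-flow
    pseudo-first-order association kinetics (per-trace exponential fits,
    kobs-versus-concentration regression, derived off-rates and complex
    half-lives), continuous-variation (Job plot) stoichiometry analysis by
    tangent intersection, isothermal titration calorimetry forward models
    and fits ("set of identical sites" and "two interdependent
    non-equivalent sites" binding-polynomial models with
    injection-by-injection dilution bookkeeping), and pull-down RT-qPCR
    enrichment arithmetic. A seeded synthetic-assay generator produces
    every assay type with known ground truth so each analysis stage is
    verifiable by parameter recovery without experimental data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
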