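Package: syncomfba
Title: Community Flux Balance Analysis for Syngas-Fermenting Synthetic Co-Cultures
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for constraint-based modeling of synthetic microbial
    communities that convert CO/H2 (syngas) into carboxylic acids and
    alcohols. Reads and writes genome-scale metabolic models (SBML Level 3
    with FBC, plus a simple tabular dialect), merges single-species models
    into a community model with species-tagged compartments and a
    ratio-parametrized community biomass reaction, solves community flux
    balance analysis (cFBA) linear programs under chemostat-style
    constraints, scans feasibility over species-ratio by growth-rate grids,
    samples the flux polytope with artificial-centering hit-and-run, and
    implements chemostat mass-balance calculations (dilution rates, gas
    conversions, degree-of-reduction and carbon balances,
    Henderson-Hasselbalch undissociated-acid fractions). Ships a generator
    for a small elementally balanced three-species toy community (a CO/H2
    acetogen, an ethanol-fed propionigen, and an ethanol-driven chain
    elongator) so the full pipeline runs without external model downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
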