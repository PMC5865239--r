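Package: nitricline
Title: Nitrifier Functional Types and the Primary Nitrite Maximum in a
    1D Water-Column Ecosystem Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds electron-balanced whole-organism stoichiometries for
    ammonia- and nitrite-oxidizing chemoautotrophs from redox
    half-reactions, converts culture measurements to biomass-specific
    kinetic traits with allometric scaling between cell sizes, and embeds
    both nitrifier functional types in a nine-variable nitrogen-cycle
    ecosystem model of an idealized stratified water column (turbulent
    diffusion, light attenuation, QUICK sinking advection, fixed-step
    RK4 integration to equilibrium). Post-processing diagnostics include
    subsistence concentrations (R*) from resource-ratio competition
    theory, primary-nitrite-maximum metrics, oxidation-rate and
    cell-abundance profiles, a nitrogen budget audit, and a
    15N-tracer incubation rate calculator. A parameter-perturbation
    ensemble summarizes uncertainty envelopes around the equilibrium
    profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
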