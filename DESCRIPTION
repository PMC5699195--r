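Package: pgpflux
Title: Mass-Action Kinetic Modelling of P-Glycoprotein Drug Efflux and Its
    Inhibition by Kinase Inhibitors
Version: 0.1.0
Authors@R:
    person("Joe", "Developer", email = "dev@example.org", role = c("aut", "cre"))
Description: Simulates P-glycoprotein (P-gp) mediated efflux of paclitaxel and
    its inhibition by tyrosine kinase inhibitors (TKIs) with a mass-action
    kinetic model: thermodynamic derivation of dissociation constants from
    docking affinities and membrane partition coefficients, a 16-variable
    stiff ODE system coupling passive membrane transport to a nine-state pump
    binding lattice, scenario simulation (dose-response sweeps, mechanism
    knockouts, ATP transition points, hypothetical parameter improvements),
    and grid-search estimation of nucleotide-binding-domain dissociation
    constants from efflux-inhibition dose-response data under competitive or
    noncompetitive substrate-site assumptions. Includes a synthetic
    calcein-efflux data generator for end-to-end testing without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
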