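Package: coilglobule
Title: Coil-to-Globule Transition Analysis for Polymer-in-Water Configurations
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Trajectory analysis for the temperature- and pressure-induced
    coil-to-globule transition of a solvated PNIPAM 30-mer in four-site
    (TIP4P-family) water. Computes the mass-weighted radius of gyration,
    Shrake-Rupley solvent-accessible surface area with Bondi radii, and
    geometric hydrogen bonds under periodic boundary conditions; classifies
    hydration-shell waters into hydrophilic (amide) and hydrophobic (methyl)
    populations and their hydrogen-bond connectivity; fits Boltzmann sigmoids
    to temperature series to estimate transition temperatures and derive
    classification cutoffs; and assembles pressure-temperature phase diagrams
    with coil, globule and hydrated-globule states. Includes a deterministic
    synthetic-configuration generator (self-avoiding chains, solvation boxes,
    temperature-series ensembles with known ground truth) so the full pipeline
    is testable without molecular-dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    bio3d,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
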