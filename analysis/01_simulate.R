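#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study inputs.
#
# Two ensembles are produced under results/sim/:
#  * `atm/`  — one pressure (0.1 MPa), 7 temperatures spanning 278-308 K,
#    with a true transition midpoint of 295 K: the input for the
#    transition-temperature analysis (stages 2-4).
#  * `grid/` — a 4-pressure x 7-temperature grid whose true midpoint first
#    rises and then falls with pressure, the shape reported for PNIPAM in
#    TIP4P/Ice water: the input for the phase-diagram analysis (stage 5).
# A third output is a single fully solvated configuration at bulk density
# used by the hydration-shell analysis (stage 3).

library(coilglobule)

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("generating the atmospheric-pressure ensemble (truth: T_C = 295 K) ...")
atm_spec <- ensemble_spec(tc_true = 295, frames_per_point = 40, seed = 2026)
atm <- generate_ensemble(atm_spec, file.path(out, "atm"))
message("  ", nrow(atm$files), " state points, ", atm_spec$frames_per_point, " frames each")

message("generating the pressure-temperature grid (truth: midpoints 285/293/299/289 K) ...")
grid_spec <- ensemble_spec(
  pressures = c(0.1, 50, 200, 350),
  tc_true = c("0.1" = 285, "50" = 293, "200" = 299, "350" = 289),
  frames_per_point = 12, seed = 2027
)
grid <- generate_ensemble(grid_spec, file.path(out, "grid"))
message("  ", nrow(grid$files), " state points, ", grid_spec$frames_per_point, " frames each")

message("building a fully solvated extended chain at 0.997 g/cm^3 ...")
ch <- build_chain(compactness = 0, seed = 101)
sol <- solvate(ch$topology, ch$frame, box = 8.5, density = 0.997, seed = 101)
write_gro(sol$topology, sol$frame, file.path(out, "solvated_coil.gro"))
write_topology(sol$topology, file.path(out, "solvated_coil_topology.tsv"))
message(
  "  ", sum(sol$topology$atoms$role == "water_O"), " waters around a chain with R_G = ",
  round(radius_of_gyration(sol$frame, sol$topology), 2), " nm"
)
message("done; outputs under ", out)
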