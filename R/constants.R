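# Shared per-element constants.
#
# Bondi van der Waals radii (nm): H 0.120, C 0.170, N 0.155, O 0.152.
# Masses are standard atomic weights (u). Roles map to elements; the
# synthetic residue template carries united-atom masses for carbons with
# implicit hydrogens, while topologies built from bare coordinate files
# fall back to these per-element values.

.BONDI_RADIUS <- c(H = 0.120, C = 0.170, N = 0.155, O = 0.152)
.ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999)

.ROLE_RADIUS <- c(
  backbone_C = 0.170, carbonyl_C = 0.170, amide_N = 0.155, amide_O = 0.152,
  amide_H = 0.120, isopropyl_CH = 0.170, methyl_C = 0.170, methyl_H = 0.120,
  backbone_H = 0.120, water_O = 0.152, water_H = 0.120
)

.ROLE_MASS <- c(
  backbone_C = 12.011, carbonyl_C = 12.011, amide_N = 14.007, amide_O = 15.999,
  amide_H = 1.008, isopropyl_CH = 12.011, methyl_C = 12.011, methyl_H = 1.008,
  backbone_H = 1.008, water_O = 15.999, water_H = 1.008
)

# Molar mass of water (g/mol) and Avogadro's number, for density <-> count.
.M_WATER <- 18.015
.N_AVOGADRO <- 6.02214076e23
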