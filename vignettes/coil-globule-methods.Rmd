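---
title: "Methods: coil-to-globule transition analysis for a solvated PNIPAM 30-mer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coil-to-globule transition analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Poly(N-isopropylacrylamide) — PNIPAM — is the canonical thermoresponsive
polymer: in water a single chain is an extended, strongly hydrated coil at
low temperature and collapses into a compact, partially dehydrated globule
above a transition temperature near room temperature, the chain-level
counterpart of the LCST demixing of the solution. Simulation studies of
this transition track a small set of structural observables along
temperature (and pressure) series — the chain's radius of gyration R_G,
its solvent-accessible surface area (SASA), hydrogen-bond counts, and the
population of the first hydration shell — fit a sigmoid to the
temperature dependence, and read off a transition temperature and
classification cutoffs. The behaviour of the transition also depends on
the water model: rigid four-site models such as TIP4P/2005 and TIP4P/Ice
differ in charges, Lennard-Jones parameters and M-site offset, and shift
the transition by about 10 K.

This package implements that analysis chain as reusable, tested
components, together with a synthetic-configuration generator that
produces polymer-in-water inputs with *known* ground truth, so every
stage — file parsing, periodic geometry, observables, shell statistics,
sigmoid fits, phase-map assembly — can be validated end to end without
molecular-dynamics trajectories.

## Observables

**Radius of gyration.** `radius_of_gyration()` computes the mass-weighted
quantity sqrt(Σ m_i |r_i − r_com|² / Σ m_i). It assumes a whole molecule;
`unwrap_polymer()` makes the chain whole by shifting atoms across
periodic images along the bond graph (breadth-first, each bonded pair
placed at its minimum-image separation), and is idempotent.

**SASA.** `sasa()` is a Shrake–Rupley estimator: each solute atom carries
a sphere of radius (Bondi radius + probe radius, default probe 0.14 nm);
a deterministic Fibonacci-lattice point set (default 960 points per atom)
samples the sphere, and the atom contributes the unoccluded fraction of
its extended-sphere area. The deterministic lattice makes the estimator
reproducible and auditable against closed forms: an isolated atom gives
4πR² and two fused equal spheres give 4πR(R + d/2), both reproduced
within 1% at 960 points in the tests. Bondi radii are fixed at H 0.120,
C 0.170, N 0.155, O 0.152 nm. Hydrogens present in the topology are
surface atoms like any other; waters are excluded both as surface and as
occluders, so the area is that of the polymer against a rolling
water-sized probe. Whether the original analyses included hydrogens, and
which exact radii they used, is not derivable from the outputs alone, so
both choices are explicit arguments with the defaults above.

**Hydrogen bonds.** `find_hbonds()` enumerates (donor, H, acceptor)
triples under the geometric criterion: donor–acceptor distance strictly
below 0.35 nm and H–donor–acceptor angle strictly below 30°. The angle is
taken at the donor between the D→H and D→A vectors, the convention of the
standard trajectory tools; it is configurable through
`hbond_criterion()`. Donors are water oxygens (through both hydrogens)
and amide nitrogens (through the amide hydrogen); acceptors are water and
carbonyl oxygens. All pair distances are minimum-image, including
polymer–polymer pairs. The implementation is cross-checked in the tests
against a brute-force all-triples oracle on random periodic boxes.

## Hydration-shell statistics

`classify_shell()` partitions water molecules by the position of their
oxygen: *hydrophilic* within 0.35 nm of any amide N/O, *hydrophobic*
within 0.55 nm of any methyl carbon. The two categories may overlap; the
*first shell* is their union with each water counted once, and the *bulk*
is everything else (no intermediate zone). The hydrophobic fraction F is
|hydrophobic| / |first shell|, so F ≤ 1 by construction even for waters
in both categories — reported analyses in this literature do not state how such waters
were attributed, so this package picks the convention that keeps F a
proper fraction and documents it rather than guessing another intent.

`water_connectivity()` reports water–water hydrogen bonds per molecule
within a domain (shell or bulk). A bond between molecules A and B counts
*once*, not once per partner: typical bulk values near 1.8 bonds per
molecule under this criterion are about half the per-participant
coordination (~3.6), which indicates the once-per-bond convention is the
one behind the published tables. Bonds bridging shell and bulk are
excluded from both domains and reported separately, since their
attribution is likewise not specified.

## Transition temperature and classification

`fit_sigmoid()` fits the symmetric four-parameter logistic (Boltzmann)

y(T) = A_glob + (A_coil − A_glob) / (1 + exp((T − T_C)/w)),

by bounded Levenberg–Marquardt least squares (via minpack.lm), with
inverse-variance weights when every point carries a positive SD (the
weighting is configurable; whether the original fits were weighted is not
stated). Initialization is deterministic — plateaus from the endpoint
means, T_C at the steepest finite difference — so fits are reproducible
without a seed. A flat series, a series whose endpoint plateaus
coincide, or a fitted midpoint pinned at the search bound (10 K beyond
the data range) raises a no-transition error rather than returning a
spurious midpoint. The symmetric logistic was chosen over asymmetric
sigmoid families because it makes the inflection point coincide with the
plateau midpoint, which is exactly how the classification cutoffs are
defined below.

`estimate_tc()` averages the R_G and SASA midpoints. The quoted
uncertainty is the larger of half the |difference| of the two midpoints
and the propagated standard error of the mean — a documented convention
of this package, since published "±" values come without a formula.

`derive_cutoff()` evaluates the fitted curve at T_C, i.e. the plateau
midpoint (A_coil + A_glob)/2. Applied to R_G at atmospheric pressure this
construction yields the 1.2 nm coil/globule cutoff scale, and applied to
the shell occupancy it yields the 12.5 waters-per-residue
hydrated-globule cutoff scale used by `classify_state()`:

* coil if mean R_G ≥ 1.2 nm (the tie goes to coil, since the globule rule
  is strictly "smaller than");
* otherwise globule, and hydrated globule if the mean hydration per
  residue is ≥ 12.5 (this tie is inclusive).

`build_phase_map()` labels a (T, P) grid, reports per-pressure boundary
temperatures as the midpoint between the warmest coil point and the
coolest globule point (published phase boundaries at a finite set of
state points are guides to the eye; the midpoint is the defensible
point estimate), marks a pressure unresolved when all its points share
one label, and reruns the labeling under an alternative R_G cutoff
(default 1.1 nm) as a sensitivity check — only points with
1.1 ≤ R_G < 1.2 nm can change label.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with recorded
ground truth. It emulates the *statistical structure* of single-chain
coil–globule data — a 30-unit chain whose ensemble-mean R_G and shell
occupancy follow a logistic in temperature with a prescribed midpoint,
width, plateaus and frame noise, in a periodic box of water — and makes
no claim to force-field realism: water is geometric (rigid three-site
coordinates at the model geometry, M site implied), chains are
self-avoiding walks, and Boltzmann sampling is nowhere involved. Passing
recovery tests therefore demonstrates the correctness of the *analysis*,
not the physics of any simulation engine.

**Residue template.** One vinyl-amide repeating unit with 9 atoms: two
backbone carbons, carbonyl carbon, amide O, amide N, amide H, isopropyl
CH and two methyl carbons — exactly the role inventory the shell rules
reference (2 methyl_C, 1 amide_N, 1 amide_O per unit). Carbons with
implicit hydrogens carry united-atom masses. Bond lengths are
0.10–0.153 nm.

**Chains.** `build_chain()` grows a self-avoiding backbone walk whose
direction persistence decreases with `compactness`; above a
compactness-dependent confinement radius the walk is pulled back toward
its centroid, which produces compact globules at compactness 1
(R_G ≈ 1.0 nm on average — the packing limit of a hard self-avoiding
walk without relaxation) and stiff coils at 0 (R_G ≈ 2.0 nm).
Atacticity is approximated by a random chirality flip of the side-group
frame per residue. The self-avoidance constraint (heavy atoms ≥ 0.25 nm)
applies between non-adjacent residues; within a residue and between
bonded neighbours, chemistry forces atoms closer (the amide O···N 1-3
distance is ~0.20 nm in any realistic geometry), so those pairs are
excluded from the check.

**Solvation.** `solvate()` fills the box with waters on a jittered
lattice at the requested mass density (0.997 g/cm³ by default), removing
sites within 0.24 nm of the solute, so the water count is the
density-implied value minus the excluded sites: about 900 in a 3 nm box
and about 20,000 in the 8.5 nm box used for the full-density analyses.

**Ensembles.** `generate_ensemble()` draws, for each state point, frames
from a *two-state mixture*: a frame is either a coil or a globule, and
the number of coil frames is stratified to the logistic weight
s(T) = 1/(1 + exp((T − T_C*)/w)). Because the mixture weight enters every
ensemble mean linearly, R_G(T), SASA(T) and the shell occupancy all
follow logistics with the *same* prescribed midpoint — which is what
single-chain transition data look like, bimodal frame distributions near
T_C included. (An earlier design that scheduled a continuous compactness
and imposed only R_G produced a SASA curve whose inflection lagged the
R_G midpoint by ~2 K, because SASA responds nonlinearly to R_G; the
mixture construction removes that bias by design.) Each frame's chain is
built at the compactness calibrated for its state's R_G plateau — via a
measured, frozen compactness→mean-R_G map — and rescaled isotropically
about its centre of mass to the plateau plus Gaussian frame noise; the
rescaling makes the R_G ground truth exact at the cost of slightly
distorted bond lengths in ensemble frames (acceptable in a geometry-only
pipeline; `build_chain()` output itself is undistorted). Hydration
waters are re-placed every frame from
the bulk-density lattice restricted to the shell region, sized to a
logistic occupancy target (plateaus 12 and 5 waters per residue by
default — the capacity of the shell at bulk density bounds the coil
plateau from above at about 12.6 for an extended chain in the default
6 nm box), plus a far-from-chain bulk population that keeps the per-frame
atom count constant. Every generator is a pure function of (parameters,
seed), and manifests record all truths and seeds.

**Default problem sizes.** The package's study defaults are desk scale:
a 6 nm box, 7 temperatures spanning 278–308 K every 5 K, logistic width
2 K, R_G plateaus 1.45/0.85 nm, R_G frame noise 0.05 nm (the size of the
error bars typical of well-averaged single-chain series), 40–60 frames
per state point for midpoint estimation and 12 per state point for
phase-map labeling. At these sizes the transition midpoint is recovered
within ~1 K and the full test suite runs in well under half an hour on a
single core. The production-scale system (8.5 nm box, ~20,000–22,000 waters)
is generated for the full-density hydration analyses, where only one
configuration per seed is needed.

## What the synthetic data do and do not show

Recovery of a known midpoint, the hydrophobic-dominance bound F > 0.8,
and the shell-vs-bulk connectivity ordering validate the machinery:
geometry kernels, shell bookkeeping, fitting and classification. They do
not reproduce trajectory-derived numbers — transition temperatures of
real PNIPAM/water systems (e.g. 288.5 K vs 298.5 K for the two water
models), tabulated per-molecule connectivity values, or published
figure curves — which require the original long MD trajectories. Where
this package's statistics are applied to real trajectory data, the
file formats (GRO, multi-model PDB, a TSV topology sidecar) and the
role-mapping table in `read_configuration()` are the interface.

## Numerical choices and edge cases

* Strict "<" comparisons at both hydrogen-bond cutoffs; ties are
  excluded. R_G exactly at the cutoff labels coil; hydration exactly at
  the cutoff labels hydrated globule.
* Minimum-image displacement wraps componentwise into [−L/2, L/2); only
  orthorhombic boxes are supported and triclinic input is rejected.
* The SASA point set is a Fibonacci lattice, so doubling the point count
  changes the two-sphere test area by under 0.5%.
* Sigmoid fitting bounds: width > 0, midpoint within 10 K of the data
  range; violations raise a no-transition error.
* An empty first shell makes F undefined: the frame is flagged and
  excluded from F statistics rather than contributing 0 or 1.
* The chain generator retries placement (60 direction proposals per
  residue, up to 80 restarts with a gradually relaxed confinement
  radius) and reports the seed on failure; the ensemble generator
  retries a failed chain with a fresh recorded sub-seed.
* Analysis windows default to the trailing third of frames, the generic
  analogue of analysing the last segment of a production trajectory;
  explicit frame ranges override.

## Known limitations

* No energetics: the generator cannot exhibit genuinely
  temperature-dependent hydrogen-bond statistics or water structure; all
  temperature dependence is imposed through the compactness/occupancy
  schedules.
* The shell-occupancy plateau reachable at bulk density bounds the
  achievable hydration truth; schedules above capacity saturate.
* Only the symmetric logistic is implemented; strongly asymmetric
  transitions would bias the inflection-point cutoff construction.
* XTC/TRR/DCD binary trajectories are out of scope; conversion to
  multi-frame GRO or PDB is expected upstream.
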