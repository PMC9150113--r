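# Synthetic polymer-in-water configuration generators.
#
# Everything here is geometric: chains are self-avoiding walks decorated
# with an amide/isopropyl side group per repeating unit, waters are rigid
# three-site molecules placed by rules (lattice at a target density, or
# shell-biased placement with a known occupancy), and temperature-series
# ensembles impose a logistic-in-temperature ground truth on R_G and shell
# occupancy so that every downstream stage can be tested against known
# values. No energetics are involved. All generators are deterministic
# given (parameters, seed) and leave the caller's RNG state untouched.

# Evaluate `code` under a temporary RNG seed, restoring the global state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) rm(".Random.seed", envir = genv)
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

.runit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

.cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Repeating-unit template of the synthetic chain
#'
#' One vinyl-amide repeating unit in local coordinates (nm): two backbone
#' carbons, a carbonyl carbon with amide O and N (plus the polar amide H),
#' an isopropyl CH and its two methyl carbons -- the role inventory the
#' hydration-shell rules need (2 methyl_C, 1 amide_N, 1 amide_O per unit).
#' Carbons with implicit hydrogens carry united-atom masses; radii are
#' Bondi. The local x axis is the backbone propagation direction and the
#' side chain extends into +y.
#'
#' @return A list with `atoms` (data.frame: name, element, role, mass,
#'   radius, x, y, z), `bonds` (within-unit index pairs), `n_atoms`, and
#'   the indices of the backbone attachment atoms (`head`, `tail`).
#' @export
residue_template <- function() {
  atoms <- data.frame(
    name = c("C1", "C2", "CC", "OC", "NA1", "HN", "CH", "CG1", "CG2"),
    element = c("C", "C", "C", "O", "N", "H", "C", "C", "C"),
    role = c(
      "backbone_C", "backbone_C", "carbonyl_C", "amide_O", "amide_N",
      "amide_H", "isopropyl_CH", "methyl_C", "methyl_C"
    ),
    mass = c(14.027, 13.019, 12.011, 15.999, 14.007, 1.008, 13.019, 15.035, 15.035),
    radius = c(0.170, 0.170, 0.170, 0.152, 0.155, 0.120, 0.170, 0.170, 0.170),
    x = c(0, 0.153, 0.153, 0.058, 0.253, 0.351, 0.253, 0.378, 0.128),
    y = c(0, 0, 0.152, 0.229, 0.242, 0.222, 0.389, 0.461, 0.461),
    z = c(0, 0, 0, 0, 0, 0, 0, 0.047, 0.047),
    stringsAsFactors = FALSE
  )
  bonds <- rbind(
    c(1, 2), c(2, 3), c(3, 4), c(3, 5), c(5, 6), c(5, 7), c(7, 8), c(7, 9)
  )
  list(atoms = atoms, bonds = bonds, n_atoms = nrow(atoms), head = 1L, tail = 2L)
}

# Heavy-atom flag within the template
.template_heavy <- function(template) template$atoms$element != "H"

# Mean built R_G (nm) of a 30-unit chain as a function of compactness,
# measured once over 20 seeds per grid point and lightly monotonised.
# The ensemble generator inverts this map so that the isotropic rescale
# to the scheduled R_G target stays close to a factor of 1, keeping the
# rescaling distortion (and hence the SASA scatter) small.
.RG_BY_COMPACTNESS <- list(
  c = seq(0, 1, by = 0.1),
  rg = c(1.95, 1.89, 1.81, 1.57, 1.28, 1.18, 1.15, 1.11, 1.08, 1.05, 1.03)
)

.compactness_for_rg <- function(rg_target) {
  m <- .RG_BY_COMPACTNESS
  if (rg_target >= m$rg[1]) {
    return(0)
  }
  if (rg_target <= m$rg[length(m$rg)]) {
    return(1)
  }
  stats::approx(x = rev(m$rg), y = rev(m$c), xout = rg_target)$y
}

#' Build a self-avoiding synthetic chain
#'
#' Grows an `n`-unit chain as a self-avoiding backbone walk whose
#' step-direction persistence decreases -- and whose pull toward the chain
#' centroid increases -- with `compactness`. At `compactness` 0 the walk is
#' a stiff worm-like coil (R_G around 1.6 nm and above for 30 units); at 1
#' it collapses into a compact globule (R_G around 1 nm and below). Side
#' groups are attached per unit in a local frame with a random chirality
#' flip per residue, a coarse stand-in for atactic stereochemistry. Heavy
#' atoms of non-adjacent residues are kept at least `min_sep` apart
#' (adjacent residues and within-residue pairs are excluded from the check
#' because bonded geometry forces them closer).
#'
#' @param template A [residue_template()].
#' @param n Number of repeating units (default 30).
#' @param compactness In [0, 1]: 0 extended, 1 collapsed.
#' @param seed RNG seed.
#' @param min_sep Heavy-atom clash distance between non-adjacent residues,
#'   nm (default 0.25).
#' @return A list with `topology` (a [cg_topology()] with full polymer
#'   connectivity) and `frame` (a [cg_frame()]; the box is a generous cube
#'   around the chain, meant to be replaced by [solvate()]).
#' @export
build_chain <- function(template = residue_template(), n = 30, compactness, seed = 1,
                        min_sep = 0.25) {
  stopifnot(compactness >= 0, compactness <= 1, n >= 1)
  with_seed(seed, .build_chain_impl(template, n, compactness, seed, min_sep))
}

.build_chain_impl <- function(template, n, compactness, seed, min_sep) {
  tl <- as.matrix(template$atoms[, c("x", "y", "z")])
  heavy <- .template_heavy(template)
  step_len <- 0.153
  noise <- 0.35
  pull <- 1.6 * compactness
  persist <- 1 - compactness
  # confinement radius: the walk is pulled back toward its centroid only
  # once it strays beyond r_conf, which shrinks with compactness
  r_conf0 <- if (compactness > 1e-6) 0.56 / compactness else Inf
  max_dir_tries <- 60L
  max_restarts <- 80L
  for (restart in seq_len(max_restarts)) {
    r_conf <- r_conf0 * (1 + 0.03 * (restart - 1))
    coords <- vector("list", n)
    flips <- sample(c(1, -1), n, replace = TRUE)
    d_prev <- .runit()
    origin <- c(0, 0, 0)
    tail_pos <- NULL
    ok <- TRUE
    heavy_sofar <- NULL # heavy atoms of residues 1..i-2
    heavy_prev <- NULL # heavy atoms of residue i-1
    for (i in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(max_dir_tries)) {
        if (i == 1L) {
          d <- d_prev
        } else {
          cen <- colMeans(do.call(rbind, coords[seq_len(i - 1L)]))
          to_cen <- cen - tail_pos
          ncen <- sqrt(sum(to_cen^2))
          u_cen <- if (ncen > 1e-9) to_cen / ncen else .runit()
          # the inward pull weakens over whole-chain restarts (not over
          # per-step retries), so a rare jammed seed eventually succeeds
          # while typical seeds collapse tightly on the first attempts
          pull_eff <- if (ncen > r_conf) pull * max(0.2, 1 - (restart - 1) / 40) else 0
          noise_eff <- noise * (1 + try / 10)
          v <- persist * d_prev + noise_eff * stats::rnorm(3) + pull_eff * u_cen
          nv <- sqrt(sum(v^2))
          d <- if (nv > 1e-9) v / nv else .runit()
        }
        org <- if (i == 1L) origin else tail_pos + step_len * d
        # local frame: e1 along the walk, e2/e3 random orthonormal pair
        e1 <- d
        a <- .runit()
        e2 <- a - sum(a * e1) * e1
        ne2 <- sqrt(sum(e2^2))
        if (ne2 < 1e-6) next
        e2 <- e2 / ne2
        e3 <- .cross3(e1, e2)
        R <- cbind(e1, e2, e3 * flips[i])
        xyz <- tl %*% t(R)
        xyz <- sweep(xyz, 2, org, "+")
        if (!is.null(heavy_sofar)) {
          dmin <- min(fields_rdist_min(xyz[heavy, , drop = FALSE], heavy_sofar))
          if (dmin < min_sep) next
        }
        coords[[i]] <- xyz
        tail_pos <- xyz[template$tail, ]
        d_prev <- d
        heavy_sofar <- rbind(heavy_sofar, heavy_prev)
        heavy_prev <- xyz[heavy, , drop = FALSE]
        placed <- TRUE
        break
      }
      if (!placed) {
        ok <- FALSE
        break
      }
    }
    if (ok) {
      xyz <- do.call(rbind, coords)
      at <- template$atoms[rep(seq_len(template$n_atoms), n), ]
      at$residue <- rep(seq_len(n), each = template$n_atoms)
      rownames(at) <- NULL
      offs <- (rep(seq_len(n), each = nrow(template$bonds)) - 1L) * template$n_atoms
      bonds <- template$bonds[rep(seq_len(nrow(template$bonds)), n), ] + offs
      if (n > 1L) {
        link <- cbind(
          (seq_len(n - 1L) - 1L) * template$n_atoms + template$tail,
          seq_len(n - 1L) * template$n_atoms + template$head
        )
        bonds <- rbind(bonds, link)
      }
      top <- cg_topology(at[, c("name", "element", "role", "mass", "radius", "residue")], bonds)
      ext <- apply(xyz, 2, function(v) diff(range(v)))
      L <- max(ext) + 2
      xyz <- sweep(xyz, 2, colMeans(xyz))
      xyz <- sweep(xyz, 2, rep(L / 2, 3), "+")
      return(list(topology = top, frame = cg_frame(xyz, rep(L, 3))))
    }
  }
  stop(
    "chain placement failed after ", max_restarts, " restarts (seed = ", seed,
    ", compactness = ", compactness, ")",
    call. = FALSE
  )
}

# min distances between each row of A and the point set B (plain Euclidean,
# used during chain growth where there is no box yet)
fields_rdist_min <- function(A, B) {
  d <- matrix(0, nrow(A), nrow(B))
  for (k in 1:3) d <- d + outer(A[, k], B[, k], "-")^2
  sqrt(apply(d, 1, min))
}

# Rigid three-site water at oxygen position `O` with a random orientation.
# Returns a 3 x 3 matrix of rows O, H1, H2.
.place_water <- function(O, r_OH = 0.09572, theta_deg = 104.52) {
  half <- theta_deg * pi / 360
  e1 <- .runit()
  a <- .runit()
  e2 <- a - sum(a * e1) * e1
  n2 <- sqrt(sum(e2^2))
  while (n2 < 1e-6) {
    a <- .runit()
    e2 <- a - sum(a * e1) * e1
    n2 <- sqrt(sum(e2^2))
  }
  e2 <- e2 / n2
  h1 <- O + r_OH * (cos(half) * e1 + sin(half) * e2)
  h2 <- O + r_OH * (cos(half) * e1 - sin(half) * e2)
  rbind(O, h1, h2, deparse.level = 0)
}

.water_atoms_df <- function(n_waters, first_residue) {
  data.frame(
    name = rep(c("OW", "HW1", "HW2"), n_waters),
    element = rep(c("O", "H", "H"), n_waters),
    role = rep(c("water_O", "water_H", "water_H"), n_waters),
    mass = rep(c(15.999, 1.008, 1.008), n_waters),
    radius = rep(c(0.152, 0.120, 0.120), n_waters),
    residue = rep(seq_len(n_waters) + first_residue - 1L, each = 3L),
    stringsAsFactors = FALSE
  )
}

#' Solvate a configuration at a target density
#'
#' Fills a cubic box of side `box` with rigid three-site waters on a
#' jittered lattice at the target mass density, removing every site whose
#' oxygen would come within `clearance` (minimum image) of a solute atom.
#' The solute (if any) is centred in the box first and must fit in it. The
#' water geometry (O-H length, H-O-H angle) comes from the water model; the
#' massless M site is implied and not stored.
#'
#' @param topology,frame Solute topology and frame, or `NULL` for neat water.
#' @param box Cubic box edge, nm.
#' @param density Target water mass density, g/cm^3 (default 0.997).
#' @param model A [water_model()] (geometry source).
#' @param seed RNG seed.
#' @param clearance Minimum solute-to-water-oxygen distance, nm (default 0.24).
#' @return A list with `topology` and `frame` including the added waters.
#' @export
solvate <- function(topology = NULL, frame = NULL, box, density = 0.997,
                    model = water_model("TIP4P/2005"), seed = 1, clearance = 0.24) {
  stopifnot(box > 0, density > 0)
  with_seed(seed, .solvate_impl(topology, frame, box, density, model, clearance))
}

.solvate_impl <- function(topology, frame, box, density, model, clearance) {
  n_target <- round(density * box^3 * 1e-21 / .M_WATER * .N_AVOGADRO)
  if (n_target < 1) stop("density unattainable: box too small for a single water", call. = FALSE)
  solute_xyz <- NULL
  if (!is.null(topology)) {
    stopifnot(inherits(frame, "cg_frame"))
    ext <- apply(frame$xyz, 2, function(v) diff(range(v)))
    if (any(ext > box)) {
      stop(sprintf(
        "solute does not fit in the box: extent %.2f nm > box %.2f nm",
        max(ext), box
      ), call. = FALSE)
    }
    solute_xyz <- sweep(frame$xyz, 2, colMeans(frame$xyz))
    solute_xyz <- sweep(solute_xyz, 2, rep(box / 2, 3), "+")
  }
  m <- ceiling(n_target^(1 / 3))
  a <- box / m
  grid <- as.matrix(expand.grid(x = seq_len(m), y = seq_len(m), z = seq_len(m)))
  sites <- (grid - 0.5) * a
  pick <- sort(sample.int(nrow(sites), n_target))
  sites <- sites[pick, , drop = FALSE]
  sites <- sites + matrix(stats::runif(3 * n_target, -0.15 * a, 0.15 * a), ncol = 3)
  sites <- sites %% box
  if (!is.null(solute_xyz)) {
    keep <- rep(TRUE, nrow(sites))
    chunk <- 4000L
    for (s in seq(1L, nrow(sites), by = chunk)) {
      e <- min(s + chunk - 1L, nrow(sites))
      D <- mic_distance_matrix(sites[s:e, , drop = FALSE], solute_xyz, rep(box, 3))
      keep[s:e] <- apply(D, 1, min) >= clearance
    }
    sites <- sites[keep, , drop = FALSE]
  }
  nw <- nrow(sites)
  r_oh_nm <- model$r_OH / 10
  wxyz <- matrix(0, 3 * nw, 3)
  for (i in seq_len(nw)) {
    wxyz[(3 * i - 2):(3 * i), ] <- .place_water(sites[i, ], r_oh_nm, model$theta_HOH)
  }
  if (is.null(topology)) {
    at <- .water_atoms_df(nw, 1L)
    top <- cg_topology(at)
    return(list(topology = top, frame = cg_frame(wxyz, rep(box, 3))))
  }
  first_res <- max(topology$atoms$residue) + 1L
  at <- rbind(topology$atoms, .water_atoms_df(nw, first_res))
  rownames(at) <- NULL
  top <- cg_topology(at, topology$bonds)
  fr <- cg_frame(rbind(solute_xyz, wxyz), rep(box, 3),
    time = frame$time,
    temperature = frame$temperature, pressure = frame$pressure
  )
  list(topology = top, frame = fr)
}

#' Specification of a synthetic temperature-series ensemble
#'
#' Collects the ground truths and sizes for [generate_ensemble()]: the
#' temperature/pressure grid, the true transition midpoint per pressure,
#' the true coil/globule plateaus of R_G and of the first-shell occupancy
#' per residue, frame noise, and counts. Defaults are desk scale: a 6 nm
#' box, 7 temperatures spanning 278-308 K, shell-tracking waters plus a
#' small bulk population.
#'
#' @param n_residues Repeating units (default 30).
#' @param box Cubic box edge, nm.
#' @param temperatures Temperature grid, K.
#' @param pressures Pressure grid, MPa.
#' @param tc_true Named numeric vector of true midpoints (K), one per
#'   pressure (names = pressure values), or a single number used for all.
#' @param width_true True logistic width, K.
#' @param rg_coil,rg_glob True R_G plateaus, nm (coil > globule).
#' @param occ_coil,occ_glob True first-shell waters per residue plateaus.
#' @param noise_rg Frame-to-frame Gaussian SD of R_G, nm.
#' @param noise_occ Frame-to-frame SD of the target shell count per residue.
#' @param frames_per_point Frames per (T, P) state point.
#' @param n_bulk_waters Bulk waters added per frame.
#' @param seed Base RNG seed.
#' @return An `ensemble_spec` object (a validated list).
#' @export
ensemble_spec <- function(n_residues = 30, box = 6.0,
                          temperatures = seq(278, 308, by = 5), pressures = 0.1,
                          tc_true = 295, width_true = 2,
                          rg_coil = 1.45, rg_glob = 0.85,
                          occ_coil = 12, occ_glob = 5,
                          noise_rg = 0.05, noise_occ = 0.8,
                          frames_per_point = 50, n_bulk_waters = 150, seed = 1) {
  if (length(tc_true) == 1L && is.null(names(tc_true))) {
    tc_true <- stats::setNames(rep(tc_true, length(pressures)), pressures)
  }
  if (!all(as.character(pressures) %in% names(tc_true))) {
    stop("tc_true must provide a midpoint for every pressure", call. = FALSE)
  }
  stopifnot(rg_coil > rg_glob, occ_coil > occ_glob, width_true > 0, frames_per_point >= 1)
  obj <- list(
    n_residues = n_residues, box = box, temperatures = temperatures,
    pressures = pressures, tc_true = tc_true, width_true = width_true,
    rg_coil = rg_coil, rg_glob = rg_glob, occ_coil = occ_coil, occ_glob = occ_glob,
    noise_rg = noise_rg, noise_occ = noise_occ,
    frames_per_point = frames_per_point, n_bulk_waters = n_bulk_waters, seed = seed
  )
  class(obj) <- "ensemble_spec"
  obj
}

#' Generate a synthetic temperature-series ensemble
#'
#' For each (temperature, pressure) state point, frames are drawn from a
#' two-state mixture whose coil weight follows the logistic schedule in
#' temperature with the true midpoint of that pressure: the number of coil
#' frames is stratified to the logistic weight, each frame's chain is built
#' at the compactness calibrated for its state's R_G plateau and rescaled
#' isotropically about its centre of mass to the plateau value plus
#' Gaussian frame noise (the rescaling gives an exact, known ground truth
#' at the cost of slightly distorted bond lengths). Because the mixture
#' weight enters every observable linearly, the ensemble means of R_G,
#' SASA and shell occupancy are all logistic in temperature with the same
#' midpoint, and frame distributions are bimodal near the transition.
#' Waters are re-placed each frame: a shell population sized to the
#' state's occupancy plateau plus a bulk population that keeps the atom
#' count constant. Frames are written as multi-frame GRO per state point,
#' with a topology sidecar and a manifest recording every truth and seed
#' (including the per-point realized mixture targets `rg_target_emp`,
#' `occ_target_emp`).
#'
#' @param spec An [ensemble_spec()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly: a list with the spec fields, the file
#'   table (`files`: pressure, temperature, path) and per-state-point
#'   truths.
#' @export
generate_ensemble <- function(spec, out_dir) {
  stopifnot(inherits(spec, "ensemble_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, .generate_ensemble_impl(spec, out_dir))
}

.generate_ensemble_impl <- function(spec, out_dir) {
  template <- residue_template()
  files <- list()
  truths <- list()
  top_path <- file.path(out_dir, "topology.tsv")
  top_written <- FALSE
  n_chain_atoms <- template$n_atoms * spec$n_residues
  for (p in spec$pressures) {
    tc <- spec$tc_true[[as.character(p)]]
    for (Tk in spec$temperatures) {
      s_coil <- 1 / (1 + exp((Tk - tc) / spec$width_true))
      rg_target <- spec$rg_glob + (spec$rg_coil - spec$rg_glob) * s_coil
      occ_target <- spec$occ_glob + (spec$occ_coil - spec$occ_glob) * s_coil
      # two-state mixture: each frame is a coil or a globule, with the coil
      # count stratified to the logistic weight so the ensemble mean of
      # every observable (R_G, SASA, occupancy) is logistic in T with the
      # prescribed midpoint; frame distributions are bimodal near T_C, as
      # single-chain transition data are
      n_coil <- round(s_coil * spec$frames_per_point)
      # interleave the two states evenly along the frame sequence so any
      # contiguous analysis window sees the same mixture fraction
      cum <- round(seq_len(spec$frames_per_point) * n_coil / spec$frames_per_point)
      state_is_coil <- diff(c(0L, cum)) == 1L
      rg_emp <- (n_coil * spec$rg_coil + (spec$frames_per_point - n_coil) * spec$rg_glob) /
        spec$frames_per_point
      occ_emp <- (n_coil * spec$occ_coil + (spec$frames_per_point - n_coil) * spec$occ_glob) /
        spec$frames_per_point
      frames <- vector("list", spec$frames_per_point)
      topo <- NULL
      for (f in seq_len(spec$frames_per_point)) {
        rg_base <- if (state_is_coil[f]) spec$rg_coil else spec$rg_glob
        occ_base <- if (state_is_coil[f]) spec$occ_coil else spec$occ_glob
        # a rare placement failure at extreme compactness is retried with a
        # fresh sub-seed; the sequence of draws stays deterministic
        ch <- NULL
        for (attempt in 1:10) {
          chain_seed <- sample.int(.Machine$integer.max, 1L)
          ch <- tryCatch(
            build_chain(template, spec$n_residues, compactness = .compactness_for_rg(rg_base), seed = chain_seed),
            error = function(e) NULL
          )
          if (!is.null(ch)) break
        }
        if (is.null(ch)) stop("ensemble chain generation failed repeatedly at T = ", Tk, " K", call. = FALSE)
        rg_f <- max(0.4, rg_base + stats::rnorm(1, 0, spec$noise_rg))
        xyz <- ch$frame$xyz
        com <- colSums(xyz * ch$topology$atoms$mass) / sum(ch$topology$atoms$mass)
        rg_now <- radius_of_gyration(ch$frame, ch$topology)
        xyz <- sweep(xyz, 2, com) * (rg_f / rg_now)
        xyz <- sweep(xyz, 2, rep(spec$box / 2, 3), "+")
        occ_f <- max(0, occ_base + stats::rnorm(1, 0, spec$noise_occ))
        sol <- .place_shell_waters(
          ch$topology, xyz, spec$box,
          n_shell = round(occ_f * spec$n_residues),
          n_bulk = spec$n_bulk_waters,
          n_total = round(spec$occ_coil * spec$n_residues) + spec$n_bulk_waters
        )
        if (is.null(topo)) topo <- sol$topology
        frames[[f]] <- cg_frame(sol$xyz, rep(spec$box, 3),
          time = 5 * f,
          temperature = Tk, pressure = p
        )
      }
      path <- file.path(out_dir, sprintf("traj_P%g_T%g.gro", p, Tk))
      write_gro(topo, frames, path)
      if (!top_written) {
        write_topology(topo, top_path)
        top_written <- TRUE
      }
      files[[length(files) + 1L]] <- data.frame(
        pressure = p, temperature = Tk, path = path,
        n_frames = spec$frames_per_point
      )
      truths[[length(truths) + 1L]] <- data.frame(
        pressure = p, temperature = Tk, tc_true = tc,
        rg_target = rg_target, occ_target = occ_target,
        n_coil_frames = n_coil, rg_target_emp = rg_emp, occ_target_emp = occ_emp
      )
    }
  }
  manifest <- list(
    spec = unclass(spec),
    topology = top_path,
    files = do.call(rbind, files),
    truths = do.call(rbind, truths),
    n_chain_atoms = n_chain_atoms
  )
  .write_manifest(manifest, file.path(out_dir, "manifest.yaml"))
  invisible(manifest)
}

.write_manifest <- function(manifest, path) {
  sp <- manifest$spec
  sp$tc_true <- as.list(sp$tc_true)
  out <- list(
    spec = sp,
    topology = manifest$topology,
    n_chain_atoms = manifest$n_chain_atoms,
    files = split(manifest$files, seq_len(nrow(manifest$files))),
    truths = split(manifest$truths, seq_len(nrow(manifest$truths)))
  )
  if (requireNamespace("yaml", quietly = TRUE)) {
    yaml::write_yaml(out, path)
  } else {
    dput(out, file = sub("\\.yaml$", ".Rtxt", path))
  }
  invisible(path)
}

# Shell-biased water placement on a jittered bulk-density lattice: lattice
# sites with >= `clearance` solute clearance are classified as shell sites
# (within 0.54 nm of a methyl carbon or 0.345 nm of an amide N/O, just
# inside the classification radii) or far sites (>= 0.65 nm from the
# chain); n_shell sites are sampled from the shell population (all of them
# when the target exceeds the capacity at bulk density) and n_bulk from the
# far population. When n_total is given the bulk population is sized to
# make the total water count exactly n_total regardless of shell yield, so
# every frame of a trajectory has the same atom count.
.place_shell_waters <- function(chain_top, chain_xyz, box, n_shell, n_bulk,
                                n_total = NULL, clearance = 0.26) {
  at <- chain_top$atoms
  phob_xyz <- chain_xyz[at$role == "methyl_C", , drop = FALSE]
  phil_xyz <- chain_xyz[at$role %in% c("amide_N", "amide_O"), , drop = FALSE]
  heavy_xyz <- chain_xyz[at$element != "H", , drop = FALSE]
  bx <- rep(box, 3)
  a <- 0.31 # bulk-density lattice spacing, nm
  m <- max(2L, floor(box / a))
  a <- box / m
  g <- as.matrix(expand.grid(seq_len(m), seq_len(m), seq_len(m)))
  sites <- (g - 0.5) * a + matrix(stats::runif(3 * nrow(g), -0.12 * a, 0.12 * a), ncol = 3)
  sites <- sites %% box
  dmin_heavy <- rep(Inf, nrow(sites))
  chunk <- 4000L
  for (s in seq(1L, nrow(sites), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(sites))
    D <- mic_distance_matrix(sites[s:e, , drop = FALSE], heavy_xyz, bx)
    dmin_heavy[s:e] <- apply(D, 1, min)
  }
  clear_ok <- dmin_heavy >= clearance
  d_phob <- rep(Inf, nrow(sites))
  if (nrow(phob_xyz)) {
    D <- mic_distance_matrix(sites, phob_xyz, bx)
    d_phob <- apply(D, 1, min)
  }
  d_phil <- rep(Inf, nrow(sites))
  if (nrow(phil_xyz)) {
    D <- mic_distance_matrix(sites, phil_xyz, bx)
    d_phil <- apply(D, 1, min)
  }
  shell_sites <- which(clear_ok & (d_phob < 0.54 | d_phil < 0.345))
  far_sites <- which(dmin_heavy >= 0.65)
  take_shell <- if (length(shell_sites) > n_shell) sort(sample(shell_sites, n_shell)) else shell_sites
  placed <- length(take_shell)
  if (!is.null(n_total)) n_bulk <- max(0L, n_total - placed)
  if (length(far_sites) < n_bulk) {
    stop("bulk water placement failed: only ", length(far_sites), " far lattice sites for ",
      n_bulk, " bulk waters",
      call. = FALSE
    )
  }
  take_far <- sort(sample(far_sites, n_bulk))
  O_list <- sites[c(take_shell, take_far), , drop = FALSE]
  nw <- nrow(O_list)
  wxyz <- matrix(0, 3 * nw, 3)
  for (i in seq_len(nw)) wxyz[(3 * i - 2):(3 * i), ] <- .place_water(O_list[i, ])
  atw <- .water_atoms_df(nw, max(at$residue) + 1L)
  all_at <- rbind(at, atw)
  rownames(all_at) <- NULL
  list(
    topology = cg_topology(all_at, chain_top$bonds),
    xyz = rbind(chain_xyz, wxyz)
  )
}

#' Hydrogen-bond test fixtures
#'
#' Small configurations with analytically known or brute-force-checkable
#' hydrogen-bond sets.
#'
#' * `ideal_dimer`: two waters; the donor's hydrogen is placed so the
#'   H-donor-acceptor angle is exactly `params$angle` (degrees) at a
#'   donor-acceptor distance `params$d` (nm). The acceptor's hydrogens
#'   point away so no reciprocal bond forms.
#' * `random_box`: `params$n` waters with uniform positions and random
#'   orientations in a cubic box of side `params$L`.
#' * `shell_bulk`: a short chain with a sparse shell water population plus
#'   a dense far-from-chain water cluster, so shell connectivity is lower
#'   than bulk connectivity on average (an excluded-volume effect).
#'
#' @param kind `"ideal_dimer"`, `"random_box"` or `"shell_bulk"`.
#' @param params Named list of parameters (see above).
#' @param seed RNG seed.
#' @return A list with `topology` and `frame`.
#' @export
make_hbond_fixture <- function(kind = c("ideal_dimer", "random_box", "shell_bulk"),
                               params = list(), seed = 1) {
  kind <- match.arg(kind)
  with_seed(seed, switch(kind,
    ideal_dimer = .fixture_dimer(params),
    random_box = .fixture_random_box(params),
    shell_bulk = .fixture_shell_bulk(params)
  ))
}

.fixture_dimer <- function(params) {
  d <- if (is.null(params$d)) 0.30 else params$d
  ang <- if (is.null(params$angle)) 0 else params$angle
  L <- 3
  r_oh <- 0.09572
  ctr <- rep(L / 2, 3)
  O_d <- ctr
  O_a <- ctr + c(d, 0, 0)
  th <- ang * pi / 180
  h1 <- O_d + r_oh * c(cos(th), sin(th), 0)
  h2 <- O_d + r_oh * c(-0.26, -0.96, 0) # points away: never satisfies the angle
  # acceptor hydrogens point along +x, away from the donor
  ha1 <- O_a + r_oh * c(cos(0.912), sin(0.912), 0)
  ha2 <- O_a + r_oh * c(cos(0.912), -sin(0.912), 0)
  xyz <- rbind(O_d, h1, h2, O_a, ha1, ha2, deparse.level = 0)
  top <- cg_topology(.water_atoms_df(2L, 1L))
  list(topology = top, frame = cg_frame(xyz, rep(L, 3)))
}

.fixture_random_box <- function(params) {
  n <- if (is.null(params$n)) 50L else params$n
  L <- if (is.null(params$L)) 1.5 else params$L
  xyz <- matrix(0, 3 * n, 3)
  for (i in seq_len(n)) {
    O <- stats::runif(3, 0, L)
    xyz[(3 * i - 2):(3 * i), ] <- .place_water(O)
  }
  top <- cg_topology(.water_atoms_df(n, 1L))
  list(topology = top, frame = cg_frame(xyz, rep(L, 3)))
}

.fixture_shell_bulk <- function(params) {
  n_res <- if (is.null(params$n_residues)) 10L else params$n_residues
  box <- if (is.null(params$box)) 5 else params$box
  chain_seed <- sample.int(.Machine$integer.max, 1L)
  ch <- .build_chain_impl(residue_template(), n_res, 0.3, chain_seed, 0.25)
  xyz <- sweep(ch$frame$xyz, 2, colMeans(ch$frame$xyz))
  # push the chain toward one corner so a far bulk region exists
  xyz <- sweep(xyz, 2, rep(box * 0.3, 3), "+")
  sol <- .place_shell_waters(ch$topology, xyz, box,
    n_shell = 8L * n_res, n_bulk = 0L
  )
  # dense bulk cluster in the opposite corner: jittered lattice at high
  # local density so bulk waters hydrogen-bond frequently
  side <- 1.6
  m <- 6L
  a <- side / m
  g <- as.matrix(expand.grid(seq_len(m), seq_len(m), seq_len(m)))
  sites <- (g - 0.5) * a + box * 0.62
  sites <- sites + matrix(stats::runif(3 * nrow(sites), -0.1 * a, 0.1 * a), ncol = 3)
  wb <- matrix(0, 3 * nrow(sites), 3)
  for (i in seq_len(nrow(sites))) wb[(3 * i - 2):(3 * i), ] <- .place_water(sites[i, ])
  at <- rbind(sol$topology$atoms, .water_atoms_df(nrow(sites), max(sol$topology$atoms$residue) + 1L))
  rownames(at) <- NULL
  list(
    topology = cg_topology(at, ch$topology$bonds),
    frame = cg_frame(rbind(sol$xyz, wb), rep(box, 3))
  )
}
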