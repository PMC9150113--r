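# Per-frame structural observables: mass-weighted radius of gyration,
# Shrake-Rupley solvent-accessible surface area, and geometric hydrogen
# bonds. Distances entering pair criteria are minimum-image; R_G and SASA
# assume the polymer has been made whole (unwrap_polymer()).

#' Geometric hydrogen-bond criterion
#'
#' The acceptance rule for a (donor, hydrogen, acceptor) triple: the
#' acceptor-donor distance must be lower than `max_da_distance` and the
#' hydrogen-donor-acceptor angle (at the donor, between the D-H and D-A
#' vectors) lower than `max_hda_angle`. Both comparisons are strict.
#'
#' @param max_da_distance Maximum donor-acceptor distance in nm (default 0.35).
#' @param max_hda_angle Maximum H-donor-acceptor angle in degrees (default 30).
#' @return An object of class `hbond_criterion`.
#' @export
hbond_criterion <- function(max_da_distance = 0.35, max_hda_angle = 30) {
  if (!is.numeric(max_da_distance) || max_da_distance <= 0) stop("max_da_distance must be > 0", call. = FALSE)
  if (!is.numeric(max_hda_angle) || max_hda_angle <= 0 || max_hda_angle >= 90) {
    stop("max_hda_angle must be in (0, 90) degrees", call. = FALSE)
  }
  structure(list(max_da_distance = max_da_distance, max_hda_angle = max_hda_angle),
    class = "hbond_criterion"
  )
}

#' Mass-weighted radius of gyration
#'
#' `sqrt( sum_i m_i |r_i - r_com|^2 / sum_i m_i )` with the mass-weighted
#' centre of mass, over the selected atoms (default: all polymer atoms).
#' The selection must be whole (not split across periodic boundaries);
#' use [unwrap_polymer()] first.
#'
#' @param frame A [cg_frame()].
#' @param topology A [cg_topology()] supplying masses.
#' @param selection Integer atom indices (default: polymer atoms).
#' @return Radius of gyration in nm.
#' @export
radius_of_gyration <- function(frame, topology, selection = polymer_atoms(topology)) {
  if (!length(selection)) stop("empty selection for radius of gyration", call. = FALSE)
  m <- topology$atoms$mass[selection]
  r <- frame$xyz[selection, , drop = FALSE]
  com <- colSums(r * m) / sum(m)
  dr <- sweep(r, 2, com)
  sqrt(sum(m * rowSums(dr^2)) / sum(m))
}

# Deterministic quasi-uniform points on the unit sphere (Fibonacci lattice).
fibonacci_sphere <- function(n) {
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  r <- sqrt(pmax(0, 1 - z^2))
  ga <- pi * (3 - sqrt(5))
  phi <- (k - 1) * ga
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' For each solute atom, a quasi-uniform point set is placed on the sphere
#' of radius (Bondi radius + probe radius); the accessible fraction is the
#' fraction of points not inside any other solute atom's extended sphere,
#' and the atom contributes that fraction of its extended-sphere area.
#' Waters are excluded both as surface atoms and as occluders: the area is
#' that of the polymer against a rolling solvent probe. Hydrogen atoms, when
#' present in the topology, are included as surface atoms.
#'
#' @param frame A [cg_frame()] with the polymer whole.
#' @param topology A [cg_topology()] supplying Bondi radii (nm).
#' @param probe Probe radius in nm (default 0.14, a water-sized probe).
#' @param n_sphere_points Points per atom (default 960).
#' @param selection Atom indices forming the solute (default: polymer atoms).
#' @return Total solvent-accessible surface area in nm^2.
#' @export
sasa <- function(frame, topology, probe = 0.14, n_sphere_points = 960,
                 selection = polymer_atoms(topology)) {
  if (!length(selection)) stop("empty solute selection for SASA", call. = FALSE)
  rad <- topology$atoms$radius[selection]
  bad <- which(!is.finite(rad) | rad <= 0)
  if (length(bad)) {
    stop(
      "missing van der Waals radius for atom ", selection[bad[1]],
      " (", topology$atoms$name[selection[bad[1]]], ")",
      call. = FALSE
    )
  }
  xyz <- frame$xyz[selection, , drop = FALSE]
  R <- rad + probe
  n <- length(selection)
  pts <- fibonacci_sphere(n_sphere_points)
  # neighbour lists from the pairwise extended-sphere overlap criterion
  d2 <- as.matrix(stats::dist(xyz))^2
  total <- 0
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (R[i] + R)^2)
    nb <- nb[nb != i]
    if (!length(nb)) {
      total <- total + 4 * pi * R[i]^2
      next
    }
    P <- pts * R[i]
    P <- sweep(P, 2, xyz[i, ], "+")
    free <- rep(TRUE, n_sphere_points)
    # nearest occluders first so most points are culled early
    nb <- nb[order(d2[i, nb])]
    for (j in nb) {
      if (!any(free)) break
      dj <- sweep(P[free, , drop = FALSE], 2, xyz[j, ])
      inside <- rowSums(dj^2) < R[j]^2
      free[free] <- !inside
    }
    total <- total + mean(free) * 4 * pi * R[i]^2
  }
  total
}

# Donor table: one row per (donor heavy atom, attached hydrogen).
# Water O donates through both hydrogens; amide N through its amide H.
.donor_table <- function(topology) {
  at <- topology$atoms
  wo <- which(at$role == "water_O")
  wh <- which(at$role == "water_H")
  o_for_h <- wo[match(at$residue[wh], at$residue[wo])]
  out <- data.frame(donor = o_for_h, hydrogen = wh)
  an <- which(at$role == "amide_N")
  if (length(an)) {
    ah <- which(at$role == "amide_H")
    h_for_n <- ah[match(at$residue[an], at$residue[ah])]
    if (anyNA(h_for_n)) {
      bad <- at$residue[an[which(is.na(h_for_n))[1]]]
      stop("donor amide_N in residue ", bad, " has no attached amide_H", call. = FALSE)
    }
    out <- rbind(out, data.frame(donor = an, hydrogen = h_for_n))
  }
  out[stats::complete.cases(out), , drop = FALSE]
}

#' Find geometric hydrogen bonds
#'
#' Enumerates every (donor, hydrogen, acceptor) triple satisfying the
#' geometric criterion: donor-acceptor minimum-image distance strictly
#' below the cutoff and H-donor-acceptor angle strictly below the angular
#' cutoff. Donors are water oxygens (via both hydrogens) and polymer amide
#' nitrogens (via the amide hydrogen); acceptors are water oxygens and
#' carbonyl (amide) oxygens. Water-water pairs within the same molecule are
#' excluded. All distances are minimum-image.
#'
#' @param frame A [cg_frame()].
#' @param topology A [cg_topology()].
#' @param criterion An [hbond_criterion()].
#' @return A data.frame with columns `donor`, `hydrogen`, `acceptor`
#'   (atom indices), `distance` (nm), `angle` (degrees) and `category`
#'   (`"polymer-polymer"`, `"polymer-water"` or `"water-water"`).
#' @export
find_hbonds <- function(frame, topology, criterion = hbond_criterion()) {
  stopifnot(inherits(criterion, "hbond_criterion"))
  at <- topology$atoms
  don <- .donor_table(topology)
  acc <- which(at$role %in% c("water_O", "amide_O"))
  empty <- data.frame(
    donor = integer(0), hydrogen = integer(0), acceptor = integer(0),
    distance = numeric(0), angle = numeric(0), category = character(0)
  )
  if (!nrow(don) || !length(acc)) {
    return(empty)
  }
  # stage 1: candidate (donor heavy atom, acceptor) pairs within the
  # distance cutoff, found chunk-wise so memory stays bounded for large
  # solvated boxes
  dheavy <- unique(don$donor)
  AX <- frame$xyz[acc, , drop = FALSE]
  chunk <- max(1L, floor(8e6 / length(acc)))
  d_atom <- integer(0)
  a_atom <- integer(0)
  dist_da <- numeric(0)
  for (s in seq(1L, length(dheavy), by = chunk)) {
    e <- min(s + chunk - 1L, length(dheavy))
    D <- mic_distance_matrix(frame$xyz[dheavy[s:e], , drop = FALSE], AX, frame$box)
    hit <- which(D < criterion$max_da_distance, arr.ind = TRUE)
    if (nrow(hit)) {
      d_atom <- c(d_atom, dheavy[s:e][hit[, 1]])
      a_atom <- c(a_atom, acc[hit[, 2]])
      dist_da <- c(dist_da, D[hit])
    }
  }
  # same-molecule exclusion (covers water self-pairs; a polymer N is never
  # its own acceptor since acceptors are oxygens)
  keep <- !(at$residue[d_atom] == at$residue[a_atom] &
    at$role[d_atom] == "water_O" & at$role[a_atom] == "water_O")
  d_atom <- d_atom[keep]
  a_atom <- a_atom[keep]
  dist_da <- dist_da[keep]
  if (!length(d_atom)) {
    return(empty)
  }
  # stage 2: expand candidates over the donor's hydrogens and test all
  # angles in one vectorised pass
  ord <- order(don$donor)
  don_sorted <- don[ord, ]
  udon <- unique(don_sorted$donor)
  nmax <- nrow(frame$xyz)
  first_of <- integer(nmax)
  count_of <- integer(nmax)
  first_of[udon] <- match(udon, don_sorted$donor)
  count_of[udon] <- as.integer(tabulate(don_sorted$donor, nbins = nmax)[udon])
  nh <- count_of[d_atom]
  rep_i <- rep.int(seq_along(d_atom), nh)
  hyd_idx <- sequence(nh, from = first_of[d_atom])
  dd <- d_atom[rep_i]
  aa <- a_atom[rep_i]
  hh <- don_sorted$hydrogen[hyd_idx]
  VA <- mic_displacement(frame$xyz[dd, , drop = FALSE], frame$xyz[aa, , drop = FALSE], frame$box)
  VH <- mic_displacement(frame$xyz[dd, , drop = FALSE], frame$xyz[hh, , drop = FALSE], frame$box)
  cosang <- rowSums(VA * VH) / sqrt(rowSums(VA^2) * rowSums(VH^2))
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  sel <- ang < criterion$max_hda_angle
  if (!any(sel)) {
    return(empty)
  }
  res <- data.frame(
    donor = dd[sel], hydrogen = hh[sel], acceptor = aa[sel],
    distance = dist_da[rep_i][sel], angle = ang[sel],
    category = mapply(.hb_category, at$role[dd[sel]], at$role[aa[sel]], USE.NAMES = FALSE)
  )
  rownames(res) <- NULL
  res
}

.hb_category <- function(role_d, role_a) {
  dw <- role_d == "water_O"
  aw <- role_a == "water_O"
  if (dw && aw) "water-water" else if (!dw && !aw) "polymer-polymer" else "polymer-water"
}

#' Normalize a series to the number of repeating units
#'
#' Divides per-frame counts (e.g. polymer-polymer hydrogen bonds or shell
#' occupancies) by the number of repeating units of the chain.
#'
#' @param values Numeric vector of per-frame values.
#' @param n_residues Number of repeating units (default 30).
#' @return `values / n_residues`.
#' @export
per_residue_series <- function(values, n_residues = 30) {
  stopifnot(n_residues > 0)
  values / n_residues
}
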