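# Hydration-shell statistics: first-shell classification of waters into
# hydrophilic (amide N/O) and hydrophobic (methyl C) populations, the
# hydrophobic fraction F, and water-water hydrogen-bond connectivity per
# molecule in the shell and bulk domains.

#' Classify waters into the first hydration shell
#'
#' A water molecule is hydrophilic when its oxygen lies within `r_philic`
#' of any amide N or amide O of the polymer, and hydrophobic when its
#' oxygen lies within `r_phobic` of any methyl carbon. The two categories
#' may overlap; the first shell is their union (each water counted once)
#' and the bulk is its complement. All distances are minimum-image.
#'
#' @param frame A [cg_frame()].
#' @param topology A [cg_topology()] with amide_N, amide_O and methyl_C
#'   roles present.
#' @param r_philic Hydrophilic cutoff from amide N/O atoms, nm (default 0.35).
#' @param r_phobic Hydrophobic cutoff from methyl carbons, nm (default 0.55).
#' @return An object of class `shell_assignment`: water molecule ids
#'   (residue indices) in `hydrophilic`, `hydrophobic`, `first_shell`,
#'   `bulk`; counts; `n_per_residue` (first-shell count / number of
#'   repeating units); and `n_residues`.
#' @export
classify_shell <- function(frame, topology, r_philic = 0.35, r_phobic = 0.55) {
  stopifnot(r_philic > 0, r_phobic > 0)
  at <- topology$atoms
  philic_ref <- which(at$role %in% c("amide_N", "amide_O"))
  phobic_ref <- which(at$role == "methyl_C")
  if (!length(philic_ref) && !length(phobic_ref)) {
    stop("no polymer reference atoms (amide N/O, methyl C) in topology", call. = FALSE)
  }
  wo <- water_oxygens(topology)
  wid <- at$residue[wo]
  WX <- frame$xyz[wo, , drop = FALSE]
  near_any <- function(ref, cutoff) {
    if (!length(ref) || !length(wo)) {
      return(logical(length(wo)))
    }
    D <- mic_distance_matrix(WX, frame$xyz[ref, , drop = FALSE], frame$box)
    apply(D < cutoff, 1, any)
  }
  is_philic <- near_any(philic_ref, r_philic)
  is_phobic <- near_any(phobic_ref, r_phobic)
  n_res <- length(unique(at$residue[at$role %in% .POLYMER_ROLES]))
  shell <- is_philic | is_phobic
  obj <- list(
    frame_label = frame$time,
    hydrophilic = wid[is_philic],
    hydrophobic = wid[is_phobic],
    first_shell = wid[shell],
    bulk = wid[!shell],
    n_philic = sum(is_philic),
    n_phobic = sum(is_phobic),
    n_shell = sum(shell),
    n_bulk = sum(!shell),
    n_residues = n_res,
    n_per_residue = sum(shell) / n_res,
    r_philic = r_philic,
    r_phobic = r_phobic
  )
  class(obj) <- "shell_assignment"
  obj
}

#' @export
print.shell_assignment <- function(x, ...) {
  cat(sprintf(
    "shell_assignment: %d shell waters (%d hydrophilic, %d hydrophobic, overlap %d), %d bulk; %.2f per residue\n",
    x$n_shell, x$n_philic, x$n_phobic, x$n_philic + x$n_phobic - x$n_shell,
    x$n_bulk, x$n_per_residue
  ))
  invisible(x)
}

#' Hydrophobic fraction of the first hydration shell
#'
#' The number of waters in the first shell of methyl groups divided by the
#' total number of waters in the polymer first shell. Waters in both
#' categories count in the numerator and once in the denominator, so the
#' fraction is in [0, 1] by construction.
#'
#' @param assignment A [classify_shell()] result.
#' @return The fraction F.
#' @export
hydrophobic_fraction <- function(assignment) {
  stopifnot(inherits(assignment, "shell_assignment"))
  if (assignment$n_shell == 0L) {
    stop("hydrophobic fraction undefined: first hydration shell is empty", call. = FALSE)
  }
  assignment$n_phobic / assignment$n_shell
}

#' Water-water hydrogen-bond connectivity per molecule
#'
#' Counts unique water-water hydrogen bonds whose two partner molecules
#' both belong to the requested domain (first shell or bulk) and divides by
#' the number of waters in that domain. Each bond counts once, not once per
#' partner; bonds bridging shell and bulk are excluded from both domains
#' and reported separately.
#'
#' @param frame A [cg_frame()].
#' @param topology A [cg_topology()].
#' @param criterion An [hbond_criterion()].
#' @param domain `"first_shell"` or `"bulk"`.
#' @param assignment Optional precomputed [classify_shell()] result.
#' @return Bonds per molecule (numeric scalar), with attributes `n_bonds`,
#'   `n_molecules` and `n_cross` (shell-bulk bridging bonds).
#' @export
water_connectivity <- function(frame, topology, criterion = hbond_criterion(),
                               domain = c("first_shell", "bulk"),
                               assignment = NULL) {
  domain <- match.arg(domain)
  if (is.null(assignment)) assignment <- classify_shell(frame, topology)
  members <- assignment[[domain]]
  if (!length(members)) stop("empty domain: no waters in ", domain, call. = FALSE)
  hb <- find_hbonds(frame, topology, criterion)
  ww <- hb[hb$category == "water-water", , drop = FALSE]
  at <- topology$atoms
  # unique bonds: unordered molecule pair + specific donor/acceptor atoms can
  # produce two triples (one per donor H or reciprocal donation); a "bond"
  # here is an unordered pair of molecules joined by at least one triple
  mol_d <- at$residue[ww$donor]
  mol_a <- at$residue[ww$acceptor]
  key <- paste(pmin(mol_d, mol_a), pmax(mol_d, mol_a))
  uq <- !duplicated(key)
  mol_d <- mol_d[uq]
  mol_a <- mol_a[uq]
  in_d <- mol_d %in% members
  in_a <- mol_a %in% members
  other <- if (domain == "bulk") assignment$first_shell else assignment$bulk
  cross <- sum((mol_d %in% members & mol_a %in% other) | (mol_a %in% members & mol_d %in% other))
  n_bonds <- sum(in_d & in_a)
  structure(n_bonds / length(members),
    n_bonds = n_bonds, n_molecules = length(members), n_cross = cross
  )
}

#' Per-frame hydration time series with window statistics
#'
#' Runs [classify_shell()] (and optionally [water_connectivity()]) over a
#' trajectory and returns the per-frame table together with mean and SD
#' over an analysis window. Frames whose first shell is empty have `F`
#' recorded as NA and are excluded from the F statistics.
#'
#' @param frames List of [cg_frame()] objects.
#' @param topology A [cg_topology()].
#' @param criterion [hbond_criterion()] for the connectivity columns.
#' @param r_philic,r_phobic Shell radii, nm.
#' @param window Analysis window: `NULL` for all frames, a single fraction
#'   f in (0,1] meaning the trailing fraction of frames (e.g. 1/3 for the
#'   last third), or an integer range `c(first, last)`.
#' @param connectivity Logical: also compute shell/bulk connectivity per
#'   frame (slower; default FALSE).
#' @return A list with `table` (per-frame data.frame: time, n_shell,
#'   n_per_residue, n_philic, n_phobic, F, and optionally conn_shell,
#'   conn_bulk) and `summary` (mean and SD of each column over the window,
#'   plus the window frame indices).
#' @export
hydration_series <- function(frames, topology, criterion = hbond_criterion(),
                             r_philic = 0.35, r_phobic = 0.55,
                             window = NULL, connectivity = FALSE) {
  n <- length(frames)
  if (!n) stop("no frames", call. = FALSE)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    a <- classify_shell(frames[[i]], topology, r_philic, r_phobic)
    F_val <- if (a$n_shell > 0L) a$n_phobic / a$n_shell else NA_real_
    row <- data.frame(
      time = frames[[i]]$time, n_shell = a$n_shell,
      n_per_residue = a$n_per_residue, n_philic = a$n_philic,
      n_phobic = a$n_phobic, F = F_val
    )
    if (connectivity) {
      row$conn_shell <- if (a$n_shell > 0L) as.numeric(water_connectivity(frames[[i]], topology, criterion, "first_shell", a)) else NA_real_
      row$conn_bulk <- if (a$n_bulk > 0L) as.numeric(water_connectivity(frames[[i]], topology, criterion, "bulk", a)) else NA_real_
    }
    rows[[i]] <- row
  }
  tab <- do.call(rbind, rows)
  idx <- analysis_window(n, window)
  sub <- tab[idx, , drop = FALSE]
  num <- setdiff(names(sub), "time")
  summ <- data.frame(
    variable = num,
    mean = vapply(num, function(v) mean(sub[[v]], na.rm = TRUE), numeric(1)),
    sd = vapply(num, function(v) stats::sd(sub[[v]], na.rm = TRUE), numeric(1)),
    n = vapply(num, function(v) sum(!is.na(sub[[v]])), numeric(1)),
    row.names = NULL
  )
  list(table = tab, summary = summ, window = idx)
}

#' Resolve an analysis window into frame indices
#'
#' @param n_frames Number of frames available.
#' @param window `NULL` (all frames), a fraction f in (0,1] (trailing
#'   fraction, e.g. 1/3 keeps the last third), or `c(first, last)` frame
#'   indices.
#' @return Integer vector of retained frame indices.
#' @export
analysis_window <- function(n_frames, window = NULL) {
  if (is.null(window)) {
    return(seq_len(n_frames))
  }
  if (length(window) == 1L) {
    stopifnot(window > 0, window <= 1)
    first <- n_frames - max(1L, floor(window * n_frames)) + 1L
    return(seq.int(first, n_frames))
  }
  stopifnot(length(window) == 2L, window[1] >= 1, window[2] <= n_frames, window[1] <= window[2])
  seq.int(window[1], window[2])
}
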