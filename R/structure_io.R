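# Configuration / trajectory I/O and periodic-boundary geometry.
#
# Internal unit is nm throughout (GRO is native nm; PDB Angstrom are
# converted on read and write). Only orthorhombic boxes are supported;
# triclinic input is rejected.

.POLYMER_ROLES <- c(
  "backbone_C", "carbonyl_C", "amide_N", "amide_O", "amide_H",
  "isopropyl_CH", "methyl_C", "methyl_H", "backbone_H"
)
.WATER_ROLES <- c("water_O", "water_H")
.ALL_ROLES <- c(.POLYMER_ROLES, .WATER_ROLES)

# Default atom-name -> role map. Covers the synthetic naming scheme of this
# package plus common GROMACS water names; users can supply their own map
# for other naming schemes.
.DEFAULT_ROLE_MAP <- c(
  C1 = "backbone_C", C2 = "backbone_C", CC = "carbonyl_C",
  OC = "amide_O", NA1 = "amide_N", HN = "amide_H",
  CH = "isopropyl_CH", CG1 = "methyl_C", CG2 = "methyl_C",
  OW = "water_O", HW1 = "water_H", HW2 = "water_H"
)

#' Atom topology annotation
#'
#' A `cg_topology` holds the per-atom annotation the analyses need: atom
#' name, element, role (backbone/side-chain polymer roles or water O/H),
#' mass, van der Waals (Bondi) radius, residue index (1..n for the polymer
#' chain; each water molecule gets its own residue index after the polymer),
#' and the polymer bond list.
#'
#' @param atoms A data.frame with columns `name`, `element`, `role`, `mass`
#'   (u), `radius` (nm, Bondi), `residue` (integer).
#' @param bonds Two-column integer matrix of bonded atom-index pairs
#'   (polymer connectivity; water molecules are implicit O,H,H triples).
#' @return An object of class `cg_topology`.
#' @export
cg_topology <- function(atoms, bonds = matrix(integer(0), ncol = 2)) {
  stopifnot(is.data.frame(atoms))
  need <- c("name", "element", "role", "mass", "radius", "residue")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("topology atoms table is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  bad_role <- setdiff(unique(atoms$role), .ALL_ROLES)
  if (length(bad_role)) stop("unknown atom roles: ", paste(bad_role, collapse = ", "), call. = FALSE)
  if (any(!is.finite(atoms$mass)) || any(atoms$mass <= 0)) stop("all atom masses must be positive", call. = FALSE)
  bonds <- matrix(as.integer(bonds), ncol = 2)
  obj <- list(atoms = atoms, bonds = bonds)
  class(obj) <- "cg_topology"
  obj
}

#' @export
print.cg_topology <- function(x, ...) {
  np <- sum(x$atoms$role %in% .POLYMER_ROLES)
  nw <- sum(x$atoms$role == "water_O")
  cat(sprintf(
    "cg_topology: %d atoms (%d polymer atoms in %d residues, %d waters), %d polymer bonds\n",
    nrow(x$atoms), np,
    length(unique(x$atoms$residue[x$atoms$role %in% .POLYMER_ROLES])),
    nw, nrow(x$bonds)
  ))
  invisible(x)
}

is_water_atom <- function(topology) topology$atoms$role %in% .WATER_ROLES
polymer_atoms <- function(topology) which(topology$atoms$role %in% .POLYMER_ROLES)
water_oxygens <- function(topology) which(topology$atoms$role == "water_O")

#' Validate topology invariants
#'
#' Checks the structural invariants the analyses rely on: every repeating
#' unit has exactly 2 methyl carbons, 1 amide N and 1 amide O; each water
#' molecule is one O plus two H sharing a residue index; masses are
#' positive; and the polymer bond list connects the chain into a single
#' component.
#'
#' @param topology A [cg_topology()].
#' @return `topology`, invisibly, if valid; otherwise an error.
#' @export
validate_topology <- function(topology) {
  at <- topology$atoms
  pres <- sort(unique(at$residue[at$role %in% .POLYMER_ROLES]))
  for (r in pres) {
    sel <- at$residue == r
    if (sum(sel & at$role == "methyl_C") != 2L) stop("residue ", r, ": expected exactly 2 methyl_C atoms", call. = FALSE)
    if (sum(sel & at$role == "amide_N") != 1L) stop("residue ", r, ": expected exactly 1 amide_N atom", call. = FALSE)
    if (sum(sel & at$role == "amide_O") != 1L) stop("residue ", r, ": expected exactly 1 amide_O atom", call. = FALSE)
  }
  wres <- unique(at$residue[at$role %in% .WATER_ROLES])
  for (r in wres) {
    sel <- at$residue == r
    if (sum(sel & at$role == "water_O") != 1L || sum(sel & at$role == "water_H") != 2L) {
      stop("water residue ", r, ": expected 1 water_O + 2 water_H", call. = FALSE)
    }
  }
  poly <- polymer_atoms(topology)
  if (length(poly) && nrow(topology$bonds)) {
    comp <- .bond_components(topology$bonds, poly)
    if (length(unique(comp)) != 1L) stop("polymer bond list does not form a single connected component", call. = FALSE)
  }
  invisible(topology)
}

# Connected-component labels over the polymer bond graph (indices restricted
# to `nodes`); simple union-find.
.bond_components <- function(bonds, nodes) {
  idx <- match(nodes, nodes)
  parent <- seq_along(nodes)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  pos <- match(seq_len(max(nodes)), nodes)
  for (k in seq_len(nrow(bonds))) {
    a <- pos[bonds[k, 1]]
    b <- pos[bonds[k, 2]]
    if (is.na(a) || is.na(b)) next
    ra <- find(a)
    rb <- find(b)
    if (ra != rb) parent[ra] <- rb
  }
  vapply(seq_along(nodes), find, integer(1))
}

#' Single-configuration container
#'
#' A `cg_frame` is one configuration: an N x 3 coordinate matrix in nm, an
#' orthorhombic box (Lx, Ly, Lz in nm), a time label, and the temperature /
#' pressure labels of the parent state point (NA when unknown).
#'
#' @param xyz N x 3 numeric matrix of coordinates in nm.
#' @param box Numeric length-3 vector of box edge lengths in nm.
#' @param time Time label (ps or frame index; monotone within a trajectory).
#' @param temperature,pressure State-point labels (K, MPa), optional.
#' @return An object of class `cg_frame`.
#' @export
cg_frame <- function(xyz, box, time = 0, temperature = NA_real_, pressure = NA_real_) {
  xyz <- as.matrix(xyz)
  stopifnot(ncol(xyz) == 3L, is.numeric(xyz))
  box <- as.numeric(box)
  if (length(box) != 3L || any(!is.finite(box)) || any(box <= 0)) {
    stop("box must be three positive orthorhombic edge lengths (nm)", call. = FALSE)
  }
  structure(
    list(xyz = unname(xyz), box = box, time = time, temperature = temperature, pressure = pressure),
    class = "cg_frame"
  )
}

#' @export
print.cg_frame <- function(x, ...) {
  cat(sprintf(
    "cg_frame: %d atoms, box %.3f x %.3f x %.3f nm, t = %s\n",
    nrow(x$xyz), x$box[1], x$box[2], x$box[3], format(x$time)
  ))
  invisible(x)
}

# ---------------------------------------------------------------------------
# GRO format (fixed-column, nm)

.format_gro_block <- function(topology, frame, title = NULL) {
  at <- topology$atoms
  n <- nrow(frame$xyz)
  stopifnot(n == nrow(at))
  if (is.null(title)) title <- sprintf("coilglobule frame t= %.4f", frame$time)
  resname <- ifelse(at$role %in% .WATER_ROLES, "SOL", "PNI")
  lines <- sprintf(
    "%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
    at$residue %% 100000L, resname, substr(at$name, 1, 5), seq_len(n) %% 100000L,
    frame$xyz[, 1], frame$xyz[, 2], frame$xyz[, 3]
  )
  c(title, sprintf("%5d", n), lines, sprintf("%10.5f%10.5f%10.5f", frame$box[1], frame$box[2], frame$box[3]))
}

#' Write configurations in GRO format
#'
#' Writes one frame, or a multi-frame trajectory, in the fixed-column GRO
#' format (coordinates and box in nm). The frame time is embedded in the
#' title line as `t= <time>`.
#'
#' @param topology A [cg_topology()] (atom names and residue indices).
#' @param frames A single [cg_frame()] or a list of frames.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gro <- function(topology, frames, path) {
  if (inherits(frames, "cg_frame")) frames <- list(frames)
  out <- unlist(lapply(frames, function(fr) .format_gro_block(topology, fr)), use.names = FALSE)
  writeLines(out, path)
  invisible(path)
}

.parse_gro_block <- function(lines, offset) {
  # lines: full file vector; offset: index of the title line
  if (offset > length(lines)) return(NULL)
  title <- lines[offset]
  if (offset + 1L > length(lines)) stop("GRO parse error at line ", offset, ": truncated header", call. = FALSE)
  n <- suppressWarnings(as.integer(trimws(lines[offset + 1L])))
  if (is.na(n) || n < 0) stop("GRO parse error at line ", offset + 1L, ": bad atom count '", lines[offset + 1L], "'", call. = FALSE)
  last <- offset + 1L + n + 1L
  if (last > length(lines)) {
    stop("GRO parse error: truncated frame starting at line ", offset,
      " (need ", last - length(lines), " more lines)",
      call. = FALSE
    )
  }
  al <- lines[(offset + 2L):(offset + 1L + n)]
  residue <- suppressWarnings(as.integer(substr(al, 1, 5)))
  name <- trimws(substr(al, 11, 15))
  x <- suppressWarnings(as.numeric(substr(al, 21, 28)))
  y <- suppressWarnings(as.numeric(substr(al, 29, 36)))
  z <- suppressWarnings(as.numeric(substr(al, 37, 44)))
  bad <- which(is.na(residue) | is.na(x) | is.na(y) | is.na(z) | !nzchar(name))
  if (length(bad)) {
    stop("GRO parse error at line ", offset + 1L + bad[1], ": malformed atom record '", al[bad[1]], "'", call. = FALSE)
  }
  boxv <- suppressWarnings(as.numeric(strsplit(trimws(lines[last]), "\\s+")[[1]]))
  if (length(boxv) < 3 || any(is.na(boxv[1:3]))) {
    stop("GRO parse error at line ", last, ": missing or malformed box line", call. = FALSE)
  }
  if (length(boxv) > 3 && any(abs(boxv[-(1:3)]) > 1e-9)) {
    stop("GRO parse error at line ", last, ": triclinic box not supported", call. = FALSE)
  }
  tm <- regmatches(title, regexec("t=\\s*([-0-9.eE+]+)", title))[[1]]
  time <- if (length(tm) == 2L) as.numeric(tm[2]) else NA_real_
  list(
    residue = residue, name = name, xyz = cbind(x, y, z), box = boxv[1:3],
    time = time, next_offset = last + 1L, n = n
  )
}

.roles_from_names <- function(name, role_map, where = "") {
  role <- unname(role_map[name])
  if (anyNA(role)) {
    unk <- unique(name[is.na(role)])
    stop("unknown atom name(s) ", where, ": ", paste(utils::head(unk, 5), collapse = ", "),
      "; extend the role map to cover them",
      call. = FALSE
    )
  }
  role
}

.element_from_role <- function(role) {
  c(
    backbone_C = "C", carbonyl_C = "C", amide_N = "N", amide_O = "O",
    amide_H = "H", isopropyl_CH = "C", methyl_C = "C", methyl_H = "H",
    backbone_H = "H", water_O = "O", water_H = "H"
  )[role]
}

#' Read a single configuration (GRO or PDB)
#'
#' Reads one frame plus a partial topology (names, residues, and roles
#' resolved through an atom-name to role map). Masses, radii and the bond
#' list are not stored in either format; attach them from a topology
#' sidecar ([read_topology()]) or use the returned partial topology with
#' the default per-role values.
#'
#' @param path File path.
#' @param format `"GRO"` or `"PDB"` (default: guessed from the extension).
#' @param role_map Named character vector mapping atom names to roles.
#' @return A list with elements `topology` (partial [cg_topology()], masses
#'   and Bondi radii filled from the per-role defaults) and `frame`
#'   ([cg_frame()], coordinates in nm).
#' @export
read_configuration <- function(path, format = c("auto", "GRO", "PDB"), role_map = .DEFAULT_ROLE_MAP) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- toupper(sub(".*\\.", "", path))
    format <- if (ext == "PDB") "PDB" else "GRO"
  }
  if (format == "GRO") {
    lines <- readLines(path)
    if (!length(lines)) stop("empty GRO file: ", path, call. = FALSE)
    blk <- .parse_gro_block(lines, 1L)
    role <- .roles_from_names(blk$name, role_map, paste0("in ", path))
    frame <- cg_frame(blk$xyz, blk$box, time = ifelse(is.na(blk$time), 0, blk$time))
    top <- .partial_topology(blk$name, role, blk$residue)
    return(list(topology = top, frame = frame))
  }
  frames <- .read_pdb_frames(path, role_map)
  list(topology = frames$topology, frame = frames$frames[[1]])
}

.partial_topology <- function(name, role, residue) {
  cg_topology(data.frame(
    name = name, element = unname(.element_from_role(role)), role = role,
    mass = unname(.ROLE_MASS[role]), radius = unname(.ROLE_RADIUS[role]),
    residue = residue, stringsAsFactors = FALSE
  ))
}

#' Read a multi-frame trajectory (multi-frame GRO or multi-model PDB)
#'
#' Frames are returned in file order; time labels must be monotone
#' increasing (GRO titles carry `t=`; PDB MODEL numbers are used as times).
#' For large GRO trajectories a `callback` can be supplied: it is called as
#' `callback(frame, i)` per frame and frames are then not accumulated, so
#' the working set stays bounded.
#'
#' @inheritParams read_configuration
#' @param callback Optional function applied to each frame in turn.
#' @return A list with `topology` and `frames` (list of [cg_frame()];
#'   empty when a callback is used).
#' @export
read_trajectory <- function(path, format = c("auto", "GRO", "PDB"), role_map = .DEFAULT_ROLE_MAP,
                            callback = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- toupper(sub(".*\\.", "", path))
    format <- if (ext == "PDB") "PDB" else "GRO"
  }
  if (format == "PDB") {
    res <- .read_pdb_frames(path, role_map)
    if (!is.null(callback)) {
      for (i in seq_along(res$frames)) callback(res$frames[[i]], i)
      res$frames <- list()
    }
    return(res)
  }
  lines <- readLines(path)
  if (!length(lines)) stop("empty trajectory file: ", path, call. = FALSE)
  frames <- list()
  top <- NULL
  offset <- 1L
  i <- 0L
  last_time <- -Inf
  while (offset <= length(lines)) {
    if (!nzchar(trimws(lines[offset])) && offset == length(lines)) break
    i <- i + 1L
    blk <- tryCatch(.parse_gro_block(lines, offset), error = function(e) {
      stop("frame ", i, ": ", conditionMessage(e), call. = FALSE)
    })
    if (is.null(top)) {
      role <- .roles_from_names(blk$name, role_map, paste0("in ", path))
      top <- .partial_topology(blk$name, role, blk$residue)
    }
    tm <- if (is.na(blk$time)) i else blk$time
    if (tm <= last_time) stop("frame ", i, ": time labels not strictly increasing", call. = FALSE)
    last_time <- tm
    fr <- cg_frame(blk$xyz, blk$box, time = tm)
    if (is.null(callback)) frames[[i]] <- fr else callback(fr, i)
    offset <- blk$next_offset
  }
  if (i == 0L) stop("no frames found in ", path, call. = FALSE)
  list(topology = top, frames = frames)
}

# Multi-model PDB read via bio3d; coordinates converted Angstrom -> nm.
.read_pdb_frames <- function(path, role_map) {
  pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  name <- trimws(pdb$atom$elety)
  residue <- as.integer(pdb$atom$resno)
  role <- .roles_from_names(name, role_map, paste0("in ", path))
  top <- .partial_topology(name, role, residue)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  box <- .pdb_cryst1_box(path)
  frames <- lapply(seq_len(nrow(xyz)), function(k) {
    m <- matrix(xyz[k, ], ncol = 3, byrow = TRUE) / 10 # Angstrom -> nm
    cg_frame(m, box, time = k)
  })
  list(topology = top, frames = frames)
}

.pdb_cryst1_box <- function(path) {
  ln <- readLines(path, n = 500L)
  cr <- grep("^CRYST1", ln, value = TRUE)
  if (!length(cr)) stop("PDB file has no CRYST1 record (box required): ", path, call. = FALSE)
  a <- as.numeric(substr(cr[1], 7, 15))
  b <- as.numeric(substr(cr[1], 16, 24))
  c3 <- as.numeric(substr(cr[1], 25, 33))
  ang <- c(as.numeric(substr(cr[1], 34, 40)), as.numeric(substr(cr[1], 41, 47)), as.numeric(substr(cr[1], 48, 54)))
  if (any(abs(ang - 90) > 1e-3)) stop("triclinic PDB box not supported (angles must be 90)", call. = FALSE)
  c(a, b, c3) / 10
}

#' Write a multi-model PDB file (Angstrom)
#'
#' @param topology A [cg_topology()].
#' @param frames A [cg_frame()] or list of frames (one MODEL each).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(topology, frames, path) {
  if (inherits(frames, "cg_frame")) frames <- list(frames)
  at <- topology$atoms
  resname <- ifelse(at$role %in% .WATER_ROLES, "SOL", "PNI")
  box <- frames[[1]]$box * 10
  out <- sprintf("CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1", box[1], box[2], box[3], 90, 90, 90)
  n <- nrow(at)
  for (k in seq_along(frames)) {
    xyz <- frames[[k]]$xyz * 10
    rec <- sprintf(
      "ATOM  %5d %-4s%-4s %4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
      seq_len(n) %% 100000L, substr(at$name, 1, 4), resname, at$residue %% 10000L,
      xyz[, 1], xyz[, 2], xyz[, 3], at$element
    )
    out <- c(out, sprintf("MODEL %8d", k), rec, "ENDMDL")
  }
  writeLines(c(out, "END"), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Topology sidecar (TSV)

#' Write / read the topology sidecar
#'
#' The sidecar is a TSV with columns index, name, element, role, mass,
#' radius, residue, bonds (comma-separated partner indices), carrying the
#' annotation that GRO/PDB cannot.
#'
#' @param topology A [cg_topology()].
#' @param path File path.
#' @return `write_topology` returns `path` invisibly; `read_topology`
#'   returns a [cg_topology()].
#' @export
write_topology <- function(topology, path) {
  at <- topology$atoms
  n <- nrow(at)
  partners <- vector("list", n)
  b <- topology$bonds
  for (k in seq_len(nrow(b))) {
    partners[[b[k, 1]]] <- c(partners[[b[k, 1]]], b[k, 2])
    partners[[b[k, 2]]] <- c(partners[[b[k, 2]]], b[k, 1])
  }
  bonds_str <- vapply(partners, function(p) paste(sort(p), collapse = ","), character(1))
  df <- data.frame(
    index = seq_len(n), name = at$name, element = at$element, role = at$role,
    mass = at$mass, radius = at$radius, residue = at$residue, bonds = bonds_str,
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_topology
#' @export
read_topology <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE, colClasses = c(bonds = "character"))
  pairs <- list()
  for (i in seq_len(nrow(df))) {
    if (!nzchar(df$bonds[i]) || is.na(df$bonds[i])) next
    js <- as.integer(strsplit(df$bonds[i], ",")[[1]])
    for (j in js) if (j > i) pairs[[length(pairs) + 1L]] <- c(i, j)
  }
  bonds <- if (length(pairs)) do.call(rbind, pairs) else matrix(integer(0), ncol = 2)
  cg_topology(df[, c("name", "element", "role", "mass", "radius", "residue")], bonds)
}

# ---------------------------------------------------------------------------
# Periodic-boundary geometry

#' Minimum-image displacement vector
#'
#' Componentwise displacement from `a` to `b`, wrapped into
#' `[-L/2, L/2)` per box dimension; the minimum-image distance is the norm
#' of the result.
#'
#' @param a,b Numeric 3-vectors (nm).
#' @param box Orthorhombic box edge lengths (nm).
#' @return Numeric 3-vector, the wrapped displacement `b - a`.
#' @export
minimum_image_vector <- function(a, b, box) {
  stopifnot(all(box > 0))
  d <- b - a
  d - box * round(d / box)
}

# Vectorised minimum-image displacements: B[i,] - A[i,] (recycling a single
# row), wrapped. Used by all pair-distance computations.
mic_displacement <- function(A, B, box) {
  if (is.null(dim(A))) A <- matrix(A, nrow = max(1, NROW(B)), ncol = 3, byrow = TRUE)
  if (is.null(dim(B))) B <- matrix(B, nrow = max(1, NROW(A)), ncol = 3, byrow = TRUE)
  d <- B - A
  d - rep(box, each = nrow(d)) * round(d / rep(box, each = nrow(d)))
}

# All minimum-image distances between row sets X (n x 3) and Y (m x 3):
# returns an n x m matrix. Memory ~ 3*n*m doubles; fine at the problem
# sizes used here (<= ~10^7 pairs).
mic_distance_matrix <- function(X, Y, box) {
  n <- nrow(X)
  m <- nrow(Y)
  out <- matrix(0, n, m)
  for (k in 1:3) {
    d <- outer(X[, k], Y[, k], "-")
    d <- d - box[k] * round(d / box[k])
    out <- out + d * d
  }
  sqrt(out)
}

#' Unwrap the polymer across periodic boundaries
#'
#' Shifts polymer coordinates by lattice vectors so that every bonded pair
#' sits at its minimum-image separation, making the molecule whole. Water
#' coordinates are untouched. Idempotent on an already-whole chain.
#'
#' @param frame A [cg_frame()].
#' @param topology A [cg_topology()] whose bond list connects the polymer
#'   into a single component.
#' @return A new [cg_frame()] with the polymer whole.
#' @export
unwrap_polymer <- function(frame, topology) {
  poly <- polymer_atoms(topology)
  if (!length(poly)) {
    return(frame)
  }
  b <- topology$bonds
  if (!nrow(b)) stop("cannot unwrap: topology has no polymer bonds", call. = FALSE)
  adj <- vector("list", nrow(frame$xyz))
  for (k in seq_len(nrow(b))) {
    adj[[b[k, 1]]] <- c(adj[[b[k, 1]]], b[k, 2])
    adj[[b[k, 2]]] <- c(adj[[b[k, 2]]], b[k, 1])
  }
  xyz <- frame$xyz
  visited <- rep(FALSE, nrow(xyz))
  root <- poly[1]
  visited[root] <- TRUE
  queue <- root
  nseen <- 1L
  while (length(queue)) {
    cur <- queue[1]
    queue <- queue[-1]
    for (nb in adj[[cur]]) {
      if (!visited[nb]) {
        visited[nb] <- TRUE
        nseen <- nseen + 1L
        xyz[nb, ] <- xyz[cur, ] + minimum_image_vector(xyz[cur, ], xyz[nb, ], frame$box)
        queue <- c(queue, nb)
      }
    }
  }
  if (nseen != length(poly)) {
    stop("polymer is disconnected: reached ", nseen, " of ", length(poly), " atoms from the bond list", call. = FALSE)
  }
  out <- frame
  out$xyz <- xyz
  out
}
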