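# Four-site rigid water models (TIP4P family).
#
# Units in this file are Angstrom and elementary charge, matching the usual
# tabulation of TIP4P-family parameters; everything else in the package works
# in nm. The only derived quantity is the molecular dipole, used as an
# analytic validation surface for the parameter sets.

# 1 e*Angstrom in Debye (10^-18 esu cm)
.EA_TO_DEBYE <- 4.803

# Standard rigid TIP4P-family geometry (shared by TIP4P/2005 and TIP4P/Ice).
.TIP4P_R_OH <- 0.9572 # Angstrom
.TIP4P_THETA_HOH <- 104.52 # degrees

.WATER_MODELS <- list(
  "TIP4P/2005" = list(
    epsilon = 93.2, sigma = 3.1589, q_H = 0.5564, d_OM = 0.1546,
    mu_ref = 2.305, rho_ref = 0.9979
  ),
  "TIP4P/Ice" = list(
    epsilon = 106.1, sigma = 3.1668, q_H = 0.5897, d_OM = 0.1577,
    mu_ref = 2.426, rho_ref = 0.993
  )
)

#' Built-in four-site water model parameter sets
#'
#' Returns the parameter set of one of the two supported rigid four-site
#' water models, TIP4P/2005 or TIP4P/Ice. Both place a Lennard-Jones centre
#' on the oxygen, a positive partial charge `q_H` on each hydrogen and the
#' compensating negative charge `-2 q_H` on a massless M site displaced by
#' `d_OM` from the oxygen along the H-O-H bisector. The rigid molecular
#' geometry (O-H length 0.9572 Angstrom, H-O-H angle 104.52 degrees) is the
#' standard TIP4P-family geometry and is stored in the object so that the
#' dipole check is self-contained.
#'
#' @param name Model name, `"TIP4P/2005"` or `"TIP4P/Ice"`.
#' @return An object of class `water_model`: a list with fields `name`,
#'   `epsilon` (LJ well depth, K), `sigma` (LJ size, Angstrom), `q_H`
#'   (hydrogen charge, e), `d_OM` (O to M-site distance, Angstrom),
#'   `mu_ref` (reference dipole, Debye), `rho_ref` (reference density at
#'   298 K and 0.1 MPa, g/cm^3), `r_OH` (Angstrom) and `theta_HOH`
#'   (degrees). The LJ well depth is carried in kelvin as tabulated; no
#'   energetics are computed from it.
#' @examples
#' m <- water_model("TIP4P/2005")
#' dipole_moment(m) # ~2.305 D
#' @export
water_model <- function(name) {
  if (!is.character(name) || length(name) != 1L || !(name %in% names(.WATER_MODELS))) {
    stop(
      "unsupported water model: ", deparse(substitute(name)), " (",
      paste(format(name), collapse = ", "), "); supported models are ",
      paste(names(.WATER_MODELS), collapse = ", "),
      call. = FALSE
    )
  }
  p <- .WATER_MODELS[[name]]
  obj <- c(list(name = name), p, list(r_OH = .TIP4P_R_OH, theta_HOH = .TIP4P_THETA_HOH))
  class(obj) <- "water_model"
  validate_water_model(obj)
}

#' @export
print.water_model <- function(x, ...) {
  cat("Four-site rigid water model:", x$name, "\n")
  cat(sprintf("  epsilon   %8.4f K      (LJ well depth)\n", x$epsilon))
  cat(sprintf("  sigma     %8.4f A      (LJ size)\n", x$sigma))
  cat(sprintf("  q_H       %8.4f e      (hydrogen charge; q_M = %.4f e)\n", x$q_H, -2 * x$q_H))
  cat(sprintf("  d_OM      %8.4f A      (O to M-site distance)\n", x$d_OM))
  cat(sprintf("  r_OH      %8.4f A, theta_HOH %.2f deg (rigid geometry)\n", x$r_OH, x$theta_HOH))
  cat(sprintf("  mu_ref    %8.3f D      (tabulated dipole; computed %.3f D)\n", x$mu_ref, dipole_moment(x)))
  cat(sprintf("  rho_ref   %8.4f g/cm^3 (tabulated density, 298 K, 0.1 MPa)\n", x$rho_ref))
  invisible(x)
}

validate_water_model <- function(m) {
  stopifnot(
    m$q_H > 0, m$d_OM > 0, m$d_OM < m$r_OH,
    m$epsilon > 0, m$sigma > 0, m$r_OH > 0,
    m$theta_HOH > 0, m$theta_HOH < 180
  )
  m
}

#' Position of the massless M site
#'
#' Places the negative-charge M site of a four-site water on the H-O-H
#' bisector, on the hydrogen side of the oxygen, at distance `d_OM` from O.
#' Works in any length unit (the result is in the unit of the inputs).
#'
#' @param O,H1,H2 Numeric 3-vectors: oxygen and hydrogen positions.
#' @param d_OM O to M-site distance, in the same unit as the coordinates.
#' @return A numeric 3-vector, the M-site position.
#' @export
msite_position <- function(O, H1, H2, d_OM) {
  stopifnot(length(O) == 3L, length(H1) == 3L, length(H2) == 3L, d_OM >= 0)
  u1 <- H1 - O
  u2 <- H2 - O
  n1 <- sqrt(sum(u1^2))
  n2 <- sqrt(sum(u2^2))
  if (n1 < 1e-12 || n2 < 1e-12) {
    stop("degenerate water geometry: hydrogen coincides with oxygen", call. = FALSE)
  }
  bis <- u1 / n1 + u2 / n2
  nb <- sqrt(sum(bis^2))
  # the bisector vanishes when the two O-H bonds are anti-parallel (collinear H-O-H)
  if (nb < 1e-8) {
    stop("degenerate water geometry: H-O-H is collinear, bisector undefined", call. = FALSE)
  }
  O + d_OM * bis / nb
}

#' Molecular dipole moment of a four-site water model
#'
#' Builds the rigid molecule in a reference frame (O at the origin, bisector
#' along +z), places `+q_H` on each hydrogen and `-2 q_H` on the M site, and
#' returns the magnitude of the charge dipole `|sum q_i r_i|` converted from
#' e*Angstrom to Debye (1 e*Angstrom = 4.803 D). For the symmetric geometry
#' this equals the closed form `2 q_H (r_OH cos(theta/2) - d_OM) * 4.803`.
#'
#' @param model A [water_model()] object (full rigid geometry and charges).
#' @return Dipole moment in Debye.
#' @export
dipole_moment <- function(model) {
  if (!inherits(model, "water_model")) stop("`model` must be a water_model object", call. = FALSE)
  need <- c("q_H", "d_OM", "r_OH", "theta_HOH")
  miss <- need[!vapply(need, function(f) is.numeric(model[[f]]) && length(model[[f]]) == 1L && is.finite(model[[f]]), logical(1))]
  if (length(miss)) stop("water model is missing geometry/charge fields: ", paste(miss, collapse = ", "), call. = FALSE)
  half <- model$theta_HOH * pi / 360 # theta/2 in radians
  O <- c(0, 0, 0)
  H1 <- c(sin(half), 0, cos(half)) * model$r_OH
  H2 <- c(-sin(half), 0, cos(half)) * model$r_OH
  M <- msite_position(O, H1, H2, model$d_OM)
  q <- c(model$q_H, model$q_H, -2 * model$q_H)
  mu_vec <- q[1] * H1 + q[2] * H2 + q[3] * M
  sqrt(sum(mu_vec^2)) * .EA_TO_DEBYE
}

#' Write / read a water model as key: value text
#'
#' Serializes a [water_model()] to a small structured text file (one
#' `key: value` pair per line) so parameter sets can be inspected and
#' validated outside R, and reads such a file back.
#'
#' @param model A `water_model` object.
#' @param path File path.
#' @return `write_water_model` returns `path` invisibly; `read_water_model`
#'   returns a validated `water_model`.
#' @export
write_water_model <- function(model, path) {
  stopifnot(inherits(model, "water_model"))
  flds <- names(model)
  vals <- vapply(flds, function(f) {
    v <- model[[f]]
    if (is.character(v)) v else format(v, digits = 10)
  }, character(1))
  writeLines(paste0(flds, ": ", vals), path)
  invisible(path)
}

#' @rdname write_water_model
#' @export
read_water_model <- function(path) {
  ln <- readLines(path)
  ln <- ln[nzchar(trimws(ln))]
  kv <- regmatches(ln, regexec("^([A-Za-z_]+):\\s*(.*)$", ln))
  bad <- which(lengths(kv) != 3L)
  if (length(bad)) stop("malformed water model file at line ", bad[1], ": ", ln[bad[1]], call. = FALSE)
  keys <- vapply(kv, `[`, character(1), 2L)
  vals <- vapply(kv, `[`, character(1), 3L)
  obj <- lapply(seq_along(keys), function(i) {
    if (keys[i] == "name") vals[i] else as.numeric(vals[i])
  })
  names(obj) <- keys
  class(obj) <- "water_model"
  validate_water_model(obj)
}
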