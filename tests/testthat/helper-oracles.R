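# Independent oracles used across the suite. These deliberately share no
# code with the package internals they check: brute-force enumeration over
# periodic images and all (donor, H, acceptor) triples, and closed-form
# sphere-intersection areas.

# Minimum-image displacement by explicit minimisation over the 27
# neighbouring images.
brute_min_image <- function(a, b, box) {
  best <- Inf
  bv <- NULL
  for (i in -1:1) {
    for (j in -1:1) {
      for (k in -1:1) {
        d <- (b + c(i, j, k) * box) - a
        n2 <- sum(d^2)
        if (n2 < best) {
          best <- n2
          bv <- d
        }
      }
    }
  }
  bv
}

# All-triples hydrogen-bond enumeration under the same donor/acceptor
# chemistry the package defines (water O via both H; amide N via amide H;
# acceptors water O and amide O), returning a sorted key per bond.
brute_hbonds <- function(frame, top, crit) {
  at <- top$atoms
  don <- list()
  for (r in unique(at$residue[at$role == "water_O"])) {
    o <- which(at$residue == r & at$role == "water_O")
    for (h in which(at$residue == r & at$role == "water_H")) {
      don[[length(don) + 1]] <- c(o, h)
    }
  }
  for (r in unique(at$residue[at$role == "amide_N"])) {
    nn <- which(at$residue == r & at$role == "amide_N")
    h <- which(at$residue == r & at$role == "amide_H")
    don[[length(don) + 1]] <- c(nn, h[1])
  }
  acc <- which(at$role %in% c("water_O", "amide_O"))
  keys <- character(0)
  for (dh in don) {
    for (a in acc) {
      d <- dh[1]
      h <- dh[2]
      if (d == a) next
      if (at$role[d] == "water_O" && at$role[a] == "water_O" &&
        at$residue[d] == at$residue[a]) {
        next
      }
      va <- brute_min_image(frame$xyz[d, ], frame$xyz[a, ], frame$box)
      if (sqrt(sum(va^2)) >= crit$max_da_distance) next
      vh <- brute_min_image(frame$xyz[d, ], frame$xyz[h, ], frame$box)
      cosang <- sum(va * vh) / sqrt(sum(va^2) * sum(vh^2))
      ang <- acos(max(-1, min(1, cosang))) * 180 / pi
      if (ang < crit$max_hda_angle) keys <- c(keys, paste(d, h, a))
    }
  }
  sort(keys)
}

hbond_keys <- function(hb) sort(paste(hb$donor, hb$hydrogen, hb$acceptor))

# Exposed area of two intersecting equal spheres of radius R at centre
# distance d < 2R (spherical-cap closed form).
two_sphere_area <- function(R, d) 4 * pi * R * (R + d / 2)

# Expected water count at density rho (g/cm^3) in a cubic box of side L nm.
expected_waters <- function(rho, L) rho * L^3 * 1e-21 / 18.015 * 6.02214076e23

# Minimal hand-built topology: a few polymer atoms with given roles plus
# n_water three-site waters whose coordinates the caller supplies.
tiny_topology <- function(roles, n_water = 0) {
  poly <- data.frame(
    name = paste0("P", seq_along(roles)), element = "C", role = roles,
    mass = 12, radius = 0.17, residue = 1, stringsAsFactors = FALSE
  )
  if (n_water > 0) {
    w <- data.frame(
      name = rep(c("OW", "HW1", "HW2"), n_water),
      element = rep(c("O", "H", "H"), n_water),
      role = rep(c("water_O", "water_H", "water_H"), n_water),
      mass = rep(c(15.999, 1.008, 1.008), n_water),
      radius = rep(c(0.152, 0.120, 0.120), n_water),
      residue = rep(seq_len(n_water) + 1L, each = 3L),
      stringsAsFactors = FALSE
    )
    poly <- rbind(poly, w)
  }
  cg_topology(poly)
}

# A water (O + 2 H) laid flat in the xy plane at oxygen position `o`,
# hydrogens pointing along `dir` (unit 2-vector-ish in xy).
flat_water <- function(o, dir = c(1, 0, 0)) {
  dir <- dir / sqrt(sum(dir^2))
  perp <- c(-dir[2], dir[1], 0)
  half <- 104.52 * pi / 360
  r <- 0.09572
  rbind(
    o,
    o + r * (cos(half) * dir + sin(half) * perp),
    o + r * (cos(half) * dir - sin(half) * perp),
    deparse.level = 0
  )
}
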