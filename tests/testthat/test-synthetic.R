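test_that("chain construction counts, bonds and clash rule hold", {
  tpl <- residue_template()
  ch <- build_chain(tpl, n = 30, compactness = 0.5, seed = 17)
  expect_equal(nrow(ch$frame$xyz), 30 * tpl$n_atoms)
  expect_silent(validate_topology(ch$topology))

  # every bonded distance equals the template bond length
  b <- ch$topology$bonds
  d <- sqrt(rowSums((ch$frame$xyz[b[, 1], ] - ch$frame$xyz[b[, 2], ])^2))
  expect_true(all(d > 0.09 & d < 0.17))
  tl <- as.matrix(tpl$atoms[, c("x", "y", "z")])
  ref <- sqrt(rowSums((tl[tpl$bonds[, 1], ] - tl[tpl$bonds[, 2], ])^2))
  intra <- d[seq_len(nrow(tpl$bonds) * 30)]
  expect_equal(intra, rep(ref, 30), tolerance = 0.01)

  # heavy atoms of non-adjacent residues stay >= 0.25 nm apart
  at <- ch$topology$atoms
  heavy <- which(at$element != "H")
  xyz <- ch$frame$xyz[heavy, ]
  res <- at$residue[heavy]
  D <- as.matrix(dist(xyz))
  sep <- abs(outer(res, res, "-")) >= 2
  expect_gte(min(D[sep]), 0.25)
})

test_that("compactness separates extended from collapsed conformations", {
  rg_at <- function(compactness, s) {
    ch <- build_chain(compactness = compactness, seed = s)
    radius_of_gyration(ch$frame, ch$topology)
  }
  rg <- sapply(1:20, function(s) c(rg_at(0, s), rg_at(1, s)))
  expect_true(all(rg[1, ] > rg[2, ])) # same-seed ordering, every seed
  expect_gt(mean(rg[1, ]), 1.6) # extended coil
  expect_lte(mean(rg[2, ]), 1.05) # collapsed globule, R_G around 1 nm and below
})

test_that("chain generation is deterministic given the seed", {
  a <- build_chain(compactness = 0.4, seed = 99)
  b <- build_chain(compactness = 0.4, seed = 99)
  expect_identical(a$frame$xyz, b$frame$xyz)
  c2 <- build_chain(compactness = 0.4, seed = 100)
  expect_false(identical(a$frame$xyz, c2$frame$xyz))
})

test_that("solvation hits the density-implied water count and keeps clearance", {
  s <- solvate(NULL, NULL, box = 3, density = 0.997, seed = 2)
  nw <- sum(s$topology$atoms$role == "water_O")
  expect_lt(abs(nw - expected_waters(0.997, 3)), 18)

  ch <- build_chain(n = 10, compactness = 0.5, seed = 4)
  sol <- solvate(ch$topology, ch$frame, box = 4, density = 0.997, seed = 4)
  wo <- which(sol$topology$atoms$role == "water_O")
  solute <- which(!sol$topology$atoms$role %in% c("water_O", "water_H"))
  # no water oxygen within the clearance of any solute atom
  dmin <- min(coilglobule:::mic_distance_matrix(
    sol$frame$xyz[wo, ], sol$frame$xyz[solute, ], sol$frame$box
  ))
  expect_gte(dmin, 0.24)

  # seeding contract: different coordinates, same count within 2%
  s2 <- solvate(NULL, NULL, box = 3, density = 0.997, seed = 3)
  nw2 <- sum(s2$topology$atoms$role == "water_O")
  expect_false(identical(s$frame$xyz, s2$frame$xyz))
  expect_lt(abs(nw2 - nw) / nw, 0.02)

  # counts scale as L^3 at fixed density
  counts <- sapply(c(2, 3, 4), function(L) {
    sum(solvate(NULL, NULL, box = L, density = 0.997, seed = 1)$topology$atoms$role == "water_O")
  })
  expect_equal(counts / expected_waters(0.997, c(2, 3, 4)), rep(1, 3), tolerance = 0.02)

  big <- build_chain(n = 30, compactness = 0, seed = 2)
  expect_error(solvate(big$topology, big$frame, box = 2, density = 0.997), "does not fit")
  expect_error(solvate(NULL, NULL, box = 0.2, density = 0.997), "unattainable")
})

test_that("ensembles are reproducible and impose the scheduled ground truth", {
  spec <- ensemble_spec(
    temperatures = seq(283, 303, 5), frames_per_point = 3,
    n_bulk_waters = 40, seed = 5, noise_rg = 0, noise_occ = 0
  )
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  m1 <- generate_ensemble(spec, d1)
  m2 <- generate_ensemble(spec, d2)
  for (i in seq_len(nrow(m1$files))) {
    expect_identical(readLines(m1$files$path[i]), readLines(m2$files$path[i])) # same seed, same bytes
  }

  # zero frame noise: measured mean R_G equals the realized mixture target
  top <- read_topology(m1$topology)
  for (i in seq_len(nrow(m1$files))) {
    tr <- read_trajectory(m1$files$path[i])
    rgs <- vapply(tr$frames, function(fr) {
      radius_of_gyration(unwrap_polymer(fr, top), top)
    }, numeric(1))
    expect_equal(mean(rgs), m1$truths$rg_target_emp[i], tolerance = 1e-3)
  }
  # scheduled mean R_G decreases monotonically with temperature
  ord <- order(m1$truths$temperature)
  expect_true(all(diff(m1$truths$rg_target[ord]) <= 0))
})

test_that("hydrogen-bond fixtures have their stated properties", {
  dz <- make_hbond_fixture("ideal_dimer", list(d = 0.30, angle = 0))
  expect_equal(nrow(find_hbonds(dz$frame, dz$topology)), 1L)

  # shell connectivity below bulk connectivity on average (excluded volume)
  diffs <- sapply(1:4, function(s) {
    fx <- make_hbond_fixture("shell_bulk", list(n_residues = 8), seed = s)
    a <- classify_shell(fx$frame, fx$topology)
    cs <- as.numeric(water_connectivity(fx$frame, fx$topology, domain = "first_shell", assignment = a))
    cb <- as.numeric(water_connectivity(fx$frame, fx$topology, domain = "bulk", assignment = a))
    cb - cs
  })
  expect_gt(mean(diffs), 0)
})
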