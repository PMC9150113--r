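test_that("radius of gyration matches hand geometry and is rigid-motion invariant", {
  top2 <- tiny_topology(c("backbone_C", "backbone_C"))
  f <- cg_frame(rbind(c(1, 1, 1), c(1.4, 1, 1)), c(5, 5, 5))
  expect_equal(radius_of_gyration(f, top2, 1:2), 0.2) # symmetric dumbbell: d/2

  top1 <- tiny_topology("backbone_C")
  expect_equal(radius_of_gyration(cg_frame(matrix(c(1, 2, 3), 1), c(5, 5, 5)), top1, 1), 0)

  top4 <- tiny_topology(rep("backbone_C", 4))
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)) + 1
  expect_equal(radius_of_gyration(cg_frame(sq, c(5, 5, 5)), top4, 1:4), sqrt(2) / 2)

  expect_error(radius_of_gyration(f, top2, integer(0)), "empty")

  # rigid motion invariance and linear scaling
  set.seed(3)
  pts <- matrix(stats::runif(30, 0, 2), ncol = 3)
  topn <- tiny_topology(rep("backbone_C", 10))
  rg0 <- radius_of_gyration(cg_frame(pts, c(9, 9, 9)), topn, 1:10)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3, byrow = TRUE)
  moved <- pts %*% t(R) + 2
  expect_equal(radius_of_gyration(cg_frame(moved, c(9, 9, 9)), topn, 1:10), rg0)
  expect_equal(radius_of_gyration(cg_frame(pts * 2.5, c(9, 9, 9)), topn, 1:10), rg0 * 2.5)
})

test_that("SASA reproduces closed forms and converges with the point count", {
  top1 <- tiny_topology("amide_O")
  top1$atoms$radius <- 0.152
  f1 <- cg_frame(matrix(c(1, 1, 1), 1), c(4, 4, 4))
  expect_equal(sasa(f1, top1, selection = 1), 4 * pi * 0.292^2, tolerance = 0.01)

  # two identical extended spheres: isolated when far apart, cap formula when fused
  R <- 0.31
  topc <- tiny_topology(c("backbone_C", "backbone_C"))
  topc$atoms$radius <- R - 0.14
  far <- cg_frame(rbind(c(1, 1, 1), c(2.5, 1, 1)), c(6, 6, 6))
  expect_equal(sasa(far, topc, selection = 1:2), 2 * 4 * pi * R^2, tolerance = 0.01)
  d <- 0.3
  near <- cg_frame(rbind(c(1, 1, 1), c(1 + d, 1, 1)), c(6, 6, 6))
  a960 <- sasa(near, topc, selection = 1:2, n_sphere_points = 960)
  expect_equal(a960, two_sphere_area(R, d), tolerance = 0.01)
  a1920 <- sasa(near, topc, selection = 1:2, n_sphere_points = 1920)
  expect_lt(abs(a1920 - a960) / a960, 0.005)

  bad <- topc
  bad$atoms$radius[2] <- NA
  expect_error(sasa(near, bad, selection = 1:2), "radius for atom 2")
})

test_that("hydrogen-bond detection applies both strict cutoffs", {
  crit <- hbond_criterion()
  dz <- make_hbond_fixture("ideal_dimer", list(d = 0.30, angle = 0))
  hb <- find_hbonds(dz$frame, dz$topology, crit)
  expect_equal(nrow(hb), 1L)
  expect_equal(hb$category, "water-water")
  expect_equal(hb$distance, 0.30, tolerance = 1e-9)

  # distance beyond the cutoff fails
  far <- make_hbond_fixture("ideal_dimer", list(d = 0.36, angle = 0))
  expect_equal(nrow(find_hbonds(far$frame, far$topology, crit)), 0L)
  just_out <- make_hbond_fixture("ideal_dimer", list(d = 0.3501, angle = 0))
  expect_equal(nrow(find_hbonds(just_out$frame, just_out$topology, crit)), 0L)
  # angle just outside fails, just inside passes
  at30 <- make_hbond_fixture("ideal_dimer", list(d = 0.30, angle = 30.5))
  expect_equal(nrow(find_hbonds(at30$frame, at30$topology, crit)), 0L)
  at29 <- make_hbond_fixture("ideal_dimer", list(d = 0.30, angle = 29.5))
  expect_equal(nrow(find_hbonds(at29$frame, at29$topology, crit)), 1L)

  expect_error(hbond_criterion(max_hda_angle = 95), "degrees")
  expect_error(hbond_criterion(max_da_distance = -1), "> 0")
})

test_that("hydrogen-bond sets equal the brute-force oracle on random periodic boxes", {
  crit <- hbond_criterion()
  for (s in 1:6) {
    fx <- make_hbond_fixture("random_box", list(n = 40, L = 1.4), seed = s)
    expect_equal(hbond_keys(find_hbonds(fx$frame, fx$topology, crit)),
      brute_hbonds(fx$frame, fx$topology, crit),
      info = paste("seed", s)
    )
  }
})

test_that("hydrogen-bond set is invariant under atom relabeling", {
  crit <- hbond_criterion()
  fx <- make_hbond_fixture("random_box", list(n = 30, L = 1.3), seed = 12)
  hb <- find_hbonds(fx$frame, fx$topology, crit)
  # permute whole molecules (keeps O,H,H grouping but reorders molecules)
  set.seed(1)
  n_mol <- max(fx$topology$atoms$residue)
  perm <- sample(n_mol)
  new_order <- unlist(lapply(perm, function(r) which(fx$topology$atoms$residue == r)))
  top2 <- cg_topology(within(fx$topology$atoms[new_order, ], residue <- rep(seq_len(n_mol), each = 3L)))
  fr2 <- cg_frame(fx$frame$xyz[new_order, ], fx$frame$box)
  hb2 <- find_hbonds(fr2, top2, crit)
  # map back to original indices and compare the triple sets
  back <- match(seq_len(nrow(fx$frame$xyz)), new_order)
  remapped <- sort(paste(new_order[hb2$donor], new_order[hb2$hydrogen], new_order[hb2$acceptor]))
  expect_equal(remapped, hbond_keys(hb))
  expect_true(!is.null(back))
})

test_that("per-residue normalization is linear and commutes with the mean", {
  expect_equal(per_residue_series(60), 2)
  expect_equal(per_residue_series(0), 0)
  x <- c(10, 20, 40)
  expect_equal(mean(per_residue_series(x)), per_residue_series(mean(x)))
})
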