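# Shell classification rules on hand-placed waters, the hydrophobic
# fraction, and the water-water connectivity statistic with its
# bond-counting convention.

shell_fixture <- function() {
  # polymer: one amide N at (1,1,1), one amide O far away, two methyl C at
  # (3,1,1) and far; waters hand-placed relative to those
  roles <- c("amide_N", "amide_O", "methyl_C", "methyl_C")
  top <- tiny_topology(roles, n_water = 4)
  poly <- rbind(
    c(1, 1, 1), # N
    c(6, 6, 6), # amide O (far corner)
    c(3, 1, 1), # methyl
    c(6, 6, 1) # methyl (far)
  )
  w1 <- flat_water(c(1.30, 1, 1)) # 0.30 from N, 1.70/… from methyls -> hydrophilic only
  w2 <- flat_water(c(3.50, 1, 1)) # 0.50 from methyl, 2.50 from N   -> hydrophobic only
  w3 <- flat_water(c(1, 1.30, 1) + c(0, 0, 0)) # 0.30 from N; dist to methyl (3,1,1) = 2.02 -> philic
  w4 <- flat_water(c(4.9, 4.9, 4.9)) # bulk
  xyz <- rbind(poly, w1, w2, w3, w4)
  list(topology = top, frame = cg_frame(xyz, c(8, 8, 8)))
}

test_that("shell classification applies the two-radius rule with union semantics", {
  fx <- shell_fixture()
  a <- classify_shell(fx$frame, fx$topology)
  expect_equal(a$n_philic, 2L)
  expect_equal(a$n_phobic, 1L)
  expect_equal(a$n_shell, 3L)
  expect_equal(a$n_bulk, 1L)

  # a water near both reference sets is in both categories, counted once
  both <- shell_fixture()
  # move w2's oxygen to 0.30 from N and 0.50 from the methyl at (3,1,1):
  # place at (2.55, 1, 1): 1.55 from N (no) — instead craft a geometry where
  # N and methyl are 0.7 apart
  roles <- c("amide_N", "amide_O", "methyl_C", "methyl_C")
  top <- tiny_topology(roles, n_water = 1)
  poly <- rbind(c(1, 1, 1), c(6, 6, 6), c(1.7, 1, 1), c(6, 6, 1))
  w <- flat_water(c(1.3, 1, 1)) # 0.30 from N and 0.40 from methyl
  a2 <- classify_shell(cg_frame(rbind(poly, w), c(8, 8, 8)), top)
  expect_equal(a2$n_philic, 1L)
  expect_equal(a2$n_phobic, 1L)
  expect_equal(a2$n_shell, 1L) # union counts the water once
  expect_equal(hydrophobic_fraction(a2), 1)

  no_poly <- cg_topology(fx$topology$atoms[fx$topology$atoms$role %in% c("water_O", "water_H"), ])
  expect_error(classify_shell(fx$frame, no_poly), "no polymer")
})

test_that("hydrophobic fraction is |hydrophobic| / |first shell| and fails on an empty shell", {
  fx <- shell_fixture()
  a <- classify_shell(fx$frame, fx$topology)
  expect_equal(hydrophobic_fraction(a), 1 / 3)
  # push the radii down so the shell is empty
  a_empty <- classify_shell(fx$frame, fx$topology, r_philic = 0.01, r_phobic = 0.01)
  expect_error(hydrophobic_fraction(a_empty), "empty")
})

test_that("shell membership is monotone in the radii and F stays in [0,1]", {
  fx <- make_hbond_fixture("shell_bulk", list(n_residues = 8), seed = 3)
  radii_phob <- c(0.35, 0.45, 0.55, 0.65)
  prev <- -1
  for (r in radii_phob) {
    a <- classify_shell(fx$frame, fx$topology, r_phobic = r)
    expect_gte(a$n_phobic, prev)
    expect_gte(a$n_shell, a$n_phobic)
    f <- hydrophobic_fraction(a)
    expect_gte(f, 0)
    expect_lte(f, 1)
    prev <- a$n_phobic
  }
  # first-shell count is monotone in the hydrophilic radius too
  a1 <- classify_shell(fx$frame, fx$topology, r_philic = 0.25)
  a2 <- classify_shell(fx$frame, fx$topology, r_philic = 0.45)
  expect_gte(a2$n_shell, a1$n_shell)
})

test_that("water connectivity counts each bond once and matches the oracle", {
  # two waters forming one bond, plus a distant polymer so the bulk domain
  # is well defined
  top <- tiny_topology(c("carbonyl_C", "amide_O", "methyl_C", "methyl_C"), n_water = 2)
  poly <- rbind(c(6, 6, 6), c(6, 6.5, 6), c(6.5, 6, 6), c(6, 6, 6.5))
  wd <- flat_water(c(1, 1, 1), dir = c(1, 0, 0))
  u <- (wd[2, ] - wd[1, ]) / sqrt(sum((wd[2, ] - wd[1, ])^2)) # along one O-H bond
  wa <- flat_water(c(1, 1, 1) + 0.30 * u, dir = u) # acceptor O on the H direction; its H point away
  fr <- cg_frame(rbind(poly, wd, wa), c(8, 8, 8))
  a <- classify_shell(fr, top)
  expect_equal(a$n_bulk, 2L)
  conn <- water_connectivity(fr, top, domain = "bulk", assignment = a)
  expect_equal(as.numeric(conn), 0.5) # 1 unique bond / 2 molecules
  expect_equal(attr(conn, "n_bonds"), 1L)
  expect_error(water_connectivity(fr, top, domain = "first_shell", assignment = a), "empty domain")

  # random dense box: per-molecule value equals unique oracle bonds / N
  crit <- hbond_criterion()
  for (s in 1:3) {
    fx <- make_hbond_fixture("random_box", list(n = 40, L = 1.4), seed = s)
    topx <- rbind(
      data.frame(
        name = "P", element = "C", role = "methyl_C", mass = 12,
        radius = 0.17, residue = 0L, stringsAsFactors = FALSE
      ),
      fx$topology$atoms
    )
    top_all <- cg_topology(topx)
    fr_all <- cg_frame(rbind(c(10, 10, 10), fx$frame$xyz), c(20, 20, 20))
    # enlarge box so every water is bulk (far from the lone polymer atom)
    a_all <- classify_shell(fr_all, top_all)
    expect_equal(a_all$n_bulk, 40L)
    conn <- water_connectivity(fr_all, top_all, crit, "bulk", a_all)
    keys <- brute_hbonds(fr_all, top_all, crit)
    # oracle triples -> unique molecule pairs
    parts <- do.call(rbind, strsplit(keys, " "))
    mol <- matrix(top_all$atoms$residue[as.integer(parts)], ncol = 3)
    upairs <- unique(paste(pmin(mol[, 1], mol[, 3]), pmax(mol[, 1], mol[, 3])))
    expect_equal(as.numeric(conn), length(upairs) / 40)
  }
})

test_that("summing per-molecule connectivity over the domain recovers the unique bond count", {
  fx <- make_hbond_fixture("shell_bulk", list(n_residues = 8), seed = 5)
  a <- classify_shell(fx$frame, fx$topology)
  for (dom in c("first_shell", "bulk")) {
    conn <- water_connectivity(fx$frame, fx$topology, domain = dom, assignment = a)
    expect_equal(as.numeric(conn) * attr(conn, "n_molecules"), attr(conn, "n_bonds"))
  }
})

test_that("hydration series respects the analysis window and propagates per-frame values", {
  fx <- shell_fixture()
  frames <- lapply(1:6, function(i) {
    fr <- fx$frame
    fr$time <- i
    fr
  })
  hs <- hydration_series(frames, fx$topology, window = NULL)
  expect_equal(nrow(hs$table), 6L)
  expect_equal(hs$summary$sd[hs$summary$variable == "n_shell"], 0) # constant occupancy
  expect_equal(
    hs$summary$mean[hs$summary$variable == "n_per_residue"],
    hs$summary$mean[hs$summary$variable == "n_shell"] / 1
  ) # one polymer residue here

  hs2 <- hydration_series(frames, fx$topology, window = c(4, 6))
  expect_equal(hs2$window, 4:6)
  expect_equal(analysis_window(9, 1 / 3), 7:9)
  expect_equal(analysis_window(5, NULL), 1:5)
})
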