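test_that("GRO write/read round-trips coordinates to format precision", {
  ch <- build_chain(n = 2, compactness = 0.2, seed = 3)
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(ch$topology, ch$frame, path)
  back <- read_configuration(path, format = "GRO")
  expect_equal(nrow(back$frame$xyz), nrow(ch$frame$xyz))
  expect_equal(back$topology$atoms$name, ch$topology$atoms$name)
  expect_equal(back$frame$xyz, ch$frame$xyz, tolerance = 1e-3)
  expect_equal(back$frame$box, ch$frame$box, tolerance = 1e-5)
})

test_that("PDB round-trip converts Angstrom to nm", {
  ch <- build_chain(n = 2, compactness = 0.2, seed = 4)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ch$topology, ch$frame, path)
  back <- read_configuration(path, format = "PDB")
  expect_equal(back$frame$xyz, ch$frame$xyz, tolerance = 1e-3)
  expect_equal(back$topology$atoms$role, ch$topology$atoms$role)
})

test_that("malformed GRO input is rejected with a line reference", {
  path <- withr::local_tempfile(fileext = ".gro")
  ch <- build_chain(n = 1, compactness = 0, seed = 1)
  lines <- readLines(write_gro(ch$topology, ch$frame, path))
  # drop the final box line
  writeLines(lines[-length(lines)], path)
  expect_error(read_configuration(path), "box|truncated")
  writeLines(character(0), path)
  expect_error(read_configuration(path), "empty")
  # triclinic box line (nonzero off-diagonal entries)
  writeLines(c(lines[-length(lines)], "   3.0   3.0   3.0   0.0   0.0   1.2   0.0   0.0   0.0"), path)
  expect_error(read_configuration(path), "triclinic")
})

test_that("multi-frame trajectories keep file order, demand monotone times, and stream via callback", {
  ch <- build_chain(n = 2, compactness = 0.2, seed = 5)
  frames <- lapply(1:3, function(i) {
    fr <- ch$frame
    fr$time <- 5 * i
    fr$xyz <- fr$xyz + 0.01 * i
    fr
  })
  path <- withr::local_tempfile(fileext = ".gro")
  write_gro(ch$topology, frames, path)
  tr <- read_trajectory(path)
  expect_length(tr$frames, 3)
  times <- vapply(tr$frames, function(f) f$time, numeric(1))
  expect_true(all(diff(times) > 0))

  seen <- integer(0)
  out <- read_trajectory(path, callback = function(fr, i) seen <<- c(seen, i))
  expect_equal(seen, 1:3)
  expect_length(out$frames, 0) # bounded working set: nothing accumulated

  # truncated final frame names the frame index
  lines <- readLines(path)
  writeLines(lines[1:(length(lines) - 2)], path)
  expect_error(read_trajectory(path), "frame 3")

  writeLines(character(0), path)
  expect_error(read_trajectory(path), "empty")
})

test_that("minimum image wraps into [-L/2, L/2) and matches 27-image brute force", {
  expect_equal(
    sqrt(sum(minimum_image_vector(c(0.1, 0, 0), c(8.4, 0, 0), rep(8.5, 3))^2)),
    0.2,
    tolerance = 1e-12
  )
  expect_equal(minimum_image_vector(c(1, 2, 3), c(1, 2, 3), rep(5, 3)), c(0, 0, 0))
  set.seed(7)
  box <- c(3, 3, 3)
  for (i in 1:200) {
    a <- stats::runif(3, 0, 3)
    b <- stats::runif(3, 0, 3)
    got <- minimum_image_vector(a, b, box)
    ref <- brute_min_image(a, b, box)
    expect_equal(sqrt(sum(got^2)), sqrt(sum(ref^2)), tolerance = 1e-12)
    expect_lte(sqrt(sum(got^2)), sqrt(3) / 2 * 3 + 1e-12)
  }
})

test_that("unwrapping makes the polymer whole and is idempotent", {
  ch <- build_chain(n = 10, compactness = 0.2, seed = 9)
  box <- ch$frame$box
  wrapped <- ch$frame
  wrapped$xyz <- wrapped$xyz %% rep(box, each = nrow(wrapped$xyz))
  un <- unwrap_polymer(wrapped, ch$topology)
  b <- ch$topology$bonds
  dmax <- max(sqrt(rowSums((un$xyz[b[, 1], ] - un$xyz[b[, 2], ])^2)))
  expect_lt(dmax, 0.2)
  un2 <- unwrap_polymer(un, ch$topology)
  expect_equal(un2$xyz, un$xyz)
  # disconnected polymer is refused
  broken <- ch$topology
  broken$bonds <- broken$bonds[-15, , drop = FALSE]
  expect_error(unwrap_polymer(wrapped, broken), "disconnected")
})

test_that("topology sidecar round-trips atoms and bonds", {
  ch <- build_chain(n = 3, compactness = 0.3, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_topology(ch$topology, path)
  back <- read_topology(path)
  expect_equal(back$atoms$role, ch$topology$atoms$role)
  expect_equal(back$atoms$mass, ch$topology$atoms$mass)
  key <- function(b) sort(paste(pmin(b[, 1], b[, 2]), pmax(b[, 1], b[, 2])))
  expect_equal(key(back$bonds), key(ch$topology$bonds))
  expect_silent(validate_topology(back))
})

test_that("topology invariants are enforced", {
  ch <- build_chain(n = 2, compactness = 0.2, seed = 6)
  bad <- ch$topology
  bad$atoms$role[which(bad$atoms$role == "methyl_C")[1]] <- "backbone_C"
  expect_error(validate_topology(bad), "methyl_C")
  expect_error(
    cg_topology(data.frame(
      name = "X", element = "C", role = "not_a_role",
      mass = 1, radius = 0.1, residue = 1
    )),
    "unknown atom roles"
  )
})
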