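logistic <- function(T, A_coil, A_glob, T_C, w) {
  A_glob + (A_coil - A_glob) / (1 + exp((T - T_C) / w))
}

test_that("sigmoid fit recovers noiseless model data exactly", {
  Tg <- seq(278, 308, by = 5)
  y <- logistic(Tg, 1.6, 0.8, 295, 2)
  fit <- fit_sigmoid(temperature_series("R_G", Tg, y))
  expect_true(fit$converged)
  expect_equal(fit$T_C, 295, tolerance = 0.1)
  expect_equal(fit$A_coil, 1.6, tolerance = 1e-3)
  expect_equal(fit$A_glob, 0.8, tolerance = 1e-3)
  expect_equal(fit$w, 2, tolerance = 0.01)
})

test_that("degenerate series are refused", {
  Tg <- seq(278, 308, by = 5)
  expect_error(fit_sigmoid(temperature_series("R_G", Tg, rep(1.2, 7))), "flat")
  expect_error(fit_sigmoid(temperature_series("R_G", Tg[1:3], c(1, 2, 3))), "at least 4")
  expect_error(temperature_series("R_G", c(280, 280, 290, 300), 1:4), "strictly increasing")
  expect_error(temperature_series("R_G", Tg, rnorm(7), sd = rep(-1, 7)), ">= 0")
})

test_that("noiseless recovery holds across random parameter draws", {
  set.seed(21)
  Tg <- seq(278, 308, by = 3)
  for (i in 1:20) {
    A_coil <- runif(1, 1.2, 2.0)
    A_glob <- runif(1, 0.5, 1.0)
    T_C <- runif(1, 285, 300)
    w <- runif(1, 1, 4)
    fit <- fit_sigmoid(temperature_series("x", Tg, logistic(Tg, A_coil, A_glob, T_C, w)))
    expect_equal(fit$T_C, T_C, tolerance = 0.05)
    expect_equal(fit$w, w, tolerance = 0.05)
    expect_equal(derive_cutoff(fit), (A_coil + A_glob) / 2, tolerance = 1e-3)
    # inflection value equals the curve at the midpoint
    expect_equal(predict(fit, fit$T_C), derive_cutoff(fit), tolerance = 1e-9)
  }
})

test_that("noisy replicates recover the midpoint within half a kelvin on average", {
  set.seed(33)
  Tg <- seq(278, 308, by = 5)
  truth <- logistic(Tg, 1.6, 0.8, 295, 2)
  noise_sd <- 0.05 * diff(range(truth))
  est <- replicate(100, {
    y <- truth + rnorm(length(Tg), 0, noise_sd)
    fit <- tryCatch(fit_sigmoid(temperature_series("R_G", Tg, y, sd = rep(noise_sd, length(Tg)))),
      error = function(e) NULL
    )
    if (is.null(fit)) NA_real_ else fit$T_C
  })
  est <- est[!is.na(est)]
  expect_gt(length(est), 90)
  expect_lt(abs(mean(est) - 295), 0.5)
  expect_lt(sd(est), 2)
})

test_that("transition temperature is the symmetric average of the two midpoints", {
  Tg <- seq(278, 308, by = 5)
  f1 <- fit_sigmoid(temperature_series("R_G", Tg, logistic(Tg, 1.6, 0.8, 297, 2)))
  f2 <- fit_sigmoid(temperature_series("SASA", Tg, logistic(Tg, 55, 45, 300, 2)))
  tc <- estimate_tc(f1, f2)
  expect_equal(tc$tc, 298.5, tolerance = 0.1)
  expect_gte(tc$uncertainty, abs(f1$T_C - f2$T_C) / 2 - 1e-9)
  tc_rev <- estimate_tc(f2, f1)
  expect_equal(tc_rev$tc, tc$tc)
  expect_equal(tc_rev$uncertainty, tc$uncertainty)
  expect_error(estimate_tc(f1, "not a fit"), "converged")
})

test_that("inflection-point cutoffs come out at the plateau midpoint", {
  Tg <- seq(278, 308, by = 5)
  f <- fit_sigmoid(temperature_series("R_G", Tg, logistic(Tg, 1.6, 0.8, 295, 2)))
  expect_equal(derive_cutoff(f), 1.2, tolerance = 1e-3)
  fh <- fit_sigmoid(temperature_series("hydration", Tg, logistic(Tg, 17, 8, 295, 2)))
  expect_equal(derive_cutoff(fh), 12.5, tolerance = 1e-3)
  fs <- fit_sigmoid(temperature_series("x", Tg, logistic(Tg, 0.7, -0.7, 295, 2)))
  expect_equal(derive_cutoff(fs), 0, tolerance = 1e-3)
})

test_that("state classification follows the rules and is monotone in R_G", {
  expect_equal(classify_state(1.30, 14), "coil")
  expect_equal(classify_state(1.20, 14), "coil") # tie at the cutoff stays coil
  expect_equal(classify_state(1.10, 13.0), "hydrated_globule")
  expect_equal(classify_state(1.10, 12.5), "hydrated_globule") # hydration tie is inclusive
  expect_equal(classify_state(1.10, 10), "globule")
  # monotone: raising R_G can only move globule -> coil
  ord <- c(globule = 0, hydrated_globule = 0, coil = 1)
  for (h in c(5, 12.5, 20)) {
    labs <- classify_state(seq(0.8, 1.6, by = 0.05), h)
    expect_true(all(diff(ord[labs]) >= 0))
  }
})

test_that("phase map recovers boundaries, flags unresolved pressures, and bounds the sensitivity set", {
  grid <- expand.grid(pressure = c(0.1, 50, 200, 350), temperature = seq(278, 308, 5))
  tc_of_p <- c("0.1" = 285, "50" = 293, "200" = 299, "350" = 289) # rises then falls
  grid$mean_rg <- logistic(grid$temperature, 1.45, 0.85, tc_of_p[as.character(grid$pressure)], 2)
  grid$mean_hydration <- logistic(grid$temperature, 14, 6, tc_of_p[as.character(grid$pressure)], 2)
  pm <- build_phase_map(grid)
  b <- pm$boundary$t_boundary[match(c(0.1, 50, 200, 350), pm$boundary$pressure)]
  expect_true(all(pm$boundary$resolved))
  expect_gt(b[2], b[1])
  expect_gt(b[3], b[2])
  expect_lt(b[4], b[3])

  # all-coil grid: unresolved boundaries, no crash
  flat <- grid
  flat$mean_rg <- 1.5
  pm2 <- build_phase_map(flat)
  expect_true(all(!pm2$boundary$resolved))
  expect_true(all(is.na(pm2$boundary$t_boundary)))

  # moving the cutoff 1.2 -> 1.1 changes labels only where 1.1 <= R_G < 1.2
  changed <- pm$sensitivity
  expect_true(all(changed$mean_rg >= 1.1 & changed$mean_rg < 1.2))
  unchanged <- pm$map[pm$map$label == pm$map$alt_label, ]
  expect_true(all(unchanged$mean_rg < 1.1 | unchanged$mean_rg >= 1.2))

  expect_error(build_phase_map(grid[grid$pressure == 0.1, ]), "at least 2 pressures")
})
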