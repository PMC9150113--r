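# Transition-temperature estimation and phase-diagram assembly.
#
# The sigmoid family is the symmetric four-parameter logistic (Boltzmann)
#   y(T) = A_glob + (A_coil - A_glob) / (1 + exp((T - T_C)/w)),
# so the low-temperature plateau is A_coil, the high-temperature plateau is
# A_glob, the inflection point sits at T_C and the observable value there
# is (A_coil + A_glob)/2 — which is exactly how the classification cutoffs
# (1.2 nm for R_G, 12.5 waters per residue for hydration) are derived.

#' Temperature series of an observable
#'
#' @param observable Observable name (e.g. `"R_G"`, `"SASA"`).
#' @param temperature Strictly increasing temperatures, K.
#' @param mean,sd Per-temperature mean and standard deviation.
#' @param n_frames Frames behind each mean (optional).
#' @param pressure Pressure label, MPa.
#' @return An object of class `temperature_series` (a data.frame with
#'   attributes `observable` and `pressure`).
#' @export
temperature_series <- function(observable, temperature, mean, sd = rep(0, length(mean)),
                               n_frames = rep(NA_integer_, length(mean)), pressure = NA_real_) {
  stopifnot(length(temperature) == length(mean), length(sd) == length(mean))
  if (is.unsorted(temperature, strictly = TRUE)) {
    stop("temperatures must be strictly increasing", call. = FALSE)
  }
  if (any(sd < 0)) stop("standard deviations must be >= 0", call. = FALSE)
  df <- data.frame(temperature = temperature, mean = mean, sd = sd, n_frames = n_frames)
  attr(df, "observable") <- observable
  attr(df, "pressure") <- pressure
  class(df) <- c("temperature_series", "data.frame")
  df
}

.boltzmann <- function(T, A_coil, A_glob, T_C, w) {
  A_glob + (A_coil - A_glob) / (1 + exp((T - T_C) / w))
}

#' Fit a Boltzmann sigmoid to a temperature series
#'
#' Least-squares fit of the symmetric logistic, weighted by 1/SD^2 when all
#' SDs are positive (set `weighted = FALSE` to disable). Initialization is
#' deterministic: plateaus from the means of the two endpoint pairs, T_C at
#' the steepest finite difference, width a quarter of the grid spacing
#' scale. The midpoint is constrained to within 10 K of the data range and
#' the width to be positive.
#'
#' @param series A [temperature_series()] (or data.frame with columns
#'   `temperature`, `mean`, `sd`); at least 4 points.
#' @param weighted Use inverse-variance weights when all SDs > 0.
#' @return An object of class `sigmoid_fit`: `A_coil`, `A_glob`, `T_C`,
#'   `w`, `se` (named standard errors), `converged`, `resid_norm`,
#'   `observable`, `pressure`.
#' @export
fit_sigmoid <- function(series, weighted = TRUE) {
  if (nrow(series) < 4L) stop("need at least 4 temperature points to fit a sigmoid", call. = FALSE)
  T <- series$temperature
  y <- series$mean
  s <- series$sd
  rng <- diff(range(y))
  if (rng <= .Machine$double.eps^0.5 * max(1, abs(mean(y)))) {
    stop("no transition detectable: observable series is flat", call. = FALSE)
  }
  ne <- max(2L, min(3L, floor(length(T) / 3)))
  A_coil0 <- mean(y[seq_len(ne)])
  A_glob0 <- mean(y[seq.int(length(y) - ne + 1L, length(y))])
  if (abs(A_coil0 - A_glob0) < 1e-3 * rng) {
    stop("no transition detectable: endpoint plateaus coincide", call. = FALSE)
  }
  slopes <- abs(diff(y) / diff(T))
  k <- which.max(slopes)
  T_C0 <- (T[k] + T[k + 1]) / 2
  w0 <- max(diff(range(T)) / 20, mean(diff(T)) / 4)
  # inverse-variance weights, with SDs floored at 20% of the largest SD so
  # an under-dispersed point (small-sample SD estimate) cannot dominate
  wts <- if (weighted && all(s > 0)) 1 / pmax(s, 0.2 * max(s))^2 else rep(1, length(y))
  dat <- data.frame(T = T, y = y)
  # a width below a quarter of the grid spacing is unidentifiable on the
  # grid (the sigmoid degenerates to a step and the gradient vanishes)
  w_min <- max(1e-3, mean(diff(T)) / 4)
  lower <- c(-Inf, -Inf, min(T) - 10, w_min)
  upper <- c(Inf, Inf, max(T) + 10, 10 * diff(range(T)))
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A_glob + (A_coil - A_glob) / (1 + exp((T - T_C) / w)),
      data = dat,
      start = list(A_coil = A_coil0, A_glob = A_glob0, T_C = T_C0, w = w0),
      lower = c(A_coil = lower[1], A_glob = lower[2], T_C = lower[3], w = lower[4]),
      upper = c(A_coil = upper[1], A_glob = upper[2], T_C = upper[3], w = upper[4]),
      weights = wts,
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) stop("sigmoid fit did not converge (no transition?)", call. = FALSE)
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"], error = function(e) rep(NA_real_, 4))
  # a midpoint pinned at the box bound means the data do not bracket a
  # transition
  if (cf[["T_C"]] <= min(T) - 10 + 1e-6 || cf[["T_C"]] >= max(T) + 10 - 1e-6) {
    stop("no transition within the temperature range: fitted midpoint at bound", call. = FALSE)
  }
  obj <- list(
    A_coil = unname(cf[["A_coil"]]), A_glob = unname(cf[["A_glob"]]),
    T_C = unname(cf[["T_C"]]), w = unname(cf[["w"]]),
    se = c(
      A_coil = unname(se[["A_coil"]]), A_glob = unname(se[["A_glob"]]),
      T_C = unname(se[["T_C"]]), w = unname(se[["w"]])
    ),
    converged = TRUE,
    resid_norm = sqrt(sum(stats::residuals(fit)^2)),
    observable = attr(series, "observable"),
    pressure = attr(series, "pressure")
  )
  class(obj) <- "sigmoid_fit"
  obj
}

#' @export
print.sigmoid_fit <- function(x, ...) {
  cat(sprintf(
    "sigmoid_fit [%s%s]: T_C = %.2f +/- %.2f K, width %.2f K, plateaus %.3f (coil) -> %.3f (globule)\n",
    if (is.null(x$observable)) "?" else x$observable,
    if (is.na(x$pressure)) "" else sprintf(" @ %g MPa", x$pressure),
    x$T_C, x$se[["T_C"]], x$w, x$A_coil, x$A_glob
  ))
  invisible(x)
}

#' Predict from a sigmoid fit
#' @param object A `sigmoid_fit`.
#' @param temperature Temperatures, K.
#' @param ... Unused.
#' @export
predict.sigmoid_fit <- function(object, temperature, ...) {
  .boltzmann(temperature, object$A_coil, object$A_glob, object$T_C, object$w)
}

#' Transition temperature from the R_G and SASA fits
#'
#' The transition temperature is the arithmetic mean of the two sigmoid
#' midpoints. The quoted uncertainty is the larger of (a) half the absolute
#' difference between the two midpoints and (b) the standard error of the
#' mean propagated from the per-fit midpoint standard errors.
#'
#' @param fit_rg,fit_sasa Converged [fit_sigmoid()] results.
#' @return A list with `tc` (K), `uncertainty` (K) and the two midpoints.
#' @export
estimate_tc <- function(fit_rg, fit_sasa) {
  for (f in list(fit_rg, fit_sasa)) {
    if (!inherits(f, "sigmoid_fit") || !isTRUE(f$converged)) {
      stop("estimate_tc requires two converged sigmoid fits", call. = FALSE)
    }
  }
  tcs <- c(fit_rg$T_C, fit_sasa$T_C)
  half_diff <- abs(diff(tcs)) / 2
  prop <- sqrt(sum(c(fit_rg$se[["T_C"]], fit_sasa$se[["T_C"]])^2, na.rm = TRUE)) / 2
  list(tc = mean(tcs), uncertainty = max(half_diff, prop), tc_rg = tcs[1], tc_sasa = tcs[2])
}

#' Classification cutoff from a sigmoid inflection point
#'
#' The observable value at the fitted midpoint; for the symmetric logistic
#' this is the plateau average (A_coil + A_glob)/2. Applied to the R_G fit
#' at atmospheric pressure this yields the coil/globule cutoff; applied to
#' the hydration fit it yields the hydrated-globule cutoff.
#'
#' @param fit A converged [fit_sigmoid()] result.
#' @return The cutoff value, in the observable's unit.
#' @export
derive_cutoff <- function(fit) {
  if (!inherits(fit, "sigmoid_fit") || !isTRUE(fit$converged)) {
    stop("derive_cutoff requires a converged sigmoid fit", call. = FALSE)
  }
  (fit$A_coil + fit$A_glob) / 2
}

#' Classify a state point as coil, globule or hydrated globule
#'
#' Coil when the window-averaged R_G is greater than or equal to the R_G
#' cutoff; otherwise globule; a globule whose mean hydration per repeating
#' unit is equal to or greater than the hydration cutoff is a hydrated
#' globule.
#'
#' @param mean_rg Mean radius of gyration, nm.
#' @param mean_hydration Mean first-shell waters per repeating unit.
#' @param rg_cutoff R_G cutoff, nm (default 1.2).
#' @param hyd_cutoff Hydration cutoff per residue (default 12.5).
#' @return `"coil"`, `"globule"` or `"hydrated_globule"` (vectorized).
#' @export
classify_state <- function(mean_rg, mean_hydration, rg_cutoff = 1.2, hyd_cutoff = 12.5) {
  ifelse(mean_rg >= rg_cutoff, "coil",
    ifelse(mean_hydration >= hyd_cutoff, "hydrated_globule", "globule")
  )
}

#' Assemble a pressure-temperature phase map
#'
#' Labels every (T, P) state point with [classify_state()], reports the
#' per-pressure boundary temperature (midpoint between the warmest coil
#' point and the coolest globule point), and reruns the labeling with an
#' alternative R_G cutoff as a sensitivity check.
#'
#' @param states A data.frame with columns `pressure` (MPa), `temperature`
#'   (K), `mean_rg` (nm) and `mean_hydration` (per residue).
#' @param rg_cutoff R_G cutoff, nm (default 1.2).
#' @param hyd_cutoff Hydration cutoff (default 12.5).
#' @param alt_rg_cutoff Alternative R_G cutoff for the sensitivity rerun
#'   (default 1.1 nm; `NULL` to skip).
#' @return A list with `map` (the input plus `label` and `alt_label`),
#'   `boundary` (per pressure: `t_boundary` K or NA when unresolved, the
#'   bracketing temperatures, and `resolved`), and `sensitivity` (rows
#'   whose label changed under the alternative cutoff).
#' @export
build_phase_map <- function(states, rg_cutoff = 1.2, hyd_cutoff = 12.5, alt_rg_cutoff = 1.1) {
  need <- c("pressure", "temperature", "mean_rg", "mean_hydration")
  miss <- setdiff(need, names(states))
  if (length(miss)) stop("states table is missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (length(unique(states$pressure)) < 2L || length(unique(states$temperature)) < 2L) {
    stop("phase map needs at least 2 pressures and 2 temperatures", call. = FALSE)
  }
  map <- states
  map$label <- classify_state(map$mean_rg, map$mean_hydration, rg_cutoff, hyd_cutoff)
  if (!is.null(alt_rg_cutoff)) {
    map$alt_label <- classify_state(map$mean_rg, map$mean_hydration, alt_rg_cutoff, hyd_cutoff)
  }
  prs <- sort(unique(map$pressure))
  bnd <- do.call(rbind, lapply(prs, function(p) {
    sub <- map[map$pressure == p, ]
    coil_t <- sub$temperature[sub$label == "coil"]
    glob_t <- sub$temperature[sub$label != "coil"]
    if (!length(coil_t) || !length(glob_t)) {
      return(data.frame(
        pressure = p, t_boundary = NA_real_, t_coil = NA_real_,
        t_globule = NA_real_, resolved = FALSE
      ))
    }
    tw <- max(coil_t)
    tg <- min(glob_t)
    data.frame(
      pressure = p, t_boundary = (tw + tg) / 2, t_coil = tw,
      t_globule = tg, resolved = TRUE
    )
  }))
  sens <- if (!is.null(alt_rg_cutoff)) map[map$label != map$alt_label, , drop = FALSE] else NULL
  list(map = map, boundary = bnd, sensitivity = sens)
}
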