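#' State-occupancy probabilities over age
#'
#' The probability of being in each state at each age on a grid from
#' `start_age` to `age_max`, given a start-age distribution over states:
#' `occupancy(u) = initial' P(start_age, u)` under the piecewise-constant
#' Gompertz model.
#'
#' @param object an [intensity_params()] or fitted [wlemsm()] model.
#' @param start_age starting age, years.
#' @param initial probability vector over states at `start_age`; no mass on
#'   the absorbing state.
#' @param profile named covariate values.
#' @param age_max end of the age grid (horizon), years.
#' @param step evaluation step in years (default 0.25).
#' @param grid an [age_grid()]; defaults to the fit's grid for `wlemsm`
#'   objects.
#' @return an object of class `"occupancy_curve"`: list with `ages`, the
#'   `occupancy` matrix (ages x states), `start_age` and the state space.
#' @export
#' @examples
#' st <- transition_structure(state_space(c("alive", "dead"),
#'   absorbing = "dead", working = "alive"))
#' p <- intensity_params(st, log_q0 = log(0.05))
#' oc <- occupancy(p, 50, c(1, 0), age_max = 75)
#' state_expectancy(oc, "alive")  # (1 - exp(-1.25)) / 0.05
occupancy <- function(object, start_age = 50, initial, profile = numeric(0),
                      age_max = 75, step = 0.25, grid = NULL) {
  if (inherits(object, "wlemsm")) {
    if (is.null(grid)) grid <- object$grid
    object <- object$params
  }
  stopifnot(inherits(object, "intensity_params"))
  if (is.null(grid)) grid <- age_grid()
  if (step <= 0) stop("step must be positive")
  sp <- object$structure$space
  initial <- as.numeric(initial)
  if (length(initial) != n_states(sp))
    stop("initial distribution must have one entry per state")
  if (abs(sum(initial) - 1) > 1e-8) stop("initial distribution must sum to 1")
  abscodes <- unname(sp$codes[sp$absorbing])
  if (any(initial[abscodes] > 0))
    stop("initial distribution puts mass on the absorbing state")
  z <- check_profile(profile, object$covariates)
  spec <- lik_spec(object$structure, object$covariates, grid,
                   matrix(z, 1, length(z)))
  occ <- cpp_occupancy(ip_flatten(object), spec, z, initial,
                       start_age, age_max, step)
  ages <- seq(start_age, by = step, length.out = nrow(occ))
  colnames(occ) <- sp$labels
  structure(list(ages = ages, occupancy = occ, start_age = start_age,
                 space = sp, profile = profile),
            class = "occupancy_curve")
}

#' @export
print.occupancy_curve <- function(x, ...) {
  cat(sprintf("Occupancy curve: ages %.2f-%.2f (%d points, %d states)\n",
              min(x$ages), max(x$ages), length(x$ages), ncol(x$occupancy)))
  print(utils::head(round(x$occupancy, 4), 3))
  cat("...\n")
  invisible(x)
}

#' @export
#' @method plot occupancy_curve
plot.occupancy_curve <- function(x, ...) {
  graphics::matplot(x$ages, x$occupancy, type = "l", lty = 1, lwd = 2,
                    xlab = "Age (years)", ylab = "Occupancy probability",
                    ylim = c(0, 1), ...)
  graphics::legend("right", legend = colnames(x$occupancy),
                   col = seq_len(ncol(x$occupancy)), lty = 1, lwd = 2,
                   bty = "n")
  invisible(x)
}

#' Expected years spent in a set of states
#'
#' Trapezoidal integral over age of the summed occupancy of the given state
#' subset, from the curve's start age to its horizon -- for working states
#' this is the (horizon-truncated) working life expectancy contribution.
#'
#' @param curve an [occupancy_curve()].
#' @param states state labels or codes (non-empty).
#' @return years, a scalar.
#' @export
state_expectancy <- function(curve, states) {
  stopifnot(inherits(curve, "occupancy_curve"))
  if (length(states) == 0) stop("empty state subset")
  if (is.character(states)) {
    if (!all(states %in% curve$space$labels)) stop("unknown state label")
    idx <- match(states, curve$space$labels)
  } else {
    idx <- as.integer(states)
    if (!all(idx %in% curve$space$codes)) stop("unknown state code")
  }
  y <- rowSums(curve$occupancy[, idx, drop = FALSE])
  a <- curve$ages
  sum(diff(a) * (y[-1] + y[-length(y)]) / 2)
}

# expectancies for each working state (+ total) from a theta vector
wle_point <- function(theta, spec, sp, init, z, start_age, age_max, step) {
  occ <- cpp_occupancy(theta, spec, z, init, start_age, age_max, step)
  ages <- seq(start_age, by = step, length.out = nrow(occ))
  widx <- unname(sp$codes[sp$working])
  e <- vapply(widx, function(i) {
    y <- occ[, i]
    sum(diff(ages) * (y[-1] + y[-length(y)]) / 2)
  }, numeric(1))
  c(stats::setNames(e, sp$working), total = sum(e))
}

# empirical initial-state distribution in the entry age band for a stratum
entry_distribution <- function(data, profile, start_age, band) {
  obs <- data$obs
  sp <- data$space
  first <- !duplicated(obs$subject_id)
  in_band <- first & obs$age >= start_age & obs$age < start_age + band &
    !is.na(obs$state) &
    !(obs$state %in% unname(sp$codes[sp$absorbing]))
  sel <- in_band
  pnames <- names(profile)
  pnames <- intersect(pnames, names(obs))
  for (nm in pnames) sel <- sel & obs[[nm]] == profile[[nm]]
  fallback <- FALSE
  if (!any(sel)) {
    sel <- in_band
    fallback <- TRUE
    if (!any(sel)) stop("no subjects enter in [", start_age, ", ",
                        start_age + band, ")")
    warning("no subjects of this profile enter in [", start_age, ", ",
            start_age + band, "); using the all-strata entry distribution")
  }
  tab <- tabulate(obs$state[sel], nbins = n_states(sp))
  list(init = tab / sum(tab), fallback = fallback, n = sum(sel))
}

# clip negative eigenvalues to repair an indefinite draw covariance
nearest_psd <- function(V) {
  e <- eigen(V, symmetric = TRUE)
  if (all(e$values >= 0)) return(V)
  lam <- pmax(e$values, 0)
  e$vectors %*% (lam * t(e$vectors))
}

#' Marginal working life expectancy with simulation confidence intervals
#'
#' Computes, for one covariate profile, the expected years spent in each
#' working state (and their total) from `start_age` to the horizon, under
#' the fitted model.  The start-age state distribution is the empirical
#' distribution of observed states among the profile's stratum in the entry
#' age band `[start_age, start_age + entry_band)` -- a marginal expectancy
#' rather than one conditioned on a single initial state.  An empty stratum
#' falls back to the all-strata entry distribution with a warning.
#'
#' Confidence intervals follow the parametric-simulation recipe: `n_draws`
#' parameter vectors are drawn from the asymptotic multivariate normal
#' distribution of the maximum likelihood estimator (mean = estimate,
#' covariance = inverse observed information), the expectancies are
#' recomputed for each draw, and the 2.5th/97.5th percentiles are reported.
#' A non-positive-semidefinite covariance is repaired to the nearest PSD
#' matrix with a warning.  Draws with non-finite expectancies are dropped
#' and counted; more than 1% dropped is an error.
#'
#' @param fit a fitted [wlemsm()] model.
#' @param data the [panel_data()] supplying the entry-state distribution.
#' @param profile named covariate values defining the stratum.
#' @param start_age starting age, years (default 50).
#' @param age_max horizon age (default 75); expectancies are truncated
#'   here.
#' @param step occupancy integration step, years.
#' @param entry_band width of the entry age band, years (default 2, the
#'   wave spacing).
#' @param ci compute confidence intervals?
#' @param n_draws number of parameter draws (default 500).
#' @param seed optional seed; fully determines the draws.
#' @param level confidence level (default 0.95).
#' @return an object of class `"wle"`: list with `estimates` (named vector:
#'   one entry per working state plus `total`), `ci` (2 x k matrix), the
#'   retained `draws`, `n_dropped`, the initial distribution used, and
#'   metadata.
#' @export
wle <- function(fit, data, profile = numeric(0), start_age = 50,
                age_max = 75, step = 0.25, entry_band = 2,
                ci = TRUE, n_draws = 500, seed = NULL, level = 0.95) {
  stopifnot(inherits(fit, "wlemsm"), inherits(data, "panel_data"))
  sp <- fit$space
  z <- check_profile(profile, fit$covariates)
  ed <- entry_distribution(data, profile, start_age, entry_band)
  spec <- lik_spec(fit$structure, fit$covariates, fit$grid,
                   matrix(z, 1, length(z)))
  est <- wle_point(fit$theta, spec, sp, ed$init, z, start_age, age_max, step)

  ci_mat <- NULL; draws <- NULL; n_dropped <- 0L; flagged <- FALSE
  if (ci) {
    if (n_draws < 1) stop("n_draws must be >= 1")
    if (!is.null(seed)) set.seed(seed)
    V <- fit$vcov
    ev <- eigen((V + t(V)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8 * max(abs(ev))) {
      warning("covariance matrix is not positive semidefinite; ",
              "repaired to the nearest PSD matrix")
      V <- nearest_psd((V + t(V)) / 2)
    }
    th_draws <- MASS::mvrnorm(n_draws, mu = fit$theta, Sigma = V)
    if (n_draws == 1) th_draws <- matrix(th_draws, 1)
    draws <- matrix(NA_real_, n_draws, length(est),
                    dimnames = list(NULL, names(est)))
    for (d in seq_len(n_draws))
      draws[d, ] <- wle_point(th_draws[d, ], spec, sp, ed$init, z,
                              start_age, age_max, step)
    ok <- apply(is.finite(draws), 1, all)
    n_dropped <- sum(!ok)
    if (n_dropped > 0.01 * n_draws)
      stop(n_dropped, " of ", n_draws,
           " parameter draws gave non-finite expectancies")
    draws <- draws[ok, , drop = FALSE]
    alpha <- (1 - level) / 2
    ci_mat <- apply(draws, 2, stats::quantile, probs = c(alpha, 1 - alpha))
    flagged <- any(est < ci_mat[1, ] | est > ci_mat[2, ])
  }
  structure(list(profile = profile, start_age = start_age, age_max = age_max,
                 estimates = est, ci = ci_mat, draws = draws,
                 n_draws = if (ci) n_draws else 0L, n_dropped = n_dropped,
                 point_outside_ci = flagged,
                 initial = ed$init, initial_fallback = ed$fallback,
                 level = level, space = sp),
            class = "wle")
}

#' @export
print.wle <- function(x, digits = 2, ...) {
  cat(sprintf("Working life expectancy from age %g (horizon %g)\n",
              x$start_age, x$age_max))
  if (length(x$profile))
    cat("Profile:", paste(names(x$profile), unlist(x$profile), sep = "=",
                          collapse = ", "), "\n")
  for (k in seq_along(x$estimates)) {
    cat(sprintf("  %-12s %s", names(x$estimates)[k],
                formatC(x$estimates[k], format = "f", digits = digits)))
    if (!is.null(x$ci))
      cat(sprintf(" (%s, %s)",
                  formatC(x$ci[1, k], format = "f", digits = digits),
                  formatC(x$ci[2, k], format = "f", digits = digits)))
    cat(" years\n")
  }
  if (x$point_outside_ci)
    cat("note: point estimate outside the percentile CI for some quantity\n")
  invisible(x)
}

#' Working life expectancy report in study-table layout
#'
#' One row per covariate profile (e.g. no strain/strain by sex), with the
#' total expectancy from the three-state (collapsed) model and the full-
#' and part-time expectancies from the four-state model, each with its
#' percentile CI.
#'
#' @param fit_total fitted three-state [wlemsm()] model (may be `NULL` to
#'   report the four-state total instead).
#' @param fit_parts fitted four-state [wlemsm()] model.
#' @param data_total,data_parts the datasets the two models were fitted to.
#' @param profiles data frame of covariate combinations, one row per report
#'   row; default: all combinations of 0/1 for the fit's covariates.
#' @param ... passed to [wle()] (`start_age`, `n_draws`, `seed`, ...).
#' @return a data frame of class `"wle_table"`.
#' @export
wle_table <- function(fit_parts, data_parts, fit_total = NULL,
                      data_total = NULL, profiles = NULL, ...) {
  stopifnot(inherits(fit_parts, "wlemsm"))
  if (is.null(profiles)) {
    profiles <- expand.grid(rep(list(0:1), length(fit_parts$covariates)))
    names(profiles) <- fit_parts$covariates
  }
  out <- vector("list", nrow(profiles))
  for (j in seq_len(nrow(profiles))) {
    prof <- unlist(profiles[j, , drop = FALSE])
    w4 <- wle(fit_parts, data_parts, prof, ...)
    row <- profiles[j, , drop = FALSE]
    for (k in seq_along(w4$estimates)) {
      nm <- names(w4$estimates)[k]
      row[[nm]] <- w4$estimates[k]
      if (!is.null(w4$ci)) {
        row[[paste0(nm, "_lo")]] <- w4$ci[1, k]
        row[[paste0(nm, "_hi")]] <- w4$ci[2, k]
      }
    }
    if (!is.null(fit_total)) {
      w3 <- wle(fit_total, data_total, prof, ...)
      row$total <- unname(w3$estimates["total"])
      if (!is.null(w3$ci)) {
        row$total_lo <- w3$ci[1, "total"]
        row$total_hi <- w3$ci[2, "total"]
      }
    }
    out[[j]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("wle_table", "data.frame")
  res
}

#' @export
print.wle_table <- function(x, digits = 2, ...) {
  covs <- setdiff(names(x), grep("_(lo|hi)$", names(x), value = TRUE))
  qty <- covs[vapply(covs, function(nm)
    paste0(nm, "_lo") %in% names(x), logical(1))]
  covs <- setdiff(covs, qty)
  fmt <- function(e, lo, hi)
    sprintf("%s (%s, %s)", formatC(e, format = "f", digits = digits),
            formatC(lo, format = "f", digits = digits),
            formatC(hi, format = "f", digits = digits))
  disp <- x[covs]
  for (nm in qty)
    disp[[nm]] <- fmt(x[[nm]], x[[paste0(nm, "_lo")]], x[[paste0(nm, "_hi")]])
  cat("Working life expectancies (years, 95% CI)\n")
  print(as.data.frame(disp), row.names = FALSE)
  invisible(x)
}

#' Paired-draw difference in working life expectancy between two strata
#'
#' Difference CI for an exposure contrast (e.g. strain minus no strain):
#' the same parameter draws are used for both covariate profiles, the
#' per-draw difference in each expectancy is formed, and percentile CIs of
#' the differences are reported.  Pairing the draws removes the common
#' parameter noise from the contrast.
#'
#' @param fit a fitted [wlemsm()] model.
#' @param data the dataset supplying entry-state distributions.
#' @param covariate the exposure covariate to contrast (1 minus 0).
#' @param profile named values of the remaining covariates.
#' @inheritParams wle
#' @return list with `difference` (exposed minus unexposed, per quantity),
#'   `ci`, and the two [wle()] objects.
#' @export
strain_gap <- function(fit, data, covariate = "strain", profile = numeric(0),
                       start_age = 50, age_max = 75, step = 0.25,
                       entry_band = 2, n_draws = 500, seed = NULL,
                       level = 0.95) {
  stopifnot(inherits(fit, "wlemsm"))
  if (!covariate %in% fit$covariates) stop("unknown covariate: ", covariate)
  base <- profile[setdiff(names(profile), covariate)]
  p0 <- c(stats::setNames(0, covariate), base)[fit$covariates]
  names(p0) <- fit$covariates
  p1 <- c(stats::setNames(1, covariate), base)[fit$covariates]
  names(p1) <- fit$covariates
  if (is.null(seed)) seed <- sample.int(.Machine$integer.max, 1)
  w0 <- wle(fit, data, p0, start_age, age_max, step, entry_band,
            ci = TRUE, n_draws = n_draws, seed = seed, level = level)
  w1 <- wle(fit, data, p1, start_age, age_max, step, entry_band,
            ci = TRUE, n_draws = n_draws, seed = seed, level = level)
  nd <- min(nrow(w0$draws), nrow(w1$draws))
  diffs <- w1$draws[seq_len(nd), , drop = FALSE] -
    w0$draws[seq_len(nd), , drop = FALSE]
  alpha <- (1 - level) / 2
  list(difference = w1$estimates - w0$estimates,
       ci = apply(diffs, 2, stats::quantile, probs = c(alpha, 1 - alpha)),
       exposed = w1, unexposed = w0)
}
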