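#' Crude-rate starting values for the panel likelihood
#'
#' For each allowed transition r -> s the baseline log-intensity starts at
#' the log crude rate: observed r -> s wave pairs divided by person-years
#' observed in r (the summed lengths of intervals starting in r).  Age
#' slopes and covariate effects start at zero.  Transitions never observed
#' fall back to `log(0.001)` with a warning.
#'
#' @param data a [panel_data()] object.
#' @param structure a [transition_structure()]; default: all transitions
#'   among alive states plus alive -> absorbing.
#' @param covariates covariate names the parameter object should carry.
#' @return an [intensity_params()] object.
#' @export
initial_values <- function(data, structure = NULL, covariates = character()) {
  stopifnot(inherits(data, "panel_data"))
  if (nrow(data$obs) == 0) stop("empty dataset")
  if (is.null(structure)) structure <- transition_structure(data$space)
  obs <- data$obs
  n <- n_states(data$space)
  counts <- matrix(0, n, n)
  py <- numeric(n)
  for (id in unique(obs$subject_id)) {
    rows <- which(obs$subject_id == id)
    if (length(rows) < 2L) next
    for (j in seq_len(length(rows) - 1L)) {
      r <- obs$state[rows[j]]
      s <- obs$state[rows[j + 1L]]
      if (is.na(r)) next
      py[r] <- py[r] + obs$age[rows[j + 1L]] - obs$age[rows[j]]
      if (!is.na(s)) counts[r, s] <- counts[r, s] + 1
    }
  }
  lq <- numeric(n_trans(structure))
  fallback <- character(0)
  for (t in seq_len(n_trans(structure))) {
    r <- structure$from[t]; s <- structure$to[t]
    if (counts[r, s] > 0 && py[r] > 0) {
      lq[t] <- log(counts[r, s] / py[r])
    } else {
      lq[t] <- log(0.001)
      fallback <- c(fallback, transition_labels(structure)[t])
    }
  }
  if (length(fallback))
    warning("transition(s) never observed, starting at log(0.001): ",
            paste(fallback, collapse = ", "))
  intensity_params(structure, covariates, log_q0 = lq, b_age = 0, beta = 0)
}

# central-difference Hessian of the analytic score
num_hessian <- function(gradfun, theta, step = 1e-4) {
  p <- length(theta)
  H <- matrix(0, p, p)
  for (j in seq_len(p)) {
    e <- numeric(p); e[j] <- step
    H[, j] <- (gradfun(theta + e) - gradfun(theta - e)) / (2 * step)
  }
  (H + t(H)) / 2
}

#' Fit a panel-observed multi-state Gompertz model
#'
#' Maximum-likelihood estimation of the continuous-time multi-state Markov
#' model with age-log-linear (Gompertz) transition intensities and
#' proportional covariate effects, from interval-censored panel data with
#' exactly dated deaths.  The likelihood is the product over consecutive
#' observation pairs of interval transition probabilities under a
#' piecewise-constant-in-age approximation (see [age_grid()]); it is
#' maximised by BFGS with analytic scores on the unconstrained flattened
#' parameter vector (intensities enter on the log scale, so positivity is
#' free), followed by Newton polishing steps using the numerical Hessian.
#' The asymptotic covariance is the inverse of the negative Hessian at the
#' optimum (central finite differences of the analytic score); when the
#' information matrix is singular or indefinite its eigenvalues are floored,
#' so unidentified directions receive very large variances, with a warning.
#'
#' @param data a [panel_data()] object.
#' @param structure a [transition_structure()]; default: all transitions
#'   among alive states plus alive -> absorbing (the work-state structure).
#' @param covariates character vector of covariate columns of `data` to
#'   enter every transition intensity multiplicatively; default: all
#'   covariate columns of `data`.
#' @param grid an [age_grid()] controlling the piecewise-constant
#'   approximation.
#' @param start optional [intensity_params()] starting values.  By default
#'   the model is fitted from two deterministic starts -- [initial_values()]
#'   crude rates with zero age slopes, and the same rates with slopes at a
#'   demographically typical +0.1/year -- and the higher optimum is kept,
#'   guarding against inferior basins of the multimodal Gompertz panel
#'   likelihood.
#' @param control list of optimiser settings: `maxit` (default 500),
#'   `reltol` (1e-9), `gtol` (gradient max-norm declaring convergence,
#'   1e-3), `hess_step` (Hessian finite-difference step, 1e-4), `polish`
#'   (maximum Newton polish steps, 10), `restarts` (BFGS restarts while the
#'   score criterion is unmet, 3), and `box` (plausibility bounds per
#'   parameter type; defaults `log_q0` in \[-20, 3\], `b_age` in
#'   \[-0.7, 0.7\], `beta` in \[-8, 8\]).  The box stops monotone-likelihood
#'   ridge runaways in sparse transition cells (the Gompertz analogue of
#'   separation); interior optima are unaffected, and parameters estimated
#'   at a bound are reported with a warning.
#' @return an object of class `"wlemsm"` with components `params` (the
#'   fitted [intensity_params()]), `loglik`, `vcov`, `converged`,
#'   `gradient`, `n_subjects`, `n_intervals`, `warnings`, and the model
#'   configuration.  Methods: `print`, `summary`, `coef`, `vcov`, `logLik`,
#'   `predict`, `plot`, `simulate`.
#' @seealso [wle()] for working life expectancies from a fitted model,
#'   [hazard_ratios()] for per-transition covariate effects.
#' @export
#' @examples
#' \donttest{
#' cohort <- make_study_cohort(default_scenario(n_subjects = 300), seed = 1)
#' fit <- wlemsm(cohort$panel)
#' summary(fit)
#' }
wlemsm <- function(data, structure = NULL, covariates = data$covariates,
                   grid = age_grid(), start = NULL, control = list()) {
  stopifnot(inherits(data, "panel_data"))
  if (is.null(structure)) structure <- transition_structure(data$space)
  ctl <- modifyList(list(maxit = 500L, reltol = 1e-9, gtol = 1e-3,
                         hess_step = 1e-4, polish = 10L, restarts = 3L,
                         box = list(log_q0 = c(-20, 3), b_age = c(-0.7, 0.7),
                                    beta = c(-8, 8))),
                    control)
  warn <- character(0)
  wh <- function(w) { warn <<- c(warn, conditionMessage(w)); invokeRestart("muffleWarning") }

  # Deterministic multi-start: the Gompertz panel likelihood can be
  # multimodal in (log q0, b_age) for sparsely observed transitions, and the
  # zero-slope crude start sometimes sits in an inferior basin.  Fit from
  # crude rates with slopes 0 and with slopes at a demographically typical
  # +0.1/year, and keep the higher optimum.  A user-supplied start replaces
  # the pair.
  if (is.null(start)) {
    iv <- withCallingHandlers(
      initial_values(data, structure, covariates), warning = wh)
    iv2 <- iv
    iv2$b_age[] <- 0.1
    starts <- list(iv, iv2)
  } else {
    stopifnot(inherits(start, "intensity_params"))
    starts <- list(start)
  }

  pi_ <- panel_intervals(data, covariates)
  if (pi_$n_intervals == 0) stop("no likelihood intervals in the data")
  spec <- lik_spec(structure, covariates, grid, pi_$Z)

  negll <- function(th) -cpp_panel_loglik(th, spec, pi_$ints, FALSE)$loglik
  neggr <- function(th) -cpp_panel_loglik(th, spec, pi_$ints, TRUE)$grad
  grfun <- function(th) cpp_panel_loglik(th, spec, pi_$ints, TRUE)$grad

  # Plausibility box for the parameter space.  Sparse transition cells have
  # a monotone likelihood (the supremum sits at an infinite slope or a zero
  # rate, the Gompertz analogue of separation); bounding the space at
  # scientifically absurd values stops those ridge runaways while leaving
  # interior optima untouched.
  nt <- n_trans(structure)
  ncv <- length(covariates)
  lob <- rep(c(ctl$box$log_q0[1], ctl$box$b_age[1],
               rep(ctl$box$beta[1], ncv)), nt)
  hib <- rep(c(ctl$box$log_q0[2], ctl$box$b_age[2],
               rep(ctl$box$beta[2], ncv)), nt)
  clamp <- function(th) pmin(pmax(th, lob), hib)
  # score with outward components at active bounds projected away
  proj <- function(th, g) {
    g[th <= lob + 1e-6 & g < 0] <- 0
    g[th >= hib - 1e-6 & g > 0] <- 0
    g
  }
  # BFGS with restarts (a fresh inverse-Hessian approximation frees stalled
  # search directions); fall back to bounded L-BFGS-B if the unconstrained
  # path leaves the box
  optimize_from <- function(theta0) {
    opt <- stats::optim(clamp(theta0), negll, neggr, method = "BFGS",
                        control = list(maxit = ctl$maxit,
                                       reltol = ctl$reltol))
    for (rs in seq_len(ctl$restarts)) {
      inside <- all(opt$par >= lob - 1e-8 & opt$par <= hib + 1e-8)
      if (inside && opt$convergence == 0L &&
          max(abs(proj(opt$par, -neggr(opt$par)))) < ctl$gtol) break
      opt2 <- stats::optim(clamp(opt$par), negll, neggr, method = "L-BFGS-B",
                           lower = lob, upper = hib,
                           control = list(maxit = min(ctl$maxit, 200L),
                                          factr = ctl$reltol /
                                            .Machine$double.eps))
      opt2$counts <- opt$counts + opt2$counts
      opt <- opt2
      opt$par <- clamp(opt$par)
      if (opt$convergence == 0L &&
          max(abs(proj(opt$par, -neggr(opt$par)))) < ctl$gtol) break
    }
    opt
  }
  opts <- lapply(starts, function(s) optimize_from(ip_flatten(s)))
  opt <- opts[[which.max(vapply(opts, function(o) -o$value, numeric(1)))]]
  theta <- clamp(opt$par)
  H <- num_hessian(grfun, theta, ctl$hess_step)
  g <- proj(theta, grfun(theta))
  ll <- -negll(theta)

  # Newton polish with the computed Hessian, backtracking on the step
  for (it in seq_len(ctl$polish)) {
    if (max(abs(g)) < ctl$gtol / 10) break
    step <- tryCatch(drop(solve(H, g)), error = function(e)
      tryCatch(drop(MASS::ginv(H) %*% g), error = function(e2) NULL))
    if (is.null(step) || !all(is.finite(step))) break
    accepted <- FALSE
    for (alpha in 2^-(0:4)) {
      cand <- clamp(theta - alpha * step)
      llc <- -negll(cand)
      if (!is.finite(llc) || llc < ll - 1e-8) next
      gc_ <- proj(cand, grfun(cand))
      if (max(abs(gc_)) >= max(abs(g))) next
      theta <- cand; ll <- llc; g <- gc_; accepted <- TRUE
      break
    }
    if (!accepted) break
  }

  vc <- tryCatch({
    V <- solve(-H)
    if (any(!is.finite(V)) || any(diag(V) < 0)) stop("indefinite")
    V
  }, error = function(e) {
    # Singular or indefinite information: a Moore-Penrose inverse would
    # assign ZERO variance to null directions, understating the uncertainty
    # of unidentified parameters; floor the information eigenvalues instead
    # so those directions get very large, finite variances.
    warn <<- c(warn, paste(
      "observed information is singular or indefinite;",
      "null directions given variance 1e6 (unidentified parameters)"))
    e_ <- eigen(-H, symmetric = TRUE)
    lam <- pmax(e_$values, 1e-6)
    e_$vectors %*% ((1 / lam) * t(e_$vectors))
  })
  vc <- (vc + t(vc)) / 2
  if (any(diag(vc) < 0)) {
    warn <- c(warn,
      "negative variance estimate; the Hessian is not negative definite at the optimum")
  }
  n_floored <- cpp_panel_loglik(theta, spec, pi_$ints, FALSE)$n_floored
  if (n_floored > 0)
    warn <- c(warn, sprintf("%d interval probabilities floored at 1e-300", n_floored))

  at_bound <- theta <= lob + 1e-6 | theta >= hib - 1e-6
  if (any(at_bound))
    warn <- c(warn, paste0(
      "parameter(s) at the plausibility bound (monotone likelihood or ",
      "unidentified cell): ",
      paste(names(ip_flatten(ip_unflatten(theta, structure, covariates,
                                          grid$origin)))[at_bound],
            collapse = ", ")))
  converged <- (opt$convergence == 0L) && (max(abs(g)) < ctl$gtol)
  if (!converged)
    warn <- c(warn, sprintf(
      "not converged: optim code %d, gradient max-norm %.3g (gtol %.3g)",
      opt$convergence, max(abs(g)), ctl$gtol))

  params <- ip_unflatten(theta, structure, covariates, origin = grid$origin)
  dimnames(vc) <- list(names(ip_flatten(params)), names(ip_flatten(params)))
  fit <- structure(list(
    params = params, theta = stats::setNames(theta, names(ip_flatten(params))),
    loglik = ll, vcov = vc, gradient = g, converged = converged,
    n_subjects = length(unique(data$obs$subject_id)),
    n_intervals = pi_$n_intervals, n_floored = n_floored,
    structure = structure, covariates = covariates, grid = grid,
    space = data$space, warnings = warn, optim = opt[c("counts", "convergence")],
    call = match.call()), class = "wlemsm")
  for (w in warn) warning(w, call. = FALSE)
  fit
}

#' @export
print.wlemsm <- function(x, digits = 4, ...) {
  cat("Panel-observed multi-state Gompertz model (", n_states(x$space),
      " states, ", n_trans(x$structure), " transitions)\n", sep = "")
  cat("Subjects:", x$n_subjects, " intervals:", x$n_intervals,
      " log-likelihood:", format(x$loglik, digits = 8), "\n")
  cat("Converged:", x$converged,
      sprintf(" (gradient max-norm %.2e)\n", max(abs(x$gradient))))
  print(x$params, digits = digits)
  invisible(x)
}

#' @export
coef.wlemsm <- function(object, ...) object$theta

#' @export
vcov.wlemsm <- function(object, ...) object$vcov

#' @export
logLik.wlemsm <- function(object, ...) {
  structure(object$loglik, df = length(object$theta),
            nobs = object$n_intervals, class = "logLik")
}

#' @export
summary.wlemsm <- function(object, ...) {
  se <- sqrt(pmax(diag(object$vcov), 0))
  tab <- data.frame(estimate = object$theta, se = se,
                    lo95 = object$theta - 1.96 * se,
                    hi95 = object$theta + 1.96 * se)
  hrs <- lapply(object$covariates, function(cv) hazard_ratios(object, cv))
  names(hrs) <- object$covariates
  out <- list(coefficients = tab, hazard_ratios = hrs,
              loglik = object$loglik, aic = -2 * object$loglik + 2 * length(object$theta),
              converged = object$converged, n_subjects = object$n_subjects,
              n_intervals = object$n_intervals, warnings = object$warnings)
  class(out) <- "summary.wlemsm"
  out
}

#' @export
print.summary.wlemsm <- function(x, digits = 4, ...) {
  cat("Coefficients (flattened parameter vector):\n")
  print(round(x$coefficients, digits))
  for (cv in names(x$hazard_ratios)) {
    cat("\nHazard ratios for", cv, "(95% Wald CI):\n")
    print(x$hazard_ratios[[cv]], digits = digits)
  }
  cat(sprintf("\nlogLik %.4f  AIC %.4f  converged %s\n",
              x$loglik, x$aic, x$converged))
  if (length(x$warnings)) cat("Warnings:\n ", paste(x$warnings, collapse = "\n  "), "\n")
  invisible(x)
}

#' Per-transition hazard ratios for a covariate
#'
#' `exp(beta)` per allowed transition with 95% Wald confidence intervals
#' `exp(beta +- 1.96 se)`.
#'
#' @param fit a fitted [wlemsm()] model.
#' @param covariate name of a model covariate.
#' @return data frame with columns `transition`, `hr`, `lo95`, `hi95`,
#'   `beta`, `se`.
#' @export
hazard_ratios <- function(fit, covariate) {
  stopifnot(inherits(fit, "wlemsm"))
  if (!covariate %in% fit$covariates)
    stop("unknown covariate: ", covariate)
  nms <- paste0(transition_labels(fit$structure), ".", covariate)
  beta <- fit$theta[nms]
  se <- sqrt(pmax(diag(fit$vcov)[nms], 0))
  data.frame(transition = transition_labels(fit$structure),
             hr = exp(beta), lo95 = exp(beta - 1.96 * se),
             hi95 = exp(beta + 1.96 * se), beta = beta, se = se,
             row.names = NULL)
}

#' @export
#' @method predict wlemsm
predict.wlemsm <- function(object, age_from = 50, age_to = 75,
                           profile = numeric(0), ...) {
  transition_probability(object$params, age_from, age_to, profile,
                         object$grid)
}

#' @export
#' @method plot wlemsm
plot.wlemsm <- function(x, profile = numeric(0), start_age = x$grid$origin,
                        age_max = 75, initial = NULL, ...) {
  sp <- x$space
  if (is.null(initial)) {
    initial <- numeric(n_states(sp))
    initial[sp$codes[alive_states(sp)][1]] <- 1
  }
  oc <- occupancy(x, start_age = start_age, initial = initial,
                  profile = profile, age_max = age_max)
  plot(oc, ...)
}

#' @export
#' @method simulate wlemsm
simulate.wlemsm <- function(object, nsim = 1, seed = NULL,
                            design = cohort_design(), ...) {
  scen <- list(params = object$params, design = design)
  class(scen) <- "wlemsm_scenario"
  if (!is.null(seed)) set.seed(seed)
  out <- lapply(seq_len(nsim), function(i) make_study_cohort(scen)$panel)
  if (nsim == 1) out[[1]] else out
}
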