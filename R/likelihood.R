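#' Age grid for the piecewise-constant approximation
#'
#' The Gompertz intensities vary continuously with age; for likelihood and
#' occupancy computations they are frozen within age bands of `width` years,
#' evaluated at the band midpoint, so interval transition probabilities are
#' ordered products of matrix exponentials.  Bands cover `[origin, age_max]`;
#' ages beyond the last band reuse its intensities.
#'
#' @param width band width in years (default 1).
#' @param age_max upper age covered by the grid, years.
#' @param origin model age origin, years.
#' @return an object of class `"age_grid"`.
#' @export
age_grid <- function(width = 1, age_max = 110, origin = 50) {
  stopifnot(width > 0, age_max > origin)
  structure(list(origin = origin, width = width, age_max = age_max,
                 n_bands = as.integer(ceiling((age_max - origin) / width))),
            class = "age_grid")
}

#' @export
print.age_grid <- function(x, ...) {
  cat(sprintf("Age grid: %d bands of %g yr on [%g, %g], midpoint evaluation\n",
              x$n_bands, x$width, x$origin, x$origin + x$n_bands * x$width))
  invisible(x)
}

# model description consumed by the C++ core
lik_spec <- function(structure, covariates, grid, Z) {
  sp <- structure$space
  absorbing <- if (length(sp$absorbing)) unname(sp$codes[sp$absorbing[1]]) else 0L
  list(n_states = n_states(sp),
       tfrom = as.integer(structure$from), tto = as.integer(structure$to),
       n_cov = length(covariates), Z = Z,
       origin = grid$origin, band_width = grid$width,
       n_bands = grid$n_bands, absorbing = as.integer(absorbing))
}

#' Interval transition probability matrix
#'
#' P(age_from, age_to): the matrix of probabilities of being in each state at
#' `age_to` given each state at `age_from`, under the piecewise-constant
#' Gompertz model -- the ordered product over grid bands intersecting
#' `[age_from, age_to]` of `expm(Q(band) * dt)`.
#'
#' @inheritParams intensity_matrix
#' @param age_from,age_to interval endpoints in years, `age_from <= age_to`.
#' @param grid an [age_grid()].
#' @return a stochastic matrix (rows sum to 1) with state labels as dimnames.
#' @export
#' @examples
#' st <- transition_structure(state_space(c("alive", "dead"),
#'   absorbing = "dead", working = "alive"))
#' p <- intensity_params(st, log_q0 = log(0.1))
#' transition_probability(p, 50, 55)["alive", "dead"]  # 1 - exp(-0.5)
transition_probability <- function(params, age_from, age_to,
                                   profile = numeric(0), grid = age_grid()) {
  stopifnot(inherits(params, "intensity_params"))
  if (age_to < age_from) stop("age_to must be >= age_from")
  if (age_from < params$origin)
    stop("age_from is below the model origin ", params$origin)
  z <- check_profile(profile, params$covariates)
  spec <- lik_spec(params$structure, params$covariates, grid,
                   matrix(z, 1, length(z)))
  P <- cpp_tpm(ip_flatten(params), spec, z, age_from, age_to)
  dimnames(P) <- list(params$structure$space$labels,
                      params$structure$space$labels)
  P
}

#' Log-likelihood contribution of one observation interval
#'
#' For a consecutive pair of observations on one subject, starting in alive
#' state `from` at `age1`:
#' \itemize{
#'   \item observed alive state `to` at `age2`: `log P(age1, age2)[from, to]`;
#'   \item exactly dated death at `age2` (`exact_death = TRUE`): the event
#'     density `log sum_m P(age1, age2)[from, m] * Q(age2)[m, death]` over
#'     alive states m;
#'   \item censor set at `age2`: `log sum_{s in set} P(age1, age2)[from, s]`.
#' }
#'
#' @inheritParams transition_probability
#' @param from state code at `age1` (must be a single alive state).
#' @param to state code at `age2`; ignored when `censor_set` is given.
#' @param censor_set optional integer vector of candidate state codes at
#'   `age2`.
#' @param exact_death set when `to` is the absorbing state with an exact
#'   event time.
#' @return scalar log-probability (a log-density for exact deaths).
#' @export
interval_loglik <- function(params, age1, age2, from, to = NULL,
                            censor_set = NULL, exact_death = FALSE,
                            profile = numeric(0), grid = age_grid()) {
  stopifnot(inherits(params, "intensity_params"))
  sp <- params$structure$space
  abscodes <- unname(sp$codes[sp$absorbing])
  if (from %in% abscodes) stop("no interval may start from the absorbing state")
  if (age2 < age1) stop("age2 must be >= age1")
  z <- check_profile(profile, params$covariates)
  if (!is.null(censor_set)) {
    type <- 2L; to <- 0L
    cmask <- sum(bitwShiftL(1L, as.integer(censor_set) - 1L))
  } else {
    stopifnot(!is.null(to))
    type <- if (exact_death || to %in% abscodes) 1L else 0L
    cmask <- 0L
  }
  spec <- lik_spec(params$structure, params$covariates, grid,
                   matrix(z, 1, length(z)))
  ints <- list(from = as.integer(from), type = type, to = as.integer(to),
               cmask = as.integer(cmask), age1 = age1, age2 = age2, prof = 1L)
  cpp_panel_loglik(ip_flatten(params), spec, ints, FALSE)$loglik
}

#' Total interval-censored panel log-likelihood
#'
#' Sum of [interval_loglik()] over all consecutive observation pairs of all
#' subjects, each evaluated at that subject's baseline covariate profile.
#' Subjects observed only once contribute no terms.  Probabilities below
#' 1e-300 are floored before taking logs; the number of floored terms is
#' attached as attribute `"n_floored"`.
#'
#' @param data a [panel_data()] object.
#' @param params an [intensity_params()] whose covariates are columns of
#'   `data`.
#' @param grid an [age_grid()].
#' @return scalar log-likelihood with attribute `n_floored`.
#' @export
total_loglik <- function(data, params, grid = age_grid()) {
  stopifnot(inherits(data, "panel_data"), inherits(params, "intensity_params"))
  pi_ <- panel_intervals(data, params$covariates)
  if (pi_$n_intervals == 0) return(structure(0, n_floored = 0L))
  spec <- lik_spec(params$structure, params$covariates, grid, pi_$Z)
  res <- cpp_panel_loglik(ip_flatten(params), spec, pi_$ints, FALSE)
  structure(res$loglik, n_floored = res$n_floored)
}

# value + analytic gradient on the flattened parameter vector
loglik_with_grad <- function(theta, spec, ints) {
  cpp_panel_loglik(theta, spec, ints, TRUE)
}
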