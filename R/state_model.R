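#' Define a labelled state space
#'
#' A state space lists the states of a multi-state model, which of them are
#' absorbing, and which count as "working" when working life expectancy is
#' computed.  State codes are the integer codes used in data files.
#'
#' @param labels character vector of state names, in code order.
#' @param absorbing character vector of absorbing state labels (at most one
#'   in the study configurations shipped with the package).
#' @param working character vector of non-absorbing states whose occupancy
#'   counts towards working life expectancy.
#' @param codes integer codes, one per state; must be `1:length(labels)`.
#' @return an object of class `"state_space"`.
#' @seealso [work_state_space()] for the canned four- and three-state
#'   configurations, [transition_structure()] for allowed transitions.
#' @export
#' @examples
#' state_space(c("alive", "dead"), absorbing = "dead", working = "alive")
state_space <- function(labels, absorbing = character(), working = character(),
                        codes = seq_along(labels)) {
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop("state labels must be unique")
  codes <- as.integer(codes)
  if (!identical(codes, seq_along(labels)))
    stop("state codes must be contiguous integers starting at 1")
  if (!all(absorbing %in% labels)) stop("unknown absorbing state label")
  if (!all(working %in% labels)) stop("unknown working state label")
  if (length(intersect(working, absorbing)))
    stop("working states must be disjoint from absorbing states")
  structure(list(labels = labels, codes = stats::setNames(codes, labels),
                 absorbing = as.character(absorbing),
                 working = as.character(working)),
            class = "state_space")
}

#' @export
print.state_space <- function(x, ...) {
  cat("State space (", length(x$labels), " states)\n", sep = "")
  for (l in x$labels) {
    tag <- c(if (l %in% x$absorbing) "absorbing",
             if (l %in% x$working) "working")
    cat(sprintf("  %d = %s%s\n", x$codes[[l]], l,
                if (length(tag)) paste0(" [", paste(tag, collapse = ", "), "]") else ""))
  }
  invisible(x)
}

n_states <- function(space) length(space$labels)

alive_states <- function(space) setdiff(space$labels, space$absorbing)

#' Work-state spaces used in late-career working life studies
#'
#' The four-state configuration distinguishes full-time work (30+ h/week),
#' part-time work (10--29 h/week), not in work (<10 h/week), and death
#' (absorbing).  The collapsed three-state configuration merges full- and
#' part-time into a single "working" state and is the one used for total
#' working life expectancy.
#'
#' @param collapsed if `TRUE`, return the three-state configuration.
#' @return a [state_space()].
#' @export
#' @examples
#' work_state_space()
#' work_state_space(collapsed = TRUE)
work_state_space <- function(collapsed = FALSE) {
  if (collapsed)
    state_space(c("working", "not in work", "death"),
                absorbing = "death", working = "working")
  else
    state_space(c("full-time", "part-time", "not in work", "death"),
                absorbing = "death", working = c("full-time", "part-time"))
}

#' Allowed instantaneous transitions
#'
#' By default every ordered pair of distinct alive states is allowed, plus a
#' transition from each alive state to the absorbing state -- the structure
#' used for the work-state models (recovery from "not in work" back into work
#' is allowed).  Nothing may leave an absorbing state.
#'
#' @param space a [state_space()].
#' @param allowed optional two-column matrix or data frame of (from, to)
#'   state codes; `NULL` for the default structure.
#' @return an object of class `"transition_structure"` with integer vectors
#'   `$from` and `$to` of state codes.
#' @export
#' @examples
#' transition_structure(work_state_space())
transition_structure <- function(space, allowed = NULL) {
  stopifnot(inherits(space, "state_space"))
  if (is.null(allowed)) {
    al <- space$codes[alive_states(space)]
    from <- to <- integer(0)
    for (r in al) for (s in al) if (r != s) { from <- c(from, r); to <- c(to, s) }
    for (a in space$codes[space$absorbing])
      { from <- c(from, unname(al)); to <- c(to, rep(a, length(al))) }
  } else {
    allowed <- as.matrix(allowed)
    if (ncol(allowed) != 2) stop("'allowed' must have two columns (from, to)")
    from <- as.integer(allowed[, 1]); to <- as.integer(allowed[, 2])
  }
  if (!all(c(from, to) %in% space$codes)) stop("transition uses an unknown state code")
  if (any(from == to)) stop("self-transitions are not allowed")
  if (any(from %in% space$codes[space$absorbing]))
    stop("no transition may leave an absorbing state")
  if (anyDuplicated(cbind(from, to))) stop("duplicated transition")
  structure(list(space = space, from = unname(from), to = unname(to)),
            class = "transition_structure")
}

n_trans <- function(structure) length(structure$from)

transition_labels <- function(structure) {
  sp <- structure$space
  paste0(sp$labels[structure$from], "->", sp$labels[structure$to])
}

#' @export
print.transition_structure <- function(x, ...) {
  cat("Transition structure:", n_trans(x), "allowed transitions\n")
  cat(" ", paste(transition_labels(x), collapse = ", "), "\n")
  invisible(x)
}

#' Gompertz transition-intensity parameters
#'
#' One parameter block per allowed transition r -> s: the baseline
#' log-intensity at the age origin (`log_q0`, log of a rate in 1/year), the
#' Gompertz age slope (`b_age`, per year of age), and one log hazard ratio
#' per covariate (`beta`).  The intensity at age `a` for covariate values `z`
#' is `exp(log_q0 + b_age * (a - origin) + beta %*% z)`.
#'
#' @param structure a [transition_structure()].
#' @param covariates character vector of covariate names (may be empty).
#' @param log_q0,b_age numeric vectors, one value per transition (recycled).
#' @param beta numeric matrix with one row per transition and one column per
#'   covariate (a single value is recycled).
#' @param origin age origin in years; baseline intensities are at-this-age
#'   values.  Defaults to 50.
#' @return an object of class `"intensity_params"`.
#' @export
#' @examples
#' st <- transition_structure(state_space(c("alive", "dead"),
#'   absorbing = "dead", working = "alive"))
#' intensity_params(st, log_q0 = log(0.1))
intensity_params <- function(structure, covariates = character(),
                             log_q0 = log(0.1), b_age = 0, beta = 0,
                             origin = 50) {
  stopifnot(inherits(structure, "transition_structure"))
  nt <- n_trans(structure)
  nc <- length(covariates)
  log_q0 <- rep_len(as.numeric(log_q0), nt)
  b_age <- rep_len(as.numeric(b_age), nt)
  beta <- if (nc == 0) matrix(0, nt, 0) else {
    b <- if (is.matrix(beta)) beta else matrix(beta, nt, nc,
      byrow = is.null(dim(beta)) && length(beta) == nc)
    if (!all(dim(b) == c(nt, nc))) stop("'beta' must be ", nt, " x ", nc)
    b
  }
  vals <- c(log_q0, b_age, beta)
  if (!all(is.finite(vals))) stop("all intensity parameters must be finite")
  dimnames(beta) <- list(transition_labels(structure), covariates)
  structure(list(structure = structure,
                 covariates = as.character(covariates),
                 log_q0 = stats::setNames(log_q0, transition_labels(structure)),
                 b_age = stats::setNames(b_age, transition_labels(structure)),
                 beta = beta, origin = origin),
            class = "intensity_params")
}

#' @export
print.intensity_params <- function(x, digits = 4, ...) {
  cat("Gompertz intensity parameters (age origin", x$origin, "years)\n")
  tab <- cbind(log_q0 = x$log_q0, b_age = x$b_age, x$beta)
  print(round(tab, digits))
  invisible(x)
}

# flatten to the optimiser's vector: per transition [log_q0, b_age, beta_1..c]
ip_flatten <- function(params) {
  nt <- n_trans(params$structure)
  nc <- length(params$covariates)
  bs <- 2L + nc
  theta <- numeric(nt * bs)
  nms <- character(nt * bs)
  tl <- transition_labels(params$structure)
  for (t in seq_len(nt)) {
    i <- (t - 1L) * bs
    theta[i + 1L] <- params$log_q0[t]
    theta[i + 2L] <- params$b_age[t]
    nms[i + 1L] <- paste0(tl[t], ".logq0")
    nms[i + 2L] <- paste0(tl[t], ".b_age")
    if (nc) {
      theta[i + 2L + seq_len(nc)] <- params$beta[t, ]
      nms[i + 2L + seq_len(nc)] <- paste0(tl[t], ".", params$covariates)
    }
  }
  stats::setNames(theta, nms)
}

ip_unflatten <- function(theta, structure, covariates, origin = 50) {
  nt <- n_trans(structure)
  nc <- length(covariates)
  bs <- 2L + nc
  stopifnot(length(theta) == nt * bs)
  idx <- (seq_len(nt) - 1L) * bs
  beta <- if (nc) matrix(theta[rep(idx, each = nc) + 2L + seq_len(nc)],
                         nt, nc, byrow = TRUE) else matrix(0, nt, 0)
  intensity_params(structure, covariates,
                   log_q0 = theta[idx + 1L], b_age = theta[idx + 2L],
                   beta = beta, origin = origin)
}

check_profile <- function(profile, covariates) {
  profile <- unlist(profile)
  if (length(covariates) == 0) return(numeric(0))
  if (is.null(names(profile)) || !all(covariates %in% names(profile)))
    stop("profile must name every model covariate: ",
         paste(covariates, collapse = ", "))
  extra <- setdiff(names(profile), covariates)
  if (length(extra)) stop("unknown covariate in profile: ",
                          paste(extra, collapse = ", "))
  as.numeric(profile[covariates])
}

#' Transition-intensity (generator) matrix at a given age
#'
#' Evaluates the generator matrix Q of the continuous-time Markov model at
#' one age for one covariate profile.  Off-diagonal entries are the Gompertz
#' intensities `exp(log_q0 + b_age * (age - origin) + beta %*% z)` for allowed
#' transitions and zero otherwise; diagonal entries make rows sum to zero;
#' rows of absorbing states are identically zero.
#'
#' @param params an [intensity_params()] object.
#' @param age age in years, at or above the model origin.
#' @param profile named numeric vector of covariate values (one value per
#'   model covariate; empty models take an empty profile).
#' @return a square numeric matrix (units 1/year) with state labels as
#'   dimnames.
#' @export
#' @examples
#' st <- transition_structure(state_space(c("alive", "dead"),
#'   absorbing = "dead", working = "alive"))
#' intensity_matrix(intensity_params(st, log_q0 = 0), age = 50)
intensity_matrix <- function(params, age, profile = numeric(0)) {
  stopifnot(inherits(params, "intensity_params"))
  if (age < params$origin)
    stop("age ", age, " is below the model origin ", params$origin)
  z <- check_profile(profile, params$covariates)
  sp <- params$structure$space
  n <- n_states(sp)
  Q <- matrix(0, n, n, dimnames = list(sp$labels, sp$labels))
  lp <- params$log_q0 + params$b_age * (age - params$origin)
  if (length(z)) lp <- lp + drop(params$beta %*% z)
  q <- exp(lp)
  for (t in seq_along(q))
    Q[params$structure$from[t], params$structure$to[t]] <-
      Q[params$structure$from[t], params$structure$to[t]] + q[t]
  diag(Q) <- diag(Q) - rowSums(Q)
  Q
}

#' Collapse full- and part-time work into a single working state
#'
#' Maps the four-state configuration (full-time, part-time, not in work,
#' death) onto the three-state one (working, not in work, death): the two
#' working states merge, transitions between them are dropped, and state
#' codes are relabelled 1 = working, 2 = not in work, 3 = death.  Methods
#' exist for state spaces, transition structures, and panel datasets.
#'
#' @param x object to collapse.
#' @param ... unused.
#' @return the collapsed object of the same class.
#' @export
collapse_work_states <- function(x, ...) UseMethod("collapse_work_states")

check_four_state <- function(space) {
  if (length(space$working) != 2)
    stop("collapse requires the four-state configuration (two working states)")
}

# code map: old code -> new code (working states share the new code)
collapse_code_map <- function(space) {
  check_four_state(space)
  keep <- c(space$working[1], setdiff(space$labels, space$working))
  newcode <- stats::setNames(seq_along(keep), keep)
  m <- integer(length(space$labels))
  for (l in space$labels) {
    tgt <- if (l %in% space$working) space$working[1] else l
    m[space$codes[[l]]] <- newcode[[tgt]]
  }
  m
}

#' @rdname collapse_work_states
#' @export
collapse_work_states.state_space <- function(x, ...) {
  check_four_state(x)
  state_space(c("working", setdiff(x$labels, c(x$working, x$absorbing)),
                x$absorbing),
              absorbing = x$absorbing, working = "working")
}

#' @rdname collapse_work_states
#' @export
collapse_work_states.transition_structure <- function(x, ...) {
  sp <- x$space
  map <- collapse_code_map(sp)
  from <- map[x$from]; to <- map[x$to]
  keep <- from != to
  pairs <- unique(cbind(from[keep], to[keep]))
  transition_structure(collapse_work_states(sp), allowed = pairs)
}
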