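#' Read a model configuration file
#'
#' YAML (or JSON) file describing a model: state labels and codes, the
#' absorbing and working sets, allowed transitions as `"from->to"` code
#' pairs, covariate names, and age-grid settings (`age_band_width`,
#' `age_max`).  Example:
#' \preformatted{
#' states: ["full-time", "part-time", "not in work", "death"]
#' absorbing: ["death"]
#' working: ["full-time", "part-time"]
#' transitions: ["1->2", "2->1", "1->3", "3->1", "2->3", "3->2",
#'               "1->4", "2->4", "3->4"]
#' covariates: ["strain", "sex"]
#' age_band_width: 1
#' age_max: 110
#' }
#'
#' @param path YAML or JSON file path.
#' @return list with `space` ([state_space()]), `structure`
#'   ([transition_structure()]), `covariates` and `grid` ([age_grid()]).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  sp <- state_space(cfg$states,
                    absorbing = cfg$absorbing %||% character(),
                    working = cfg$working %||% character())
  st <- if (is.null(cfg$transitions)) transition_structure(sp) else {
    pairs <- do.call(rbind, lapply(cfg$transitions, function(s) {
      m <- regmatches(s, regexec("^\\s*(\\d+)\\s*->\\s*(\\d+)\\s*$", s))[[1]]
      if (length(m) != 3) stop("malformed transition: ", s)
      as.integer(m[2:3])
    }))
    transition_structure(sp, pairs)
  }
  grid <- age_grid(width = cfg$age_band_width %||% 1,
                   age_max = cfg$age_max %||% 110)
  list(space = sp, structure = st,
       covariates = as.character(cfg$covariates %||% character()),
       grid = grid)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a model configuration file
#'
#' @param structure a [transition_structure()].
#' @param covariates covariate names.
#' @param grid an [age_grid()].
#' @param path output path (`.yaml` or `.json`).
#' @return `path`, invisibly.
#' @export
write_model_config <- function(structure, covariates = character(),
                               grid = age_grid(), path) {
  sp <- structure$space
  cfg <- list(states = sp$labels, absorbing = sp$absorbing,
              working = sp$working,
              transitions = paste0(structure$from, "->", structure$to),
              covariates = covariates,
              age_band_width = grid$width, age_max = grid$age_max)
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::write_json(cfg, path, auto_unbox = FALSE, pretty = TRUE)
  else yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Serialize a fitted model to JSON
#'
#' Writes parameters, covariance, log-likelihood, and convergence
#' diagnostics; [read_fit_json()] restores a `"wlemsm"` object able to
#' drive [wle()] and [predict()] (the original data are not stored).
#'
#' @param fit a fitted [wlemsm()] model.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  stopifnot(inherits(fit, "wlemsm"))
  sp <- fit$space
  obj <- list(
    package_version = as.character(utils::packageVersion("wlemsm")),
    states = sp$labels, absorbing = sp$absorbing, working = sp$working,
    transitions = paste0(fit$structure$from, "->", fit$structure$to),
    covariates = fit$covariates,
    grid = list(width = fit$grid$width, age_max = fit$grid$age_max,
                origin = fit$grid$origin),
    theta = as.list(fit$theta), loglik = fit$loglik,
    vcov = fit$vcov, gradient = fit$gradient,
    converged = fit$converged, n_subjects = fit$n_subjects,
    n_intervals = fit$n_intervals, n_floored = fit$n_floored,
    warnings = fit$warnings)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_fit_json
#' @export
read_fit_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  sp <- state_space(obj$states, absorbing = obj$absorbing,
                    working = obj$working)
  pairs <- do.call(rbind, lapply(obj$transitions, function(s)
    as.integer(regmatches(s, regexec("(\\d+)->(\\d+)", s))[[1]][2:3])))
  st <- transition_structure(sp, pairs)
  grid <- age_grid(width = obj$grid$width, age_max = obj$grid$age_max,
                   origin = obj$grid$origin)
  theta <- unlist(obj$theta)
  params <- ip_unflatten(unname(theta), st, obj$covariates,
                         origin = grid$origin)
  vc <- as.matrix(obj$vcov)
  dimnames(vc) <- list(names(theta), names(theta))
  structure(list(params = params, theta = theta, loglik = obj$loglik,
                 vcov = vc, gradient = obj$gradient,
                 converged = obj$converged, n_subjects = obj$n_subjects,
                 n_intervals = obj$n_intervals,
                 n_floored = obj$n_floored %||% 0L,
                 structure = st, covariates = obj$covariates, grid = grid,
                 space = sp, warnings = obj$warnings %||% character(),
                 optim = NULL, call = NULL),
            class = "wlemsm")
}

# provenance block for machine-readable outputs
provenance <- function(files = character(), seed = NULL) {
  hashes <- if (length(files)) as.list(tools::md5sum(files)) else list()
  list(package_version = as.character(utils::packageVersion("wlemsm")),
       seed = seed, file_md5 = hashes, timestamp = NULL)
}
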