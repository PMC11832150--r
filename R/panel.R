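#' Long-format panel dataset of work-state observations
#'
#' Validates a long-format data frame of panel observations: one row per
#' subject-observation with a subject identifier, the age at observation
#' (years, continuous), the observed state, and baseline covariate columns.
#' The state column holds either a single state code or a censor set written
#' as codes joined by `+` (e.g. `"1+2+3"` when only "alive" is known at a
#' wave).  Death (the absorbing state) is exactly dated: its row carries the
#' age at death and must be the subject's final row.
#'
#' Validation is exhaustive: every violated invariant (ages not strictly
#' increasing, observations after death, unknown state codes, ages outside
#' 50--110, covariates varying within subject) is reported with the subject
#' id and row number in a single structured error of class
#' `"wlemsm_validation_error"` whose `problems` field is a data frame.
#'
#' @param df data frame with columns `subject_id`, `age`, `state`, and one
#'   column per covariate.
#' @param space the [state_space()] the state codes refer to.
#' @param covariates character vector of covariate column names; by default
#'   every column other than `subject_id`, `age`, `state`.
#' @return an object of class `"panel_data"`: a list with the validated
#'   observation data frame (`$obs`, with an integer `state` column, `NA`
#'   for censor sets, and an integer bitmask column `cmask`), the state
#'   space (`$space`) and covariate names (`$covariates`).
#' @seealso [read_panel()], [write_panel()], [summarize_transitions()]
#' @export
panel_data <- function(df, space = work_state_space(),
                       covariates = NULL) {
  stopifnot(inherits(space, "state_space"))
  df <- as.data.frame(df)
  need <- c("subject_id", "age", "state")
  if (!all(need %in% names(df)))
    stop("panel data needs columns: ", paste(need, collapse = ", "))
  if (is.null(covariates)) covariates <- setdiff(names(df), need)
  df$subject_id <- as.character(df$subject_id)
  df$age <- as.numeric(df$age)

  n <- n_states(space)
  parsed <- parse_state_column(df$state, n)
  df$state <- parsed$state
  df$cmask <- parsed$cmask

  probs <- data.frame(row = integer(), subject_id = character(),
                      message = character())
  bad <- function(rows, ids, msg)
    probs <<- rbind(probs, data.frame(row = rows, subject_id = ids,
                                      message = msg))
  if (any(parsed$invalid))
    bad(which(parsed$invalid), df$subject_id[parsed$invalid],
        "unknown or malformed state code")
  out_age <- !is.na(df$age) & (df$age < 50 | df$age > 110)
  if (any(out_age)) bad(which(out_age), df$subject_id[out_age],
                        "age outside [50, 110]")
  if (anyNA(df$age)) bad(which(is.na(df$age)), df$subject_id[is.na(df$age)],
                         "missing age")

  ord <- order(match(df$subject_id, unique(df$subject_id)), df$age)
  if (is.unsorted(match(df$subject_id, unique(df$subject_id)), strictly = FALSE))
    df <- df  # grouping below uses split(), order retained within subject
  abscodes <- unname(space$codes[space$absorbing])
  for (id in unique(df$subject_id)) {
    rows <- which(df$subject_id == id)
    a <- df$age[rows]
    if (anyNA(a)) next
    if (any(diff(a) <= 0))
      bad(rows[which(diff(a) <= 0) + 1L], id, "ages not strictly increasing")
    dead <- which(df$state[rows] %in% abscodes)
    if (length(dead) > 1L) bad(rows[dead[-1L]], id, "more than one death record")
    if (length(dead) >= 1L && dead[1L] < length(rows))
      bad(rows[(dead[1L] + 1L):length(rows)], id, "observation after death")
    for (cv in covariates) {
      v <- df[[cv]][rows]
      if (length(unique(v)) > 1L)
        bad(rows[1L], id, paste0("covariate '", cv, "' varies within subject"))
    }
  }
  if (nrow(probs)) {
    msg <- paste0("panel validation failed (", nrow(probs), " problem",
                  if (nrow(probs) > 1) "s" else "", "):\n",
                  paste(sprintf("  row %d, subject %s: %s", probs$row,
                                probs$subject_id, probs$message),
                        collapse = "\n"))
    stop(errorCondition(msg, problems = probs,
                        class = c("wlemsm_validation_error", "error", "condition")))
  }
  rownames(df) <- NULL
  structure(list(obs = df[c(need, "cmask", covariates)], space = space,
                 covariates = as.character(covariates)),
            class = "panel_data")
}

# state column: integer codes or "a+b+c" censor sets -> (state, cmask, invalid)
parse_state_column <- function(x, n_states) {
  x <- as.character(x)
  state <- rep(NA_integer_, length(x))
  cmask <- rep(NA_integer_, length(x))
  invalid <- logical(length(x))
  for (i in seq_along(x)) {
    parts <- suppressWarnings(as.integer(strsplit(trimws(x[i]), "+", fixed = TRUE)[[1]]))
    if (length(parts) == 0 || anyNA(parts) ||
        any(parts < 1 | parts > n_states) || anyDuplicated(parts)) {
      invalid[i] <- TRUE
      next
    }
    cmask[i] <- sum(bitwShiftL(1L, parts - 1L))
    if (length(parts) == 1L) state[i] <- parts
  }
  list(state = state, cmask = cmask, invalid = invalid)
}

render_state_column <- function(obs, n_states) {
  vapply(seq_len(nrow(obs)), function(i) {
    if (!is.na(obs$state[i])) return(as.character(obs$state[i]))
    codes <- which(bitwAnd(obs$cmask[i], bitwShiftL(1L, 0:(n_states - 1L))) > 0)
    paste(codes, collapse = "+")
  }, character(1))
}

#' @export
print.panel_data <- function(x, ...) {
  ns <- length(unique(x$obs$subject_id))
  cat("Panel dataset:", ns, "subjects,", nrow(x$obs), "observations (",
      n_states(x$space), "-state coding)\n", sep = "")
  if (length(x$covariates))
    cat("Covariates:", paste(x$covariates, collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.panel_data <- function(object, ...) {
  obs <- object$obs
  ns <- length(unique(obs$subject_id))
  deaths <- sum(obs$state %in% object$space$codes[object$space$absorbing],
                na.rm = TRUE)
  out <- list(n_subjects = ns, n_obs = nrow(obs),
              n_intervals = nrow(obs) - ns, n_deaths = deaths,
              age_range = range(obs$age),
              transitions = summarize_transitions(object))
  class(out) <- "summary.panel_data"
  out
}

#' @export
print.summary.panel_data <- function(x, ...) {
  cat("Subjects:", x$n_subjects, " observations:", x$n_obs,
      " intervals:", x$n_intervals, " deaths:", x$n_deaths, "\n")
  cat(sprintf("Age range: %.2f-%.2f\n", x$age_range[1], x$age_range[2]))
  cat("Wave-to-wave state pairs:\n")
  print(x$transitions)
  invisible(x)
}

#' Read a long-format panel CSV
#'
#' Reads and validates a UTF-8 CSV with header
#' `subject_id,age,state,<covariate...>`.  See [panel_data()] for the
#' invariants checked and the censor-set encoding of the state column.
#'
#' @param path CSV file path.
#' @param space the [state_space()] used to interpret state codes.
#' @param covariates covariate column names; default: all extra columns.
#' @return a [panel_data()] object.
#' @export
read_panel <- function(path, space = work_state_space(), covariates = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(state = "character"))
  panel_data(df, space = space, covariates = covariates)
}

#' Write a panel dataset to CSV
#'
#' Inverse of [read_panel()]: `read_panel(write_panel(d, f))` reproduces `d`
#' field by field.
#'
#' @param data a [panel_data()] object.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(data, path) {
  stopifnot(inherits(data, "panel_data"))
  out <- data$obs[c("subject_id", "age", "state", data$covariates)]
  out$state <- render_state_column(data$obs, n_states(data$space))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Observed wave-to-wave state-pair counts
#'
#' Counts consecutive observation pairs (including self-pairs, i.e. waves
#' with no observed state change) over ordered state pairs.  These are
#' observed-at-wave pairs, not inferred numbers of transitions: timing
#' between waves is interval-censored.  Censor-set observations are tallied
#' in a `"(censored)"` margin so that the grand total always equals the
#' number of consecutive observation pairs.
#'
#' @param data a [panel_data()] object.
#' @return an integer matrix of counts, rows = state at the earlier wave.
#' @export
summarize_transitions <- function(data) {
  stopifnot(inherits(data, "panel_data"))
  obs <- data$obs
  labs <- data$space$labels
  any_cens <- anyNA(obs$state)
  dn <- if (any_cens) c(labs, "(censored)") else labs
  counts <- matrix(0L, length(dn), length(dn), dimnames = list(from = dn, to = dn))
  idx <- function(s) ifelse(is.na(s), length(dn), s)
  for (id in unique(obs$subject_id)) {
    rows <- which(obs$subject_id == id)
    if (length(rows) < 2L) next
    s <- obs$state[rows]
    for (j in seq_len(length(rows) - 1L)) {
      counts[idx(s[j]), idx(s[j + 1L])] <- counts[idx(s[j]), idx(s[j + 1L])] + 1L
    }
  }
  counts
}

#' @rdname collapse_work_states
#' @export
collapse_work_states.panel_data <- function(x, ...) {
  sp <- x$space
  map <- collapse_code_map(sp)
  sp3 <- collapse_work_states(sp)
  obs <- x$obs
  obs$state <- ifelse(is.na(obs$state), NA_integer_, map[obs$state])
  obs$cmask <- vapply(obs$cmask, function(m) {
    bits <- which(bitwAnd(m, bitwShiftL(1L, seq_len(n_states(sp)) - 1L)) > 0)
    sum(bitwShiftL(1L, unique(map[bits]) - 1L))
  }, integer(1))
  obs$state <- render_state_column(obs, n_states(sp3))
  panel_data(obs[setdiff(names(obs), "cmask")], space = sp3,
             covariates = x$covariates)
}

# --- interval extraction for the likelihood ---------------------------------

all_alive_mask <- function(space) {
  al <- unname(space$codes[alive_states(space)])
  sum(bitwShiftL(1L, al - 1L))
}

# Consecutive-pair intervals in the form the likelihood core consumes.
# A censor set equal to "all alive states" in mid-sequence carries no
# information under an absorbing death state, so such rows are skipped and
# the flanking interval spans them; any other mid-sequence censor set is
# rejected.  type: 0 observed alive state, 1 exact death, 2 censor set.
panel_intervals <- function(data, covariates = data$covariates) {
  obs <- data$obs
  sp <- data$space
  abscodes <- unname(sp$codes[sp$absorbing])
  aam <- all_alive_mask(sp)
  Zall <- if (length(covariates))
    as.matrix(obs[, covariates, drop = FALSE]) else
    matrix(0, nrow(obs), 0)
  storage.mode(Zall) <- "double"

  from <- to <- type <- cmask <- prof <- integer(0)
  age1 <- age2 <- numeric(0)
  key <- apply(Zall, 1, paste, collapse = "\r")
  ukey <- unique(key)
  Z <- Zall[match(ukey, key), , drop = FALSE]
  rowprof <- match(key, ukey)

  for (id in unique(obs$subject_id)) {
    rows <- which(obs$subject_id == id)
    if (length(rows) < 2L) next
    pr <- rowprof[rows[1L]]
    cur <- rows[1L]  # last fully observed alive row
    if (is.na(obs$state[cur]))
      stop("subject ", id, ": first observation may not be a censor set")
    for (r in rows[-1L]) {
      st <- obs$state[r]
      if (is.na(st)) {
        if (obs$cmask[r] == aam && r != rows[length(rows)]) next  # uninformative
        if (obs$cmask[r] != aam && r != rows[length(rows)])
          stop("subject ", id, ": mid-sequence partial censor sets are not supported")
        from <- c(from, obs$state[cur]); to <- c(to, 0L); type <- c(type, 2L)
        cmask <- c(cmask, obs$cmask[r])
      } else if (st %in% abscodes) {
        from <- c(from, obs$state[cur]); to <- c(to, st); type <- c(type, 1L)
        cmask <- c(cmask, 0L)
      } else {
        from <- c(from, obs$state[cur]); to <- c(to, st); type <- c(type, 0L)
        cmask <- c(cmask, 0L)
      }
      age1 <- c(age1, obs$age[cur]); age2 <- c(age2, obs$age[r])
      prof <- c(prof, pr)
      if (!is.na(st) && !(st %in% abscodes)) cur <- r
    }
  }
  if (length(from) && any(from %in% abscodes))
    stop("interval starting from the absorbing state")
  list(ints = list(from = from, type = type, to = to, cmask = cmask,
                   age1 = age1, age2 = age2, prof = prof),
       Z = Z, n_intervals = length(from))
}
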