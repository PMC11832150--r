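#' Design of a synthetic biennial panel cohort
#'
#' Describes the observation design of an occupational panel study of older
#' workers: entry ages drawn from a truncated normal, biennial questionnaire
#' waves with a per-subject number of waves drawn from an empirical
#' distribution, working state at entry drawn per sex, job-strain exposure
#' prevalence per sex, exactly dated deaths, and optional non-informative
#' dropout.  Defaults emulate the published design: entry age ~ N(56, 5)
#' truncated to [50, 75], waves 2 years apart, 2--7 waves per subject with
#' weights (2666, 2741, 3492, 1252, 1142, 1539), ~90% full-time at entry
#' (92.9% men, 87.5% women), strain prevalence 15.7% (men) / 21.2% (women),
#' and 55.7% women.
#'
#' @param n_subjects number of subjects.
#' @param entry_age_mean,entry_age_sd,entry_age_range entry-age distribution
#'   (years); ages are rounded to 2 decimals.
#' @param wave_spacing years between waves.
#' @param waves_prob probability vector over 2..7 waves per subject.
#' @param dropout_prob per-wave probability of non-informative dropout
#'   (after entry).
#' @param missing_as_censor if `TRUE`, a dropped wave is recorded as a
#'   censor set over all alive states instead of truncating follow-up.
#' @param prop_female proportion of women (sex covariate coded 1).
#' @param entry_state_probs 2 x k matrix of entry-state probabilities over
#'   the working states, rows = (men, women).
#' @param strain_prevalence length-2 vector (men, women) of job-strain
#'   prevalence.
#' @param entry_offset_probs probability vector over entry-wave offsets
#'   0, 1, 2, ... (refreshment entry); default: all subjects enter at the
#'   first wave.
#' @return an object of class `"cohort_design"`.
#' @export
cohort_design <- function(n_subjects = 3000,
                          entry_age_mean = 56, entry_age_sd = 5,
                          entry_age_range = c(50, 75),
                          wave_spacing = 2,
                          waves_prob = c(2666, 2741, 3492, 1252, 1142, 1539) / 12832,
                          dropout_prob = 0,
                          missing_as_censor = FALSE,
                          prop_female = 7363 / 13225,
                          entry_state_probs = rbind(men = c(0.929, 0.071),
                                                    women = c(0.875, 0.125)),
                          strain_prevalence = c(men = 0.157, women = 0.212),
                          entry_offset_probs = 1) {
  stopifnot(n_subjects >= 1, wave_spacing > 0,
            abs(sum(waves_prob) - 1) < 1e-8,
            all(waves_prob >= 0), dropout_prob >= 0, dropout_prob <= 1,
            all(abs(rowSums(entry_state_probs) - 1) < 1e-8),
            all(strain_prevalence >= 0 & strain_prevalence <= 1),
            abs(sum(entry_offset_probs) - 1) < 1e-8)
  structure(as.list(environment()), class = "cohort_design")
}

#' @export
print.cohort_design <- function(x, ...) {
  cat("Cohort design:", x$n_subjects, "subjects, waves every", x$wave_spacing,
      "yr,", paste(range(which(x$waves_prob > 0) + 1), collapse = "-"),
      "waves per subject\n")
  cat(sprintf("Entry age ~ N(%g, %g) on [%g, %g]; strain prevalence %.1f%%/%.1f%% (m/w)\n",
              x$entry_age_mean, x$entry_age_sd, x$entry_age_range[1],
              x$entry_age_range[2], 100 * x$strain_prevalence[1],
              100 * x$strain_prevalence[2]))
  invisible(x)
}

# intensities at an exact age for precomputed linear predictors at origin
q_at <- function(lp0, b, age, origin) exp(lp0 + b * (age - origin))

#' Simulate one exact trajectory of the work-state process
#'
#' Exact simulation of the time-inhomogeneous continuous-time Markov chain
#' with Gompertz intensities, by thinning against a per-band dominating
#' rate: within each 1-year age band the proposal rate is the band-maximum
#' total exit intensity (evaluated at the band edges, valid because each
#' Gompertz intensity is monotone in age), and proposed event times are
#' accepted with probability equal to the ratio of the true total exit
#' intensity to the dominating rate.  The trajectory ends at death or at
#' `age_max`.
#'
#' @inheritParams intensity_matrix
#' @param entry_age age at entry, years (at or above the model origin).
#' @param entry_state entry state code (non-absorbing).
#' @param age_max administrative censoring age.
#' @return an object of class `"work_trajectory"`: list with `times` (ages
#'   at entry and at each jump), `states` (state codes occupied from each
#'   time), `death_age` (`NA` if censored) and `end_age`.
#' @export
simulate_trajectory <- function(params, entry_age, entry_state,
                                profile = numeric(0), age_max = 110) {
  stopifnot(inherits(params, "intensity_params"))
  sp <- params$structure$space
  abscodes <- unname(sp$codes[sp$absorbing])
  if (entry_state %in% abscodes) stop("entry state must be non-absorbing")
  z <- check_profile(profile, params$covariates)
  lp0 <- params$log_q0
  if (length(z)) lp0 <- lp0 + drop(params$beta %*% z)
  b <- params$b_age
  if (!all(is.finite(exp(lp0 + b * (age_max - params$origin)))))
    stop("non-finite dominating rate: intensities explode before age_max")
  from <- params$structure$from; to <- params$structure$to
  origin <- params$origin

  times <- entry_age; states <- as.integer(entry_state)
  a <- entry_age; s <- as.integer(entry_state)
  death_age <- NA_real_
  while (a < age_max) {
    band_lo <- origin + floor(a - origin)
    band_hi <- min(band_lo + 1, age_max)
    idx <- which(from == s)
    if (!length(idx)) break
    dom <- sum(pmax(q_at(lp0[idx], b[idx], max(a, band_lo), origin),
                    q_at(lp0[idx], b[idx], band_hi, origin)))
    if (dom <= 0) { a <- band_hi; next }
    wait <- stats::rexp(1, dom)
    if (a + wait >= band_hi) { a <- band_hi; next }
    a <- a + wait
    q <- q_at(lp0[idx], b[idx], a, origin)
    lam <- sum(q)
    if (stats::runif(1) > lam / dom) next  # thinned proposal
    s_new <- to[idx][sample.int(length(idx), 1, prob = q)]
    times <- c(times, a); states <- c(states, s_new)
    if (s_new %in% abscodes) { death_age <- a; break }
    s <- s_new
  }
  structure(list(times = times, states = states, death_age = death_age,
                 end_age = if (is.na(death_age)) age_max else death_age,
                 profile = profile),
            class = "work_trajectory")
}

#' @export
print.work_trajectory <- function(x, ...) {
  cat("Trajectory:", paste(sprintf("%s@%.2f", x$states, x$times),
                           collapse = " -> "),
      if (is.na(x$death_age)) sprintf("(censored at %.2f)", x$end_age)
      else sprintf("(death at %.2f)", x$death_age), "\n")
  invisible(x)
}

state_at <- function(traj, age) {
  traj$states[findInterval(age, traj$times)]
}

#' Observe trajectories at panel waves
#'
#' Applies the panel observation operator: each subject is observed at entry
#' and every `wave_spacing` years for its drawn number of waves (or until
#' dropout); the state recorded at a wave is the latent trajectory's state
#' at that age, so spells between waves are invisible (interval censoring).
#' A death occurring before the subject's last scheduled wave is recorded at
#' its exact age and terminates observation; later deaths are unobserved.
#'
#' @param trajectories list of [simulate_trajectory()] results, each
#'   carrying its covariate `profile`.
#' @param design a [cohort_design()]; wave counts and dropout are drawn
#'   here.
#' @param space the [state_space()] for the resulting dataset.
#' @return a [panel_data()] object.
#' @export
observe_cohort <- function(trajectories, design = cohort_design(),
                           space = work_state_space()) {
  stopifnot(inherits(design, "cohort_design"))
  aam_codes <- unname(space$codes[alive_states(space)])
  cens_code <- paste(aam_codes, collapse = "+")
  rows <- vector("list", length(trajectories))
  n_wave_choices <- seq_along(design$waves_prob) + 1L
  for (i in seq_along(trajectories)) {
    tr <- trajectories[[i]]
    id <- if (!is.null(tr$subject_id)) tr$subject_id else sprintf("S%05d", i)
    n_waves <- sample(n_wave_choices, 1, prob = design$waves_prob)
    entry <- tr$times[1]
    wave_ages <- round(entry + (seq_len(n_waves) - 1L) * design$wave_spacing, 2)
    last_scheduled <- wave_ages[length(wave_ages)]
    age <- c(); st <- c()
    for (k in seq_along(wave_ages)) {
      w <- wave_ages[k]
      if (!is.na(tr$death_age) && round(tr$death_age, 2) <= w) break
      if (k > 1 && design$dropout_prob > 0 &&
          stats::runif(1) < design$dropout_prob) {
        if (design$missing_as_censor) {
          age <- c(age, w); st <- c(st, cens_code)
          next
        } else break
      }
      age <- c(age, w); st <- c(st, as.character(state_at(tr, w)))
    }
    if (!is.na(tr$death_age) && round(tr$death_age, 2) <= last_scheduled) {
      d <- round(tr$death_age, 2)
      keep <- age < d
      age <- c(age[keep], d)
      st <- c(st[keep], as.character(unname(space$codes[space$absorbing[1]])))
    }
    if (!length(age)) next
    prof <- tr$profile
    df <- data.frame(subject_id = id, age = age, state = st,
                     stringsAsFactors = FALSE)
    for (nm in names(prof)) df[[nm]] <- unname(prof[[nm]])
    rows[[i]] <- df
  }
  panel_data(do.call(rbind, rows), space = space)
}

#' Karasek job-strain coder
#'
#' Codes binary job-strain exposure from Likert responses (1 = "Yes, often"
#' to 4 = "No, hardly ever/never") to 4 job-demand items and 5 job-control
#' items.  Items are reverse-coded (5 minus response) before averaging so
#' that higher scores mean more demands / more control.  Two median-split
#' rules are supported; "above the median" is strict, so scores exactly at
#' the median code as no strain:
#' \describe{
#'   \item{`"quadrant"`}{strain = mean demands strictly above the demand
#'     median AND mean control strictly below the control median.}
#'   \item{`"score-median"`}{strain = (mean demands - mean control) strictly
#'     above the median of that score.}
#' }
#'
#' @param demand_items n x 4 matrix (or length-4 vector) of demand
#'   responses in 1..4.
#' @param control_items n x 5 matrix (or length-5 vector) of control
#'   responses in 1..4.
#' @param medians optional list with elements `demands`, `control` (and
#'   `score` for the score-median rule); when omitted, medians of the
#'   supplied sample are used.
#' @param rule `"quadrant"` or `"score-median"`; no default is applied
#'   silently -- the rule must be chosen explicitly.
#' @return integer vector of 0/1 strain indicators with attributes `rule`
#'   and `medians`.
#' @export
assign_job_strain <- function(demand_items, control_items, medians = NULL,
                              rule = c("quadrant", "score-median")) {
  rule <- match.arg(rule)
  d <- if (is.matrix(demand_items)) demand_items else matrix(demand_items, 1)
  ct <- if (is.matrix(control_items)) control_items else matrix(control_items, 1)
  if (ncol(d) != 4) stop("demand_items must have 4 items")
  if (ncol(ct) != 5) stop("control_items must have 5 items")
  if (nrow(d) != nrow(ct)) stop("demand and control item counts differ")
  if (!all(d %in% 1:4) || !all(ct %in% 1:4))
    stop("Likert responses must be integers in 1..4")
  dscore <- rowMeans(5 - d)   # higher = more demands
  cscore <- rowMeans(5 - ct)  # higher = more control
  if (rule == "quadrant") {
    md <- if (!is.null(medians)) medians$demands else stats::median(dscore)
    mc <- if (!is.null(medians)) medians$control else stats::median(cscore)
    strain <- as.integer(dscore > md & cscore < mc)
    meds <- list(demands = md, control = mc)
  } else {
    sc <- dscore - cscore
    ms <- if (!is.null(medians)) medians$score else stats::median(sc)
    strain <- as.integer(sc > ms)
    meds <- list(score = ms)
  }
  structure(strain, rule = rule, medians = meds)
}

#' Default synthetic-study scenario
#'
#' True parameters and design for the synthetic work-state cohort.  The
#' intensity values are illustrative, constructed (no published intensities
#' exist for the motivating study): baselines and slopes are chosen so that
#', under the defaults, total working life expectancy at 50 for men without
#' strain is about 13.5 years and job strain (hazard ratio 1.35 on both
#' work-to-not-in-work exits) shortens it by roughly half a year to a year.
#' Covariates: `strain` (0/1) and `sex` (0 = men, 1 = women).
#'
#' @param n_subjects cohort size handed to [cohort_design()].
#' @param strain_hr hazard ratio of job strain on the work -> not-in-work
#'   transitions.
#' @param design optional [cohort_design()] overriding the default.
#' @return a scenario object (class `"wlemsm_scenario"`) with elements
#'   `params`, `design`, `start_age`, `horizon`.
#' @export
default_scenario <- function(n_subjects = 3000, strain_hr = 1.35,
                             design = NULL) {
  st <- transition_structure(work_state_space())
  covs <- c("strain", "sex")
  # order: FT->PT, FT->NW, PT->FT, PT->NW, NW->FT, NW->PT, FT->D, PT->D, NW->D
  log_q0 <- log(c(0.015, 0.0045, 0.150, 0.0065, 0.200, 0.100,
                  0.002, 0.0025, 0.004))
  b_age <- c(0.10, 0.30, -0.05, 0.30, -0.05, -0.05, 0.09, 0.09, 0.09)
  beta <- matrix(0, 9, 2, dimnames = list(NULL, covs))
  beta[2, "strain"] <- log(strain_hr)   # FT -> NW
  beta[4, "strain"] <- log(strain_hr)   # PT -> NW
  beta[1, "sex"] <- log(1.45)           # women move to part-time more
  beta[3, "sex"] <- log(1 / 1.3)
  beta[2, "sex"] <- log(1.12)           # slightly earlier female work exit
  beta[4, "sex"] <- log(1.12)
  beta[7, "sex"] <- -0.35               # lower female mortality
  beta[8, "sex"] <- -0.35
  beta[9, "sex"] <- -0.35
  params <- intensity_params(st, covs, log_q0 = log_q0, b_age = b_age,
                             beta = beta)
  if (is.null(design)) design <- cohort_design(n_subjects = n_subjects)
  structure(list(params = params, design = design, start_age = 50,
                 horizon = 75), class = "wlemsm_scenario")
}

#' Generate a complete synthetic study cohort with ground truth
#'
#' End-to-end fixture generator: draws covariates (sex, then job strain at
#' its per-sex prevalence), entry ages and entry states per the design,
#' simulates exact trajectories from the true parameters, applies the panel
#' observation operator, and computes the true working life expectancies
#' for each covariate profile from the true parameters with the same
#' occupancy integrator used for fitted models.
#'
#' @param scenario a scenario as from [default_scenario()].
#' @param seed optional integer seed; the seed fully determines the output.
#' @return list with `panel` (a [panel_data()]), `trajectories` (the latent
#'   truth), `true_wle` (data frame of true expectancies per profile) and
#'   `scenario`.
#' @export
make_study_cohort <- function(scenario = default_scenario(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  params <- scenario$params
  design <- scenario$design
  sp <- params$structure$space
  wcodes <- unname(sp$codes[sp$working])
  n <- design$n_subjects

  sex <- stats::rbinom(n, 1, design$prop_female)
  strain <- stats::rbinom(n, 1, design$strain_prevalence[sex + 1])
  entry_age <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      a <- stats::rnorm(1, design$entry_age_mean, design$entry_age_sd)
      if (a >= design$entry_age_range[1] && a <= design$entry_age_range[2]) break
    }
    entry_age[i] <- round(a, 2)
  }
  if (length(design$entry_offset_probs) > 1) {
    off <- sample(seq_along(design$entry_offset_probs) - 1L, n, replace = TRUE,
                  prob = design$entry_offset_probs)
    entry_age <- pmin(entry_age + off * design$wave_spacing,
                      design$entry_age_range[2])
  }
  entry_state <- integer(n)
  for (i in seq_len(n))
    entry_state[i] <- wcodes[sample.int(length(wcodes), 1,
                              prob = design$entry_state_probs[sex[i] + 1, ])]

  has_cov <- length(params$covariates) > 0
  trajectories <- vector("list", n)
  for (i in seq_len(n)) {
    prof <- if (has_cov)
      c(strain = strain[i], sex = sex[i])[params$covariates] else numeric(0)
    tr <- simulate_trajectory(params, entry_age[i], entry_state[i],
                              profile = prof, age_max = 110)
    tr$subject_id <- sprintf("S%05d", i)
    trajectories[[i]] <- tr
  }
  panel <- observe_cohort(trajectories, design, space = sp)

  profiles <- if (has_cov)
    expand.grid(strain = 0:1, sex = 0:1)[params$covariates] else
    data.frame(row.names = 1)
  tw <- vector("list", nrow(profiles))
  for (j in seq_len(nrow(profiles))) {
    prof <- unlist(profiles[j, , drop = FALSE])
    sexj <- if ("sex" %in% names(prof)) prof[["sex"]] else 0
    init <- numeric(n_states(sp))
    init[wcodes] <- design$entry_state_probs[sexj + 1, ]
    oc <- occupancy(params, start_age = scenario$start_age, initial = init,
                    profile = prof, age_max = scenario$horizon)
    e <- vapply(sp$working, function(w) state_expectancy(oc, w), numeric(1))
    tw[[j]] <- cbind(profiles[j, , drop = FALSE],
                     as.data.frame(as.list(e), check.names = FALSE),
                     total = sum(e))
  }
  true_wle <- do.call(rbind, tw)
  rownames(true_wle) <- NULL
  list(panel = panel, trajectories = trajectories, true_wle = true_wle,
       scenario = scenario)
}
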