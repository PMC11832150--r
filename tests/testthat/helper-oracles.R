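# Shared fixtures and independent reference implementations used as oracles.

two_state_space <- function()
  state_space(c("alive", "dead"), absorbing = "dead", working = "alive")

two_state_structure <- function() transition_structure(two_state_space())

two_state_params <- function(log_q0 = log(0.1), b_age = 0)
  intensity_params(two_state_structure(), log_q0 = log_q0, b_age = b_age)

# Reference generator matrix built directly from the Gompertz form
ref_Q <- function(params, age, z = numeric(0)) {
  st <- params$structure
  n <- length(st$space$labels)
  Q <- matrix(0, n, n)
  for (t in seq_along(st$from)) {
    lp <- params$log_q0[t] + params$b_age[t] * (age - params$origin)
    if (length(z)) lp <- lp + sum(params$beta[t, ] * z)
    Q[st$from[t], st$to[t]] <- Q[st$from[t], st$to[t]] + exp(lp)
  }
  diag(Q) <- -rowSums(Q)
  Q
}

# Reference interval transition probability: explicit product of
# Matrix::expm over bands of the given width, Q frozen at band midpoints.
# Independent of the package's eigendecomposition path.
ref_tpm <- function(params, a1, a2, z = numeric(0), width = 1, origin = 50) {
  n <- length(params$structure$space$labels)
  P <- diag(n)
  a <- a1
  while (a < a2 - 1e-12) {
    band_lo <- origin + floor((a - origin) / width + 1e-12) * width
    nxt <- min(band_lo + width, a2)
    Qm <- ref_Q(params, band_lo + width / 2, z)
    P <- P %*% as.matrix(Matrix::expm(Qm * (nxt - a)))
    a <- nxt
  }
  P
}

# tiny three-subject time-homogeneous panel used in several oracle tests
toy_panel <- function() {
  df <- data.frame(
    subject_id = c("a", "a", "a", "b", "b", "c", "c", "c"),
    age = c(50, 52, 54, 51, 55, 50.5, 52.5, 53.1),
    state = c("1", "2", "1", "1", "3", "2", "2", "4"),
    stringsAsFactors = FALSE)
  sp <- state_space(c("full-time", "part-time", "not in work", "death"),
                    absorbing = "death",
                    working = c("full-time", "part-time"))
  panel_data(df, space = sp)
}

# small simulated cohorts for structural tests
small_cohort <- function(n = 200, seed = 1)
  make_study_cohort(default_scenario(n_subjects = n), seed = seed)

# a scenario with elevated death and re-entry rates so that every transition
# is observed (hence identified) even in cohorts of a few hundred subjects
well_observed_scenario <- function(n) {
  scen <- default_scenario(n_subjects = n)
  scen$params$log_q0[] <- log(c(0.03, 0.008, 0.15, 0.012, 0.08, 0.06,
                                0.006, 0.008, 0.012))
  scen$params$b_age[] <- c(0.10, 0.25, -0.05, 0.25, -0.05, -0.05,
                           0.09, 0.09, 0.09)
  scen
}

well_observed_cohort <- function(n = 500, seed = 1)
  make_study_cohort(well_observed_scenario(n), seed = seed)

expect_rows_sum_to <- function(M, value, tol = 1e-10)
  expect_lt(max(abs(rowSums(M) - value)), tol)
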