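test_that("frozen chains keep their initial distribution", {
  p <- two_state_params(log_q0 = -30)  # numerically zero intensity
  oc <- occupancy(p, 50, c(1, 0), age_max = 75)
  expect_lt(max(abs(oc$occupancy[, "alive"] - 1)), 1e-10)
})

test_that("constant-hazard occupancy and expectancy match closed forms", {
  p <- two_state_params(log_q0 = log(0.05))
  oc <- occupancy(p, 50, c(1, 0), age_max = 75)
  expect_equal(unname(oc$occupancy[nrow(oc$occupancy), "alive"]), exp(-1.25),
               tolerance = 1e-6)
  expect_equal(state_expectancy(oc, "alive"), (1 - exp(-1.25)) / 0.05,
               tolerance = 1e-4)
  # including every state the expectancy is the horizon, by conservation
  expect_equal(state_expectancy(oc, c("alive", "dead")), 25, tolerance = 1e-8)
})

test_that("occupancy invariants hold over random parameter draws", {
  set.seed(61)
  st <- transition_structure(work_state_space())
  for (rep in 1:10) {
    p <- intensity_params(st, log_q0 = rnorm(9, log(0.08), 0.8),
                          b_age = rnorm(9, 0.05, 0.1))
    oc <- occupancy(p, 50, c(0.9, 0.1, 0, 0), age_max = 75)
    expect_lt(max(abs(rowSums(oc$occupancy) - 1)), 1e-8)
    expect_true(all(oc$occupancy >= -1e-12 & oc$occupancy <= 1 + 1e-12))
    expect_true(all(diff(oc$occupancy[, "death"]) > -1e-12))
    tot <- sum(vapply(st$space$labels, function(s) state_expectancy(oc, s),
                      numeric(1)))
    expect_equal(tot, 25, tolerance = 1e-8)
  }
})

test_that("halving the integration step barely moves a Gompertz expectancy", {
  p <- two_state_params(log_q0 = log(0.015), b_age = 0.05)
  e1 <- state_expectancy(occupancy(p, 50, c(1, 0), age_max = 75, step = 0.25),
                         "alive")
  e2 <- state_expectancy(occupancy(p, 50, c(1, 0), age_max = 75, step = 0.125),
                         "alive")
  expect_lt(abs(e1 - e2), 1e-4)
})

test_that("occupancy rejects bad initial distributions", {
  p <- two_state_params()
  expect_error(occupancy(p, 50, c(0.5, 0.5), age_max = 60), "absorbing")
  expect_error(occupancy(p, 50, c(0.7, 0), age_max = 60), "sum to 1")
  expect_error(state_expectancy(occupancy(p, 50, c(1, 0), age_max = 60),
                                character(0)), "empty")
})

make_fit <- function(cohort) suppressWarnings(wlemsm(cohort$panel))

# one moderately sized fitted cohort shared by the WLE blocks below
shared_cohort <- well_observed_cohort(600, seed = 43)
shared_fit <- make_fit(shared_cohort)

test_that("marginal WLE hits the no-exit limit and responds to exit rates", {
  st <- transition_structure(work_state_space())
  # no exits, no deaths: everyone stays working for the whole horizon
  p <- intensity_params(st, log_q0 = -30)
  oc <- occupancy(p, 50, c(0.9, 0.1, 0, 0), age_max = 75)
  expect_equal(state_expectancy(oc, c("full-time", "part-time")), 25,
               tolerance = 1e-8)

  # raising every work -> not-in-work intensity strictly lowers total WLE
  wle_of <- function(exit_q0) {
    lq <- log(c(0.02, exit_q0, 0.15, exit_q0, 0.06, 0.03,
                0.002, 0.002, 0.004))
    pp <- intensity_params(st, log_q0 = lq,
                           b_age = c(0.1, 0.3, -0.05, 0.3, -0.1, -0.1,
                                     0.09, 0.09, 0.09))
    state_expectancy(occupancy(pp, 50, c(0.9, 0.1, 0, 0), age_max = 75),
                     c("full-time", "part-time"))
  }
  ladder <- vapply(c(0.002, 0.005, 0.01, 0.02, 0.05), wle_of, numeric(1))
  expect_true(all(diff(ladder) < 0))
})

test_that("degenerate draw covariance collapses the CI to the point", {
  cohort <- shared_cohort
  fit0 <- shared_fit
  fit0$vcov[] <- 0
  w <- wle(fit0, cohort$panel, c(strain = 0, sex = 0), n_draws = 25, seed = 1)
  expect_equal(unname(w$ci[1, ]), unname(w$estimates), tolerance = 1e-10)
  expect_equal(unname(w$ci[2, ]), unname(w$estimates), tolerance = 1e-10)
})

test_that("WLE draws are seed-determined and components sum to the total", {
  cohort <- shared_cohort
  fit <- shared_fit
  prof <- c(strain = 0, sex = 0)
  w1 <- wle(fit, cohort$panel, prof, n_draws = 100, seed = 9)
  w2 <- wle(fit, cohort$panel, prof, n_draws = 100, seed = 9)
  expect_identical(w1$ci, w2$ci)
  expect_identical(w1$draws, w2$draws)
  w3 <- wle(fit, cohort$panel, prof, n_draws = 100, seed = 10)
  expect_false(identical(w3$ci, w1$ci))
  # at many draws, different seeds agree within Monte-Carlo noise
  wa <- wle(fit, cohort$panel, prof, n_draws = 2000, seed = 11)
  wb <- wle(fit, cohort$panel, prof, n_draws = 2000, seed = 12)
  expect_lt(max(abs(wa$ci - wb$ci)), 0.2)

  expect_equal(unname(w1$estimates["total"]),
               unname(w1$estimates["full-time"] + w1$estimates["part-time"]),
               tolerance = 1e-8)
  expect_true(all(w1$estimates >= 0 & w1$estimates <= 25))
  expect_true(all(w1$draws[, "total"] - w1$draws[, "full-time"] -
                    w1$draws[, "part-time"] < 1e-8))
})

test_that("an empty stratum falls back to the pooled entry distribution", {
  cohort <- shared_cohort
  d <- cohort$panel
  # restrict to men so the female stratum is empty
  obs <- d$obs[d$obs$sex == 0, ]
  obs$state <- wlemsm:::render_state_column(obs, 4)
  dm <- panel_data(obs[setdiff(names(obs), "cmask")], space = d$space)
  fit <- shared_fit
  expect_warning(w <- wle(fit, dm, c(strain = 0, sex = 1), ci = FALSE),
                 "all-strata")
  expect_true(is.finite(w$estimates["total"]))
})

test_that("paired-draw strain differences are deterministic and signed", {
  cohort <- shared_cohort
  fit <- shared_fit
  g1 <- suppressWarnings(strain_gap(fit, cohort$panel, "strain",
                                    profile = c(sex = 0),
                                    n_draws = 200, seed = 3))
  g2 <- suppressWarnings(strain_gap(fit, cohort$panel, "strain",
                                    profile = c(sex = 0),
                                    n_draws = 200, seed = 3))
  expect_identical(g1$ci, g2$ci)
  expect_equal(unname(g1$difference["total"]),
               unname(g1$exposed$estimates["total"] -
                      g1$unexposed$estimates["total"]))
})

test_that("the report table carries the study layout and format", {
  cohort <- shared_cohort
  fit4 <- shared_fit
  d3 <- collapse_work_states(cohort$panel)
  fit3 <- suppressWarnings(wlemsm(d3))
  tab <- wle_table(fit4, cohort$panel, fit_total = fit3, data_total = d3,
                   n_draws = 50, seed = 2)
  expect_equal(nrow(tab), 4L)  # strain x sex
  expect_true(all(c("strain", "sex", "full-time", "part-time", "total",
                    "total_lo", "total_hi") %in% names(tab)))
  out <- capture.output(print(tab))
  expect_true(any(grepl("\\d+\\.\\d{2} \\(\\d+\\.\\d{2}, \\d+\\.\\d{2}\\)",
                        out)))
})
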