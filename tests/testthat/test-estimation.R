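test_that("starting values are log crude rates with zero slopes and betas", {
  # 2 observed 1->3 pairs over 20 person-years in state 1
  df <- data.frame(
    subject_id = c("a", "a", "b", "b", "c", "c"),
    age = c(50, 60, 50, 58, 55, 57),
    state = c("1", "3", "1", "3", "1", "1"))
  sp <- state_space(c("w", "n", "d"), absorbing = "d", working = "w")
  d <- panel_data(df, space = sp)
  st <- transition_structure(sp, rbind(c(1, 2), c(1, 3), c(2, 1), c(2, 3)))
  suppressWarnings(iv <- initial_values(d, st))
  expect_equal(unname(iv$log_q0[2]), log(2 / 20), tolerance = 1e-12)
  expect_true(all(iv$b_age == 0))
  # transitions never observed fall back to log(0.001) with a warning
  expect_warning(iv2 <- initial_values(d, st), "never observed")
  expect_equal(unname(iv2$log_q0[1]), log(0.001))
})

test_that("a constant hazard is recovered within 3 SE from exact deaths", {
  set.seed(101)
  mu <- 0.1
  n <- 2000
  death <- 50 + pmax(rexp(n, mu), 0.01)
  df <- do.call(rbind, lapply(seq_len(n), function(i) {
    if (death[i] < 70)
      data.frame(subject_id = i, age = c(50, round(death[i], 4)),
                 state = c("1", "2"))
    else data.frame(subject_id = i, age = c(50, 70), state = "1")
  }))
  d <- panel_data(df, space = two_state_space())
  fit <- wlemsm(d, control = list(polish = 5L))
  est <- fit$theta["alive->dead.logq0"]
  se <- sqrt(diag(fit$vcov))["alive->dead.logq0"]
  expect_true(fit$converged)
  expect_lt(abs(est - log(mu)), 3 * se)
  # fitted log-likelihood is at least the starting value's
  suppressWarnings(iv <- initial_values(d, fit$structure))
  expect_gte(fit$loglik, as.numeric(total_loglik(d, iv)) - 1e-8)
})

test_that("the optimum is start-point and subject-order invariant", {
  cohort <- well_observed_cohort(600, seed = 41)
  d <- cohort$panel
  fit1 <- wlemsm(d)
  fit2 <- wlemsm(d, start = cohort$scenario$params)  # start at the truth
  expect_lt(max(abs(fit1$theta - fit2$theta)), 1e-4)
  expect_equal(fit1$loglik, fit2$loglik, tolerance = 1e-9)

  set.seed(2)
  ids <- sample(unique(d$obs$subject_id))
  perm <- do.call(rbind, lapply(ids, function(i) d$obs[d$obs$subject_id == i, ]))
  perm$state <- wlemsm:::render_state_column(perm, 4)
  dp <- panel_data(perm[setdiff(names(perm), "cmask")], space = d$space)
  fit3 <- wlemsm(dp)
  expect_lt(max(abs(fit1$theta - fit3$theta)), 1e-6)

  # in a well-conditioned two-state model the optimum is sharp to 1e-8
  set.seed(5)
  death <- 50 + pmax(rexp(400, 0.1), 0.01)
  df <- do.call(rbind, lapply(1:400, function(i) {
    if (death[i] < 70)
      data.frame(subject_id = i, age = c(50, round(death[i], 3)),
                 state = c("1", "2"))
    else data.frame(subject_id = i, age = c(50, 70), state = "1")
  }))
  d2 <- panel_data(df, space = two_state_space())
  dfp <- do.call(rbind, lapply(rev(unique(df$subject_id)),
                               function(i) df[df$subject_id == i, ]))
  d2p <- panel_data(dfp, space = two_state_space())
  expect_lt(max(abs(wlemsm(d2)$theta - wlemsm(d2p)$theta)), 1e-8)
})

test_that("fit results carry a coherent covariance and loglik", {
  cohort <- well_observed_cohort(500, seed = 43)
  fit <- suppressWarnings(wlemsm(cohort$panel))
  expect_true(isSymmetric(fit$vcov, tol = 1e-10))
  expect_true(all(diag(fit$vcov) >= 0))
  expect_equal(as.numeric(total_loglik(cohort$panel, fit$params, fit$grid)),
               fit$loglik, tolerance = 1e-8)
  expect_equal(unname(coef(fit)), unname(fit$theta))
  expect_equal(attr(logLik(fit), "df"), 36L)
})

test_that("hazard ratios follow the closed form", {
  cohort <- well_observed_cohort(500, seed = 43)
  fit <- suppressWarnings(wlemsm(cohort$panel))
  hr <- hazard_ratios(fit, "strain")
  b <- fit$theta[paste0(hr$transition, ".strain")]
  se <- sqrt(diag(fit$vcov)[paste0(hr$transition, ".strain")])
  expect_equal(hr$hr, unname(exp(b)), tolerance = 1e-12)
  expect_equal(hr$lo95, unname(exp(b - 1.96 * se)), tolerance = 1e-12)
  expect_equal(hr$hi95, unname(exp(b + 1.96 * se)), tolerance = 1e-12)
  expect_error(hazard_ratios(fit, "nope"), "unknown covariate")

  # beta = 0 with se = 0.1 gives HR 1.00, CI (0.82, 1.22)
  fit0 <- fit
  nm <- paste0(transition_labels(fit$structure), ".strain")
  fit0$theta[nm] <- 0
  diag(fit0$vcov)[nm] <- 0.1^2
  hr0 <- hazard_ratios(fit0, "strain")
  expect_equal(hr0$hr, rep(1, 9))
  expect_equal(round(hr0$lo95, 2), rep(0.82, 9))
  expect_equal(round(hr0$hi95, 2), rep(1.22, 9))
})

test_that("a binary-covariate effect is recovered with near-nominal coverage", {
  # 2-state model, true HR 1.5 on the exit intensity, 50 scaled-down reps
  set.seed(77)
  st <- two_state_structure()
  truth <- intensity_params(st, covariates = "x", log_q0 = log(0.15),
                            b_age = 0, beta = log(1.5))
  cover <- logical(50)
  for (r in 1:50) {
    n <- 250
    x <- rbinom(n, 1, 0.5)
    rate <- 0.15 * 1.5^x
    death <- 50 + pmax(rexp(n, rate), 0.01)
    df <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (death[i] < 66)
        data.frame(subject_id = i, age = c(50, round(death[i], 3)),
                   state = c("1", "2"), x = x[i])
      else data.frame(subject_id = i, age = c(50, 66), state = "1", x = x[i])
    }))
    d <- panel_data(df, space = two_state_space())
    fit <- wlemsm(d, covariates = "x")
    ci <- hazard_ratios(fit, "x")[1, c("lo95", "hi95")]
    cover[r] <- ci$lo95 <= 1.5 && 1.5 <= ci$hi95
  }
  expect_gte(mean(cover), 0.85)  # binomial tolerance around 0.95 at 50 reps
})

test_that("variances shrink like 1/n", {
  set.seed(55)
  vars <- sapply(c(250, 500, 1000, 2000), function(n) {
    death <- 50 + pmax(rexp(n, 0.1), 0.01)
    df <- do.call(rbind, lapply(seq_len(n), function(i) {
      if (death[i] < 70)
        data.frame(subject_id = i, age = c(50, round(death[i], 3)),
                   state = c("1", "2"))
      else data.frame(subject_id = i, age = c(50, 70), state = "1")
    }))
    fit <- wlemsm(panel_data(df, space = two_state_space()))
    diag(fit$vcov)["alive->dead.logq0"]
  })
  slope <- coef(lm(log(vars) ~ log(c(250, 500, 1000, 2000))))[2]
  expect_gt(slope, -1.3)
  expect_lt(slope, -0.7)
})
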