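test_that("zero-length intervals give the identity matrix", {
  p <- two_state_params()
  expect_equal(unname(transition_probability(p, 60, 60)), diag(2))
  expect_equal(interval_loglik(p, 60, 60, from = 1, to = 1), 0)
})

test_that("constant-hazard survival matches the closed form", {
  p <- two_state_params(log_q0 = log(0.1))
  P <- transition_probability(p, 50, 55)
  expect_equal(P["alive", "dead"], 1 - exp(-0.5), tolerance = 1e-10)
  expect_rows_sum_to(P, 1)
  # exact death density: log( exp(-0.5) * 0.1 )
  expect_equal(interval_loglik(p, 50, 55, from = 1, to = 2),
               -0.5 + log(0.1), tolerance = 1e-10)
})

test_that("matrix exponential path matches an independent oracle to 1e-10", {
  set.seed(21)
  st <- transition_structure(work_state_space())
  for (rep in 1:20) {
    p <- intensity_params(st, log_q0 = rnorm(9, log(0.1), 1), b_age = 0)
    dt <- runif(1, 0.1, 8)
    P <- transition_probability(p, 50, 50 + dt)
    ref <- as.matrix(Matrix::expm(ref_Q(p, 50) * dt))
    expect_lt(max(abs(P - ref)), 1e-10)
  }
})

test_that("piecewise bands converge to the fine-grid Gompertz oracle", {
  p <- two_state_params(log_q0 = log(0.02), b_age = 0.08)
  oracle <- ref_tpm(p, 50, 75, width = 0.01)
  P1 <- transition_probability(p, 50, 75, grid = age_grid(width = 1))
  expect_lt(max(abs(P1 - oracle)), 1e-3)
  errs <- sapply(c(2, 1, 0.5, 0.25), function(w)
    max(abs(transition_probability(p, 50, 75, grid = age_grid(width = w)) -
            oracle)))
  expect_true(all(diff(errs) < 0))
})

test_that("Chapman-Kolmogorov holds across grid boundaries", {
  set.seed(31)
  st <- transition_structure(work_state_space())
  p <- intensity_params(st, log_q0 = rnorm(9, log(0.08), 0.6),
                        b_age = rnorm(9, 0.05, 0.1))
  for (ages in list(c(50.3, 56, 60.7), c(52, 53, 54), c(50, 61, 74.9))) {
    Pac <- transition_probability(p, ages[1], ages[3])
    Pab <- transition_probability(p, ages[1], ages[2])
    Pbc <- transition_probability(p, ages[2], ages[3])
    expect_lt(max(abs(Pac - Pab %*% Pbc)), 1e-10)
  }
})

test_that("censoring over all alive states carries no information", {
  p4 <- intensity_params(transition_structure(work_state_space()),
                         log_q0 = c(rep(log(0.1), 6), rep(-30, 3)))
  # with (numerically) no death hazard the censor-set term is log(1) = 0
  expect_equal(interval_loglik(p4, 50, 56, from = 1, censor_set = 1:3), 0,
               tolerance = 1e-8)
})

test_that("intervals may not start in the absorbing state", {
  p <- two_state_params()
  expect_error(interval_loglik(p, 50, 52, from = 2, to = 2), "absorbing")
})

test_that("total log-likelihood matches a hand-assembled oracle", {
  d <- toy_panel()
  st <- transition_structure(d$space)
  set.seed(77)
  p <- intensity_params(st, log_q0 = rnorm(9, log(0.1), 0.5), b_age = 0)
  ll <- total_loglik(d, p)

  # brute force: product of matrix-exponential entries, Matrix::expm only
  Q <- ref_Q(p, 50)
  Pint <- function(dt) as.matrix(Matrix::expm(Q * dt))
  ref <- log(Pint(2)[1, 2]) + log(Pint(2)[2, 1]) +   # subject a
    log(Pint(4)[1, 3]) +                              # subject b
    log(Pint(2)[2, 2]) +                              # subject c alive pair
    log(sum(Pint(0.6)[2, 1:3] * Q[1:3, 4]))           # c: exact death
  expect_equal(as.numeric(ll), ref, tolerance = 1e-8)
})

test_that("subjects observed once contribute nothing", {
  df <- data.frame(subject_id = c("a", "b", "c"), age = 50:52, state = "1")
  d <- panel_data(df, space = two_state_space())
  expect_equal(as.numeric(total_loglik(d, two_state_params())), 0)
})

test_that("likelihood is additive, order-invariant, and shard-invariant", {
  cohort <- small_cohort(80, seed = 17)
  d <- cohort$panel
  p <- cohort$scenario$params
  ll <- as.numeric(total_loglik(d, p))

  # duplicating every subject doubles it
  obs1 <- d$obs
  obs1$state <- wlemsm:::render_state_column(obs1, 4)
  obs2 <- obs1
  obs2$subject_id <- paste0(obs2$subject_id, "_dup")
  both <- rbind(obs1, obs2)[setdiff(names(obs1), "cmask")]
  d2 <- panel_data(both, space = d$space)
  expect_equal(as.numeric(total_loglik(d2, p)), 2 * ll, tolerance = 1e-9)

  # permuting subjects leaves it unchanged
  set.seed(1)
  ids <- sample(unique(d$obs$subject_id))
  perm <- do.call(rbind, lapply(ids, function(i) d$obs[d$obs$subject_id == i, ]))
  perm$state <- wlemsm:::render_state_column(perm, 4)
  dp <- panel_data(perm[setdiff(names(perm), "cmask")], space = d$space)
  expect_equal(as.numeric(total_loglik(dp, p)), ll, tolerance = 1e-10)

  # splitting into shards and summing reproduces it
  half <- unique(d$obs$subject_id)[1:40]
  mk <- function(ids) {
    sub <- d$obs[d$obs$subject_id %in% ids, ]
    sub$state <- wlemsm:::render_state_column(sub, 4)
    panel_data(sub[setdiff(names(sub), "cmask")], space = d$space)
  }
  lls <- as.numeric(total_loglik(mk(half), p)) +
    as.numeric(total_loglik(mk(setdiff(unique(d$obs$subject_id), half)), p))
  expect_equal(lls, ll, tolerance = 1e-9)
})

test_that("analytic scores agree with central finite differences", {
  cohort <- small_cohort(60, seed = 23)
  pi_ <- wlemsm:::panel_intervals(cohort$panel)
  spec <- wlemsm:::lik_spec(cohort$scenario$params$structure,
                            c("strain", "sex"), age_grid(), pi_$Z)
  theta <- wlemsm:::ip_flatten(cohort$scenario$params)
  r <- wlemsm:::cpp_panel_loglik(theta, spec, pi_$ints, TRUE)
  num <- vapply(seq_along(theta), function(j) {
    e <- numeric(length(theta)); e[j] <- 1e-6
    (wlemsm:::cpp_panel_loglik(theta + e, spec, pi_$ints, FALSE)$loglik -
     wlemsm:::cpp_panel_loglik(theta - e, spec, pi_$ints, FALSE)$loglik) / 2e-6
  }, numeric(1))
  expect_lt(max(abs(r$grad - num)), 1e-5 * max(1, max(abs(num))))
})
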