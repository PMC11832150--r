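test_that("zero intensities give a jump-free censored trajectory", {
  p <- intensity_params(transition_structure(work_state_space()),
                        log_q0 = -300)  # numerically zero rates
  set.seed(1)
  tr <- simulate_trajectory(p, 53, 1, profile = numeric(0), age_max = 80)
  expect_equal(tr$states, 1L)
  expect_true(is.na(tr$death_age))
  expect_equal(tr$end_age, 80)
})

test_that("entry from the absorbing state is rejected", {
  p <- two_state_params()
  expect_error(simulate_trajectory(p, 50, 2), "non-absorbing")
})

test_that("exponential death waits have the right mean", {
  set.seed(7)
  p <- two_state_params(log_q0 = log(0.1))
  waits <- replicate(10000, {
    tr <- simulate_trajectory(p, 50, 1, age_max = 1e6)
    tr$death_age - 50
  })
  expect_lt(abs(mean(waits) - 10), 3 * sd(waits) / sqrt(10000))
})

test_that("thinning reproduces the Gompertz intensities band by band", {
  # empirical jumps vs integrated hazard, per transition, Poisson tolerance
  set.seed(19)
  sp <- state_space(c("w", "n", "d"), absorbing = "d", working = "w")
  st <- transition_structure(sp)
  # transitions: w->n, n->w, w->d, n->d
  p <- intensity_params(st, log_q0 = log(c(0.10, 0.15, 0.01, 0.02)),
                        b_age = c(0.12, -0.08, 0.10, 0.06))
  n_traj <- 4000
  exposure <- matrix(0, 3, 25)   # person-years by state x band
  jumps <- array(0, c(length(st$from), 25))
  for (i in seq_len(n_traj)) {
    tr <- simulate_trajectory(p, 50, sample(1:2, 1), age_max = 75)
    ts <- c(tr$times, tr$end_age)
    for (j in seq_along(tr$states)) {
      a1 <- ts[j]; a2 <- ts[j + 1]; s <- tr$states[j]
      if (s == 3) break
      for (b in floor(a1 - 50):min(floor(a2 - 50 + 1 - 1e-9), 24)) {
        lo <- max(a1, 50 + b); hi <- min(a2, 51 + b)
        if (hi > lo) exposure[s, b + 1] <- exposure[s, b + 1] + (hi - lo)
      }
      if (j < length(tr$states)) {
        t_idx <- which(st$from == s & st$to == tr$states[j + 1])
        jumps[t_idx, min(floor(a2 - 50), 24) + 1] <-
          jumps[t_idx, min(floor(a2 - 50), 24) + 1] + 1
      }
    }
  }
  # aggregate to 5-year blocks for adequate counts
  for (t in seq_along(st$from)) {
    for (blk in 1:4) {
      bands <- ((blk - 1) * 5 + 1):(blk * 5)
      expected <- 0
      for (b in bands) {
        mid_ages <- 50 + b - 1 + c(0.1, 0.3, 0.5, 0.7, 0.9)
        qbar <- mean(exp(p$log_q0[t] + p$b_age[t] * (mid_ages - 50)))
        expected <- expected + exposure[st$from[t], b] * qbar
      }
      if (expected < 20) next
      obs <- sum(jumps[t, bands])
      expect_lt(abs(obs - expected), 4 * sqrt(expected))
    }
  }
})

test_that("the observation operator records the latent state exactly", {
  cohort <- small_cohort(150, seed = 29)
  obs <- cohort$panel$obs
  trajs <- cohort$trajectories
  names(trajs) <- vapply(trajs, `[[`, "", "subject_id")
  for (i in seq_len(nrow(obs))) {
    tr <- trajs[[obs$subject_id[i]]]
    if (obs$state[i] == 4) {
      expect_equal(obs$age[i], round(tr$death_age, 2))
    } else {
      expect_equal(obs$state[i], wlemsm:::state_at(tr, obs$age[i]))
    }
  }
})

test_that("a between-wave spell is invisible in the panel", {
  sp <- work_state_space()
  tr <- structure(list(times = c(50, 51.2, 51.3), states = c(1L, 3L, 1L),
                       death_age = NA_real_, end_age = 110,
                       profile = c(strain = 0, sex = 0), subject_id = "x"),
                  class = "work_trajectory")
  set.seed(3)
  d <- observe_cohort(list(tr), cohort_design(n_subjects = 1), space = sp)
  expect_true(all(d$obs$state == 1L))  # the not-in-work spell is unseen
})

test_that("entry states, strain prevalence, and ages match the design", {
  cohort <- make_study_cohort(default_scenario(n_subjects = 4000), seed = 31)
  obs <- cohort$panel$obs
  first <- obs[!duplicated(obs$subject_id), ]
  men <- first$sex == 0
  # male full-time share at entry ~ 92.9%
  p_ft <- mean(first$state[men] == 1)
  expect_lt(abs(p_ft - 0.929),
            3 * sqrt(0.929 * 0.071 / sum(men)))
  # male strain prevalence ~ 15.7%, female ~ 21.2%
  expect_lt(abs(mean(first$strain[men]) - 0.157),
            3 * sqrt(0.157 * 0.843 / sum(men)))
  expect_lt(abs(mean(first$strain[!men]) - 0.212),
            3 * sqrt(0.212 * 0.788 / sum(!men)))
  expect_true(all(first$age >= 50 & first$age <= 75))
  expect_lt(abs(mean(first$age) - 56.6), 0.5)  # truncated N(56, 5) mean
})

test_that("same seed gives byte-identical panels, different seeds differ", {
  f1 <- tempfile(); f2 <- tempfile(); f3 <- tempfile()
  write_panel(make_study_cohort(default_scenario(n_subjects = 120),
                                seed = 99)$panel, f1)
  write_panel(make_study_cohort(default_scenario(n_subjects = 120),
                                seed = 99)$panel, f2)
  write_panel(make_study_cohort(default_scenario(n_subjects = 120),
                                seed = 100)$panel, f3)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_false(identical(unname(tools::md5sum(f1)),
                         unname(tools::md5sum(f3))))
  unlink(c(f1, f2, f3))
})

test_that("a null strain effect gives identical true WLEs across strain", {
  scen <- default_scenario(n_subjects = 50, strain_hr = 1)
  cohort <- make_study_cohort(scen, seed = 3)
  tw <- cohort$true_wle
  for (sx in 0:1)
    expect_equal(tw$total[tw$sex == sx & tw$strain == 0],
                 tw$total[tw$sex == sx & tw$strain == 1], tolerance = 1e-10)
})

test_that("the job-strain coder applies strict median splits", {
  # all-maximal demands, all-minimal control, midpoint medians
  meds <- list(demands = 2.5, control = 2.5, score = 0)
  expect_equal(as.integer(assign_job_strain(rep(1, 4), rep(4, 5), meds,
                                            rule = "quadrant")), 1L)
  expect_equal(as.integer(assign_job_strain(rep(1, 4), rep(4, 5), meds,
                                            rule = "score-median")), 1L)
  # demands exactly at the median code as no strain ("above" is strict)
  d_at_median <- c(2, 3, 2, 3)   # reverse-coded mean exactly 2.5
  expect_equal(as.integer(assign_job_strain(d_at_median, rep(4, 5), meds,
                                            rule = "quadrant")), 0L)
  expect_error(assign_job_strain(rep(0, 4), rep(4, 5), meds, "quadrant"),
               "1..4")
  expect_error(assign_job_strain(rep(1, 3), rep(4, 5), meds, "quadrant"),
               "4 items")
})

test_that("quadrant prevalence under independent items matches enumeration", {
  # exact P(mean > 2.5) for 4 and 5 iid uniform{1..4} items by enumeration
  mean4 <- rowMeans(expand.grid(rep(list(1:4), 4)))
  mean5 <- rowMeans(expand.grid(rep(list(1:4), 5)))
  p_above <- mean(mean4 > 2.5)
  p_below <- mean(mean5 < 2.5)
  p_exact <- p_above * p_below
  set.seed(41)
  n <- 5000
  dem <- matrix(sample(1:4, n * 4, TRUE), n, 4)
  ctr <- matrix(sample(1:4, n * 5, TRUE), n, 5)
  meds <- list(demands = 2.5, control = 2.5)
  strain <- assign_job_strain(dem, ctr, meds, rule = "quadrant")
  expect_lt(abs(mean(strain) - p_exact),
            3 * sqrt(p_exact * (1 - p_exact) / n))
  # enumeration value is close to the idealized continuous quarter
  expect_lt(abs(p_exact - 0.25), 0.08)
})
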