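# wlemsm

Working life expectancy (WLE) from panel-observed continuous-time
multi-state Markov models of late-career work states.

## The problem

Older workers move between full-time work, part-time work, and being out of
work, and may die; surveys observe these states only at biennial
questionnaire waves (with deaths exactly dated through register linkage),
so transition times are interval-censored.  `wlemsm` is for researchers in
occupational epidemiology and labour studies who want to estimate how long
people can be expected to keep working past age 50 — in total, full-time,
and part-time — and how an exposure such as Karasek job strain (high
demands combined with low control) changes that expectancy.

## The model

States $r = 1..n$ with one absorbing death state; instantaneous transition
intensities are Gompertz (log-linear in age) with proportional covariate
effects,

$$q_{rs}(a, z) = \exp\big(\log q^{(0)}_{rs} + b_{rs}(a - 50) + \beta_{rs}^\top z\big),$$

frozen within 1-year age bands so that interval transition probabilities
are products of matrix exponentials, $P(a_1,a_2)=\prod_k \exp(Q_k\Delta_k)$.
The interval-censored panel likelihood (with exact-death density terms and
censor-set terms) is maximised by BFGS with analytic scores; the asymptotic
covariance is the inverse observed information.  State occupancies
$\pi_0^\top P(50,u)$ are integrated over age (trapezoid, horizon 75) to
give marginal WLEs, with 95% CIs from 500 parameter draws out of the MLE's
asymptotic normal distribution.  A synthetic-cohort generator emulating a
biennial occupational panel study (entry ages ~ N(56,5) on [50,75], 2–7
waves per subject, ~90% full-time at entry, strain prevalence ~16%/21% by
sex, exactly dated deaths) provides ground truth for every stage.

## Worked example

```r
library(wlemsm)

cohort <- make_study_cohort(default_scenario(), seed = 1)    # n = 3000
fit4   <- wlemsm(cohort$panel)                   # four-state model
panel3 <- collapse_work_states(cohort$panel)
fit3   <- wlemsm(panel3)                         # three-state (total WLE)

hazard_ratios(fit3, "strain")
wle_table(fit4, cohort$panel, fit_total = fit3, data_total = panel3,
          n_draws = 500, seed = 7)
```

```
            transition    hr  lo95 hi95   beta     se
1 working->not in work 1.302 1.117 1.52  0.264 0.0779
2 not in work->working 0.916 0.615 1.36 -0.088 0.2032
3       working->death 0.724 0.284 1.85 -0.323 0.4773
4   not in work->death 0.725 0.367 1.43 -0.322 0.3468

Working life expectancies (years, 95% CI)
 strain sex            full-time         part-time                total
      0   0 11.21 (10.75, 11.58) 2.13 (1.79, 2.50) 13.38 (12.95, 13.73)
      1   0 11.39 (10.64, 11.89) 1.31 (0.96, 1.67) 12.62 (12.08, 13.18)
      0   1  10.00 (9.58, 10.39) 2.97 (2.60, 3.36) 12.97 (12.68, 13.26)
      1   1   9.95 (9.30, 10.48) 2.14 (1.73, 2.62) 12.18 (11.69, 12.67)
```

Reading the output: the fitted hazard ratio of job strain on the
work-to-not-in-work exit is 1.30 (95% CI 1.12-1.52) -- strained workers
leave work faster -- and men without strain are expected to work 13.38 more
years from age 50 (95% CI 12.95-13.73; the generator's true value for this
profile is 13.47).  The paired-draw strain contrast

```r
g <- strain_gap(fit3, panel3, "strain", profile = c(sex = 0),
                n_draws = 500, seed = 9)
```

gives a total-WLE shortfall under strain of 0.75 years (95% CI 0.24-1.34)
for men in this simulated cohort: the strain hazard ratio of 1.35 on both
work-exit intensities translates into about three quarters of a year of
working life.

A thin command-line driver with `simulate`, `fit` (with `--three-state`),
and `wle` subcommands lives at `inst/cli/wlemsm.R`.

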