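# MAP individual estimation and exposure derivation at evaluation dates.

pop <- isa_final_model()

test_that("no observations returns the prior mode (typical values)", {
  d <- dose_events((0:9) * 24, 200)
  s <- subject_record("m0", d, observations(24, NA_real_,
                                            is_missing = TRUE))
  s$covariates <- data.frame(time = 0, bmi = 30)
  m <- map_fit(s, pop)
  expect_equal(c(m$eta_cl, m$eta_v), c(0, 0))
  expect_equal(m$cl, pop$tvcl)
  expect_equal(m$v, pop$tvv * 30 / 25)
})

test_that("with a diffuse prior, rich noise-free data recover the etas", {
  # additive-only residual model: constant variance makes the MAP limit a
  # pure least-squares fit, which noise-free data pin at the true etas
  true_eta <- c(0.31, -0.24)
  gen <- population_model(sigma_prop = 0)
  s <- make_rich_subject(eta_cl = true_eta[1], eta_v = true_eta[2],
                         pop = gen)
  pop_diffuse <- population_model(omega_cl = 37, omega_v = 34,
                                  sigma_prop = 0)
  m <- map_fit(s, pop_diffuse)
  expect_lt(abs(m$eta_cl - true_eta[1]), 0.01)
  expect_lt(abs(m$eta_v - true_eta[2]), 0.01)
})

test_that("a single noise-free trough is shrunk toward the prior mode", {
  s <- make_rich_subject(n_days = 150, obs_times = 150 * 24 - 0.5)
  m <- map_fit(s, pop)  # data generated at eta = 0
  expect_lt(abs(m$eta_cl), 0.05)
  expect_lt(abs(m$eta_v), 0.05)
  ind <- list(cl = m$cl, v = m$v, ka = m$ka)
  expect_lt(abs(cmin_ss(200, 24, ind) - cmin_ss(200, 24,
                                                individual_parameters(pop))),
            pop$sigma_add)
})

test_that("exposure at a steady-state date matches the closed forms", {
  s <- make_rich_subject(n_days = 150,
                         obs_times = c(100 * 24 - 0.5, 149 * 24 - 0.5))
  # a typical-parameter estimate isolates the date/exposure logic
  m <- list(cl = 2.3, v = 523, ka = 2.5, n_obs = 2)
  e <- exposure_at_date(m, s, date = 149 * 24)
  expect_equal(e$cmin, 3.4414, tolerance = 1e-3)
  expect_equal(e$auc, 86.96, tolerance = 0.02)
  expect_equal(e$daily_dose, 200)
  # doubling the regimen doubles both outputs
  s2 <- s
  s2$doses$amount <- 400
  s2$observations$value <- 2 * s2$observations$value
  e2 <- exposure_at_date(m, s2, date = 149 * 24)
  expect_equal(e2$cmin, 2 * e$cmin, tolerance = 1e-6)
  expect_equal(e2$auc, 2 * e$auc, tolerance = 1e-6)
})

test_that("eligibility rules gate the evaluation date", {
  s <- make_rich_subject(n_days = 10, obs_times = c(47.5, 120))
  m <- map_fit(s, pop)
  expect_error(exposure_at_date(m, s, date = -5), "precedes")
  expect_error(exposure_at_date(m, s, date = 120 + 51 * 24),
               "50 days")
  e <- exposure_at_date(m, s, date = 150)
  expect_gt(e$cmin, 0)
})

test_that("the exposure table runs over a cohort and flags the ineligible", {
  g <- generate_cohort(cohort_spec(n_subjects = 6), seed = 51)
  tab <- exposure_table(g$subjects, pop)
  expect_equal(nrow(tab), 6)
  expect_true(all(tab$cmin > 0, na.rm = TRUE))
  expect_true(all(tab$n_observations_used >= 1))
})

test_that("vectorized trough MAP agrees with the generic MAP fitter", {
  set.seed(52)
  n <- 25
  bmi <- runif(n, 15, 38)
  eta1 <- rnorm(n, 0, pop$omega_cl); eta2 <- rnorm(n, 0, pop$omega_v)
  ind <- individual_parameters(pop, bmi, eta1, eta2)
  y <- cmin_ss(200, 24, ind) * (1 + rnorm(n, 0, pop$sigma_prop)) +
    rnorm(n, 0, pop$sigma_add)
  y <- pmax(y, 0.05)
  vec <- isatdm:::.map_fit_trough_vec(y, bmi, pop, 200)
  for (i in c(1, 7, 19)) {
    s <- make_rich_subject(bmi = bmi[i], n_days = 150,
                           obs_times = 150 * 24 - 0.5)
    s$observations$value <- y[i]
    m <- map_fit(s, pop)
    expect_lt(abs(vec$eta_cl[i] - m$eta_cl), 0.02)
    expect_lt(abs(vec$eta_v[i] - m$eta_v), 0.02)
  }
})

test_that("MAP limits: omega to zero and to infinity", {
  gen <- population_model(sigma_prop = 0)
  s <- make_rich_subject(eta_cl = 0.4, eta_v = 0.2, pop = gen)
  tiny <- population_model(omega_cl = 1e-6, omega_v = 1e-6)
  m <- map_fit(s, tiny)
  expect_lt(abs(m$eta_cl), 1e-3)
  huge <- population_model(omega_cl = 50, omega_v = 50, sigma_prop = 0)
  m2 <- map_fit(s, huge)
  expect_lt(abs(m2$eta_cl - 0.4), 0.01)
  expect_lt(abs(m2$eta_v - 0.2), 0.01)
})
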