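# Closed-form structural model: single-dose, steady-state and derived
# exposure metrics, checked against hand evaluations and numeric oracles.

pop <- isa_final_model()
typ <- individual_parameters(pop)  # cl 2.3, v 523, ka 2.5

test_that("individual parameter equations follow the covariate model", {
  expect_equal(typ$cl, 2.3)
  expect_equal(typ$v, 523)
  expect_equal(individual_parameters(pop, bmi = 50)$v, 1046)
  expect_equal(individual_parameters(pop, eta_cl = log(2))$cl, 4.6)
  # base model carries no BMI effect
  expect_equal(individual_parameters(isa_base_model(), bmi = 50)$v, 550)
  expect_error(individual_parameters(pop, bmi = -1), "bmi")
})

test_that("single-dose concentration matches the closed form", {
  d <- dose_events(0, 200)
  ke <- 2.3 / 523
  hand <- 200 * 2.5 / (523 * (2.5 - ke)) * (exp(-ke * 24) - exp(-2.5 * 24))
  expect_equal(concentration(24, d, typ), hand)
  expect_equal(round(concentration(24, d, typ), 4), 0.3447)
  expect_equal(concentration(0, d, typ), 0)   # pre-dose
  # superposition: two doses = sum of two shifted single-dose profiles
  d2 <- dose_events(c(0, 24), 200)
  expect_equal(concentration(30, d2, typ),
               concentration(30, d, typ) + concentration(6, d, typ))
  # dose linearity
  expect_equal(concentration(18, dose_events(0, 400), typ),
               2 * concentration(18, d, typ))
})

test_that("IV bolus and infusion routes use the standard solutions", {
  ke <- 2.3 / 523
  bolus <- dose_events(0, 200, route = "iv")
  expect_equal(concentration(10, bolus, typ), 200 / 523 * exp(-ke * 10))
  inf <- dose_events(0, 200, route = "iv", infusion_duration = 1)
  r0 <- 200 / 1
  expect_equal(concentration(0.5, inf, typ),
               r0 / 2.3 * (1 - exp(-ke * 0.5)))
  expect_equal(concentration(5, inf, typ),
               r0 / 2.3 * (1 - exp(-ke * 1)) * exp(-ke * 4))
  expect_error(dose_events(0, 200, route = "oral", infusion_duration = 1),
               "oral")
})

test_that("steady-state trough matches its formula and brute force", {
  expect_equal(round(cmin_ss(200, 24, typ), 3), 3.441)
  # long-run superposition: 20 half-lives of once-daily dosing
  n_doses <- ceiling(20 * half_life(typ) / 24)
  brute <- superposition_trough_oracle(200, 24, 2.3, 523, 2.5, n_doses)
  expect_lt(abs(cmin_ss(200, 24, typ) - brute) / brute, 0.001)
  expect_equal(cmin_ss(400, 24, typ), 2 * cmin_ss(200, 24, typ))
  expect_error(cmin_ss(200, 0, typ), "tau")
})

test_that("steady-state AUC equals dose/CL and the numeric integral", {
  expect_equal(auc_ss(200, typ), 200 / 2.3)
  expect_equal(round(auc_ss(200, typ), 2), 86.96)
  expect_equal(auc_ss(100, list(cl = 2, v = 500, ka = 2.5)), 50)
  num <- trapz_auc_oracle(200, 24, typ)
  expect_lt(abs(auc_ss(200, typ) - num) / num, 0.005)
})

test_that("tmax matches the analytic form and the numeric argmax", {
  base_ind <- individual_parameters(isa_base_model())  # cl 2.2, v 550
  expect_equal(round(tmax(base_ind), 1), 2.6)
  tt <- seq(0.01, 12, by = 0.001)
  cc <- concentration(tt, dose_events(0, 200), base_ind)
  expect_lt(abs(tmax(base_ind) - tt[which.max(cc)]), 0.01)
  # monotonicity: larger ka, same ke => earlier peak
  faster <- list(cl = 2.2, v = 550, ka = 5)
  expect_lt(tmax(faster), tmax(base_ind))
  expect_error(tmax(list(cl = 10, v = 1, ka = 2.5)), "ka > ke")
})

test_that("half-life is ln2 V/CL and scale-invariant", {
  expect_equal(round(half_life(typ), 1), 157.6)
  expect_equal(half_life(list(cl = log(2), v = 1)), 1)
  scaled <- list(cl = 2.3 * 3, v = 523 * 3)
  expect_equal(half_life(scaled), half_life(typ))
})

test_that("model constructors validate their inputs", {
  expect_error(population_model(tvcl = -1), "positive")
  expect_error(population_model(f_oral = 0), "f_oral")
  expect_error(population_model(sigma_add = -0.1), "non-negative")
  expect_equal(cv_to_omega(37), 0.37)
  expect_equal(cv_to_omega(37, exact = TRUE), sqrt(log(1 + 0.37^2)))
})
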