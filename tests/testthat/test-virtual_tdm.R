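# Virtual steady-state cohort and TDM dose-adjustment strategies.

pop <- isa_final_model()

test_that("zero variability collapses the cohort to the typical patient", {
  pop0 <- population_model(omega_cl = 0, omega_v = 0, sigma_prop = 0,
                           sigma_add = 0.001)
  co <- simulate_cohort(50, pop0, bmi_range = c(25, 25), seed = 61)
  expect_true(all(co$cl == 2.3))
  expect_true(all(co$v == 523))
  expect_equal(unique(round(co$ipred_true_cmin, 4)), 3.4414)
  expect_equal(unique(co$auc_true), 200 / 2.3)
})

test_that("the half-life filter keeps every patient inside its bounds", {
  co <- simulate_cohort(3000, pop, half_life_bounds = c(40, 400), seed = 62)
  expect_true(all(co$half_life >= 40 & co$half_life <= 400))
  expect_true(all(co$cmin_ruv > 0))
  expect_error(simulate_cohort(500, pop, half_life_bounds = c(1, 2),
                               seed = 63),
               "reject more than half")
  expect_error(simulate_cohort(10, pop, half_life_bounds = c(40, 30)),
               "ordered")
})

test_that("attainment counts inclusive-boundary membership", {
  co <- data.frame(ipred_true_cmin = c(2.0, 2.5, 3.0, 6.0),
                   auc_true = c(50, 60, 100, 233))
  a <- attainment(co)
  expect_equal(a$pct_cmin_in_range, 50)
  expect_equal(a$pct_auc_in_range, 75)
  expect_error(attainment(co, cmin_range = c(5, 2.5)), "ordered")
})

test_that("the proportional rule rounds to allowed doses, ties down", {
  expect_equal(adjust_dose_proportional(200, 1.77, 3.536), 400)
  expect_equal(adjust_dose_proportional(200, 3.536, 3.536), 200)
  expect_equal(adjust_dose_proportional(200, 14.0, 3.536), 100)
  # exact midpoint 150 between 100 and 200 breaks to the lower dose
  expect_equal(adjust_dose_proportional(200, 4, 3), 100)
  x <- adjust_dose_proportional(200, c(0.5, 2, 3.5, 9), 3.5)
  expect_true(all(x %in% c(100, 200, 300, 400)))
  expect_error(adjust_dose_proportional(200, 0, 3.5), "positive")
})

test_that("strategy none reproduces the raw attainment", {
  co <- simulate_cohort(500, pop, seed = 64)
  res <- apply_strategy(co, tdm_strategy("none"))
  a <- attainment(co)
  expect_equal(res$summary$pct_cmin_in_range, a$pct_cmin_in_range)
  expect_equal(res$summary$pct_auc_in_range, a$pct_auc_in_range)
  expect_identical(res$cohort$new_dose, co$dose)
})

test_that("all strategies keep doses in the allowed set and help, not harm", {
  co <- simulate_cohort(4000, pop, seed = 65)
  before <- attainment(co)
  for (kind in c("proportional_cmin", "mipd_cmin", "mipd_auc")) {
    res <- apply_strategy(co, tdm_strategy(kind), pop)
    expect_true(all(res$cohort$new_dose %in% c(100, 200, 300, 400)))
    expect_gt(res$summary$pct_auc_in_range,
              before$pct_auc_in_range - 1)
  }
  res_c <- apply_strategy(co, tdm_strategy("proportional_cmin"), pop)
  expect_gt(res_c$summary$pct_cmin_in_range,
            before$pct_cmin_in_range - 1)
})

test_that("with no residual error, proportional and MIPD decisions agree", {
  pop0 <- population_model(sigma_prop = 0, sigma_add = 0)
  co <- simulate_cohort(400, pop0, seed = 66)
  expect_equal(co$cmin_ruv, co$ipred_true_cmin)
  prop <- apply_strategy(co, tdm_strategy("proportional_cmin"), pop0)
  mipd <- apply_strategy(co, tdm_strategy("mipd_cmin"), pop0)
  expect_equal(mipd$cohort$new_dose, prop$cohort$new_dose)
})

test_that("patients already on target keep their dose", {
  co <- simulate_cohort(800, pop, seed = 67)
  res <- apply_strategy(co, tdm_strategy("proportional_cmin"), pop)
  inside <- co$cmin_ruv >= 2.5 & co$cmin_ruv <= 5
  expect_true(all(res$cohort$new_dose[inside] == co$dose[inside]))
})

test_that("strategy constructor derives the geometric-mean target", {
  s <- tdm_strategy("proportional_cmin")
  expect_equal(s$target_value, sqrt(2.5 * 5))
  s2 <- tdm_strategy("mipd_auc")
  expect_equal(s2$target_range, c(60, 233))
  expect_equal(s2$target_value, sqrt(60 * 233))
  expect_error(tdm_strategy("proportional_cmin", target_range = c(5, 2.5)),
               "ordered")
})

test_that("analytic lognormal theory predicts the no-TDM attainment", {
  # with IIV on CL only and fixed BMI, the trough is monotone in CL, so
  # attainment has a closed form through the lognormal CDF
  pop1 <- population_model(omega_v = 0, sigma_prop = 0, sigma_add = 0.001)
  co <- simulate_cohort(20000, pop1, bmi_range = c(25, 25),
                        half_life_bounds = c(1, 1e5), seed = 68)
  cl_at <- function(cmin_target) {
    f <- function(cl) cmin_ss(200, 24, list(cl = cl, v = 523, ka = 2.5)) -
      cmin_target
    uniroot(f, c(0.1, 50))$root
  }
  p_theory <- 100 * (plnorm(cl_at(2.5), log(2.3), 0.37) -
                       plnorm(cl_at(5.0), log(2.3), 0.37))
  sim <- attainment(co)$pct_cmin_in_range
  expect_lt(abs(sim - p_theory), 2)
})
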