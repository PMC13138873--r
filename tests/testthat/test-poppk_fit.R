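# Laplace marginal likelihood, fitting, model comparison, CWRES,
# bootstrap and shrinkage.

pop <- isa_final_model()

test_that("degenerate prior collapses the OFV to the fixed-eta -2LL", {
  g <- generate_cohort(cohort_spec(n_subjects = 2), seed = 31)
  pop0 <- population_model(omega_cl = 1e-9, omega_v = 1e-9)
  ofv <- as.numeric(marginal_neg2ll(g$subjects, pop0))
  direct <- sum(vapply(g$subjects, function(s) {
    o <- s$observations
    bmi <- interpolate_covariate(s$covariates, "bmi", 0)
    ind <- individual_parameters(pop0, bmi)
    f <- concentration(o$time, s$doses, ind, 1)
    v <- f^2 * pop0$sigma_prop^2 + pop0$sigma_add^2
    -2 * sum(dnorm(o$value, f, sqrt(v), log = TRUE))
  }, numeric(1)))
  expect_equal(ofv, direct, tolerance = 1e-5)
})

test_that("Laplace agrees with 2-D quadrature and AGQ converges to it", {
  g <- generate_cohort(cohort_spec(n_subjects = 2, samples_per_subject = 4),
                       seed = 32)
  q <- quad_ofv_oracle(g$subjects, pop)
  l <- as.numeric(marginal_neg2ll(g$subjects, pop))
  a <- as.numeric(marginal_neg2ll(g$subjects, pop, method = "agq",
                                  agq_nodes = 21))
  expect_lt(abs(l - q) / abs(q), 0.02)    # Laplace approximation quality
  expect_lt(abs(a - q) / abs(q), 1e-4)    # quadrature-grade agreement
})

test_that("the OFV is additive over independent subjects", {
  g <- generate_cohort(cohort_spec(n_subjects = 3), seed = 33)
  one <- as.numeric(marginal_neg2ll(g$subjects, pop))
  two <- as.numeric(marginal_neg2ll(c(g$subjects, g$subjects), pop))
  expect_equal(two, 2 * one, tolerance = 1e-10)
})

test_that("a fully masked fit returns the start unchanged", {
  g <- generate_cohort(cohort_spec(n_subjects = 3), seed = 34)
  f <- fit_poppk(g$subjects, start = pop, fixed = "all")
  expect_equal(f$pop$tvcl, pop$tvcl)
  expect_equal(f$n_params, 0)
  expect_equal(f$ofv, as.numeric(marginal_neg2ll(g$subjects, pop)))
  expect_true(f$converged)
})

test_that("a small fit recovers plausible estimates with diagnostics", {
  g <- generate_cohort(cohort_spec(n_subjects = 50, samples_per_subject = 6,
                                   frac_trough = 0.4,
                                   treatment_days = c(21, 28)), seed = 35)
  f <- fit_poppk(g$subjects, start = pop, fixed = "ka", n_starts = 1)
  expect_true(f$converged)
  expect_lt(abs(f$pop$tvcl / 2.3 - 1), 0.25)
  expect_true(all(is.finite(f$rse)) && all(f$rse > 0))
  expect_true(all(f$shrinkage <= 100 + 1e-6))
  expect_equal(dim(f$ebes), c(50, 2))
  # refitting self-fitted data from the optimum does not move the OFV up
  f2 <- fit_poppk(g$subjects, start = f$pop, fixed = "ka", n_starts = 1,
                  compute_rse = FALSE, compute_cwres = FALSE)
  expect_lt(f2$ofv, f$ofv + 0.5)
})

test_that("likelihood-ratio decisions follow the stated thresholds", {
  fake <- function(ofv, k) structure(list(ofv = ofv, n_params = k),
                                     class = "poppk_fit")
  r <- lrt_compare(fake(100, 3), fake(89, 4), mode = "forward")
  expect_equal(r$decision, "accept_complex")  # dOFV -11, p < 0.01
  expect_lt(r$p_value, 0.01)
  r <- lrt_compare(fake(100, 3), fake(100 - qchisq(0.95, 1), 4), "forward")
  expect_equal(r$decision, "accept_complex")  # boundary inclusive
  r <- lrt_compare(fake(100, 3), fake(98, 4), "forward")
  expect_equal(r$decision, "keep_simple")
  r <- lrt_compare(fake(100, 3), fake(94, 4), "backward")
  expect_equal(r$decision, "keep_simple")  # -6.0 not enough at 0.01
  r <- lrt_compare(fake(100, 3), fake(93, 4), "backward")
  expect_equal(r$decision, "accept_complex")  # -7.0 beats 6.63
  expect_error(lrt_compare(fake(1, 3), fake(1, 3)), "more parameters")
})

test_that("AIC selection needs a decrease of at least two", {
  fake <- function(ofv, k) structure(list(ofv = ofv, n_params = k),
                                     class = "poppk_fit")
  expect_equal(aic_compare(fake(100, 3), fake(96, 4))$decision,
               "accept_alternative")  # dAIC = -2
  expect_equal(aic_compare(fake(100, 3), fake(96.1, 4))$decision,
               "keep_reference")      # dAIC = -1.9
  expect_equal(aic_compare(fake(100, 3), fake(98, 4))$decision,
               "keep_reference")      # equal AIC
})

test_that("empty or unquantified candidate lists degrade gracefully", {
  g <- generate_cohort(cohort_spec(n_subjects = 12), seed = 36)
  base <- fit_poppk(g$subjects, start = pop, fixed = "all")
  sw <- stepwise_covariates(g$subjects, base, data.frame())
  expect_identical(sw$fit$ofv, base$ofv)
  cands <- data.frame(param = "cl", cov = "egfr_missing", form = "power",
                      stringsAsFactors = FALSE)
  expect_warning(sw2 <- stepwise_covariates(g$subjects, base, cands),
                 "skipped")
  expect_identical(sw2$fit$ofv, base$ofv)
})

test_that("gross outliers are flagged by CWRES and threshold Inf is empty", {
  g <- generate_cohort(cohort_spec(n_subjects = 20, samples_per_subject = 4),
                       seed = 37)
  # corrupt the subject's largest observation to 10x its value
  j <- which.max(g$subjects[[3]]$observations$value)
  g$subjects[[3]]$observations$value[j] <-
    10 * g$subjects[[3]]$observations$value[j]
  f <- fit_poppk(g$subjects, start = pop, fixed = "all")
  flagged <- cwres_flag(f, threshold = 3)
  expect_true(any(flagged$subject_id == g$subjects[[3]]$subject_id &
                    flagged$time == g$subjects[[3]]$observations$time[j]))
  expect_equal(nrow(cwres_flag(f, threshold = Inf)), 0)
})

test_that("bootstrap resampling is reproducible with ordered intervals", {
  g <- generate_cohort(cohort_spec(n_subjects = 25, samples_per_subject = 4),
                       seed = 38)
  f <- fit_poppk(g$subjects, start = pop, fixed = c("ka", "sigma_prop",
                                                    "sigma_add"),
                 n_starts = 1, compute_rse = FALSE, compute_cwres = FALSE)
  b <- bootstrap_poppk(g$subjects, f, n = 6, seed = 99)
  expect_equal(b$n_replicates, 6)
  expect_true(all(b$summary$ci_lo <= b$summary$median))
  expect_true(all(b$summary$median <= b$summary$ci_hi))
  b2 <- bootstrap_poppk(g$subjects, f, n = 6, seed = 99)
  expect_identical(b$replicates, b2$replicates)
  # medians from a handful of replicates stay near the point estimates
  expect_true(all(abs(b$summary$median / b$summary$estimate - 1) < 0.35))
})

test_that("eta-shrinkage follows its definition", {
  expect_equal(eta_shrinkage(rnorm(100), 1e9) > 99, TRUE)
  x <- c(-1, 0, 1)
  expect_equal(eta_shrinkage(x, sd(x)), 0)
  expect_equal(eta_shrinkage(rep(0, 10), 0.37), 100)
  expect_equal(eta_shrinkage(x, 2 * sd(x)), 50)
})
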