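# Flat-CSV dataset dialect: parsing, validation, round-trip, covariate
# interpolation and lab dichotomization.

test_that("a minimal file parses into one subject", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,AMT,RATE,EVID,DV,MDV",
               "1,0,200,0,1,.,1",
               "1,24,.,0,0,3.1,0"), f)
  subs <- read_dataset(f)
  expect_length(subs, 1)
  s <- subs[[1]]
  expect_equal(nrow(s$doses), 1)
  expect_equal(nrow(s$observations), 1)
  expect_equal(s$doses$route, "oral")
  expect_equal(s$observations$value, 3.1)
})

test_that("RATE encodes infusion duration as AMT/RATE", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,AMT,RATE,EVID,CMT,DV,MDV",
               "1,0,200,200,1,2,.,1",
               "1,24,.,0,0,2,2.5,0"), f)
  s <- read_dataset(f)[[1]]
  expect_equal(s$doses$infusion_duration, 1)
  expect_equal(s$doses$route, "iv")
})

test_that("format errors and warnings name the offending field", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,AMT,EVID,DV", "1,0,200,1,."), f)
  expect_error(read_dataset(f), "MDV")
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,AMT,RATE,EVID,DV,MDV",
               "1,0,200,0,1,.,1",
               "1,24,.,0,0,3.1,1"), f2)  # DV > 0 with MDV = 1
  expect_warning(read_dataset(f2), "MDV")
  f3 <- tempfile(fileext = ".csv")
  writeLines(c("ID,TIME,AMT,RATE,EVID,DV,MDV",
               "1,24,200,0,1,.,1",
               "1,0,.,0,0,3.1,0"), f3)
  expect_error(read_dataset(f3), "non-monotone")
})

test_that("generated cohorts round-trip through the CSV dialect", {
  g <- generate_cohort(cohort_spec(n_subjects = 8), seed = 21)
  f <- tempfile(fileext = ".csv")
  write_dataset(g$subjects, f)
  back <- read_dataset(f)
  expect_length(back, 8)
  # route mix preserved exactly
  routes0 <- unlist(lapply(g$subjects, function(s) s$doses$route), use.names = FALSE)
  routes1 <- unlist(lapply(back, function(s) s$doses$route), use.names = FALSE)
  expect_identical(routes0, routes1)
  for (i in seq_along(back)) {
    expect_identical(back[[i]]$doses$time, g$subjects[[i]]$doses$time)
    expect_identical(back[[i]]$doses$amount, g$subjects[[i]]$doses$amount)
    expect_identical(back[[i]]$observations$value,
                     g$subjects[[i]]$observations$value)
    expect_identical(back[[i]]$observations$time,
                     g$subjects[[i]]$observations$time)
    cv0 <- g$subjects[[i]]$covariates
    cv1 <- back[[i]]$covariates
    for (nm in intersect(names(cv0), names(cv1)))
      expect_identical(cv1[[nm]], cv0[[nm]])
  }
  # second pass is byte-stable on the numeric fields
  f2 <- tempfile(fileext = ".csv")
  write_dataset(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("covariate interpolation is linear with nearest-value edges", {
  cv <- data.frame(time = c(0, 48), albumin = c(30, 34))
  expect_equal(interpolate_covariate(cv, "albumin", 24), 32)
  expect_equal(interpolate_covariate(cv, "albumin", -10), 30)
  expect_equal(interpolate_covariate(cv, "albumin", 100), 34)
  expect_equal(interpolate_covariate(cv, "albumin", c(0, 48)), c(30, 34))
  one <- data.frame(time = 0, albumin = 31)
  expect_equal(interpolate_covariate(one, "albumin", 100), 31)
  expect_warning(v <- interpolate_covariate(cv, "creatinine", 0), "never")
  expect_true(is.na(v))
})

test_that("lab dichotomization uses a strict cut at twice the ULN", {
  expect_equal(dichotomize_lab(2.0 * 40, 40), 0)
  expect_equal(dichotomize_lab(2.1 * 40, 40), 1)
  expect_equal(dichotomize_lab(0.5 * 40, 40), 0)
  expect_equal(dichotomize_lab(c(10, 200), 40), c(0, 1))
  expect_error(dichotomize_lab(10, 0), "upper_limit_normal")
})

test_that("subject records enforce their invariants", {
  d <- dose_events(0, 200)
  o <- observations(24, 3)
  expect_error(subject_record("a", d, o[0, ]), "at least one")
  bad_cov <- data.frame(time = 0, bmi = 30, body_weight = 70, height = 170)
  expect_error(subject_record("a", d, o, covariates = bad_cov),
               "inconsistent")
  ok_cov <- data.frame(time = 0, bmi = 24.2, body_weight = 70, height = 170)
  expect_silent(subject_record("a", d, o, covariates = ok_cov))
  expect_error(observations(24, -1), "positive")
  expect_error(dose_events(0, 0), "positive")
})
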