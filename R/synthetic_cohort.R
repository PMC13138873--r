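#' Specification of a synthetic TDM cohort
#'
#' Describes the statistical structure of a routine-TDM isavuconazole
#' cohort: sparse, mostly trough-time sampling under once-daily dosing of
#' 100-400 mg, roughly 80% of samples drawn during oral administration,
#' and covariates spanning the ranges seen in hospitalized adults with
#' invasive fungal infection (BMI 12-40 kg/m^2, age 20-83 y). True
#' individual parameters come from `true_model` (log-normal IIV), and
#' observed concentrations carry its mixed proportional + additive
#' residual error.
#'
#' @param n_subjects number of subjects
#' @param samples_per_subject either a function `n -> integer vector` or a
#'   fixed integer; default draws Poisson(4) truncated to 1..11 (median 4)
#' @param dose_levels allowed once-daily maintenance doses (mg)
#' @param dose_weights sampling weights of `dose_levels`
#' @param frac_trough fraction of samples drawn as troughs (just before a
#'   dose); the rest fall 1-8 h post-dose
#' @param frac_iv_subjects fraction of subjects starting on IV therapy
#' @param frac_iv_days fraction of treatment days on IV for those subjects
#' @param treatment_days range of treatment durations (days)
#' @param bmi_range BMI limits (kg/m^2)
#' @param true_model generating [population_model()]
#' @param outcome_model list(intercept, slope) of the logistic
#'   success-vs-log(Cmin) model used by [generate_outcomes()]
#' @param toxicity_rate constant hepatotoxicity probability (null
#'   exposure-toxicity model)
#' @return object of class `cohort_spec`
#' @export
cohort_spec <- function(n_subjects = 41,
                        samples_per_subject = NULL,
                        dose_levels = c(100, 200, 300, 400),
                        dose_weights = c(0.15, 0.55, 0.20, 0.10),
                        frac_trough = 0.8,
                        frac_iv_subjects = 0.5,
                        frac_iv_days = 0.4,
                        treatment_days = c(10, 28),
                        bmi_range = c(12, 40),
                        true_model = isa_final_model(),
                        outcome_model = list(intercept = -2.1, slope = 1.5),
                        toxicity_rate = 0.28) {
  if (n_subjects < 1) stop("n_subjects must be >= 1")
  if (!length(dose_levels)) stop("dose_levels must be non-empty")
  if (length(dose_weights) != length(dose_levels))
    stop("dose_weights must match dose_levels")
  fr <- c(frac_trough, frac_iv_subjects, frac_iv_days)
  if (any(fr < 0 | fr > 1)) stop("fractions must be in [0, 1]")
  if (is.null(samples_per_subject))
    samples_per_subject <- function(n) pmin(pmax(rpois(n, 4), 1), 11)
  if (is.numeric(samples_per_subject)) {
    k <- samples_per_subject
    samples_per_subject <- function(n) rep_len(k, n)
  }
  structure(list(n_subjects = n_subjects,
                 samples_per_subject = samples_per_subject,
                 dose_levels = dose_levels, dose_weights = dose_weights,
                 frac_trough = frac_trough,
                 frac_iv_subjects = frac_iv_subjects,
                 frac_iv_days = frac_iv_days,
                 treatment_days = treatment_days, bmi_range = bmi_range,
                 true_model = true_model, outcome_model = outcome_model,
                 toxicity_rate = toxicity_rate),
            class = "cohort_spec")
}

# truncated-normal draw by rejection (narrow use, small n)
.rtnorm <- function(n, mean, sd, lo, hi) {
  if (hi <= lo) return(rep(lo, n))
  x <- rnorm(n, mean, sd)
  while (any(bad <- x < lo | x > hi)) x[bad] <- rnorm(sum(bad), mean, sd)
  x
}

# log-normal draw matched to a median and range by rejection
.rlnorm_rng <- function(n, median, lo, hi, sdlog = 0.6) {
  x <- median * exp(rnorm(n, 0, sdlog))
  while (any(bad <- x < lo | x > hi))
    x[bad] <- median * exp(rnorm(sum(bad), 0, sdlog))
  x
}

#' Generate a synthetic TDM cohort
#'
#' Draws subjects according to a [cohort_spec()]: covariates, a
#' once-daily dosing history (optionally starting intravenously before
#' switching to oral), sparse mostly-trough sampling times, and observed
#' concentrations simulated from the generating model with mixed residual
#' error (non-positive draws are redrawn). A hidden truth table records
#' each subject's random effects and true exposures for recovery tests.
#'
#' @param spec a [cohort_spec()]
#' @param seed optional integer seed
#' @return list with `subjects` (list of [subject_record()]) and `truth`
#'   (data frame: id, bmi, eta_cl, eta_v, cl, v, dose, cmin_true,
#'   auc_true)
#' @export
generate_cohort <- function(spec = cohort_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pop <- spec$true_model
  n <- spec$n_subjects
  ns <- spec$samples_per_subject(n)
  if (any(ns < 1)) stop("each subject needs at least one sample")

  height <- .rtnorm(n, 171, 9, 150, 188)
  bmi <- .rtnorm(n, 24, 5.5, spec$bmi_range[1], spec$bmi_range[2])
  weight <- round(bmi * (height / 100)^2, 1)
  height <- round(height)
  bmi <- round(weight / (height / 100)^2, 2)
  age <- round(.rtnorm(n, 58, 14, 20, 83))
  sex <- ifelse(runif(n) < 0.56, "male", "female")
  crea <- round(.rlnorm_rng(n, 86, 16, 398), 1)
  tbil <- round(.rlnorm_rng(n, 6, 2, 98, 0.7), 1)
  alb <- round(.rtnorm(n, 33, 6, 14, 46), 1)
  alt <- round(.rlnorm_rng(n, 30, 5, 400, 0.7), 1)
  egfr <- round(egfr_ckd_epi(crea, age, sex), 1)

  eta_cl <- rnorm(n, 0, pop$omega_cl)
  eta_v <- rnorm(n, 0, pop$omega_v)
  dose <- sample(spec$dose_levels, n, replace = TRUE,
                 prob = spec$dose_weights)
  days <- sample(seq(spec$treatment_days[1], spec$treatment_days[2]), n,
                 replace = TRUE)
  iv_start <- runif(n) < spec$frac_iv_subjects

  subjects <- vector("list", n)
  truth <- data.frame(id = character(n), bmi = bmi, eta_cl = eta_cl,
                      eta_v = eta_v, cl = NA_real_, v = NA_real_,
                      dose = dose, cmin_true = NA_real_,
                      auc_true = NA_real_, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    id <- sprintf("S%03d", i)
    ind <- individual_parameters(pop, bmi[i], eta_cl[i], eta_v[i])
    n_iv <- if (iv_start[i]) ceiling(spec$frac_iv_days * days[i]) else 0
    dose_times <- (seq_len(days[i]) - 1) * 24
    route <- rep("oral", days[i])
    route[seq_len(n_iv)] <- "iv"
    doses <- dose_events(dose_times, dose[i], route,
                         infusion_duration = ifelse(route == "iv", 1, 0))
    # sampling days 2..days, troughs 30 min before the next dose,
    # otherwise 1-8 h after that day's dose
    k <- min(ns[i], days[i] - 1)
    sdays <- sort(sample(seq(2, days[i]), k))
    trough <- runif(k) < spec$frac_trough
    t_obs <- ifelse(trough, sdays * 24 - 0.5,
                    (sdays - 1) * 24 + runif(k, 1, 8))
    t_obs <- sort(t_obs)
    f <- concentration(t_obs, doses, ind, pop$f_oral)
    y <- f * (1 + rnorm(k, 0, pop$sigma_prop)) + rnorm(k, 0, pop$sigma_add)
    while (any(bad <- y <= 0))
      y[bad] <- f[bad] * (1 + rnorm(sum(bad), 0, pop$sigma_prop)) +
        rnorm(sum(bad), 0, pop$sigma_add)
    covs <- data.frame(time = 0, body_weight = weight[i], height = height[i],
                       age = age[i], sex = sex[i], bmi = bmi[i],
                       creatinine = crea[i], egfr = egfr[i],
                       total_bilirubin = tbil[i], albumin = alb[i],
                       alt = alt[i], stringsAsFactors = FALSE)
    subjects[[i]] <- subject_record(id, doses, observations(t_obs, y))
    subjects[[i]]$covariates <- covs
    truth$id[i] <- id
    truth$cl[i] <- ind$cl
    truth$v[i] <- ind$v
    truth$cmin_true[i] <- cmin_ss(dose[i], 24, ind, pop$f_oral)
    truth$auc_true[i] <- auc_ss(dose[i], ind, pop$f_oral)
  }
  list(subjects = subjects, truth = truth)
}

#' Estimated glomerular filtration rate (CKD-EPI 2009, race-free)
#'
#' \deqn{eGFR = 141 \cdot \min(S_{cr}/\kappa, 1)^\alpha \cdot
#'   \max(S_{cr}/\kappa, 1)^{-1.209} \cdot 0.993^{age} \cdot
#'   1.018^{[female]}}
#' with serum creatinine converted from umol/L to mg/dL (division by
#' 88.4), \eqn{\kappa} = 0.7 (female) / 0.9 (male) and \eqn{\alpha} =
#' -0.329 (female) / -0.411 (male).
#'
#' @param creatinine serum creatinine (umol/L)
#' @param age age (years)
#' @param sex "male" or "female"
#' @return eGFR in mL/min/1.73m^2
#' @export
egfr_ckd_epi <- function(creatinine, age, sex) {
  if (any(creatinine <= 0)) stop("creatinine must be positive")
  if (any(age < 0)) stop("age must be non-negative")
  sex <- match.arg(tolower(as.character(sex)), c("male", "female"),
                   several.ok = TRUE)
  n <- max(length(creatinine), length(age), length(sex))
  creatinine <- rep_len(creatinine, n)
  age <- rep_len(age, n)
  sex <- rep_len(sex, n)
  scr <- creatinine / 88.4
  kappa <- ifelse(sex == "female", 0.7, 0.9)
  alpha <- ifelse(sex == "female", -0.329, -0.411)
  141 * pmin(scr / kappa, 1)^alpha * pmax(scr / kappa, 1)^(-1.209) *
    0.993^age * ifelse(sex == "female", 1.018, 1)
}

#' Simulate study outcomes for a generated cohort
#'
#' Treatment success follows a logistic exposure-response model on the
#' true steady-state trough,
#' \eqn{P(success) = logit^{-1}(a + b \ln C_{min,true})}; hepatotoxicity
#' is drawn at a constant rate (the null exposure-toxicity model).
#'
#' @param truth truth table from [generate_cohort()]
#' @param outcome_model list(intercept, slope); defaults as in
#'   [cohort_spec()]
#' @param toxicity_rate constant hepatotoxicity probability
#' @param seed optional integer seed
#' @return data frame: id, success, hepatotoxicity, discontinuation
#' @export
generate_outcomes <- function(truth,
                              outcome_model = list(intercept = -2.1,
                                                   slope = 1.5),
                              toxicity_rate = 0.28, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- plogis(outcome_model$intercept +
                outcome_model$slope * log(truth$cmin_true))
  success <- rbinom(nrow(truth), 1, p)
  hep <- rbinom(nrow(truth), 1, toxicity_rate)
  disc <- ifelse(hep == 1, rbinom(nrow(truth), 1, 0.25), 0)
  data.frame(id = truth$id, success = success, hepatotoxicity = hep,
             discontinuation = disc, stringsAsFactors = FALSE)
}
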