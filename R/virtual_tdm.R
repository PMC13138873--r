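# Virtual steady-state cohort and TDM strategy comparison.

#' TDM dose-adjustment strategy
#'
#' @param kind one of `"none"`, `"proportional_cmin"` (proportional rule
#'   on the observed noisy trough), `"mipd_cmin"` or `"mipd_auc"`
#'   (proportional rule on the MAP-Bayes trough or AUC estimated from the
#'   noisy trough)
#' @param target_range therapeutic range of the targeted metric; defaults
#'   to 2.5-5.0 mg/L for trough strategies and 60-233 mg.h/L for the AUC
#'   strategy
#' @param allowed_doses clinically usable daily doses (mg)
#' @param adjust_outside_only adjust the dose only when the monitored
#'   estimate falls outside `target_range` (routine TDM practice); set to
#'   `FALSE` to re-dose every patient toward the target
#' @return object of class `tdm_strategy`; `target_value` is the
#'   geometric mean of `target_range`
#' @export
tdm_strategy <- function(kind = c("none", "proportional_cmin", "mipd_cmin",
                                  "mipd_auc"),
                         target_range = NULL,
                         allowed_doses = c(100, 200, 300, 400),
                         adjust_outside_only = TRUE) {
  kind <- match.arg(kind)
  if (is.null(target_range))
    target_range <- if (kind == "mipd_auc") c(60, 233) else c(2.5, 5.0)
  if (target_range[1] >= target_range[2])
    stop("target_range must be ordered (low < high)")
  structure(list(kind = kind, target_range = target_range,
                 target_value = sqrt(prod(target_range)),
                 allowed_doses = sort(allowed_doses),
                 adjust_outside_only = adjust_outside_only),
            class = "tdm_strategy")
}

#' Simulate a steady-state virtual cohort
#'
#' Draws `n` virtual patients on once-daily dosing: BMI uniform over
#' `bmi_range`, independent log-normal random effects on CL and V, and a
#' plausibility filter rejecting (CL, V) pairs whose half-life falls
#' outside `half_life_bounds` (redrawn until inside). For each patient
#' the true steady-state trough (`ipred_true_cmin`), the true AUC
#' (`auc_true = dose/CL`) and a noisy observed trough (`cmin_ruv`, mixed
#' residual error; non-positive draws are redrawn) are recorded.
#'
#' @param n cohort size
#' @param pop a [population_model()]
#' @param dose starting daily dose (mg)
#' @param tau dosing interval (h)
#' @param bmi_range BMI limits (kg/m^2)
#' @param half_life_bounds plausible half-life window (h)
#' @param seed integer seed
#' @return data frame of class `virtual_cohort`: bmi, eta_cl, eta_v, cl,
#'   v, half_life, dose, ipred_true_cmin, auc_true, cmin_ruv
#' @export
simulate_cohort <- function(n = 10000, pop = isa_final_model(), dose = 200,
                            tau = 24, bmi_range = c(12, 40),
                            half_life_bounds = c(40, 400), seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (any(half_life_bounds <= 0) || half_life_bounds[1] >= half_life_bounds[2])
    stop("half_life_bounds must be positive and ordered")
  if (!is.null(seed)) set.seed(seed)
  bmi <- runif(n, bmi_range[1], bmi_range[2])
  eta_cl <- rnorm(n, 0, pop$omega_cl)
  eta_v <- rnorm(n, 0, pop$omega_v)
  ind <- individual_parameters(pop, bmi, eta_cl, eta_v)
  th <- half_life(ind)
  bad <- th < half_life_bounds[1] | th > half_life_bounds[2]
  if (mean(bad) > 0.5)
    stop("half-life plausibility bounds reject more than half of the ",
         "draws; bounds look implausible for this model")
  while (any(bad)) {
    k <- sum(bad)
    eta_cl[bad] <- rnorm(k, 0, pop$omega_cl)
    eta_v[bad] <- rnorm(k, 0, pop$omega_v)
    ind <- individual_parameters(pop, bmi, eta_cl, eta_v)
    th <- half_life(ind)
    bad <- th < half_life_bounds[1] | th > half_life_bounds[2]
  }
  ipred <- cmin_ss(dose, tau, ind, pop$f_oral)
  auc <- auc_ss(dose, ind, pop$f_oral)
  ruv <- ipred * (1 + rnorm(n, 0, pop$sigma_prop)) +
    rnorm(n, 0, pop$sigma_add)
  while (any(bad <- ruv <= 0)) {
    k <- sum(bad)
    ruv[bad] <- ipred[bad] * (1 + rnorm(k, 0, pop$sigma_prop)) +
      rnorm(k, 0, pop$sigma_add)
  }
  out <- data.frame(bmi = bmi, eta_cl = eta_cl, eta_v = eta_v,
                    cl = ind$cl, v = ind$v, half_life = th,
                    dose = dose, ipred_true_cmin = ipred, auc_true = auc,
                    cmin_ruv = ruv)
  attr(out, "tau") <- tau
  attr(out, "pop") <- pop
  class(out) <- c("virtual_cohort", "data.frame")
  out
}

#' Target attainment of a virtual cohort
#'
#' Fraction of patients whose true steady-state trough and AUC fall
#' inside the therapeutic ranges (boundaries inclusive).
#'
#' @param cohort a [simulate_cohort()] data frame
#' @param cmin_range trough target range (mg/L)
#' @param auc_range AUC target range (mg.h/L)
#' @param strategy label recorded in the summary
#' @return object of class `attainment_summary`: `n`,
#'   `pct_cmin_in_range`, `pct_auc_in_range`, `strategy`
#' @export
attainment <- function(cohort, cmin_range = c(2.5, 5.0),
                       auc_range = c(60, 233), strategy = "none") {
  if (cmin_range[1] >= cmin_range[2] || auc_range[1] >= auc_range[2])
    stop("target ranges must be ordered (low < high)")
  structure(list(
    n = nrow(cohort),
    pct_cmin_in_range = 100 * mean(cohort$ipred_true_cmin >= cmin_range[1] &
                                     cohort$ipred_true_cmin <= cmin_range[2]),
    pct_auc_in_range = 100 * mean(cohort$auc_true >= auc_range[1] &
                                    cohort$auc_true <= auc_range[2]),
    strategy = strategy), class = "attainment_summary")
}

#' @export
print.attainment_summary <- function(x, ...) {
  cat(sprintf("%s (n = %d): %.1f%% of troughs and %.1f%% of AUCs in range\n",
              x$strategy, x$n, x$pct_cmin_in_range, x$pct_auc_in_range))
  invisible(x)
}

#' Proportional dose-adjustment rule
#'
#' The ideal dose is `current_dose * target_value / observed_value`,
#' rounded to the nearest allowed dose; an exact midpoint between two
#' allowed doses rounds down (the lower, safer dose).
#'
#' @param current_dose current daily dose (mg)
#' @param observed_value monitored exposure estimate (> 0)
#' @param target_value target (same units as `observed_value`)
#' @param allowed_doses clinically usable daily doses (mg)
#' @return adjusted dose(s), elements of `allowed_doses`
#' @export
adjust_dose_proportional <- function(current_dose, observed_value,
                                     target_value,
                                     allowed_doses = c(100, 200, 300, 400)) {
  if (any(observed_value <= 0)) stop("observed_value must be positive")
  allowed <- sort(allowed_doses)
  ideal <- current_dose * target_value / observed_value
  d <- abs(outer(ideal, allowed, "-"))
  # which.min returns the first (= lower dose) on exact ties
  allowed[apply(d, 1, which.min)]
}

#' Apply a TDM strategy to a virtual cohort
#'
#' `proportional_cmin` feeds the observed noisy trough straight into the
#' proportional rule; `mipd_cmin` and `mipd_auc` first compute a MAP-Bayes
#' estimate of the individual parameters from that single trough and
#' apply the rule to the Bayes-predicted trough or AUC. With
#' `adjust_outside_only = TRUE` (default) patients whose monitored
#' estimate already lies inside the target range keep their dose. True
#' exposures are then rescaled to the new dose (dose-proportional model)
#' and summarized.
#'
#' @param cohort a [simulate_cohort()] data frame
#' @param strategy a [tdm_strategy()]
#' @param pop the generating [population_model()] (defaults to the one
#'   stored in `cohort`)
#' @param cmin_range,auc_range attainment ranges for the summary
#' @return list with `cohort` (re-dosed) and `summary`
#'   (an [attainment()] result); the cohort gains columns `new_dose` and
#'   `monitored_value`
#' @export
apply_strategy <- function(cohort, strategy, pop = attr(cohort, "pop"),
                           cmin_range = c(2.5, 5.0),
                           auc_range = c(60, 233)) {
  stopifnot(inherits(strategy, "tdm_strategy"))
  tau <- attr(cohort, "tau")
  if (is.null(tau)) tau <- 24
  if (strategy$kind == "none") {
    cohort$new_dose <- cohort$dose
    return(list(cohort = cohort,
                summary = attainment(cohort, cmin_range, auc_range,
                                     strategy = "none")))
  }
  est <- switch(strategy$kind,
    proportional_cmin = cohort$cmin_ruv,
    mipd_cmin = ,
    mipd_auc = {
      map <- .map_fit_trough_vec(cohort$cmin_ruv, cohort$bmi, pop,
                                 cohort$dose[1], tau)
      ind <- list(cl = map$cl, v = map$v, ka = pop$ka)
      if (strategy$kind == "mipd_cmin")
        cmin_ss(cohort$dose, tau, ind, pop$f_oral)
      else auc_ss(cohort$dose, ind, pop$f_oral)
    },
    stop("unknown strategy kind"))
  new_dose <- adjust_dose_proportional(cohort$dose, est,
                                       strategy$target_value,
                                       strategy$allowed_doses)
  if (strategy$adjust_outside_only) {
    inside <- est >= strategy$target_range[1] &
      est <= strategy$target_range[2]
    new_dose[inside] <- cohort$dose[inside]
  }
  scale <- new_dose / cohort$dose
  cohort$monitored_value <- est
  cohort$ipred_true_cmin <- cohort$ipred_true_cmin * scale
  cohort$auc_true <- cohort$auc_true * scale
  cohort$dose <- new_dose
  cohort$new_dose <- new_dose
  list(cohort = cohort,
       summary = attainment(cohort, cmin_range, auc_range,
                            strategy = strategy$kind))
}

#' Run the full virtual TDM study
#'
#' Simulates a steady-state cohort at the standard dose and compares the
#' no-TDM baseline with the proportional trough rule, MIPD on the Bayes
#' trough and MIPD on the Bayes AUC.
#'
#' @inheritParams simulate_cohort
#' @param cmin_range,auc_range attainment target ranges
#' @return list with `cohort` and `results`, a data frame of attainment
#'   percentages per strategy
#' @export
virtual_tdm_study <- function(n = 10000, pop = isa_final_model(),
                              dose = 200, seed = NULL,
                              bmi_range = c(12, 40),
                              half_life_bounds = c(40, 400),
                              cmin_range = c(2.5, 5.0),
                              auc_range = c(60, 233)) {
  cohort <- simulate_cohort(n, pop, dose, 24, bmi_range, half_life_bounds,
                            seed)
  kinds <- c("none", "proportional_cmin", "mipd_cmin", "mipd_auc")
  rows <- lapply(kinds, function(k) {
    tr <- if (k == "mipd_auc") auc_range else cmin_range
    res <- apply_strategy(cohort, tdm_strategy(k, target_range = tr),
                          pop, cmin_range, auc_range)
    s <- res$summary
    data.frame(strategy = k, n = s$n,
               pct_cmin_in_range = s$pct_cmin_in_range,
               pct_auc_in_range = s$pct_auc_in_range)
  })
  list(cohort = cohort, results = do.call(rbind, rows))
}
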