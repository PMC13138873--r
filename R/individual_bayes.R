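# MAP (empirical-Bayes) individual estimation and exposure derivation.

#' MAP estimate of individual parameters
#'
#' Minimizes the joint -2 log-likelihood
#' \eqn{\sum_j [\log v_j + (y_j - f_j)^2/v_j] + \eta^T \Omega^{-1} \eta}
#' over the two random effects, with residual variance
#' \eqn{v = f^2\sigma_p^2 + \sigma_a^2}. With no usable observations the
#' prior mode \eqn{\eta = 0} is returned (typical-value prediction).
#'
#' @param subject a [subject_record()]
#' @param pop a [population_model()]
#' @return object of class `map_estimate`: `eta_cl`, `eta_v`, `cl`, `v`,
#'   `n_obs`, and the subject id
#' @export
map_fit <- function(subject, pop) {
  flat <- .flatten_subjects(list(subject))[[1]]
  covdata <- .baseline_covariates(list(subject))
  mult <- .cov_multipliers(pop, covdata)
  cl_t <- pop$tvcl * mult$cl[1]
  v_t <- pop$tvv * mult$v[1]
  if (length(flat$y) == 0) {
    eta <- c(0, 0)
  } else {
    res <- .map_eta_cpp(flat, cl_t, v_t, pop$ka, pop$f_oral,
                        max(pop$omega_cl, 1e-8), max(pop$omega_v, 1e-8),
                        pop$sigma_prop, pop$sigma_add, c(0, 0))
    eta <- res$eta
    if (any(!is.finite(eta)))
      stop("MAP optimisation failed for subject ", subject$subject_id)
  }
  structure(list(subject_id = subject$subject_id, eta_cl = eta[1],
                 eta_v = eta[2], cl = cl_t * exp(eta[1]),
                 v = v_t * exp(eta[2]), ka = pop$ka,
                 n_obs = length(flat$y)),
            class = c("map_estimate", "individual_parameters"))
}

# daily dose in force at a time point: doses within the preceding 24 h,
# falling back to the most recent dose (assumed once daily)
.daily_dose_at <- function(doses, time_h) {
  recent <- doses[doses$time <= time_h, , drop = FALSE]
  if (!nrow(recent)) stop("no dose administered before the requested date")
  window <- recent[recent$time > time_h - 24, , drop = FALSE]
  if (nrow(window)) sum(window$amount) else recent$amount[nrow(recent)]
}

#' Model-predicted exposure at a clinical evaluation date
#'
#' Trough concentration and daily AUC at `date`, given a subject's dosing
#' history and MAP parameter estimates. The trough is the model
#' prediction immediately before the next dose after `date` (or one
#' dosing interval after the last dose when therapy has stopped); the AUC
#' is the daily dose in force divided by the MAP clearance. Subjects
#' without a concentration measurement within `window_days` of `date`
#' are ineligible.
#'
#' @param map_est a [map_fit()] result
#' @param subject the corresponding [subject_record()]
#' @param date evaluation time (h since the subject's first record)
#' @param tau assumed dosing interval when no later dose is recorded (h)
#' @param window_days eligibility window around `date` (days, inclusive)
#' @param f_oral oral bioavailability
#' @return list with `cmin` (mg/L), `auc` (mg.h/L), `daily_dose` (mg) and
#'   `n_obs_used`
#' @export
exposure_at_date <- function(map_est, subject, date, tau = 24,
                             window_days = 50, f_oral = 1) {
  if (date < min(subject$doses$time))
    stop("date precedes the first dose of subject ", subject$subject_id)
  o <- subject$observations
  o <- o[!o$is_missing & !is.na(o$value), , drop = FALSE]
  if (!nrow(o) || min(abs(o$time - date)) > window_days * 24)
    stop("subject ", subject$subject_id, " has no measurement within ",
         window_days, " days of the evaluation date")
  recent_dose <- max(subject$doses$time[subject$doses$time <= date])
  if (date - recent_dose > window_days * 24)
    stop("no dose within ", window_days, " days of the evaluation date")
  later <- subject$doses$time[subject$doses$time > date]
  t_trough <- if (length(later)) min(later) else
    max(subject$doses$time) + tau
  ind <- list(cl = map_est$cl, v = map_est$v, ka = map_est$ka)
  cmin <- concentration(t_trough - 1e-9, subject$doses, ind, f_oral)
  daily <- .daily_dose_at(subject$doses, date)
  list(cmin = cmin, auc = f_oral * daily / map_est$cl, daily_dose = daily,
       n_obs_used = map_est$n_obs)
}

#' Per-subject exposure table
#'
#' Convenience wrapper running [map_fit()] and [exposure_at_date()] over a
#' cohort; ineligible subjects are reported with `NA` exposures.
#'
#' @param subjects list of [subject_record()]
#' @param pop a [population_model()]
#' @param dates evaluation times (h), recycled over subjects; defaults to
#'   each subject's last observation time
#' @param ... passed to [exposure_at_date()]
#' @return data frame: id, date, cmin, auc, n_observations_used
#' @export
exposure_table <- function(subjects, pop, dates = NULL, ...) {
  n <- length(subjects)
  if (is.null(dates))
    dates <- vapply(subjects, function(s) max(s$observations$time),
                    numeric(1))
  dates <- rep_len(dates, n)
  rows <- lapply(seq_len(n), function(i) {
    m <- map_fit(subjects[[i]], pop)
    e <- tryCatch(exposure_at_date(m, subjects[[i]], dates[i], ...),
                  error = function(err) NULL)
    data.frame(id = subjects[[i]]$subject_id, date = dates[i],
               cmin = if (is.null(e)) NA_real_ else e$cmin,
               auc = if (is.null(e)) NA_real_ else e$auc,
               n_observations_used = m$n_obs, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Vectorized MAP from a single steady-state trough per patient.
# Used by the virtual TDM study: all patients share dose/tau; bmi and the
# observed trough vary. Damped Newton on the 2-d joint objective, run in
# lockstep across patients (everything vectorized).
.map_fit_trough_vec <- function(y, bmi, pop, dose, tau = 24,
                                max_iter = 100) {
  n <- length(y)
  om1 <- max(pop$omega_cl, 1e-8)
  om2 <- max(pop$omega_v, 1e-8)
  obj <- function(e1, e2) {
    ind <- list(cl = pop$tvcl * exp(e1),
                v = pop$tvv * (bmi / pop$bmi_ref)^pop$bmi_power * exp(e2),
                ka = pop$ka)
    f <- cmin_ss(dose, tau, ind, pop$f_oral)
    vr <- pmax(f^2 * pop$sigma_prop^2 + pop$sigma_add^2, 1e-12)
    (y - f)^2 / vr + log(vr) + e1^2 / om1^2 + e2^2 / om2^2
  }
  e1 <- numeric(n); e2 <- numeric(n)
  h <- 1e-4
  f0 <- obj(e1, e2)
  lam <- rep(0, n)  # per-patient Levenberg-Marquardt damping
  for (it in seq_len(max_iter)) {
    lp1 <- obj(e1 + h, e2); lm1 <- obj(e1 - h, e2)
    lp2 <- obj(e1, e2 + h); lm2 <- obj(e1, e2 - h)
    g1 <- (lp1 - lm1) / (2 * h); g2 <- (lp2 - lm2) / (2 * h)
    h11 <- (lp1 - 2 * f0 + lm1) / h^2 + lam
    h22 <- (lp2 - 2 * f0 + lm2) / h^2 + lam
    h12 <- (obj(e1 + h, e2 + h) - obj(e1 + h, e2 - h) -
              obj(e1 - h, e2 + h) + obj(e1 - h, e2 - h)) / (4 * h^2)
    det <- h11 * h22 - h12^2
    ok <- is.finite(det) & det > 1e-10 & h11 > 0
    # damped-gradient fallback while the damped Hessian is indefinite
    d1 <- ifelse(ok, (h22 * g1 - h12 * g2) / det, 0.01 * sign(g1))
    d2 <- ifelse(ok, (h11 * g2 - h12 * g1) / det, 0.01 * sign(g2))
    e1n <- e1 - d1; e2n <- e2 - d2
    f1 <- obj(e1n, e2n)
    acc <- is.finite(f1) & f1 < f0
    e1[acc] <- e1n[acc]; e2[acc] <- e2n[acc]; f0[acc] <- f1[acc]
    lam[acc] <- lam[acc] * 0.3
    lam[!acc] <- pmax(lam[!acc] * 10, 1e-4)
    moved <- if (any(acc)) max(abs(d1[acc]), abs(d2[acc])) else 0
    if (moved < 1e-9 && it > 3) break
  }
  list(eta_cl = e1, eta_v = e2,
       cl = pop$tvcl * exp(e1),
       v = pop$tvv * (bmi / pop$bmi_ref)^pop$bmi_power * exp(e2))
}
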