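#' Population pharmacokinetic model for isavuconazole
#'
#' Container for the fixed effects, interindividual variability (IIV) and
#' residual unexplained variability (RUV) of a one-compartment model with
#' first-order absorption and linear elimination:
#' \deqn{CL_i = TVCL \cdot m_{CL,i} \cdot e^{\eta_{CL,i}}, \quad
#'       V_i = TVV \cdot (BMI_i/25)^{\theta_{BMI}} \cdot m_{V,i}
#'             \cdot e^{\eta_{V,i}}}
#' with \eqn{\eta \sim N(0, \omega^2)} and observations
#' \eqn{y = f \cdot (1 + \epsilon_p) + \epsilon_a}.
#' The optional `covariates` list holds additional covariate-parameter
#' relations (multipliers \eqn{m}) used by the stepwise covariate engine;
#' each element is a list with fields `param` ("cl" or "v"), `cov`
#' (covariate name), `form` ("power", "linear" or "categorical"),
#' `ref` (centring value) and `theta` (effect size).
#'
#' Omegas and sigma_prop follow the reporting convention in which a
#' log-normal IIV printed as "CV% = 37" means a log-scale standard
#' deviation of 0.37 (set `options(isatdm.omega_cv_exact = TRUE)` to
#' convert printed CV% through \eqn{\omega = \sqrt{\log(1+CV^2)}} instead
#' when using [cv_to_omega()]).
#'
#' @param tvcl typical clearance (L/h)
#' @param tvv typical volume of distribution (L)
#' @param ka first-order absorption rate constant (1/h)
#' @param f_oral oral bioavailability, in (0, 1]
#' @param omega_cl,omega_v log-scale SD of the IIV on CL and V
#' @param sigma_prop proportional residual error SD (fraction)
#' @param sigma_add additive residual error SD (mg/L)
#' @param bmi_ref reference BMI (kg/m^2)
#' @param bmi_power exponent of the normalized-BMI effect on V (0 = no
#'   BMI effect; 1 = linear scaling as in the final model)
#' @param covariates optional list of extra covariate relations (above)
#' @return an object of class `population_model`
#' @seealso [isa_final_model()], [isa_base_model()]
#' @export
population_model <- function(tvcl = 2.3, tvv = 523, ka = 2.5, f_oral = 1,
                             omega_cl = 0.37, omega_v = 0.34,
                             sigma_prop = 0.19, sigma_add = 0.73,
                             bmi_ref = 25, bmi_power = 1,
                             covariates = list()) {
  num <- c(tvcl = tvcl, tvv = tvv, ka = ka, f_oral = f_oral,
           omega_cl = omega_cl, omega_v = omega_v,
           sigma_prop = sigma_prop, sigma_add = sigma_add, bmi_ref = bmi_ref)
  if (any(!is.finite(num)) || any(num[c("tvcl", "tvv", "ka", "bmi_ref")] <= 0))
    stop("tvcl, tvv, ka and bmi_ref must be positive and finite")
  if (f_oral <= 0 || f_oral > 1) stop("f_oral must be in (0, 1]")
  if (any(c(omega_cl, omega_v, sigma_prop, sigma_add) < 0))
    stop("variability parameters must be non-negative")
  structure(list(tvcl = tvcl, tvv = tvv, ka = ka, f_oral = f_oral,
                 omega_cl = omega_cl, omega_v = omega_v,
                 sigma_prop = sigma_prop, sigma_add = sigma_add,
                 bmi_ref = bmi_ref, bmi_power = bmi_power,
                 covariates = covariates),
            class = "population_model")
}

#' Published final and base isavuconazole models
#'
#' `isa_final_model()` returns the final covariate model (BMI scales V
#' linearly; IIV on CL and V; mixed residual error). `isa_base_model()`
#' returns the structural model before covariate inclusion.
#'
#' @return a [population_model()]
#' @export
isa_final_model <- function() population_model()

#' @rdname isa_final_model
#' @export
isa_base_model <- function() {
  population_model(tvcl = 2.2, tvv = 550, omega_cl = 0.35, omega_v = 0.56,
                   bmi_power = 0)
}

#' Convert a printed IIV CV% to a log-scale SD
#'
#' @param cv_pct coefficient of variation in percent
#' @param exact if `TRUE`, use \eqn{\omega = \sqrt{\log(1 + (CV/100)^2)}};
#'   otherwise (default) the common shorthand \eqn{\omega = CV/100}.
#' @return log-scale standard deviation
#' @export
cv_to_omega <- function(cv_pct,
                        exact = getOption("isatdm.omega_cv_exact", FALSE)) {
  if (exact) sqrt(log(1 + (cv_pct / 100)^2)) else cv_pct / 100
}

#' @export
print.population_model <- function(x, ...) {
  cat("One-compartment popPK model (first-order absorption)\n")
  cat(sprintf("  TVCL %.3g L/h   TVV %.4g L   ka %.3g 1/h   F %.3g\n",
              x$tvcl, x$tvv, x$ka, x$f_oral))
  cat(sprintf("  IIV: omega_CL %.3g, omega_V %.3g (log-scale SD)\n",
              x$omega_cl, x$omega_v))
  cat(sprintf("  RUV: proportional %.3g, additive %.3g mg/L\n",
              x$sigma_prop, x$sigma_add))
  if (x$bmi_power != 0)
    cat(sprintf("  V scales with (BMI/%g)^%g\n", x$bmi_ref, x$bmi_power))
  if (length(x$covariates))
    cat(sprintf("  + %d additional covariate relation(s)\n",
                length(x$covariates)))
  invisible(x)
}

#' Individual pharmacokinetic parameters
#'
#' Applies the final-model equations
#' \eqn{CL_i = TVCL\,e^{\eta_{CL}}} and
#' \eqn{V_i = TVV\,(BMI_i/25)^{\theta}\,e^{\eta_V}}.
#'
#' @param pop a [population_model()]
#' @param bmi body mass index (kg/m^2)
#' @param eta_cl,eta_v log-scale individual deviations
#' @return object of class `individual_parameters` with elements
#'   `cl` (L/h), `v` (L), `ka` (1/h), `eta_cl`, `eta_v`
#' @export
individual_parameters <- function(pop, bmi = pop$bmi_ref, eta_cl = 0,
                                  eta_v = 0) {
  if (any(!is.finite(bmi)) || any(bmi <= 0)) stop("bmi must be positive")
  cl <- pop$tvcl * exp(eta_cl)
  v <- pop$tvv * (bmi / pop$bmi_ref)^pop$bmi_power * exp(eta_v)
  structure(list(cl = cl, v = v, ka = pop$ka, eta_cl = eta_cl,
                 eta_v = eta_v),
            class = "individual_parameters")
}

# contribution of a single dose to the concentration at elapsed time dt
.conc_one_dose <- function(dt, amount, route, infusion_duration, cl, v, ka,
                           f_oral) {
  ke <- cl / v
  out <- numeric(length(dt))
  pos <- dt >= 0
  if (!any(pos)) return(out)
  dtp <- dt[pos]
  if (route == "oral") {
    if (abs(ka - ke) < 1e-12) stop("ka equal to ke: degenerate absorption")
    out[pos] <- f_oral * amount * ka / (v * (ka - ke)) *
      (exp(-ke * dtp) - exp(-ka * dtp))
  } else if (infusion_duration <= 0) {
    out[pos] <- amount / v * exp(-ke * dtp)
  } else {
    r0 <- amount / infusion_duration
    during <- dtp <= infusion_duration
    val <- numeric(length(dtp))
    val[during] <- r0 / cl * (1 - exp(-ke * dtp[during]))
    val[!during] <- r0 / cl * (1 - exp(-ke * infusion_duration)) *
      exp(-ke * (dtp[!during] - infusion_duration))
    out[pos] <- val
  }
  out
}

#' Predicted concentration under a dosing history
#'
#' Superposition of the closed-form single-dose solutions of the
#' one-compartment model: an oral dose contributes
#' \eqn{F D k_a / (V (k_a - k_e)) (e^{-k_e \Delta t} - e^{-k_a \Delta t})},
#' an IV bolus \eqn{(D/V) e^{-k_e \Delta t}}, and an IV infusion the
#' standard zero-order input solution. Doses in the future of `t`
#' contribute zero.
#'
#' @param t time(s) (h) at which to evaluate the concentration
#' @param doses a dose-event data frame, see [dose_events()]
#' @param ind an [individual_parameters()] object
#' @param f_oral oral bioavailability
#' @return concentration(s) in mg/L
#' @export
concentration <- function(t, doses, ind, f_oral = 1) {
  stopifnot(all(t >= 0) || all(is.finite(t)))
  conc <- numeric(length(t))
  for (d in seq_len(nrow(doses))) {
    conc <- conc + .conc_one_dose(t - doses$time[d], doses$amount[d],
                                  doses$route[d], doses$infusion_duration[d],
                                  ind$cl, ind$v, ind$ka, f_oral)
  }
  conc
}

#' Steady-state trough concentration
#'
#' Closed-form multiple-dose trough of the oral one-compartment model at
#' the end of a dosing interval of length `tau`:
#' \deqn{C_{min,ss} = \frac{F D k_a}{V (k_a - k_e)}
#'   \left[\frac{e^{-k_e\tau}}{1 - e^{-k_e\tau}} -
#'         \frac{e^{-k_a\tau}}{1 - e^{-k_a\tau}}\right]}
#'
#' @param dose dose amount (mg)
#' @param tau dosing interval (h)
#' @param ind an [individual_parameters()] object (elements may be
#'   vectors of equal length for vectorized evaluation)
#' @param f_oral oral bioavailability
#' @return trough concentration (mg/L)
#' @export
cmin_ss <- function(dose, tau, ind, f_oral = 1) {
  if (any(tau <= 0)) stop("tau must be positive")
  ke <- ind$cl / ind$v
  if (any(abs(ind$ka - ke) < 1e-12)) stop("ka equal to ke: degenerate")
  a <- f_oral * dose * ind$ka / (ind$v * (ind$ka - ke))
  a * (exp(-ke * tau) / (1 - exp(-ke * tau)) -
         exp(-ind$ka * tau) / (1 - exp(-ind$ka * tau)))
}

#' Steady-state AUC over one dosing interval
#'
#' At steady state the area under the curve over a dosing interval equals
#' dose divided by clearance: \eqn{AUC_\tau = F \cdot D / CL}.
#'
#' @inheritParams cmin_ss
#' @return AUC (mg.h/L)
#' @export
auc_ss <- function(dose, ind, f_oral = 1) {
  if (any(ind$cl <= 0)) stop("clearance must be positive")
  f_oral * dose / ind$cl
}

#' Time to peak after a single oral dose
#'
#' \eqn{T_{max} = \ln(k_a/k_e) / (k_a - k_e)} with \eqn{k_e = CL/V}.
#'
#' @param ind an [individual_parameters()] object
#' @return time of maximal concentration (h)
#' @export
tmax <- function(ind) {
  ke <- ind$cl / ind$v
  if (any(ind$ka <= ke)) stop("tmax requires ka > ke")
  log(ind$ka / ke) / (ind$ka - ke)
}

#' Elimination half-life
#'
#' \eqn{t_{1/2} = \ln(2) \cdot V / CL}.
#'
#' @param ind an [individual_parameters()] object
#' @return half-life (h)
#' @export
half_life <- function(ind) {
  if (any(ind$cl <= 0) || any(ind$v <= 0)) stop("cl and v must be positive")
  log(2) * ind$v / ind$cl
}
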