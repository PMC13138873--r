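# Independent oracles used across the suite. These deliberately avoid the
# package's computational paths (compiled likelihood, closed forms under
# test) and rely on base-R numerics instead.

# marginal -2 log-likelihood by nested adaptive 1-D quadrature over the
# two random effects, with the concentration model evaluated through the
# R-level closed forms
quad_ofv_oracle <- function(subjects, pop) {
  tot <- 0
  for (s in subjects) {
    o <- s$observations
    o <- o[!o$is_missing, , drop = FALSE]
    bmi <- suppressWarnings(interpolate_covariate(s$covariates, "bmi", 0))
    if (is.na(bmi)) bmi <- pop$bmi_ref
    lik_eta <- function(e1, e2) {
      ind <- individual_parameters(pop, bmi, e1, e2)
      f <- concentration(o$time, s$doses, ind, pop$f_oral)
      v <- f^2 * pop$sigma_prop^2 + pop$sigma_add^2
      exp(sum(dnorm(o$value, f, sqrt(v), log = TRUE)))
    }
    inner <- function(e2v) sapply(e2v, function(e2)
      integrate(function(e1v)
        sapply(e1v, function(e1) lik_eta(e1, e2)) *
          dnorm(e1v, 0, pop$omega_cl),
        -6 * pop$omega_cl, 6 * pop$omega_cl,
        rel.tol = 1e-10)$value * dnorm(e2, 0, pop$omega_v))
    L <- integrate(inner, -6 * pop$omega_v, 6 * pop$omega_v,
                   rel.tol = 1e-9)$value
    tot <- tot - 2 * log(L)
  }
  tot
}

# brute-force multiple-dose trough: superposition of single oral doses
# evaluated numerically just before the next dose
superposition_trough_oracle <- function(dose, tau, cl, v, ka, n_doses) {
  ke <- cl / v
  t_eval <- n_doses * tau
  t_doses <- (seq_len(n_doses) - 1) * tau
  dt <- t_eval - t_doses
  sum(dose * ka / (v * (ka - ke)) * (exp(-ke * dt) - exp(-ka * dt)))
}

# trapezoidal integral of the steady-state concentration profile over one
# dosing interval (dense grid)
trapz_auc_oracle <- function(dose, tau, ind, f_oral = 1, n_doses = 600,
                             n_grid = 4000) {
  doses <- dose_events((seq_len(n_doses) - 1) * tau, dose)
  tt <- seq((n_doses - 1) * tau, n_doses * tau, length.out = n_grid)
  cc <- concentration(tt, doses, ind, f_oral)
  sum(diff(tt) * (head(cc, -1) + tail(cc, -1)) / 2)
}

# grid + polish maximum-likelihood logistic fit for tiny datasets
logistic_grid_oracle <- function(x, y) {
  nll <- function(p) {
    eta <- p[1] + p[2] * log(x)
    -sum(y * eta - log1p(exp(eta)))
  }
  grid <- expand.grid(a = seq(-8, 8, by = 0.5), b = seq(-6, 6, by = 0.25))
  vals <- apply(grid, 1, nll)
  p0 <- as.numeric(grid[which.min(vals), ])
  optim(p0, nll, method = "Nelder-Mead",
        control = list(reltol = 1e-12, maxit = 5000))$par
}

# small fully-specified subject used by several tests: once-daily oral
# dosing with known random effects and noise-free observations
make_rich_subject <- function(eta_cl = 0, eta_v = 0, bmi = 25, dose = 200,
                              n_days = 14, obs_times = NULL,
                              pop = isa_final_model(), noise = 0) {
  doses <- dose_events((seq_len(n_days) - 1) * 24, dose)
  if (is.null(obs_times))
    obs_times <- c(2, 6, 25, 49, 73, 145, 241, n_days * 24 - 0.5)
  ind <- individual_parameters(pop, bmi, eta_cl, eta_v)
  f <- concentration(obs_times, doses, ind, pop$f_oral)
  y <- f
  if (noise > 0) y <- pmax(f + rnorm(length(f), 0, noise), 1e-3)
  s <- subject_record("X1", doses, observations(obs_times, y))
  s$covariates <- data.frame(time = 0, bmi = bmi)
  s
}
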