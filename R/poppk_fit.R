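# Nonlinear mixed-effects estimation (Laplace) and model-selection tools.

# flatten subject records into the structure the compiled code expects
.flatten_subjects <- function(subjects) {
  lapply(subjects, function(s) {
    o <- s$observations
    o <- o[!o$is_missing & !is.na(o$value), , drop = FALSE]
    list(obs_t = as.numeric(o$time), y = as.numeric(o$value),
         dose_t = as.numeric(s$doses$time),
         amt = as.numeric(s$doses$amount),
         oral = as.integer(s$doses$route == "oral"),
         tinf = as.numeric(s$doses$infusion_duration))
  })
}

# baseline (time-0, nearest-carried) covariate values, one row per subject
.baseline_covariates <- function(subjects,
                                 names = c("bmi", "body_weight", "age",
                                           "sex", "creatinine", "egfr",
                                           "albumin", "total_bilirubin",
                                           "alt")) {
  out <- lapply(names, function(nm) {
    vapply(subjects, function(s) {
      cv <- s$covariates
      if (is.null(cv) || !nm %in% names(cv)) return(NA_real_)
      if (nm == "sex") {
        v <- cv$sex[!is.na(cv$sex)]
        return(if (length(v)) as.numeric(v[1] == "female") else NA_real_)
      }
      suppressWarnings(interpolate_covariate(cv, nm, 0))
    }, numeric(1))
  })
  names(out) <- names
  as.data.frame(out)
}

# per-subject multipliers on CL and V from the covariate model
.cov_multipliers <- function(pop, covdata) {
  n <- nrow(covdata)
  cl_mult <- rep(1, n)
  v_mult <- rep(1, n)
  if (pop$bmi_power != 0) {
    bmi <- covdata$bmi
    if (any(is.na(bmi))) {
      bmi[is.na(bmi)] <- pop$bmi_ref
      warning("missing BMI set to the reference value")
    }
    v_mult <- (bmi / pop$bmi_ref)^pop$bmi_power
  }
  for (e in pop$covariates) {
    x <- covdata[[e$cov]]
    if (is.null(x)) stop("covariate '", e$cov, "' absent from data")
    x[is.na(x)] <- e$ref
    m <- switch(e$form,
                power = (x / e$ref)^e$theta,
                linear = pmax(1 + e$theta * (x - e$ref) / e$ref, 1e-3),
                categorical = exp(e$theta * x),
                stop("unknown covariate form '", e$form, "'"))
    if (e$param == "cl") cl_mult <- cl_mult * m else v_mult <- v_mult * m
  }
  list(cl = cl_mult, v = v_mult)
}

#' Marginal -2 log-likelihood (Laplace approximation)
#'
#' Objective function value (OFV) of a population model on a set of
#' subjects: \eqn{-2 \sum_i \log \int p(y_i|\eta)\,p(\eta)\,d\eta}, with
#' Gaussian residuals of variance
#' \eqn{IPRED^2\sigma_{prop}^2 + \sigma_{add}^2}
#' and independent log-normal random effects on CL and V. The integral is
#' approximated by Laplace's method at the per-subject posterior mode.
#'
#' With `method = "agq"` the Laplace value is refined by adaptive
#' Gauss-Hermite quadrature (an `agq_nodes`^2 grid centred at the mode and
#' scaled by the inner Hessian), which converges to the exact integral as
#' the number of nodes grows; estimation itself uses the Laplace value.
#'
#' @param subjects list of [subject_record()]
#' @param pop a [population_model()]
#' @param eta_start optional n x 2 matrix of starting random effects
#' @param method "laplace" (default) or "agq"
#' @param agq_nodes nodes per dimension for `method = "agq"`
#' @return the OFV, with attributes `eta` (posterior modes), `ofv_i`
#'   (per-subject contributions) and `hess` (inner 2x2 Hessians, one row
#'   per subject)
#' @export
marginal_neg2ll <- function(subjects, pop, eta_start = NULL,
                            method = c("laplace", "agq"), agq_nodes = 7) {
  method <- match.arg(method)
  flat <- .flatten_subjects(subjects)
  if (any(vapply(flat, function(s) length(s$y) == 0, logical(1))))
    stop("every subject needs at least one non-missing observation")
  covdata <- .baseline_covariates(subjects)
  mult <- .cov_multipliers(pop, covdata)
  n <- length(flat)
  if (is.null(eta_start)) eta_start <- matrix(0, n, 2)
  gh <- if (method == "agq") .gauss_hermite(agq_nodes) else
    list(z = numeric(0), w = numeric(0))
  res <- .laplace_ofv_cpp(flat, pop$tvcl * mult$cl, pop$tvv * mult$v,
                          pop$ka, pop$f_oral,
                          max(pop$omega_cl, 1e-8), max(pop$omega_v, 1e-8),
                          pop$sigma_prop, pop$sigma_add, eta_start,
                          gh$z, gh$w)
  if (!is.finite(res$ofv)) {
    bad <- which(!is.finite(res$ofv_i))
    stop("non-finite likelihood for subject(s) ",
         paste(vapply(subjects[bad], `[[`, "", "subject_id"),
               collapse = ", "))
  }
  structure(res$ofv, eta = res$eta, ofv_i = res$ofv_i, hess = res$hess)
}

# Gauss-Hermite nodes/weights by Golub-Welsch (weight exp(-x^2))
.gauss_hermite <- function(n) {
  if (n == 1) return(list(z = 0, w = sqrt(pi)))
  k <- seq_len(n - 1)
  J <- diag(0, n)
  J[cbind(k, k + 1)] <- sqrt(k / 2)
  J[cbind(k + 1, k)] <- sqrt(k / 2)
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(z = e$values[ord], w = sqrt(pi) * e$vectors[1, ord]^2)
}

# estimable parameter bookkeeping -------------------------------------------

.all_par_names <- c("tvcl", "tvv", "ka", "omega_cl", "omega_v",
                    "sigma_prop", "sigma_add")

.pop_to_par <- function(pop, est_names, cov_idx) {
  p <- if (length(est_names)) log(unlist(pop[est_names])) else numeric(0)
  th <- vapply(pop$covariates[cov_idx], `[[`, numeric(1), "theta")
  if (length(th)) names(th) <- paste0("theta_", cov_idx)
  c(p, th)
}

.par_to_pop <- function(par, pop, est_names, cov_idx) {
  for (nm in est_names) pop[[nm]] <- exp(par[[nm]])
  for (k in seq_along(cov_idx))
    pop$covariates[[cov_idx[k]]]$theta <- par[[paste0("theta_", cov_idx[k])]]
  pop
}

#' Fit a population model by maximum (Laplace) marginal likelihood
#'
#' Minimizes [marginal_neg2ll()] over the unmasked parameters on the log
#' scale (covariate effect sizes on their natural scale), using
#' Nelder-Mead with several deterministically jittered starting points.
#' Relative standard errors come from the observed-information Hessian;
#' empirical Bayes estimates (EBEs) are the per-subject posterior modes
#' at the final estimates.
#'
#' @param subjects list of [subject_record()]
#' @param start starting [population_model()]
#' @param fixed names of parameters to hold fixed (any of `tvcl`, `tvv`,
#'   `ka`, `omega_cl`, `omega_v`, `sigma_prop`, `sigma_add`, or `"all"`);
#'   `f_oral` and `bmi_power` are always taken from `start`
#' @param estimate_cov_thetas estimate the `theta` of covariate relations
#'   not flagged `fixed = TRUE` in `start$covariates`
#' @param n_starts number of jittered Nelder-Mead starts (first start is
#'   unjittered)
#' @param jitter_sd log-scale magnitude of the start jitter
#' @param compute_rse,compute_cwres switch off post-fit diagnostics (used
#'   internally by the stepwise engine and the bootstrap for speed)
#' @param control passed to [stats::optim()]
#' @return object of class `poppk_fit`: elements `pop` (fitted model),
#'   `ofv`, `estimates`, `rse` (%), `ebes`, `shrinkage` (%), `cwres`
#'   (data frame), `converged`, `n_params`
#' @export
fit_poppk <- function(subjects, start = isa_base_model(), fixed = "ka",
                      estimate_cov_thetas = TRUE, n_starts = 3,
                      jitter_sd = 0.2, compute_rse = TRUE,
                      compute_cwres = TRUE,
                      control = list(maxit = 1000, reltol = 1e-8)) {
  stopifnot(inherits(start, "population_model"))
  flat <- .flatten_subjects(subjects)
  covdata <- .baseline_covariates(subjects)
  nsub <- length(flat)

  if (identical(fixed, "all")) {
    est_names <- character(0)
    cov_idx <- integer(0)
  } else {
    est_names <- setdiff(.all_par_names, fixed)
    cov_idx <- if (estimate_cov_thetas && length(start$covariates)) {
      which(!vapply(start$covariates,
                    function(e) isTRUE(e$fixed), logical(1)))
    } else integer(0)
  }

  eta_env <- new.env()
  eta_env$eta <- matrix(0, nsub, 2)
  objective <- function(par) {
    pop <- .par_to_pop(as.list(par), start, est_names, cov_idx)
    mult <- .cov_multipliers(pop, covdata)
    res <- .laplace_ofv_cpp(flat, pop$tvcl * mult$cl, pop$tvv * mult$v,
                            pop$ka, pop$f_oral,
                            max(pop$omega_cl, 1e-8),
                            max(pop$omega_v, 1e-8),
                            pop$sigma_prop, pop$sigma_add, eta_env$eta,
                            numeric(0), numeric(0))
    if (!is.finite(res$ofv)) return(1e10)
    eta_env$eta <- res$eta
    res$ofv
  }

  par0 <- .pop_to_par(start, est_names, cov_idx)
  n_params <- length(par0)
  if (n_params == 0) {
    ofv <- marginal_neg2ll(subjects, start)
    fit <- list(pop = start, ofv = as.numeric(ofv),
                estimates = numeric(0), rse = numeric(0),
                ebes = attr(ofv, "eta"), shrinkage = c(cl = NA, v = NA),
                cwres = NULL, converged = TRUE, n_params = 0,
                fixed = fixed, subjects_n = nsub)
    class(fit) <- "poppk_fit"
    if (compute_cwres) fit$cwres <- cwres(fit, subjects)
    return(fit)
  }

  # deterministic low-discrepancy jitters (no RNG involvement)
  best <- NULL
  for (s in seq_len(max(1, n_starts))) {
    off <- if (s == 1) 0 else
      jitter_sd * qnorm(((seq_len(n_params) * 0.6180339887 * s + 0.3) %% 0.98)
                        + 0.01)
    eta_env$eta <- matrix(0, nsub, 2)
    o <- optim(par0 + off, objective, method = "Nelder-Mead",
               control = control)
    # Nelder-Mead restarts: rebuild the simplex at the incumbent until the
    # improvement stalls (guards against premature simplex collapse)
    for (restart in 1:4) {
      o2 <- optim(o$par, objective, method = "Nelder-Mead",
                  control = control)
      improved <- o$value - o2$value
      if (o2$value <= o$value) o <- o2
      if (improved < 0.05) break
    }
    if (is.null(best) || o$value < best$value) best <- o
  }
  par_hat <- setNames(best$par, names(par0))
  pop_hat <- .par_to_pop(as.list(par_hat), start, est_names, cov_idx)
  ofv <- marginal_neg2ll(subjects, pop_hat)
  ebes <- attr(ofv, "eta")
  rownames(ebes) <- vapply(subjects, `[[`, "", "subject_id")
  colnames(ebes) <- c("eta_cl", "eta_v")

  estimates <- c(setNames(exp(par_hat[est_names]), est_names),
                 par_hat[setdiff(names(par_hat), est_names)])
  rse <- rep(NA_real_, n_params)
  names(rse) <- names(par_hat)
  if (compute_rse) {
    h <- tryCatch(optimHess(par_hat, objective), error = function(e) NULL)
    if (!is.null(h)) {
      vc <- tryCatch(2 * solve(h), error = function(e) NULL)
      if (!is.null(vc) && all(diag(vc) > 0)) {
        se <- sqrt(diag(vc))
        rse <- 100 * se  # log-scale SE ~ CV on the natural scale
        th <- setdiff(names(par_hat), est_names)
        rse[th] <- 100 * se[match(th, names(par_hat))] /
          pmax(abs(par_hat[th]), 1e-12)
      }
    }
  }
  shrink <- c(cl = eta_shrinkage(ebes[, 1], pop_hat$omega_cl),
              v = eta_shrinkage(ebes[, 2], pop_hat$omega_v))
  fit <- list(pop = pop_hat, ofv = as.numeric(ofv), estimates = estimates,
              rse = rse, ebes = ebes, shrinkage = shrink, cwres = NULL,
              converged = best$convergence == 0, n_params = n_params,
              fixed = fixed, subjects_n = nsub)
  class(fit) <- "poppk_fit"
  if (compute_cwres) fit$cwres <- cwres(fit, subjects)
  fit
}

#' @export
print.poppk_fit <- function(x, ...) {
  cat(sprintf("popPK fit: %d subjects, OFV %.3f, %d parameter(s)%s\n",
              x$subjects_n, x$ofv, x$n_params,
              if (x$converged) "" else " [NOT CONVERGED]"))
  if (length(x$estimates)) {
    tab <- data.frame(estimate = signif(x$estimates, 4),
                      rse_pct = round(x$rse, 1))
    print(tab)
  }
  cat(sprintf("eta-shrinkage: CL %.0f%%, V %.0f%%\n",
              x$shrinkage["cl"], x$shrinkage["v"]))
  invisible(x)
}

#' Likelihood-ratio comparison of nested fits
#'
#' Forward inclusion accepts the richer model when
#' \eqn{\Delta OFV \le -\chi^2_{0.95}(df)} (-3.84 at one degree of
#' freedom); backward deletion retains it only when removing it worsens
#' the OFV by more than \eqn{\chi^2_{0.99}(df)} (6.63 at df 1).
#'
#' @param fit_simple,fit_complex nested `poppk_fit` objects
#' @param mode "forward" or "backward"
#' @return list with `delta_ofv`, `df`, `p_value`, `decision`
#' @export
lrt_compare <- function(fit_simple, fit_complex,
                        mode = c("forward", "backward")) {
  mode <- match.arg(mode)
  df <- fit_complex$n_params - fit_simple$n_params
  if (df <= 0) stop("fit_complex must have more parameters than fit_simple")
  delta <- fit_complex$ofv - fit_simple$ofv
  p <- pchisq(max(-delta, 0), df, lower.tail = FALSE)
  thr <- if (mode == "forward") qchisq(0.95, df) else qchisq(0.99, df)
  accept <- -delta >= thr
  list(delta_ofv = delta, df = df, p_value = p,
       decision = if (accept) "accept_complex" else "keep_simple",
       threshold = -thr, mode = mode)
}

#' AIC comparison of (possibly non-nested) fits
#'
#' AIC is `ofv + 2 * n_params`; the alternative is selected only when its
#' AIC is lower by at least 2.
#'
#' @param fit_ref,fit_alt `poppk_fit` objects
#' @return list with `delta_aic` (alt - ref) and `decision`
#' @export
aic_compare <- function(fit_ref, fit_alt) {
  aic_ref <- fit_ref$ofv + 2 * fit_ref$n_params
  aic_alt <- fit_alt$ofv + 2 * fit_alt$n_params
  delta <- aic_alt - aic_ref
  list(aic_ref = aic_ref, aic_alt = aic_alt, delta_aic = delta,
       decision = if (delta <= -2) "accept_alternative" else "keep_reference")
}

#' Stepwise covariate selection
#'
#' Forward inclusion at p = 0.05 (the candidate with the best
#' \eqn{\Delta OFV} enters first, one relation per cycle) followed by
#' backward deletion at p = 0.01. Candidate relations are specified as a
#' data frame with columns `param` ("cl"/"v"), `cov` (a covariate name
#' known to [subject_record()] covariates) and `form` ("power", "linear"
#' or "categorical"); continuous covariates are centred on their median
#' unless a `ref` column is supplied.
#'
#' @param subjects list of [subject_record()]
#' @param base_fit a `poppk_fit` of the covariate-free model
#' @param candidates candidate data frame (above)
#' @param forward_alpha,backward_alpha selection significance levels
#' @return list with `fit` (final), `trace` (every tested relation with
#'   its delta-OFV and decision) and `retained` (kept relations, with the
#'   IIV-variance reduction each explains)
#' @export
stepwise_covariates <- function(subjects, base_fit, candidates,
                                forward_alpha = 0.05,
                                backward_alpha = 0.01) {
  if (!nrow(candidates)) {
    return(list(fit = base_fit,
                trace = data.frame(), retained = data.frame()))
  }
  covdata <- .baseline_covariates(subjects)
  cand <- lapply(seq_len(nrow(candidates)), function(k) {
    e <- as.list(candidates[k, , drop = FALSE])
    x <- covdata[[e$cov]]
    if (is.null(x) || all(is.na(x))) return(NULL)
    ref <- if (!is.null(e$ref) && !is.na(e$ref)) e$ref else
      if (e$form == "categorical") 0 else median(x, na.rm = TRUE)
    list(param = e$param, cov = e$cov, form = e$form, ref = ref,
         theta = 0.01, fixed = FALSE)
  })
  dropped <- vapply(cand, is.null, logical(1))
  if (any(dropped))
    warning("candidate covariate(s) never quantified, skipped: ",
            paste(candidates$cov[dropped], collapse = ", "))
  cand <- cand[!dropped]

  fwd_thr <- -qchisq(1 - forward_alpha, 1)
  bwd_thr <- qchisq(1 - backward_alpha, 1)
  trace <- list()
  current_fit <- base_fit
  remaining <- cand
  retained <- list()
  step <- 0

  refit <- function(pop, start_fit) {
    fit_poppk(subjects, start = pop, fixed = start_fit$fixed,
              n_starts = 1, compute_rse = FALSE, compute_cwres = FALSE)
  }

  while (length(remaining)) {
    step <- step + 1
    fits <- vector("list", length(remaining))
    dofv <- numeric(length(remaining))
    for (k in seq_along(remaining)) {
      pop_k <- current_fit$pop
      pop_k$covariates <- c(pop_k$covariates, list(remaining[[k]]))
      fits[[k]] <- refit(pop_k, current_fit)
      dofv[k] <- fits[[k]]$ofv - current_fit$ofv
      trace[[length(trace) + 1]] <- data.frame(
        step = sprintf("forward_%d", step), param = remaining[[k]]$param,
        cov = remaining[[k]]$cov, form = remaining[[k]]$form,
        delta_ofv = dofv[k],
        decision = "tested", stringsAsFactors = FALSE)
    }
    best <- which.min(dofv)
    if (dofv[best] <= fwd_thr) {
      trace[[length(trace) + 1]] <- data.frame(
        step = sprintf("forward_%d", step),
        param = remaining[[best]]$param, cov = remaining[[best]]$cov,
        form = remaining[[best]]$form, delta_ofv = dofv[best],
        decision = "included", stringsAsFactors = FALSE)
      retained[[length(retained) + 1]] <- remaining[[best]]
      current_fit <- fits[[best]]
      remaining <- remaining[-best]
    } else break
  }

  # backward deletion on the retained relations
  repeat {
    k_rel <- length(current_fit$pop$covariates)
    if (k_rel == 0) break
    incr <- numeric(k_rel)
    fits_wo <- vector("list", k_rel)
    for (k in seq_len(k_rel)) {
      pop_k <- current_fit$pop
      pop_k$covariates <- pop_k$covariates[-k]
      fits_wo[[k]] <- refit(pop_k, current_fit)
      incr[k] <- fits_wo[[k]]$ofv - current_fit$ofv
    }
    worst <- which.min(incr)
    rel <- current_fit$pop$covariates[[worst]]
    if (incr[worst] <= bwd_thr) {
      trace[[length(trace) + 1]] <- data.frame(
        step = "backward", param = rel$param, cov = rel$cov,
        form = rel$form, delta_ofv = incr[worst], decision = "removed",
        stringsAsFactors = FALSE)
      current_fit <- fits_wo[[worst]]
    } else {
      for (k in seq_len(k_rel)) {
        rel <- current_fit$pop$covariates[[k]]
        trace[[length(trace) + 1]] <- data.frame(
          step = "backward", param = rel$param, cov = rel$cov,
          form = rel$form, delta_ofv = incr[k], decision = "retained",
          stringsAsFactors = FALSE)
      }
      break
    }
  }

  kept <- current_fit$pop$covariates
  retained_df <- if (length(kept)) {
    data.frame(param = vapply(kept, `[[`, "", "param"),
               cov = vapply(kept, `[[`, "", "cov"),
               form = vapply(kept, `[[`, "", "form"),
               theta = vapply(kept, `[[`, numeric(1), "theta"),
               iiv_variance_reduction_pct = vapply(seq_along(kept),
                 function(k) {
                   pop_k <- current_fit$pop
                   pop_k$covariates <- pop_k$covariates[-k]
                   f <- refit(pop_k, current_fit)
                   om <- if (kept[[k]]$param == "cl") "omega_cl" else
                     "omega_v"
                   100 * (1 - current_fit$pop[[om]]^2 / f$pop[[om]]^2)
                 }, numeric(1)),
               stringsAsFactors = FALSE)
  } else data.frame()
  list(fit = current_fit, trace = do.call(rbind, trace),
       retained = retained_df)
}

#' Conditional weighted residuals
#'
#' First-order conditional (FOCE) linearization of the model around the
#' empirical Bayes estimates: with \eqn{G = \partial f/\partial\eta} at
#' the EBE, \eqn{CWRES = V^{-1/2}(y - f(\hat\eta) + G\hat\eta)} where
#' \eqn{V = G\,\Omega\,G^T + diag(f^2\sigma_p^2 + \sigma_a^2)}. Under a
#' correct model CWRES are approximately standard normal.
#'
#' @param fit a `poppk_fit`
#' @param subjects the subjects the fit was computed on
#' @return data frame: subject_id, time, dv, ipred, pred, cwres
#' @export
cwres <- function(fit, subjects) {
  pop <- fit$pop
  covdata <- .baseline_covariates(subjects)
  mult <- .cov_multipliers(pop, covdata)
  omega <- diag(c(max(pop$omega_cl, 1e-8)^2, max(pop$omega_v, 1e-8)^2))
  out <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    o <- s$observations
    o <- o[!o$is_missing & !is.na(o$value), , drop = FALSE]
    eta <- fit$ebes[i, ]
    cl_t <- pop$tvcl * mult$cl[i]
    v_t <- pop$tvv * mult$v[i]
    fpred <- function(e) {
      ind <- list(cl = cl_t * exp(e[1]), v = v_t * exp(e[2]), ka = pop$ka)
      concentration(o$time, s$doses, ind, pop$f_oral)
    }
    f_eta <- fpred(eta)
    f_0 <- fpred(c(0, 0))
    h <- 1e-4
    g1 <- (fpred(eta + c(h, 0)) - fpred(eta - c(h, 0))) / (2 * h)
    g2 <- (fpred(eta + c(0, h)) - fpred(eta - c(0, h))) / (2 * h)
    G <- cbind(g1, g2)
    vres <- pmax(f_eta^2 * pop$sigma_prop^2 + pop$sigma_add^2, 1e-12)
    V <- G %*% omega %*% t(G) + diag(vres, nrow = length(vres))
    mu <- f_eta - as.vector(G %*% eta)
    w <- tryCatch(solve(t(chol(V)), o$value - mu),
                  error = function(e) (o$value - mu) / sqrt(diag(V)))
    out[[i]] <- data.frame(subject_id = s$subject_id, time = o$time,
                           dv = o$value, ipred = f_eta, pred = f_0,
                           cwres = as.numeric(w),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Flag outlying observations by |CWRES|
#'
#' @param fit a `poppk_fit` computed with `compute_cwres = TRUE`
#' @param threshold absolute CWRES cutoff (default 3)
#' @return the flagged rows of the CWRES table
#' @export
cwres_flag <- function(fit, threshold = 3) {
  if (is.null(fit$cwres)) stop("fit has no CWRES table")
  fit$cwres[abs(fit$cwres$cwres) > threshold, , drop = FALSE]
}

#' Nonparametric bootstrap of a population fit
#'
#' Resamples subjects with replacement and refits each replicate
#' (single-start, warm-started at the original estimates), reporting the
#' per-parameter median and percentile 95% confidence interval.
#'
#' @param subjects list of [subject_record()]
#' @param fit the original `poppk_fit`
#' @param n number of replicates (2000 for production use; tests use far
#'   fewer)
#' @param seed integer seed
#' @return object of class `poppk_boot`: data frame `summary` with
#'   estimate, median and CI95 per parameter; matrix `replicates`
#' @export
bootstrap_poppk <- function(subjects, fit, n = 2000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  reps <- matrix(NA_real_, n, length(fit$estimates),
                 dimnames = list(NULL, names(fit$estimates)))
  conv <- logical(n)
  for (r in seq_len(n)) {
    idx <- sample(length(subjects), replace = TRUE)
    f <- tryCatch(
      fit_poppk(subjects[idx], start = fit$pop, fixed = fit$fixed,
                n_starts = 1, compute_rse = FALSE, compute_cwres = FALSE),
      error = function(e) NULL)
    if (!is.null(f)) {
      reps[r, ] <- f$estimates[colnames(reps)]
      conv[r] <- f$converged
    }
  }
  ok <- rowSums(is.na(reps)) == 0
  s <- apply(reps[ok, , drop = FALSE], 2, quantile,
             probs = c(0.5, 0.025, 0.975))
  out <- list(summary = data.frame(parameter = colnames(reps),
                                   estimate = fit$estimates[colnames(reps)],
                                   median = s[1, ], ci_lo = s[2, ],
                                   ci_hi = s[3, ], row.names = NULL),
              replicates = reps, n_replicates = sum(ok),
              n_converged = sum(conv))
  class(out) <- "poppk_boot"
  out
}

#' @export
print.poppk_boot <- function(x, ...) {
  cat(sprintf("Nonparametric bootstrap: %d successful replicates\n",
              x$n_replicates))
  print(transform(x$summary, estimate = signif(estimate, 4),
                  median = signif(median, 4), ci_lo = signif(ci_lo, 4),
                  ci_hi = signif(ci_hi, 4)))
  invisible(x)
}

#' Eta-shrinkage
#'
#' \eqn{100 (1 - SD(EBE)/\omega)}: contraction of the empirical Bayes
#' estimates toward zero when individual data are sparse.
#'
#' @param ebes vector of empirical Bayes estimates for one random effect
#' @param omega the corresponding population log-scale SD
#' @return shrinkage in percent
#' @export
eta_shrinkage <- function(ebes, omega) {
  if (omega <= 0) return(NA_real_)
  100 * (1 - sd(ebes) / omega)
}
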