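# External-validation metrics and prediction-corrected VPC.

.check_pairs <- function(dv, ipred) {
  if (length(dv) != length(ipred)) stop("dv and ipred lengths differ")
  if (any(dv <= 0) || any(ipred <= 0) || any(!is.finite(c(dv, ipred))))
    stop("all dv and ipred values must be positive and finite")
}

#' Mean prediction error (log scale, back-transformed)
#'
#' \eqn{MPE(\%) = 100\,[\exp(\overline{\ln DV - \ln IPRED}) - 1]}, with a
#' 95% confidence interval from the Student-t interval of the
#' log-differences, back-transformed the same way.
#'
#' @param dv observed concentrations (> 0)
#' @param ipred individual model predictions (> 0)
#' @return list with `mpe_pct`, `ci95` (length-2) and `n`
#' @export
mpe <- function(dv, ipred) {
  .check_pairs(dv, ipred)
  d <- log(dv) - log(ipred)
  n <- length(d)
  m <- mean(d)
  ci <- if (n > 1) {
    half <- qt(0.975, n - 1) * sd(d) / sqrt(n)
    100 * (exp(m + c(-half, half)) - 1)
  } else c(NA_real_, NA_real_)
  list(mpe_pct = 100 * (exp(m) - 1), ci95 = ci, n = n)
}

#' Root-mean-squared relative prediction error (log scale)
#'
#' \eqn{RMSE(\%) = 100\sqrt{\exp(\overline{(\ln DV - \ln IPRED)^2}) - 1}}.
#'
#' @inheritParams mpe
#' @return list with `rmse_pct` and `n`
#' @export
rmse <- function(dv, ipred) {
  .check_pairs(dv, ipred)
  d <- log(dv) - log(ipred)
  list(rmse_pct = 100 * sqrt(exp(mean(d^2)) - 1), n = length(d))
}

# time since the most recent dose, per kept observation of a subject
.time_after_dose <- function(s) {
  o <- s$observations
  o <- o[!o$is_missing & !is.na(o$value), , drop = FALSE]
  vapply(o$time, function(t) {
    prev <- s$doses$time[s$doses$time <= t]
    if (!length(prev)) return(t)
    t - max(prev)
  }, numeric(1))
}

#' Prediction-corrected visual predictive check
#'
#' Observations (and simulated replicates of them) are multiplied by the
#' ratio of the bin-median population prediction to their own population
#' prediction, removing dose and covariate differences; observed 5/50/95
#' percentiles per time-after-dose bin are then compared with the
#' simulation-based confidence bands of the same percentiles.
#'
#' @param subjects list of [subject_record()]
#' @param pop a [population_model()]
#' @param n_sim number of simulated replicates (>= 100)
#' @param bins number of equal-count time-after-dose bins
#' @param seed integer seed for the simulation
#' @param ci level of the simulated percentile bands
#' @return object of class `pcvpc`: data frame `table` with, per bin and
#'   percentile, the observed value and the simulated band
#' @export
pcvpc <- function(subjects, pop, n_sim = 500, bins = 10, seed = NULL,
                  ci = 0.95) {
  if (n_sim < 100) stop("n_sim must be at least 100")
  if (!is.null(seed)) set.seed(seed)
  covdata <- .baseline_covariates(subjects)
  mult <- .cov_multipliers(pop, covdata)

  obs <- list()
  for (i in seq_along(subjects)) {
    s <- subjects[[i]]
    o <- s$observations
    o <- o[!o$is_missing & !is.na(o$value), , drop = FALSE]
    ind0 <- list(cl = pop$tvcl * mult$cl[i], v = pop$tvv * mult$v[i],
                 ka = pop$ka)
    pred <- concentration(o$time, s$doses, ind0, pop$f_oral)
    obs[[i]] <- data.frame(subject = i, time = o$time, dv = o$value,
                           pred = pred, tad = .time_after_dose(s))
  }
  obs <- do.call(rbind, obs)
  if (any(obs$pred <= 0)) {
    drop <- obs$pred <= 0
    warning(sum(drop), " observation(s) with non-positive population ",
            "prediction dropped from the VPC")
    obs <- obs[!drop, , drop = FALSE]
  }
  # equal-count bins that never split tied time-after-dose values
  # (routine TDM data cluster heavily at the nominal trough time)
  ux <- sort(unique(obs$tad))
  if (length(ux) <= bins) {
    obs$bin <- match(obs$tad, ux)
  } else {
    cnt <- as.integer(table(factor(obs$tad, levels = ux)))
    grp <- pmin(bins, ceiling(cumsum(cnt) / (length(obs$tad) / bins)))
    grp <- cummax(grp)
    grp <- match(grp, sort(unique(grp)))  # consecutive labels
    obs$bin <- grp[match(obs$tad, ux)]
  }
  if (length(unique(obs$bin)) < bins)
    warning("fewer than ", bins, " distinct bins after tie-preserving ",
            "binning")

  med_pred <- tapply(obs$pred, obs$bin, median)
  obs$pc <- obs$dv * med_pred[as.character(obs$bin)] / obs$pred

  probs <- c(0.05, 0.5, 0.95)
  obs_q <- do.call(rbind, lapply(split(obs, obs$bin), function(b) {
    data.frame(bin = b$bin[1], tad_mid = median(b$tad),
               percentile = probs, observed = quantile(b$pc, probs),
               row.names = NULL)
  }))

  # simulate replicates of the same design
  nobs <- nrow(obs)
  sim_q <- array(NA_real_, c(n_sim, length(unique(obs$bin)), 3),
                 dimnames = list(NULL, sort(unique(obs$bin)), probs))
  for (r in seq_len(n_sim)) {
    e1 <- rnorm(length(subjects), 0, pop$omega_cl)
    e2 <- rnorm(length(subjects), 0, pop$omega_v)
    fsim <- numeric(nobs)
    for (i in seq_along(subjects)) {
      rows <- obs$subject == i
      if (!any(rows)) next
      s <- subjects[[i]]
      ind <- list(cl = pop$tvcl * mult$cl[i] * exp(e1[i]),
                  v = pop$tvv * mult$v[i] * exp(e2[i]), ka = pop$ka)
      fsim[rows] <- concentration(obs$time[rows], s$doses, ind, pop$f_oral)
    }
    ysim <- fsim * (1 + rnorm(nobs, 0, pop$sigma_prop)) +
      rnorm(nobs, 0, pop$sigma_add)
    pc <- ysim * med_pred[as.character(obs$bin)] / obs$pred
    for (b in sort(unique(obs$bin)))
      sim_q[r, as.character(b), ] <- quantile(pc[obs$bin == b], probs)
  }
  a <- (1 - ci) / 2
  tab <- do.call(rbind, lapply(sort(unique(obs$bin)), function(b) {
    data.frame(bin = b,
               tad_mid = obs_q$tad_mid[obs_q$bin == b][1],
               percentile = probs,
               observed = obs_q$observed[obs_q$bin == b],
               sim_lo = apply(sim_q[, as.character(b), ], 2, quantile, a),
               sim_med = apply(sim_q[, as.character(b), ], 2, median),
               sim_hi = apply(sim_q[, as.character(b), ], 2, quantile,
                              1 - a),
               row.names = NULL)
  }))
  structure(list(table = tab, n_sim = n_sim, ci = ci), class = "pcvpc")
}

#' @export
print.pcvpc <- function(x, ...) {
  cat(sprintf("pcVPC: %d bins x 3 percentiles, %d simulations\n",
              length(unique(x$table$bin)), x$n_sim))
  inside <- with(x$table, observed >= sim_lo & observed <= sim_hi)
  cat(sprintf("observed percentiles inside the %.0f%% simulated band: ",
              100 * x$ci), sum(inside), "/", length(inside), "\n")
  invisible(x)
}

#' Plot a pcVPC (requires ggplot2)
#'
#' @param x a [pcvpc()] result
#' @param ... unused
#' @return a ggplot object
#' @export
plot_pcvpc <- function(x, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  tab <- x$table
  tab$percentile <- factor(tab$percentile)
  ggplot2::ggplot(tab, ggplot2::aes(x = tad_mid, group = percentile)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = sim_lo, ymax = sim_hi),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = sim_med), colour = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = observed), colour = "black") +
    ggplot2::geom_point(ggplot2::aes(y = observed), colour = "black") +
    ggplot2::labs(x = "time after dose (h)",
                  y = "prediction-corrected concentration (mg/L)",
                  title = "Prediction-corrected visual predictive check")
}
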