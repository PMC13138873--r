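# Exploratory exposure-response / exposure-toxicity logistic regressions.

#' Logistic regression of a binary outcome on log-exposure
#'
#' Maximum-likelihood fit of `outcome ~ log(exposure)` with the p-value
#' from the likelihood-ratio test against the intercept-only model.
#' Complete separation is reported as such rather than yielding a
#' spurious p-value.
#'
#' @param records data frame with columns `cmin`, `auc` and the outcome
#'   column (0/1); typically [exposure_table()] joined to outcome labels
#' @param exposure `"cmin"` or `"auc"`
#' @param outcome name of the outcome column (e.g. `"success"`,
#'   `"hepatotoxicity"`, `"discontinuation"`)
#' @return object of class `logistic_result`: `intercept`, `slope` (per
#'   log-unit of exposure), `p_value` (LRT), `n`, `separated`, and
#'   `curve(x)` giving the fitted success probability at exposure `x`
#' @export
fit_exposure_outcome <- function(records, exposure = c("cmin", "auc"),
                                 outcome = "success") {
  exposure <- match.arg(exposure)
  x <- records[[exposure]]
  y <- records[[outcome]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(y) < 2 || length(unique(y)) < 2)
    stop("outcome '", outcome, "' shows no variation; nothing to fit")
  if (any(x <= 0)) stop("exposures must be positive")
  lx <- log(x)
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ lx, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  separated <- sep_warn && max(abs(coef(fit))) > 15
  null_fit <- glm(y ~ 1, family = binomial())
  p <- if (separated) NA_real_ else
    pchisq(null_fit$deviance - fit$deviance, df = 1, lower.tail = FALSE)
  a <- unname(coef(fit)[1]); b <- unname(coef(fit)[2])
  structure(list(intercept = a, slope = b, p_value = p, n = length(y),
                 separated = separated, exposure = exposure,
                 outcome = outcome, deviance = fit$deviance,
                 vcov = summary(fit)$cov.unscaled,
                 curve = function(x) plogis(a + b * log(x))),
            class = "logistic_result")
}

#' @export
print.logistic_result <- function(x, ...) {
  cat(sprintf("logistic %s ~ log(%s), n = %d\n", x$outcome, x$exposure, x$n))
  if (x$separated) {
    cat("complete separation: slope unbounded, no p-value reported\n")
  } else {
    cat(sprintf("  slope %.3f per log-unit (OR %.2f), LRT p = %.3g\n",
                x$slope, exp(x$slope), x$p_value))
  }
  invisible(x)
}

#' Sensitivity refits under record-removal rules
#'
#' Repeats [fit_exposure_outcome()] after applying each drop rule in
#' turn. Rules are lists with a `kind`:
#' \describe{
#'   \item{`centre`}{drop all records of `centre` (needs a `centre`
#'     column)}
#'   \item{`quantile`}{drop records whose exposure lies outside the
#'     `probs = c(lo, hi)` quantiles}
#'   \item{`ids`}{drop the explicit subject `ids` (extreme values
#'     identified clinically rather than numerically)}
#' }
#'
#' @param records as in [fit_exposure_outcome()]
#' @param drop_rules list of rules (above)
#' @param ... passed to [fit_exposure_outcome()]
#' @return named list of `logistic_result`s, one per rule, each with a
#'   `dropped` attribute giving the number of removed records
#' @export
sensitivity_refit <- function(records, drop_rules, ...) {
  args <- list(...)
  exposure <- if (is.null(args$exposure)) "cmin" else
    match.arg(args$exposure, c("cmin", "auc"))
  out <- list()
  for (rule in drop_rules) {
    keep <- rep(TRUE, nrow(records))
    label <- rule$kind
    if (rule$kind == "centre") {
      keep <- !(records$centre %in% rule$centre)
      label <- paste0("drop_centre_", paste(rule$centre, collapse = "+"))
    } else if (rule$kind == "quantile") {
      x <- records[[exposure]]
      qs <- quantile(x, rule$probs, na.rm = TRUE)
      keep <- x >= qs[1] & x <= qs[2]
      label <- sprintf("drop_%s_outside_q%g_q%g", exposure, rule$probs[1],
                       rule$probs[2])
    } else if (rule$kind == "ids") {
      keep <- !(records$id %in% rule$ids)
      label <- paste0("drop_ids_", length(rule$ids))
    } else stop("unknown drop rule kind '", rule$kind, "'")
    res <- fit_exposure_outcome(records[keep, , drop = FALSE], ...)
    attr(res, "dropped") <- sum(!keep)
    out[[label]] <- res
  }
  out
}
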