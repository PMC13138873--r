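#' Dose-event table
#'
#' @param time hours since the subject's first record (>= 0)
#' @param amount dose amount (mg, > 0)
#' @param route "oral" or "iv"
#' @param infusion_duration infusion duration (h); must be 0 for oral doses
#' @param imputed logical; `TRUE` when the dose time was assumed rather
#'   than recorded (nominal once-daily schedules)
#' @return a data frame of dose events
#' @export
dose_events <- function(time, amount, route = "oral", infusion_duration = 0,
                        imputed = FALSE) {
  n <- length(time)
  route <- rep_len(route, n)
  infusion_duration <- rep_len(infusion_duration, n)
  imputed <- rep_len(imputed, n)
  if (any(amount <= 0)) stop("dose amount must be positive")
  if (any(time < 0)) stop("dose time must be non-negative")
  if (any(infusion_duration < 0)) stop("infusion_duration must be >= 0")
  if (!all(route %in% c("oral", "iv"))) stop("route must be 'oral' or 'iv'")
  if (any(route == "oral" & infusion_duration > 0))
    stop("oral doses cannot have an infusion duration")
  data.frame(time = as.numeric(time),
             amount = as.numeric(rep_len(amount, n)), route = route,
             infusion_duration = as.numeric(infusion_duration),
             imputed = as.logical(imputed))
}

#' Observation table
#'
#' @param time hours since the subject's first record
#' @param value measured concentration (mg/L); `NA` allowed when missing
#' @param is_missing logical MDV analogue
#' @param imputed logical; `TRUE` for assumed (nominal trough) times
#' @return a data frame of observations
#' @export
observations <- function(time, value, is_missing = FALSE, imputed = FALSE) {
  n <- length(time)
  is_missing <- rep_len(is_missing, n)
  imputed <- rep_len(imputed, n)
  if (any(time < 0)) stop("observation time must be non-negative")
  if (any(!is_missing & (is.na(value) | value <= 0)))
    stop("non-missing observations must have a positive value")
  data.frame(time = as.numeric(time), value = as.numeric(value),
             is_missing = as.logical(is_missing),
             imputed = as.logical(imputed))
}

#' Subject record
#'
#' One patient's dosing history, concentration observations and
#' time-stamped covariates.
#'
#' @param subject_id identifier
#' @param doses data frame from [dose_events()]
#' @param obs data frame from [observations()]
#' @param covariates data frame with a `time` column plus any of:
#'   `body_weight`, `height`, `age`, `sex` ("male"/"female"), `bmi`,
#'   `creatinine`, `egfr`, `total_bilirubin`, `albumin`, `alt`, `ast`,
#'   `alp`, `ggt`
#' @param centre study centre (1, 2 or 3)
#' @param outcome_labels optional list with elements `success`,
#'   `hepatotoxicity`, `discontinuation` (0/1) and `eval_time` (h)
#' @return object of class `subject_record`
#' @export
subject_record <- function(subject_id, doses, obs, covariates = NULL,
                           centre = 1L, outcome_labels = NULL) {
  if (nrow(obs) < 1) stop("a subject needs at least one observation")
  if (!is.null(covariates)) {
    if (!"time" %in% names(covariates)) stop("covariates need a time column")
    if (all(c("bmi", "body_weight", "height") %in% names(covariates))) {
      ok <- is.na(covariates$bmi) | is.na(covariates$body_weight) |
        is.na(covariates$height) |
        abs(covariates$bmi -
              covariates$body_weight / (covariates$height / 100)^2) <= 0.5
      if (!all(ok)) stop("bmi inconsistent with weight/height^2 (> 0.5)")
    }
  }
  structure(list(subject_id = subject_id, centre = as.integer(centre),
                 doses = doses[order(doses$time), , drop = FALSE],
                 observations = obs[order(obs$time), , drop = FALSE],
                 covariates = covariates, outcome_labels = outcome_labels),
            class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("Subject %s (centre %d): %d doses, %d observations\n",
              x$subject_id, x$centre, nrow(x$doses), nrow(x$observations)))
  invisible(x)
}

# column dialect: NONMEM-style flat CSV
.cov_cols <- c(BW = "body_weight", HT = "height", AGE = "age", SEX = "sex",
               BMI = "bmi", CREA = "creatinine", EGFR = "egfr",
               TBIL = "total_bilirubin", ALB = "albumin", ALT = "alt",
               AST = "ast", ALP = "alp", GGT = "ggt")

#' Dataset dialect configuration
#'
#' Fixes the column naming and unit conventions of the flat CSV dataset:
#' times in hours, amounts in mg, concentrations in mg/L, "." for missing.
#' `EVID` 1 marks dose rows, 0 observation rows, 2 covariate-only rows.
#' `CMT` 1 is the depot (oral dosing), 2 the central compartment (IV);
#' `RATE > 0` on an IV row encodes an infusion of duration `AMT/RATE`.
#' `SEX` is coded 0 = male, 1 = female.
#'
#' @param id,time,amt,rate,evid,cmt,dv,mdv,centre,imputed column names
#' @return a named list of column names
#' @export
dataset_dialect <- function(id = "ID", time = "TIME", amt = "AMT",
                            rate = "RATE", evid = "EVID", cmt = "CMT",
                            dv = "DV", mdv = "MDV", centre = "CENTRE",
                            imputed = "IMPUTED") {
  list(id = id, time = time, amt = amt, rate = rate, evid = evid, cmt = cmt,
       dv = dv, mdv = mdv, centre = centre, imputed = imputed)
}

#' Read a NONMEM-dialect longitudinal dataset
#'
#' @param path CSV file path
#' @param dialect a [dataset_dialect()]
#' @return list of [subject_record()] objects
#' @export
read_dataset <- function(path, dialect = dataset_dialect()) {
  df <- read.csv(path, na.strings = c(".", "NA", ""),
                 stringsAsFactors = FALSE)
  mandatory <- c(dialect$id, dialect$time, dialect$amt, dialect$evid,
                 dialect$dv, dialect$mdv)
  missing_cols <- setdiff(mandatory, names(df))
  if (length(missing_cols))
    stop("dataset format error: missing mandatory column(s) ",
         paste(missing_cols, collapse = ", "))
  if (!dialect$rate %in% names(df)) df[[dialect$rate]] <- 0
  if (!dialect$cmt %in% names(df)) df[[dialect$cmt]] <- 1
  if (!dialect$centre %in% names(df)) df[[dialect$centre]] <- 1
  if (!dialect$imputed %in% names(df)) df[[dialect$imputed]] <- 0
  df[[dialect$rate]][is.na(df[[dialect$rate]])] <- 0
  df[[dialect$mdv]][is.na(df[[dialect$mdv]])] <- 0

  lapply(split(df, factor(df[[dialect$id]], levels = unique(df[[dialect$id]]))),
         function(sub) {
    tm <- sub[[dialect$time]]
    if (is.unsorted(tm)) {
      stop("non-monotone TIME within ID ", sub[[dialect$id]][1])
    }
    ev <- sub[[dialect$evid]]
    bad <- ev == 0 & sub[[dialect$mdv]] == 1 & !is.na(sub[[dialect$dv]]) &
      sub[[dialect$dv]] > 0
    if (any(bad))
      warning("ID ", sub[[dialect$id]][1],
              ": DV > 0 on MDV = 1 row(s); value ignored")
    drow <- sub[ev == 1, , drop = FALSE]
    doses <- dose_events(
      time = drow[[dialect$time]],
      amount = drow[[dialect$amt]],
      route = ifelse(drow[[dialect$cmt]] == 2, "iv", "oral"),
      infusion_duration = ifelse(drow[[dialect$rate]] > 0,
                                 drow[[dialect$amt]] / drow[[dialect$rate]],
                                 0),
      imputed = drow[[dialect$imputed]] == 1)
    orow <- sub[ev == 0, , drop = FALSE]
    obs <- observations(
      time = orow[[dialect$time]],
      value = ifelse(orow[[dialect$mdv]] == 1, NA_real_,
                     orow[[dialect$dv]]),
      is_missing = orow[[dialect$mdv]] == 1,
      imputed = orow[[dialect$imputed]] == 1)
    covs <- .extract_covariates(sub, dialect)
    subject_record(subject_id = as.character(sub[[dialect$id]][1]),
                   doses = doses, obs = obs, covariates = covs,
                   centre = sub[[dialect$centre]][1])
  })
}

.extract_covariates <- function(sub, dialect) {
  present <- intersect(names(.cov_cols), names(sub))
  if (!length(present)) return(NULL)
  covs <- sub[, c(dialect$time, present), drop = FALSE]
  names(covs) <- c("time", unname(.cov_cols[present]))
  keep <- rowSums(!is.na(covs[, -1, drop = FALSE])) > 0
  covs <- covs[keep, , drop = FALSE]
  if (!nrow(covs)) return(NULL)
  for (nm in setdiff(names(covs), c("time", "sex")))
    covs[[nm]] <- as.numeric(covs[[nm]])
  covs$time <- as.numeric(covs$time)
  if ("sex" %in% names(covs))
    covs$sex <- c("male", "female")[covs$sex + 1]
  covs <- covs[!duplicated(covs), , drop = FALSE]
  rownames(covs) <- NULL
  covs
}

#' Write subject records back to the flat CSV dialect
#'
#' Inverse of [read_dataset()]: dose rows get `EVID = 1`, observations
#' `EVID = 0`; covariate records whose time does not coincide with an
#' event are written as `EVID = 2` rows. Numeric fields round-trip
#' exactly (written with full precision).
#'
#' @param subjects list of [subject_record()]
#' @param path output CSV path
#' @param dialect a [dataset_dialect()]
#' @return `path`, invisibly
#' @export
write_dataset <- function(subjects, path, dialect = dataset_dialect()) {
  rows <- lapply(subjects, function(s) {
    d <- s$doses
    dr <- data.frame(ID = s$subject_id, CENTRE = s$centre, TIME = d$time,
                     EVID = 1, AMT = d$amount,
                     RATE = ifelse(d$infusion_duration > 0,
                                   d$amount / d$infusion_duration, 0),
                     CMT = ifelse(d$route == "iv", 2, 1),
                     DV = NA_real_, MDV = 1, IMPUTED = as.integer(d$imputed))
    o <- s$observations
    or <- data.frame(ID = s$subject_id, CENTRE = s$centre, TIME = o$time,
                     EVID = 0, AMT = NA_real_, RATE = 0, CMT = 2,
                     DV = o$value, MDV = as.integer(o$is_missing),
                     IMPUTED = as.integer(o$imputed))
    out <- rbind(dr, or)
    cv <- s$covariates
    if (!is.null(cv)) {
      extra <- setdiff(cv$time, out$TIME)
      if (length(extra)) {
        out <- rbind(out,
                     data.frame(ID = s$subject_id, CENTRE = s$centre,
                                TIME = extra, EVID = 2, AMT = NA_real_,
                                RATE = 0, CMT = 1, DV = NA_real_, MDV = 1,
                                IMPUTED = 0))
      }
      for (nm in names(.cov_cols)) out[[nm]] <- NA_real_
      idx <- match(out$TIME, cv$time)
      for (nm in names(.cov_cols)) {
        col <- .cov_cols[[nm]]
        if (col %in% names(cv)) {
          vals <- cv[[col]]
          if (col == "sex") vals <- as.numeric(vals == "female")
          out[[nm]] <- vals[idx]
        }
      }
    }
    out[order(out$TIME, -out$EVID), , drop = FALSE]
  })
  all_rows <- do.call(rbind, rows)
  tmp <- all_rows
  for (j in seq_along(tmp))
    if (is.numeric(tmp[[j]]))
      tmp[[j]] <- ifelse(is.na(tmp[[j]]), ".",
                         format(tmp[[j]], digits = 17, scientific = FALSE,
                                trim = TRUE))
  write.csv(tmp, path, row.names = FALSE, quote = FALSE, na = ".")
  invisible(path)
}

#' Linear interpolation of a time-varying covariate
#'
#' Linearly interpolates between the two quantified values bracketing
#' `query_time`; before the first or after the last quantified value the
#' nearest value is carried.
#'
#' @param covariates covariate data frame with a `time` column
#' @param name covariate column name
#' @param query_time time (h) at which the value is needed
#' @return interpolated value(s); `NA` (with a warning) when the
#'   covariate was never quantified
#' @export
interpolate_covariate <- function(covariates, name, query_time) {
  if (is.null(covariates) || !name %in% names(covariates)) {
    warning("covariate '", name, "' never quantified")
    return(rep(NA_real_, length(query_time)))
  }
  ok <- !is.na(covariates[[name]])
  if (!any(ok)) {
    warning("covariate '", name, "' never quantified")
    return(rep(NA_real_, length(query_time)))
  }
  x <- covariates$time[ok]
  y <- covariates[[name]][ok]
  if (length(x) == 1) return(rep(y, length(query_time)))
  approx(x, y, xout = query_time, rule = 2, ties = "ordered")$y
}

#' Dichotomize a laboratory value at twice its upper limit of normal
#'
#' @param value measured value
#' @param upper_limit_normal the analyte's upper limit of normal (> 0)
#' @return 1 when `value > 2 * upper_limit_normal`, else 0
#' @export
dichotomize_lab <- function(value, upper_limit_normal) {
  if (any(upper_limit_normal <= 0)) stop("upper_limit_normal must be > 0")
  as.integer(value > 2 * upper_limit_normal)
}
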