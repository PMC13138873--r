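# Seeded end-to-end pipeline tying the analysis stages together.

# deterministic per-stage seed derived from the global seed and stage name
.stage_seed <- function(global_seed, stage) {
  codes <- utf8ToInt(stage)
  (global_seed + sum(codes * seq_along(codes) * 131L)) %% 2147483647L
}

#' Default pipeline configuration
#'
#' @param seed global seed; each stage derives its own stream from it
#' @param out_dir output directory (created if needed)
#' @param n_subjects synthetic cohort size for the estimation stages
#' @param n_virtual virtual cohort size for the TDM study
#' @param stages subset of the pipeline to run
#' @return a config list accepted by [run_pipeline()]
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("isatdm_run_"),
                            n_subjects = 41, n_virtual = 10000,
                            stages = c("simulate_cohort", "fit", "evaluate",
                                       "bayes_exposure", "pkpd",
                                       "virtual_tdm")) {
  list(seed = as.integer(seed), out_dir = out_dir,
       n_subjects = n_subjects, n_virtual = n_virtual, stages = stages)
}

#' Run the analysis pipeline
#'
#' Executes, in order, the requested subset of: synthetic-cohort
#' generation, population fit, model evaluation (pcVPC and log-scale
#' prediction-error metrics), MAP-Bayes exposure derivation, exploratory
#' exposure-response regression, and the virtual TDM study. Every stage
#' draws its randomness from a seed derived deterministically from the
#' global seed and the stage name, so stages are independently
#' reproducible; outputs (CSV/JSON) carry the seed in a metadata file.
#'
#' @param config a [pipeline_config()] list or path to a YAML file with
#'   the same fields
#' @return named list of stage results, invisibly; files are written to
#'   `config$out_dir`
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("seed", "out_dir", "stages"))
    if (is.null(config[[field]]))
      stop("pipeline config validation error: missing block '", field, "'")
  if (is.null(config$n_subjects)) config$n_subjects <- 41
  if (is.null(config$n_virtual)) config$n_virtual <- 10000
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  pop <- isa_final_model()

  run_stage <- function(stage, fun) {
    if (!stage %in% config$stages) return(NULL)
    set.seed(.stage_seed(config$seed, stage))
    tryCatch(fun(), error = function(e)
      stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  res$cohort <- run_stage("simulate_cohort", function() {
    g <- generate_cohort(cohort_spec(n_subjects = config$n_subjects))
    g$outcomes <- generate_outcomes(g$truth)
    write_dataset(g$subjects, file.path(config$out_dir, "cohort.csv"))
    write.csv(g$truth, file.path(config$out_dir, "truth.csv"),
              row.names = FALSE)
    write.csv(g$outcomes, file.path(config$out_dir, "outcomes.csv"),
              row.names = FALSE)
    g
  })

  res$fit <- run_stage("fit", function() {
    if (is.null(res$cohort)) stop("fit requires the simulate_cohort stage")
    f <- fit_poppk(res$cohort$subjects, start = isa_final_model(),
                   fixed = "ka")
    jsonlite::write_json(
      list(ofv = f$ofv, estimates = as.list(f$estimates),
           rse_pct = as.list(round(f$rse, 1)),
           shrinkage_pct = as.list(round(f$shrinkage, 1)),
           converged = f$converged),
      file.path(config$out_dir, "fit.json"), auto_unbox = TRUE,
      digits = NA)
    f
  })

  res$evaluate <- run_stage("evaluate", function() {
    if (is.null(res$fit)) stop("evaluate requires the fit stage")
    cw <- res$fit$cwres
    metrics <- list(mpe = mpe(cw$dv, pmax(cw$ipred, 1e-6)),
                    rmse = rmse(cw$dv, pmax(cw$ipred, 1e-6)))
    vpc <- pcvpc(res$cohort$subjects, res$fit$pop, n_sim = 200,
                 seed = .stage_seed(config$seed, "evaluate_vpc"))
    write.csv(vpc$table, file.path(config$out_dir, "pcvpc.csv"),
              row.names = FALSE)
    jsonlite::write_json(metrics, file.path(config$out_dir, "metrics.json"),
                         auto_unbox = TRUE, digits = NA)
    list(metrics = metrics, vpc = vpc)
  })

  res$bayes_exposure <- run_stage("bayes_exposure", function() {
    if (is.null(res$cohort))
      stop("bayes_exposure requires the simulate_cohort stage")
    tab <- exposure_table(res$cohort$subjects, pop)
    write.csv(tab, file.path(config$out_dir, "exposure.csv"),
              row.names = FALSE)
    tab
  })

  res$pkpd <- run_stage("pkpd", function() {
    if (is.null(res$bayes_exposure))
      stop("pkpd requires the bayes_exposure stage")
    rec <- merge(res$bayes_exposure, res$cohort$outcomes, by = "id")
    fit <- fit_exposure_outcome(rec, "cmin", "success")
    jsonlite::write_json(
      list(intercept = fit$intercept, slope = fit$slope,
           p_value = fit$p_value, n = fit$n, separated = fit$separated),
      file.path(config$out_dir, "pkpd.json"), auto_unbox = TRUE,
      digits = NA)
    fit
  })

  res$virtual_tdm <- run_stage("virtual_tdm", function() {
    study <- virtual_tdm_study(n = config$n_virtual, pop = pop,
                               seed = .stage_seed(config$seed,
                                                  "virtual_tdm"))
    write.csv(study$results, file.path(config$out_dir, "tdm_results.csv"),
              row.names = FALSE)
    write.csv(study$cohort, file.path(config$out_dir, "tdm_cohort.csv"),
              row.names = FALSE)
    study
  })

  jsonlite::write_json(
    list(seed = config$seed, stages = config$stages,
         n_subjects = config$n_subjects, n_virtual = config$n_virtual,
         timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    file.path(config$out_dir, "run_metadata.json"), auto_unbox = TRUE)
  invisible(res)
}
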