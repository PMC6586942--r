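#' Run the complete evaluation pipeline
#'
#' One-call replication of the full analysis on a cohort table: clock
#' predictions for every sample, accuracy metrics per model and stratum,
#' model-level and CpG-level age correlations, between-stratum error
#' comparisons, and a machine-readable run manifest. All outputs are
#' written atomically (staged in a temporary directory, then moved), so an
#' aborted run leaves no partial tables.
#'
#' Files written to `out_dir`:
#' \describe{
#'   \item{`predictions.csv`}{per-sample: `sample_id`, `age`, `gender`,
#'     `age_group`, one predicted-age column per model.}
#'   \item{`accuracy.csv`}{one row per (model, stratum) with r, r^2, MAD,
#'     SEE, PCP at each threshold, mean/median signed error.}
#'   \item{`model_corr.csv`}{predicted-vs-chronological r and r^2 per model
#'     and stratum.}
#'   \item{`cpg_corr.csv`}{per-CpG age correlations.}
#'   \item{`group_tests.csv`}{pooled-variance t-tests on signed errors
#'     between age groups and genders.}
#'   \item{`manifest.json`}{seed, package and R versions, input hash,
#'     configuration, exclusion and warning counts.}
#' }
#'
#' @param cohort A [cohort_table] or path to a cohort file
#'   ([read_cohort()]).
#' @param out_dir Output directory (created if needed).
#' @param models Model selection, see [resolve_models()].
#' @param config An [eval_config()].
#' @param seed Integer recorded in the manifest (the pipeline itself is
#'   deterministic; the seed matters when `cohort` was simulated).
#' @return Invisibly, a list with the five report tibbles, the manifest
#'   list and `out_dir`.
#' @export
run_full_analysis <- function(cohort, out_dir, models = "all",
                              config = eval_config(), seed = NA_integer_) {
  t0 <- Sys.time()
  cohort_path <- NA_character_
  if (is.character(cohort)) {
    cohort_path <- cohort
    if (!file.exists(cohort)) stop("[cohort_io] cohort file not found: ",
                                   cohort)
    cohort <- read_cohort(cohort)
  }
  stopifnot(inherits(cohort, "cohort_table"))
  models <- resolve_models(models)

  validation <- validate_cohort(cohort, models)
  predictions <- predict_cohort(cohort, models)
  accuracy <- evaluate_models(predictions, cohort$samples, config)
  model_corr <- accuracy[, c("model", "stratum", "n", "r", "r_squared")]
  cpg_corr <- cpg_correlation_table(cohort)
  group_tests <- group_difference_stats(predictions, cohort$samples)

  wide <- tidyr::pivot_wider(
    predictions[, c("sample_id", "model", "predicted_age")],
    names_from = "model", values_from = "predicted_age")
  pred_table <- dplyr::left_join(
    cohort$samples[, c("sample_id", "age", "gender", "age_group")],
    wide, by = "sample_id")

  manifest <- list(
    seed = seed,
    generated = format(t0, "%Y-%m-%d %H:%M:%S %Z"),
    package_version = as.character(utils::packageVersion("pyroage")),
    r_version = R.version.string,
    cohort_file = cohort_path,
    cohort_md5 = if (!is.na(cohort_path))
      unname(tools::md5sum(cohort_path)) else NA_character_,
    n_samples = nrow(cohort$samples),
    n_cpgs = ncol(cohort$methylation),
    models = names(models),
    thresholds = config$thresholds,
    see_denominator = config$see_denominator,
    strata = config$strata,
    n_ingestion_issues = nrow(cohort$issues),
    n_validation_issues = nrow(validation),
    n_excluded_predictions = sum(predictions$excluded),
    n_negative_predictions = sum(predictions$negative, na.rm = TRUE)
  )

  stage <- tempfile("pyroage-run-")
  dir.create(stage)
  on.exit(unlink(stage, recursive = TRUE), add = TRUE)
  readr::write_csv(pred_table, file.path(stage, "predictions.csv"),
                   na = "NA", progress = FALSE)
  write_report(accuracy, file.path(stage, "accuracy.csv"))
  readr::write_csv(model_corr, file.path(stage, "model_corr.csv"),
                   na = "NA", progress = FALSE)
  readr::write_csv(cpg_corr, file.path(stage, "cpg_corr.csv"), na = "NA",
                   progress = FALSE)
  readr::write_csv(group_tests, file.path(stage, "group_tests.csv"),
                   na = "NA", progress = FALSE)
  jsonlite::write_json(manifest, file.path(stage, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  for (f in list.files(stage)) {
    ok <- file.rename(file.path(stage, f), file.path(out_dir, f))
    if (!ok) ok <- file.copy(file.path(stage, f), file.path(out_dir, f),
                             overwrite = TRUE)
    if (!ok) stop("[cli_app] cannot write output file: ",
                  file.path(out_dir, f))
  }
  invisible(list(predictions = pred_table, accuracy = accuracy,
                 model_corr = model_corr, cpg_corr = cpg_corr,
                 group_tests = group_tests, manifest = manifest,
                 out_dir = out_dir))
}
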