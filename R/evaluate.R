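#' Evaluation configuration
#'
#' @param thresholds Strictly positive, sorted error tolerances in years for
#'   the percentage of correct predictions (default 5, 7.5, 10).
#' @param see_denominator `"n"` (RMSE form, default) or `"n_minus_2"`; see
#'   [see_error()].
#' @param strata Strata to report: any of `"All"`, `"Men"`, `"Women"`,
#'   `"I"`, `"II"`, `"III"`.
#' @param min_n Smallest stratum size for which a correlation is reported
#'   (default 3); smaller strata keep their error metrics but get `NA` for
#'   `r` with a warning.
#' @return A list of class `eval_config`.
#' @export
eval_config <- function(thresholds = c(5, 7.5, 10),
                        see_denominator = c("n", "n_minus_2"),
                        strata = c("All", "Men", "Women", "I", "II", "III"),
                        min_n = 3L) {
  see_denominator <- match.arg(see_denominator)
  stopifnot(
    is.numeric(thresholds), length(thresholds) > 0,
    all(thresholds > 0), !is.unsorted(thresholds, strictly = TRUE),
    all(strata %in% c("All", "Men", "Women", "I", "II", "III")),
    min_n >= 1
  )
  structure(list(thresholds = thresholds, see_denominator = see_denominator,
                 strata = strata, min_n = as.integer(min_n)),
            class = "eval_config")
}

# logical membership of each meta row in a named stratum
stratum_mask <- function(meta, stratum) {
  switch(stratum,
    All = rep(TRUE, nrow(meta)),
    Men = meta$gender == "M",
    Women = meta$gender == "F",
    I = meta$age_group == "I",
    II = meta$age_group == "II",
    III = meta$age_group == "III",
    stop("unknown stratum: ", stratum)
  )
}

#' Evaluate clock predictions against chronological age
#'
#' Joins per-sample predictions (see [predict_cohort()]) to sample metadata
#' and computes, for every model and stratum: Pearson r and r^2 between
#' predicted and chronological age, MAD, SEE, the percentage of correct
#' predictions at each threshold, and the mean and median signed error
#' (predicted minus chronological). Samples excluded from a model are
#' excluded from all of that model's metrics; the count is reported.
#'
#' @param predictions Tibble from [predict_cohort()].
#' @param meta Sample metadata: the `samples` element of a [cohort_table]
#'   (or any data frame with `sample_id`, `age`, `gender`, `age_group`).
#' @param config An [eval_config()].
#' @return Tibble with one row per (model, stratum): columns `model`,
#'   `stratum`, `n`, `n_excluded`, `r`, `r_squared`, `mad`, `see`, one
#'   `pcp_<threshold>` column per threshold, `mean_error`, `median_error`.
#' @export
evaluate_models <- function(predictions, meta, config = eval_config()) {
  stopifnot(inherits(config, "eval_config"))
  meta <- tibble::as_tibble(meta)
  if (is.null(meta[["age_group"]])) meta$age_group <- assign_age_group(meta$age)
  joined <- dplyr::inner_join(predictions, meta, by = "sample_id")
  if (nrow(joined) == 0) stop("no predictions join to the sample metadata")
  pcp_cols <- paste0("pcp_", config$thresholds)
  rows <- list()
  for (model in unique(predictions$model)) {
    pm <- joined[joined$model == model, ]
    for (stratum in config$strata) {
      keep <- stratum_mask(pm, stratum)
      sub <- pm[keep, ]
      used <- sub[!sub$excluded & !is.na(sub$predicted_age), ]
      n <- nrow(used)
      row <- tibble::tibble(model = model, stratum = stratum, n = n,
                            n_excluded = nrow(sub) - n)
      if (n == 0) {
        row[c("r", "r_squared", "mad", "see", pcp_cols,
              "mean_error", "median_error")] <- NA_real_
        rows <- c(rows, list(row))
        next
      }
      err <- used$predicted_age - used$age
      r <- NA_real_
      if (n >= config$min_n && stats::sd(used$predicted_age) > 0 &&
          stats::sd(used$age) > 0) {
        r <- pearson_r(used$predicted_age, used$age)
      } else {
        warning("stratum ", stratum, " for model ", model,
                ": n = ", n, " below min_n or degenerate; r not reported")
      }
      row$r <- r
      row$r_squared <- r^2
      row$mad <- mad_error(used$predicted_age, used$age)
      row$see <- see_error(used$predicted_age, used$age,
                           config$see_denominator)
      for (i in seq_along(config$thresholds)) {
        row[[pcp_cols[i]]] <- pcp(used$predicted_age, used$age,
                                  config$thresholds[i])
      }
      row$mean_error <- mean(err)
      row$median_error <- stats::median(err)
      rows <- c(rows, list(row))
    }
  }
  dplyr::bind_rows(rows)
}

#' Per-CpG correlation with chronological age
#'
#' Pearson correlation (and r^2) between each CpG's percent methylation and
#' chronological age, for the requested strata, with a flag for the 16 CpGs
#' used by the built-in clocks. A constant methylation column yields `NA`
#' with `undefined = TRUE` rather than an error.
#'
#' @param table A [cohort_table].
#' @param strata Character vector of stratum names (default All/Men/Women).
#' @return Tibble with columns `gene`, `index`, `cpg`, `stratum`, `n`, `r`,
#'   `r_squared`, `in_model`, `undefined`.
#' @export
cpg_correlation_table <- function(table, strata = c("All", "Men", "Women")) {
  stopifnot(inherits(table, "cohort_table"))
  meta <- table$samples
  cpgs <- colnames(table$methylation)
  info <- parse_cpg_label(cpgs)
  in_model <- cpgs %in% model_cpg_labels()
  rows <- list()
  for (stratum in strata) {
    keep <- stratum_mask(meta, stratum)
    if (sum(keep) < 3) {
      stop("stratum ", stratum, " has fewer than 3 samples")
    }
    age <- meta$age[keep]
    sub <- table$methylation[keep, , drop = FALSE]
    for (j in seq_along(cpgs)) {
      v <- sub[, j]
      ok <- !is.na(v)
      undefined <- sum(ok) < 3 || stats::sd(v[ok]) == 0 ||
        stats::sd(age[ok]) == 0
      r <- if (undefined) NA_real_ else pearson_r(v, age)
      rows <- c(rows, list(tibble::tibble(
        gene = info$gene[j], index = info$index[j], cpg = cpgs[j],
        stratum = stratum, n = sum(ok), r = r, r_squared = r^2,
        in_model = in_model[j], undefined = undefined
      )))
    }
  }
  dplyr::bind_rows(rows)
}

#' Mean absolute correlation over a CpG subset
#'
#' Arithmetic mean of |r| over all panel CpGs or over the 16 clock CpGs,
#' within one stratum of a [cpg_correlation_table()] result.
#'
#' @param rows Output of [cpg_correlation_table()].
#' @param subset `"all"` or `"model_cpgs"`.
#' @param stratum Stratum to average over (default `"All"`).
#' @return Mean absolute Pearson r (single number).
#' @export
mean_absolute_r <- function(rows, subset = c("all", "model_cpgs"),
                            stratum = "All") {
  subset <- match.arg(subset)
  sel <- rows[rows$stratum == stratum & !rows$undefined, ]
  if (subset == "model_cpgs") sel <- sel[sel$in_model, ]
  if (nrow(sel) == 0) stop("no defined correlations in the requested subset")
  mean(abs(sel$r))
}

#' Between-stratum comparison of prediction errors
#'
#' Two-sample two-sided Student t-tests (pooled variance) on signed
#' prediction errors, per model, for each requested stratum pair, plus the
#' per-stratum mean and median signed error. P-values are reported raw;
#' `bonferroni = TRUE` adds an adjusted column (correction across all pairs
#' within a model).
#'
#' @param predictions Tibble from [predict_cohort()].
#' @param meta Sample metadata (as in [evaluate_models()]).
#' @param pairs List of length-2 character vectors of stratum names; default
#'   the three age-group pairs plus Men vs Women.
#' @param bonferroni Add a Bonferroni-adjusted p-value column?
#' @return Tibble with columns `model`, `stratum_a`, `stratum_b`, `n_a`,
#'   `n_b`, `mean_error_a`, `mean_error_b`, `median_error_a`,
#'   `median_error_b`, `mean_diff`, `t`, `p_value` (and `p_bonferroni`),
#'   `degenerate` (TRUE when both strata had zero error variance).
#' @export
group_difference_stats <- function(predictions, meta,
                                   pairs = list(c("I", "II"), c("I", "III"),
                                                c("II", "III"),
                                                c("Men", "Women")),
                                   bonferroni = FALSE) {
  meta <- tibble::as_tibble(meta)
  if (is.null(meta[["age_group"]])) meta$age_group <- assign_age_group(meta$age)
  joined <- dplyr::inner_join(predictions, meta, by = "sample_id")
  joined <- joined[!joined$excluded & !is.na(joined$predicted_age), ]
  rows <- list()
  for (model in unique(predictions$model)) {
    pm <- joined[joined$model == model, ]
    pm$error <- pm$predicted_age - pm$age
    for (pair in pairs) {
      ea <- pm$error[stratum_mask(pm, pair[1])]
      eb <- pm$error[stratum_mask(pm, pair[2])]
      if (length(ea) < 2 || length(eb) < 2) {
        stop("stratum pair ", pair[1], "-", pair[2], " for model ", model,
             " needs at least 2 samples per stratum")
      }
      degenerate <- stats::sd(ea) == 0 && stats::sd(eb) == 0
      if (degenerate) {
        d <- mean(ea) - mean(eb)
        t_stat <- if (d == 0) 0 else sign(d) * Inf
        p <- if (d == 0) 1 else 0
      } else {
        ht <- stats::t.test(ea, eb, var.equal = TRUE)
        t_stat <- unname(ht$statistic)
        p <- ht$p.value
      }
      rows <- c(rows, list(tibble::tibble(
        model = model, stratum_a = pair[1], stratum_b = pair[2],
        n_a = length(ea), n_b = length(eb),
        mean_error_a = mean(ea), mean_error_b = mean(eb),
        median_error_a = stats::median(ea),
        median_error_b = stats::median(eb),
        mean_diff = mean(ea) - mean(eb), t = t_stat, p_value = p,
        degenerate = degenerate
      )))
    }
  }
  out <- dplyr::bind_rows(rows)
  if (bonferroni) {
    out <- dplyr::mutate(out,
      p_bonferroni = stats::p.adjust(.data$p_value, "bonferroni"),
      .after = "p_value")
  }
  out
}

#' Write / read an evaluation report
#'
#' CSV reports carry one row per (model, stratum) with all metric columns at
#' full precision; JSON mirrors the same records. A write-then-read round
#' trip reproduces every numeric value exactly.
#'
#' @param report Tibble from [evaluate_models()].
#' @param path Output path.
#' @param format `"csv"` or `"json"` (default guessed from the extension).
#' @return `path` invisibly (`write_report`); the report tibble
#'   (`read_report`).
#' @export
write_report <- function(report, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  }
  stopifnot(is.data.frame(report), nrow(report) > 0)
  if (format == "csv") {
    readr::write_csv(tibble::as_tibble(report), path, na = "NA",
                     progress = FALSE)
  } else {
    jsonlite::write_json(report, path, dataframe = "rows", digits = I(17),
                         na = "null", pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "json") "json" else "csv"
  }
  if (format == "csv") {
    # read as text and convert with R's own (correctly rounded) parser so
    # the write/read round trip is bit-exact
    out <- readr::read_csv(path, col_types = readr::cols(.default = "c"),
                           progress = FALSE)
    out[] <- lapply(out, function(col) {
      utils::type.convert(col, as.is = TRUE, na.strings = "NA")
    })
  } else {
    out <- tibble::as_tibble(jsonlite::fromJSON(path))
  }
  for (col in intersect(names(out), c("n", "n_excluded"))) {
    out[[col]] <- as.integer(out[[col]])
  }
  out
}
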