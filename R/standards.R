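#' DNA methylation standard series
#'
#' Observations of one pyrosequencing assay on control DNA of known
#' methylation level (0, 25, 50, 75 and 100%). A complete series has at
#' least one observation per expected level; replicates are allowed.
#'
#' @param cpg CpG label (`GENE_CpGk`).
#' @param expected Expected levels, each in \{0, 25, 50, 75, 100\}.
#' @param observed Observed percent methylation, in [0, 100].
#' @param replicate Replicate identifiers (recycled).
#' @return Object of class `standard_series`.
#' @export
standard_series <- function(cpg, expected, observed, replicate = 1L) {
  parse_cpg_label(cpg)
  stopifnot(length(expected) == length(observed),
            all(expected %in% c(0, 25, 50, 75, 100)),
            all(observed >= 0 & observed <= 100))
  structure(
    list(cpg = cpg,
         observations = tibble::tibble(
           expected = as.numeric(expected), observed = as.numeric(observed),
           replicate = rep_len(replicate, length(expected)))),
    class = "standard_series"
  )
}

#' Read standard series from CSV
#'
#' Expects columns `cpg`, `expected_level`, `observed` and optionally
#' `replicate`.
#'
#' @param path CSV file path.
#' @return Named list of [standard_series], one per CpG.
#' @export
read_standards <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  stopifnot(all(c("cpg", "expected_level", "observed") %in% names(df)))
  if (is.null(df[["replicate"]])) df$replicate <- 1L
  out <- lapply(split(df, df$cpg), function(d) {
    standard_series(d$cpg[1], d$expected_level, d$observed, d$replicate)
  })
  out[order(names(out))]
}

#' Assess an assay against methylation standards
#'
#' Quantifies PCR amplification bias of a pyrosequencing assay from its
#' standard series: per-level mean deviation (observed minus expected), the
#' least-squares line of observed on expected, and a bias class driven by
#' the mean deviation over the intermediate levels (25/50/75) only, because
#' the 0% and 100% standards sit near their expected values even for
#' strongly biased assays. With mean intermediate deviation `d`:
#' `|d| <= slight_cut` is `none`; negative `d` beyond `strong_cut` is
#' `strong_unmethylated` (preferential amplification of the unmethylated
#' allele), in between `slight_unmethylated`; positive `d` analogously
#' `slight_methylated` / `strong_methylated`.
#'
#' @param series A [standard_series].
#' @param slight_cut,strong_cut Class boundaries in percentage points
#'   (defaults 5 and 20).
#' @return List of class `bias_report`: `cpg`, `level_deviation` (tibble
#'   with `expected`, `mean_observed`, `deviation`), `slope`, `intercept`,
#'   `intermediate_deviation`, `bias_class`.
#' @export
assess_standards <- function(series, slight_cut = 5, strong_cut = 20) {
  stopifnot(inherits(series, "standard_series"), slight_cut < strong_cut)
  obs <- series$observations
  missing_levels <- setdiff(c(0, 25, 50, 75, 100), unique(obs$expected))
  if (length(missing_levels) > 0) {
    stop("incomplete standard series for ", series$cpg, ": no observation ",
         "at level(s) ", paste(missing_levels, collapse = ", "))
  }
  level_means <- vapply(split(obs$observed, obs$expected), mean, 0)
  levels <- as.numeric(names(level_means))
  dev <- tibble::tibble(expected = levels,
                        mean_observed = unname(level_means),
                        deviation = unname(level_means) - levels)
  fit <- stats::lm(observed ~ expected, data = obs)
  d <- mean(dev$deviation[dev$expected %in% c(25, 50, 75)])
  bias_class <- if (abs(d) <= slight_cut) {
    "none"
  } else if (d < 0) {
    if (abs(d) > strong_cut) "strong_unmethylated" else "slight_unmethylated"
  } else {
    if (abs(d) > strong_cut) "strong_methylated" else "slight_methylated"
  }
  structure(
    list(cpg = series$cpg, level_deviation = dev,
         slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         intermediate_deviation = d, bias_class = bias_class),
    class = "bias_report"
  )
}

#' @export
print.bias_report <- function(x, ...) {
  cat("<bias_report>", x$cpg, "- class:", x$bias_class, "\n")
  cat(sprintf("  observed = %.3f + %.4f * expected; mean intermediate deviation %.2f\n",
              x$intercept, x$slope, x$intermediate_deviation))
  invisible(x)
}

#' Simulate a standard series
#'
#' Generates observations at the five standard levels under a bias
#' scenario: `none` reproduces the expected level plus noise; `slight`
#' shifts the intermediate levels down by 5 points (a mild preference for
#' the unmethylated allele); `strong_unmethylated` collapses the
#' intermediate levels towards 0 (observed base profile 0, 2, 3, 5, 95),
#' the signature of a severely biased assay. Values are clamped to
#' [0, 100].
#'
#' @param cpg CpG label.
#' @param bias `"none"`, `"slight"` or `"strong_unmethylated"`.
#' @param noise_sd Gaussian measurement noise sd, percentage points.
#' @param seed Integer seed (local RNG, does not disturb the global state).
#' @param replicates Observations per level.
#' @return A [standard_series].
#' @export
generate_standards <- function(cpg,
                               bias = c("none", "slight",
                                        "strong_unmethylated"),
                               noise_sd = 0, seed = 1L, replicates = 1L) {
  bias <- match.arg(bias)
  expected <- rep(c(0, 25, 50, 75, 100), each = replicates)
  base <- switch(bias,
    none = expected,
    slight = ifelse(expected %in% c(25, 50, 75), expected - 5, expected),
    strong_unmethylated = rep(c(0, 2, 3, 5, 95), each = replicates)
  )
  observed <- with_local_seed(seed, base + stats::rnorm(length(base), 0,
                                                        noise_sd))
  standard_series(cpg, expected, pmin(100, pmax(0, observed)),
                  replicate = rep(seq_len(replicates), times = 5))
}

#' Compare PCR-cycle replicate conditions
#'
#' Paired comparison of percent methylation measured on the same DNA under
#' two amplification conditions (e.g. 45 vs 50 PCR cycles), across the CpGs
#' of an assay panel: per-CpG difference, mean difference, and a paired
#' two-sided Student t-test. When every per-CpG difference is identical the
#' t-test is degenerate and flagged as such (zero-variance differences;
#' `p = 1` if the common difference is 0, else `p = 0`).
#'
#' @param values_a,values_b Named numeric vectors (names = CpG labels) of
#'   observed percent methylation under each condition; the CpG sets must
#'   match and contain at least 2 CpGs.
#' @param label_a,label_b Condition labels.
#' @param alpha Significance level for the `significant` flag.
#' @return List of class `replicate_comparison`: `per_cpg` (tibble with
#'   `cpg`, values, `difference`), `mean_difference`, `t`, `p_value`,
#'   `significant`, `degenerate`, condition labels.
#' @export
compare_cycle_replicates <- function(values_a, values_b,
                                     label_a = "45 cycles",
                                     label_b = "50 cycles", alpha = 0.05) {
  if (is.null(names(values_a)) || is.null(names(values_b))) {
    stop("replicate values must be named by CpG label")
  }
  unpaired <- c(setdiff(names(values_a), names(values_b)),
                setdiff(names(values_b), names(values_a)))
  if (length(unpaired) > 0) {
    stop("unpaired CpG(s): ", paste(unique(unpaired), collapse = ", "))
  }
  if (length(values_a) < 2) stop("need at least 2 paired CpGs")
  values_b <- values_b[names(values_a)]
  diffs <- values_a - values_b
  degenerate <- stats::sd(diffs) == 0
  if (degenerate) {
    t_stat <- if (mean(diffs) == 0) 0 else sign(mean(diffs)) * Inf
    p <- if (mean(diffs) == 0) 1 else 0
  } else {
    ht <- stats::t.test(values_a, values_b, paired = TRUE)
    t_stat <- unname(ht$statistic)
    p <- ht$p.value
  }
  structure(
    list(per_cpg = tibble::tibble(cpg = names(values_a),
                                  value_a = unname(values_a),
                                  value_b = unname(values_b),
                                  difference = unname(diffs)),
         label_a = label_a, label_b = label_b,
         mean_difference = mean(diffs), t = t_stat, p_value = p,
         significant = p < alpha, degenerate = degenerate),
    class = "replicate_comparison"
  )
}

#' @export
print.replicate_comparison <- function(x, ...) {
  cat("<replicate_comparison>", x$label_a, "vs", x$label_b, "over",
      nrow(x$per_cpg), "CpGs\n")
  cat(sprintf("  mean difference %.3f; paired t = %.3f, p = %.4g%s%s\n",
              x$mean_difference, x$t, x$p_value,
              if (x$significant) " (significant)" else " (not significant)",
              if (x$degenerate) " [degenerate: zero-variance differences]"
              else ""))
  invisible(x)
}

#' Effect of duplicate measurement averaging on prediction accuracy
#'
#' Given two replicate measurements of the same cohort, computes clock
#' predictions from each replicate and from the element-wise mean of the
#' duplicates, and evaluates all three on the full cohort (All stratum).
#' Averaging independent measurement noise shrinks its sd by sqrt(2), so
#' the mean-of-duplicates evaluation is expected to outperform either
#' single replicate.
#'
#' @param rep1,rep2 [cohort_table] objects covering the same samples and
#'   the model's required CpGs; samples present in only one replicate are
#'   dropped with a warning.
#' @param model A [clock_model] or built-in model name.
#' @param config An [eval_config()]; only its thresholds and SEE policy are
#'   used (evaluation is on the All stratum).
#' @return Tibble with rows `rep1`, `rep2`, `mean` (column `dataset`) and
#'   the [evaluate_models()] metric columns.
#' @export
duplicate_average_analysis <- function(rep1, rep2, model,
                                       config = eval_config()) {
  stopifnot(inherits(rep1, "cohort_table"), inherits(rep2, "cohort_table"))
  model <- resolve_models(model)[[1]]
  common <- intersect(rep1$samples$sample_id, rep2$samples$sample_id)
  dropped <- c(setdiff(rep1$samples$sample_id, common),
               setdiff(rep2$samples$sample_id, common))
  if (length(dropped) > 0) {
    warning("sample(s) present in one replicate only, dropped: ",
            paste(dropped, collapse = ", "))
  }
  if (length(common) == 0) stop("replicates share no samples")
  need <- model$required_cpgs
  for (nm in c("rep1", "rep2")) {
    tab <- get(nm)
    absent <- setdiff(need, colnames(tab$methylation))
    if (length(absent) > 0) {
      stop(nm, " lacks required CpG(s) for model ", model$name, ": ",
           paste(absent, collapse = ", "))
    }
  }
  sub <- function(tab) {
    idx <- match(common, tab$samples$sample_id)
    t2 <- cohort_table(tab$samples[idx, c("sample_id", "age", "gender")],
                       tab$methylation[idx, need, drop = FALSE])
    t2
  }
  r1 <- sub(rep1)
  r2 <- sub(rep2)
  mean_tab <- cohort_table(r1$samples[, c("sample_id", "age", "gender")],
                           (r1$methylation + r2$methylation) / 2)
  cfg <- eval_config(thresholds = config$thresholds,
                     see_denominator = config$see_denominator,
                     strata = "All", min_n = config$min_n)
  one <- function(tab, label) {
    rep <- evaluate_models(predict_cohort(tab, model), tab$samples, cfg)
    dplyr::bind_cols(tibble::tibble(dataset = label), rep)
  }
  dplyr::bind_rows(one(r1, "rep1"), one(r2, "rep2"), one(mean_tab, "mean"))
}
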