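test_that("a perfect predictor scores perfectly in every stratum", {
  tab <- linear_cohort(n = 20)
  preds <- tibble::tibble(
    sample_id = tab$samples$sample_id, model = "oracle",
    predicted_age = tab$samples$age, excluded = FALSE,
    reason = NA_character_)
  rep <- evaluate_models(preds, tab$samples)
  all_row <- rep[rep$stratum == "All", ]
  expect_equal(all_row$r, 1)
  expect_equal(all_row$mad, 0)
  expect_equal(all_row$see, 0)
  expect_equal(all_row$pcp_5, 100)
  expect_equal(all_row$mean_error, 0)
})

test_that("report layout is models x strata with consistent stratum sizes", {
  tab <- simulate_cohort(seed = 11)
  preds <- predict_cohort(tab)
  rep <- evaluate_models(preds, tab$samples)
  expect_equal(nrow(rep), 36)
  expect_equal(unique(rep$stratum),
               c("All", "Men", "Women", "I", "II", "III"))
  for (m in unique(rep$model)) {
    rm_ <- rep[rep$model == m, ]
    n_all <- rm_$n[rm_$stratum == "All"]
    expect_equal(sum(rm_$n[rm_$stratum %in% c("I", "II", "III")]), n_all)
    expect_equal(sum(rm_$n[rm_$stratum %in% c("Men", "Women")]), n_all)
    # PCP non-decreasing in threshold, row-wise
    expect_true(all(rm_$pcp_5 <= rm_$pcp_7.5 & rm_$pcp_7.5 <= rm_$pcp_10))
    expect_true(all(rm_$mad <= rm_$see))
  }
  expect_equal(rep$r_squared, rep$r^2)
})

test_that("evaluation is invariant under permutation of sample order", {
  tab <- simulate_cohort(cohort_design(n_groups = c(10L, 10L, 10L),
                                       seed = 12), seed = 13)
  preds <- predict_cohort(tab)
  rep1 <- evaluate_models(preds, tab$samples)
  perm <- withr::with_seed(1, sample(nrow(preds)))
  rep2 <- evaluate_models(preds[perm, ], tab$samples)
  expect_equal(dplyr::arrange(rep1, model, stratum),
               dplyr::arrange(rep2, model, stratum))
})

test_that("samples excluded from a model drop out of its metrics", {
  tab <- linear_cohort(n = 10)
  meth <- tab$methylation
  meth[1:2, "ELOVL2_CpG6"] <- NA
  tab2 <- cohort_table(tab$samples[, c("sample_id", "age", "gender")], meth)
  # the shrunken group-I stratum triggers the documented small-n warning
  rep <- suppressWarnings(evaluate_models(predict_cohort(tab2),
                                          tab2$samples))
  bek <- rep[rep$model == "Bekaert" & rep$stratum == "All", ]
  expect_equal(bek$n, 8)
  expect_equal(bek$n_excluded, 2)
  park <- rep[rep$model == "Park" & rep$stratum == "All", ]
  expect_equal(park$n, 10)
})

test_that("per-CpG correlation table flags model CpGs and degenerate columns", {
  tab <- simulate_cohort(seed = 14)
  cc <- cpg_correlation_table(tab)
  expect_equal(nrow(cc), 156)           # 52 CpGs x 3 strata
  expect_equal(sum(cc$in_model), 48)    # 16 per stratum

  # a noise-free CpG is exactly linear in age
  meta <- tab$samples
  params <- default_cpg_params(c("ELOVL2_CpG6", "ASPA_CpG1"))
  params$noise_sd <- 0
  lin <- generate_methylation(meta, params, seed = 1)
  cl <- cpg_correlation_table(lin, strata = "All")
  expect_equal(cl$r[cl$cpg == "ELOVL2_CpG6"], 1)
  expect_equal(cl$r[cl$cpg == "ASPA_CpG1"], -1)

  # constant column: undefined flag, no error
  const <- cohort_table(
    meta[, c("sample_id", "age", "gender")],
    matrix(50, nrow(meta), 1, dimnames = list(NULL, "KLF14_CpG1")))
  ccst <- cpg_correlation_table(const, strata = "All")
  expect_true(ccst$undefined)
  expect_true(is.na(ccst$r))
})

test_that("mean_absolute_r averages |r| over the requested subset", {
  rows <- tibble::tibble(
    gene = c("ELOVL2", "ASPA", "KLF14"), index = c(6L, 1L, 4L),
    cpg = c("ELOVL2_CpG6", "ASPA_CpG1", "KLF14_CpG4"), stratum = "All",
    n = 10L, r = c(0.5, -0.5, NA), r_squared = c(0.25, 0.25, NA),
    in_model = c(TRUE, TRUE, FALSE), undefined = c(FALSE, FALSE, TRUE))
  expect_equal(mean_absolute_r(rows), 0.5)
  expect_equal(mean_absolute_r(rows[2, ]), 0.5)
  expect_equal(mean_absolute_r(rows, "model_cpgs"), 0.5)
  expect_error(mean_absolute_r(rows[3, ]), "no defined correlations")
})

test_that("group comparisons match the pooled-variance t and its symmetries", {
  tab <- simulate_cohort(seed = 15)
  preds <- predict_cohort(tab, "ZbiecPiekarska1")
  gd <- group_difference_stats(preds, tab$samples,
                               pairs = list(c("I", "III")))
  joined <- dplyr::inner_join(preds, tab$samples, by = "sample_id")
  err <- joined$predicted_age - joined$age
  a <- err[joined$age_group == "I"]
  b <- err[joined$age_group == "III"]
  expect_equal(gd$t, oracle_pooled_t(a, b), tolerance = 1e-12)
  expect_equal(gd$mean_diff, mean(a) - mean(b))
  expect_equal(gd$n_a, length(a))

  swapped <- group_difference_stats(preds, tab$samples,
                                    pairs = list(c("III", "I")))
  expect_equal(swapped$t, -gd$t)
  expect_equal(swapped$p_value, gd$p_value)

  # identical error distributions in both strata
  meta <- tibble::tibble(sample_id = sprintf("x%d", 1:8),
                         age = c(20, 25, 30, 33, 51, 56, 61, 64),
                         gender = "M")
  meta$age_group <- assign_age_group(meta$age)
  p0 <- tibble::tibble(sample_id = meta$sample_id, model = "toy",
                       predicted_age = meta$age + c(1, -1, 2, -2,
                                                    1, -1, 2, -2),
                       excluded = FALSE, reason = NA_character_)
  same <- group_difference_stats(p0, meta, pairs = list(c("I", "III")))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  withb <- group_difference_stats(preds, tab$samples, bonferroni = TRUE)
  expect_true(all(withb$p_bonferroni >= withb$p_value))
})

test_that("reports round-trip exactly through CSV and JSON", {
  tab <- simulate_cohort(seed = 16)
  rep <- evaluate_models(predict_cohort(tab), tab$samples)
  for (ext in c(".csv", ".json")) {
    path <- withr::local_tempfile(fileext = ext)
    write_report(rep, path)
    back <- read_report(path)
    expect_equal(nrow(back), 36)
    for (col in names(rep)) {
      expect_identical(back[[col]], rep[[col]], label = paste(ext, col))
    }
  }
  one <- rep[1, ]
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(one, path)
  expect_equal(nrow(read_report(path)), 1)
  expect_error(write_report(rep[0, ], path), "nrow")
})
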