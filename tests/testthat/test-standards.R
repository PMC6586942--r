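test_that("an identity calibration is recognised as unbiased", {
  s <- standard_series("ELOVL2_CpG6", c(0, 25, 50, 75, 100),
                       c(0, 25, 50, 75, 100))
  rep <- assess_standards(s)
  expect_equal(rep$slope, 1, tolerance = 1e-12)
  expect_equal(rep$intercept, 0, tolerance = 1e-12)
  expect_equal(rep$bias_class, "none")
  expect_equal(rep$level_deviation$deviation, rep(0, 5))
})

test_that("a perfectly linear biased assay is recovered to 1e-9", {
  expected <- c(0, 25, 50, 75, 100)
  s <- standard_series("KLF14_CpG1", expected, 2.5 + 0.9 * expected)
  rep <- assess_standards(s)
  expect_equal(rep$slope, 0.9, tolerance = 1e-9)
  expect_equal(rep$intercept, 2.5, tolerance = 1e-9)
})

test_that("bias classes follow the intermediate-level thresholds", {
  expected <- c(0, 25, 50, 75, 100)
  # strongly collapsed intermediate levels
  strong <- standard_series("PDE4C_CpG1", expected, c(0, 2, 3, 5, 95))
  expect_equal(assess_standards(strong)$bias_class, "strong_unmethylated")
  # constant +3 at intermediate levels: inside the default slight_cut
  plus3 <- standard_series("ASPA_CpG1", expected, c(0, 28, 53, 78, 100))
  expect_equal(assess_standards(plus3)$bias_class, "none")
  # tighter slight_cut pushes the same series into slight_methylated
  expect_equal(assess_standards(plus3, slight_cut = 2)$bias_class,
               "slight_methylated")
  minus8 <- standard_series("ASPA_CpG1", expected, c(0, 17, 42, 67, 100))
  expect_equal(assess_standards(minus8)$bias_class, "slight_unmethylated")
  # missing level
  expect_error(
    assess_standards(standard_series("ASPA_CpG1", c(0, 25, 50, 100),
                                     c(0, 25, 50, 100))),
    "incomplete")
})

test_that("classification uses level means: order- and replicate-invariant", {
  expected <- rep(c(0, 25, 50, 75, 100), each = 2)
  observed <- c(0, 0, 20, 24, 44, 48, 70, 72, 99, 100)
  s1 <- assess_standards(standard_series("FHL2_CpG2", expected, observed,
                                         replicate = rep(1:2, 5)))
  shuffle <- withr::with_seed(3, sample(length(expected)))
  s2 <- assess_standards(standard_series("FHL2_CpG2", expected[shuffle],
                                         observed[shuffle]))
  expect_equal(s1$bias_class, s2$bias_class)
  expect_equal(s1$intermediate_deviation, s2$intermediate_deviation)
})

test_that("generated standards round-trip through the classifier", {
  clean <- generate_standards("ELOVL2_CpG6", "none", noise_sd = 0)
  expect_equal(clean$observations$observed, clean$observations$expected)
  expect_equal(assess_standards(clean)$bias_class, "none")
  strong <- generate_standards("PDE4C_CpG1", "strong_unmethylated",
                               noise_sd = 1, seed = 8, replicates = 3)
  expect_equal(assess_standards(strong)$bias_class, "strong_unmethylated")
  slight <- generate_standards("ASPA_CpG1", "slight", noise_sd = 0)
  expect_equal(slight$observations$observed[slight$observations$expected
                                            == 50], 45)
  a <- generate_standards("ASPA_CpG1", "none", noise_sd = 2, seed = 5)
  b <- generate_standards("ASPA_CpG1", "none", noise_sd = 2, seed = 5)
  expect_identical(a$observations, b$observations)
})

test_that("standards CSV files load into per-CpG series", {
  path <- write_cohort_fixture(c(
    "cpg,expected_level,observed,replicate",
    "PDE4C_CpG1,0,0.4,1", "PDE4C_CpG1,25,2.1,1", "PDE4C_CpG1,50,3.0,1",
    "PDE4C_CpG1,75,5.2,1", "PDE4C_CpG1,100,94.8,1",
    "ELOVL2_CpG6,0,0.1,1", "ELOVL2_CpG6,25,24.5,1", "ELOVL2_CpG6,50,49,1",
    "ELOVL2_CpG6,75,74,1", "ELOVL2_CpG6,100,98,1"
  ))
  series <- read_standards(path)
  expect_named(series, c("ELOVL2_CpG6", "PDE4C_CpG1"))
  expect_equal(assess_standards(series$PDE4C_CpG1)$bias_class,
               "strong_unmethylated")
  expect_equal(assess_standards(series$ELOVL2_CpG6)$bias_class, "none")
})

test_that("cycle-replicate comparison handles paired, shifted and degenerate data", {
  withr::with_seed(21, {
    v45 <- stats::setNames(runif(16, 10, 90), model_cpg_labels())
    v50 <- v45 + rnorm(16, 0, 1.5)
  })
  cmp <- compare_cycle_replicates(v45, v50)
  expect_equal(cmp$mean_difference, mean(v45 - v50))
  d <- v45 - v50
  expect_equal(cmp$t, mean(d) / (stats::sd(d) / sqrt(length(d))),
               tolerance = 1e-12)
  expect_false(cmp$degenerate)

  same <- compare_cycle_replicates(v45, v45)
  expect_equal(same$mean_difference, 0)
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  shifted <- compare_cycle_replicates(v45 - 2, v45 - 4)
  expect_equal(shifted$mean_difference, 2)
  expect_true(shifted$degenerate)
  expect_equal(shifted$p_value, 0)

  expect_error(compare_cycle_replicates(v45[1], v45[1] + 1), "at least 2")
  expect_error(compare_cycle_replicates(v45, v50[-3]), "unpaired")
})

test_that("duplicate averaging with identical replicates reproduces a single run", {
  tab <- linear_cohort(n = 10)
  out <- duplicate_average_analysis(tab, tab, "ZbiecPiekarska1")
  expect_equal(out$dataset, c("rep1", "rep2", "mean"))
  metric_cols <- setdiff(names(out), c("dataset", "model", "stratum"))
  expect_equal(out[1, metric_cols], out[3, metric_cols],
               ignore_attr = TRUE)
  expect_equal(out[2, metric_cols], out[3, metric_cols],
               ignore_attr = TRUE)
})

test_that("duplicate averaging drops samples present in one replicate only", {
  tab <- linear_cohort(n = 8)
  sub <- cohort_table(tab$samples[1:6, c("sample_id", "age", "gender")],
                      tab$methylation[1:6, ])
  expect_warning(out <- duplicate_average_analysis(sub, tab,
                                                   "ZbiecPiekarska1"),
                 "dropped")
  expect_equal(unique(out$n), 6L)
})
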