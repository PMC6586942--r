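test_that("cohort metadata sampling honours the design exactly", {
  meta <- sample_cohort_meta(cohort_design(seed = 4))
  expect_equal(nrow(meta), 100)
  expect_equal(as.vector(table(meta$age_group)), c(34L, 33L, 33L))
  expect_equal(sum(meta$gender == "F"), 42)
  expect_equal(sum(meta$gender == "M"), 58)
  expect_true(all(meta$age[meta$age_group == "I"] %in% 19:34))
  expect_true(all(meta$age[meta$age_group == "III"] %in% 50:65))
  expect_true(all(meta$age == round(meta$age)))

  expect_identical(meta, sample_cohort_meta(cohort_design(seed = 4)))
  expect_false(identical(meta, sample_cohort_meta(cohort_design(seed = 5))))

  single <- sample_cohort_meta(cohort_design(n_groups = c(1L, 0L, 0L),
                                             n_female = 1L, n_male = 0L))
  expect_equal(nrow(single), 1)
  expect_true(single$age >= 19 && single$age <= 34)

  expect_error(cohort_design(n_female = 10L, n_male = 10L),
               "do not sum")
  expect_error(cohort_design(age_ranges = list(c(19, 40), c(35, 49),
                                               c(50, 65))),
               "non-overlapping")
})

test_that("noise_for_target_r inverts the linear-model correlation", {
  expect_equal(noise_for_target_r(0.4, 13, 0.5), 0.4 * 13 * sqrt(3))
  expect_equal(noise_for_target_r(-0.4, 13, -0.5), 0.4 * 13 * sqrt(3))
  expect_lt(noise_for_target_r(0.4, 13, 0.9999), 0.1)
  expect_error(noise_for_target_r(0, 13, 0.5), "nonzero")
  expect_error(noise_for_target_r(0.4, 13, 1), "target_r")
  expect_error(noise_for_target_r(0.4, 13, -0.5), "sign")

  # Monte-Carlo oracle: population correlation hits the target
  withr::with_seed(99, {
    n <- 2e5
    age <- rnorm(n, 42, 13)
    sigma <- noise_for_target_r(0.4, 13, 0.862)
    y <- 10 + 0.4 * age + rnorm(n, 0, sigma)
    expect_equal(stats::cor(age, y), 0.862, tolerance = 0.005)
  })
})

test_that("generated methylation has the requested correlation structure", {
  meta <- sample_cohort_meta(cohort_design(seed = 6))
  exact <- default_cpg_params(c("ELOVL2_CpG6", "ASPA_CpG1"))
  exact$noise_sd <- 0
  tab <- generate_methylation(meta, exact, seed = 1)
  expect_equal(abs(stats::cor(tab$methylation[, 1], meta$age)), 1)
  expect_equal(attr(tab, "n_clamped"), 0)

  # same seed, same table; different seed, different noise
  t1 <- generate_methylation(meta, default_cpg_params(), seed = 3)
  t2 <- generate_methylation(meta, default_cpg_params(), seed = 3)
  expect_identical(t1$methylation, t2$methylation)
  t3 <- generate_methylation(meta, default_cpg_params(), seed = 4)
  expect_false(identical(t1$methylation, t3$methylation))

  # flat trajectory with explicit noise: near-zero correlation
  flat <- tibble::tibble(cpg = "KLF14_CpG1", intercept = 50, slope = 0,
                         noise_sd = 4, target_r = NA_real_)
  tf <- generate_methylation(meta, flat, seed = 5)
  expect_lt(abs(stats::cor(tf$methylation[, 1], meta$age)), 0.3)

  # clamping is counted and warned about
  clampy <- tibble::tibble(cpg = "KLF14_CpG1", intercept = 99, slope = 0,
                           noise_sd = 6, target_r = NA_real_)
  expect_warning(tc <- generate_methylation(meta, clampy, seed = 6),
                 "clamped")
  expect_gt(attr(tc, "n_clamped"), 0)

  # a large cohort recovers a single target correlation tightly
  big <- sample_cohort_meta(cohort_design(n_groups = c(1700L, 1650L, 1650L),
                                          seed = 7))
  one <- default_cpg_params("ELOVL2_CpG6")
  tb <- generate_methylation(big, one, seed = 8)
  expect_equal(stats::cor(tb$methylation[, 1], big$age), 0.862,
               tolerance = 0.02)
})

test_that("epigenetic-drift option widens the spread with age", {
  meta <- sample_cohort_meta(cohort_design(n_groups = c(800L, 0L, 800L),
                                           n_female = 672L, n_male = 928L,
                                           seed = 8))
  p <- tibble::tibble(cpg = "FHL2_CpG2", intercept = 50, slope = 0,
                      noise_sd = 5, target_r = NA_real_)
  tab <- generate_methylation(meta, p, seed = 9, drift = 1)
  young <- stats::sd(tab$methylation[meta$age_group == "I", 1])
  old <- stats::sd(tab$methylation[meta$age_group == "III", 1])
  expect_gt(old, young * 1.3)
})

test_that("model-faithful parameters make each clock exact at the anchors", {
  ages <- c(25, 60)
  for (nm in names(builtin_models())) {
    params <- model_faithful_params(nm, age_anchors = ages)
    meta <- tibble::tibble(sample_id = c("a", "b"), age = ages,
                           gender = "M")
    tab <- generate_methylation(meta, params, seed = 1)
    pred <- predict_cohort(tab, nm)
    expect_equal(pred$predicted_age, ages, tolerance = 1e-9,
                 label = paste("anchor fidelity for", nm))
    expect_true(all(tab$methylation >= 0 & tab$methylation <= 100))
  }
})

test_that("model-faithful construction enforces its preconditions", {
  expect_error(model_faithful_params("Bekaert", anchor = "ASPA_CpG1"),
               "ELOVL2_CpG6")
  expect_error(model_faithful_params("Thong", anchor = "ELOVL2_CpG6"),
               "not a CpG of model")
  # pushing the covariates up makes the quadratic argument negative
  bad_base <- tibble::tibble(
    cpg = c("ASPA_CpG1", "EDARADD_CpG1", "PDE4C_CpG1"),
    intercept = c(50, 50, 80), slope = c(0, 0, 0))
  expect_error(model_faithful_params("Bekaert", base_params = bad_base),
               "no anchor root|outside \\[0, 100\\]")
  expect_error(
    model_faithful_params("ZbiecPiekarska1",
                          base_params = tibble::tibble(
                            cpg = "ELOVL2_CpG1", intercept = 30,
                            slope = 0.3)),
    "lack required CpG")
})

test_that("simulate_cohort is deterministic end to end", {
  a <- simulate_cohort(cohort_design(seed = 31), seed = 32)
  b <- simulate_cohort(cohort_design(seed = 31), seed = 32)
  expect_identical(a$methylation, b$methylation)
  expect_identical(a$samples, b$samples)
})
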