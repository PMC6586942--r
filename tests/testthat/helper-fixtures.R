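# shared fixtures, built in code

# small complete cohort over the 16 clock CpGs with exactly linear
# age trajectories (no noise) -- every clock applies without exclusions
linear_cohort <- function(n = 12, seed = 101) {
  meta <- withr::with_seed(seed, tibble::tibble(
    sample_id = sprintf("L%02d", seq_len(n)),
    age = sample(19:65, n, replace = TRUE),
    gender = sample(c("M", "F"), n, replace = TRUE)
  ))
  params <- default_cpg_params(model_cpg_labels())
  params$noise_sd <- 0
  generate_methylation(meta, params, seed = seed + 1)
}

# native-dialect cohort CSV written to a temp file
write_cohort_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# brute-force metric oracles: explicit loops, independent of the package
oracle_mad <- function(p, c) {
  s <- 0
  for (i in seq_along(p)) s <- s + abs(p[i] - c[i])
  s / length(p)
}

oracle_see <- function(p, c, df_adjust = FALSE) {
  s <- 0
  for (i in seq_along(p)) s <- s + (p[i] - c[i])^2
  sqrt(s / (length(p) - if (df_adjust) 2 else 0))
}

oracle_pcp <- function(p, c, thr) {
  hits <- 0
  for (i in seq_along(p)) if (abs(p[i] - c[i]) <= thr) hits <- hits + 1
  100 * hits / length(p)
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sxy <- sxx <- syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  sxy / sqrt(sxx * syy)
}

# textbook pooled-variance two-sample t statistic
oracle_pooled_t <- function(a, b) {
  na <- length(a)
  nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
    (na + nb - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
}
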