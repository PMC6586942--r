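#' Run code under a temporary RNG seed
#'
#' Evaluates `expr` with the RNG seeded to `seed`, then restores the prior
#' global RNG state, so generators are deterministic without disturbing the
#' caller's random stream.
#'
#' @param seed Integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_local_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(),
                      inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Design of a synthetic blood cohort
#'
#' Describes the sampling frame the generator emulates: three age groups of
#' adult donors with fixed sizes and non-overlapping integer age ranges,
#' and a fixed gender split. The defaults reproduce a 100-donor design:
#' groups of 34/33/33 over ages 19-34 / 35-49 / 50-65 and 42 women / 58
#' men.
#'
#' @param n_groups Integer vector of the three group sizes.
#' @param age_ranges List of three `c(min, max)` integer age ranges,
#'   ordered and non-overlapping.
#' @param n_female,n_male Gender counts; must sum to `sum(n_groups)`. When
#'   `NULL`, `n_female` defaults to `round(0.42 * n)` with the remainder
#'   male.
#' @param seed Integer seed driving metadata sampling.
#' @return A list of class `cohort_design`.
#' @export
cohort_design <- function(n_groups = c(34L, 33L, 33L),
                          age_ranges = list(c(19L, 34L), c(35L, 49L),
                                            c(50L, 65L)),
                          n_female = NULL, n_male = NULL, seed = 1L) {
  stopifnot(length(n_groups) == 3L, all(n_groups >= 0),
            length(age_ranges) == 3L)
  n <- sum(n_groups)
  if (is.null(n_female)) n_female <- round(0.42 * n)
  if (is.null(n_male)) n_male <- n - n_female
  if (n_female + n_male != n) {
    stop("gender counts (", n_female, " F + ", n_male,
         " M) do not sum to total n = ", n)
  }
  lo <- vapply(age_ranges, `[`, 0, 1)
  hi <- vapply(age_ranges, `[`, 0, 2)
  if (any(lo > hi) || any(lo <= 0) ||
      is.unsorted(c(rbind(lo, hi)), strictly = TRUE)) {
    stop("age ranges must be positive, ordered and non-overlapping")
  }
  structure(list(n_groups = as.integer(n_groups), age_ranges = age_ranges,
                 n_female = as.integer(n_female),
                 n_male = as.integer(n_male), seed = as.integer(seed)),
            class = "cohort_design")
}

#' Sample cohort metadata from a design
#'
#' Ages are drawn uniformly (integer years) within each group's range with
#' the designed group sizes; genders are a random permutation of the
#' designed counts. Deterministic given `design$seed`.
#'
#' @param design A [cohort_design()].
#' @return Tibble with `sample_id`, `age`, `gender`, `age_group`.
#' @export
sample_cohort_meta <- function(design = cohort_design()) {
  stopifnot(inherits(design, "cohort_design"))
  with_local_seed(design$seed, {
    ages <- unlist(lapply(1:3, function(g) {
      rng <- design$age_ranges[[g]]
      sample(seq(rng[1], rng[2]), design$n_groups[g], replace = TRUE)
    }))
    gender <- sample(c(rep("F", design$n_female), rep("M", design$n_male)))
    tibble::tibble(
      sample_id = sprintf("S%04d", seq_along(ages)),
      age = as.numeric(ages),
      gender = gender,
      age_group = assign_age_group(ages)
    )
  })
}

#' Noise level that hits a target age correlation
#'
#' For a CpG trajectory `a + b * age + N(0, sigma^2)` with independent
#' noise, the population Pearson correlation with age is
#' `r = b * sd(age) / sqrt(b^2 sd(age)^2 + sigma^2)`. Inverting gives the
#' noise sd that achieves a requested correlation:
#' `sigma = |b| * sd(age) * sqrt(1 / r^2 - 1)`.
#'
#' @param slope Trajectory slope `b`, percent per year; nonzero, with
#'   `sign(slope) == sign(target_r)`.
#' @param age_sd Standard deviation of age in the cohort, years.
#' @param target_r Target Pearson correlation, `0 < |target_r| < 1`.
#' @return Noise standard deviation in percentage points.
#' @export
#' @examples
#' noise_for_target_r(0.4, 13, 0.5)   # |b| * sd * sqrt(3)
noise_for_target_r <- function(slope, age_sd, target_r) {
  if (any(slope == 0)) stop("slope must be nonzero")
  if (any(abs(target_r) <= 0) || any(abs(target_r) >= 1)) {
    stop("target_r must satisfy 0 < |target_r| < 1")
  }
  if (any(sign(target_r) != sign(slope))) {
    stop("sign(target_r) must equal sign(slope)")
  }
  abs(slope) * age_sd * sqrt(1 / target_r^2 - 1)
}

#' Default per-CpG generation parameters
#'
#' One row per panel CpG with a linear-in-age trajectory: slope
#' `0.45 * r_ref` percent per year (sign from the reference correlation,
#' so strongly age-correlated CpGs move faster), intercept anchored so the
#' noise-free value is 50% at age 42, and `target_r` set to the reference
#' correlation. With these choices noise-free values stay within roughly
#' [29, 71] over ages 19-65 and the derived noise sd never exceeds ~6
#' points, so clamping at the [0, 100] bounds is negligible and empirical
#' correlations track their targets.
#'
#' @param cpgs Optional subset of CpG labels (default: all 52).
#' @return Tibble with columns `cpg`, `intercept`, `slope`, `noise_sd`
#'   (`NA` = derive from `target_r`), `target_r`.
#' @export
default_cpg_params <- function(cpgs = NULL) {
  panel <- cpg_panel()
  if (!is.null(cpgs)) {
    missing <- setdiff(cpgs, panel$cpg)
    if (length(missing) > 0) {
      stop("unknown CpG(s): ", paste(missing, collapse = ", "))
    }
    panel <- panel[match(cpgs, panel$cpg), ]
  }
  slope <- 0.45 * panel$r_all
  tibble::tibble(
    cpg = panel$cpg,
    intercept = 50 - slope * 42,
    slope = slope,
    noise_sd = NA_real_,
    target_r = panel$r_all
  )
}

#' Generate a synthetic methylation matrix
#'
#' Each CpG is generated independently as
#' `clamp(intercept + slope * age + eps, 0, 100)` with Gaussian noise
#' `eps ~ N(0, noise_sd^2)` per sample. When `noise_sd` is `NA` and
#' `target_r` is given, the noise sd is derived with
#' [noise_for_target_r()] from the empirical age sd of `meta`, so the
#' population correlation with age equals the target. Clamping events are
#' counted and raised as a warning (heavy clamping distorts the target
#' correlation). `drift > 0` adds linear heteroscedasticity emulating
#' epigenetic drift: the noise sd scales by
#' `1 + drift * (age - min(age)) / (max(age) - min(age))`.
#'
#' @param meta Sample metadata tibble ([sample_cohort_meta()]).
#' @param params Parameter tibble ([default_cpg_params()]); `noise_sd = 0`
#'   gives exactly linear trajectories.
#' @param seed Integer seed.
#' @param drift Relative noise-sd increase from youngest to oldest age
#'   (default 0 = homoscedastic).
#' @return A [cohort_table]; the number of clamped cells is available as
#'   `attr(x, "n_clamped")`.
#' @export
generate_methylation <- function(meta, params, seed = 1L, drift = 0) {
  meta <- tibble::as_tibble(meta)
  stopifnot(nrow(params) > 0, all(c("cpg", "intercept", "slope") %in%
                                    names(params)))
  if (is.null(params[["noise_sd"]])) params$noise_sd <- NA_real_
  if (is.null(params[["target_r"]])) params$target_r <- NA_real_
  parse_cpg_label(params$cpg)
  age <- meta$age
  age_sd <- stats::sd(age)
  sds <- params$noise_sd
  derive <- is.na(sds)
  if (any(derive & is.na(params$target_r))) {
    stop("params need noise_sd or target_r for every CpG")
  }
  if (any(derive)) {
    sds[derive] <- noise_for_target_r(params$slope[derive], age_sd,
                                      params$target_r[derive])
  }
  n <- length(age)
  scale_i <- if (drift > 0 && diff(range(age)) > 0) {
    1 + drift * (age - min(age)) / diff(range(age))
  } else {
    rep(1, n)
  }
  raw <- with_local_seed(seed, {
    eps <- matrix(stats::rnorm(n * nrow(params)), n, nrow(params))
    sweep(eps, 2, sds, `*`) * scale_i +
      outer(age, params$slope) +
      matrix(params$intercept, n, nrow(params), byrow = TRUE)
  })
  clamped <- sum(raw < 0 | raw > 100)
  if (clamped > 0) {
    warning(clamped, " of ", length(raw), " generated values clamped to ",
            "[0, 100]; heavy clamping distorts target correlations")
  }
  colnames(raw) <- params$cpg
  tab <- cohort_table(meta[, intersect(names(meta),
                                       c("sample_id", "age", "gender"))],
                      pmin(pmax(raw, 0), 100))
  attr(tab, "n_clamped") <- clamped
  tab
}

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper: samples metadata from the design, then generates
#' methylation for it. Metadata sampling is driven by `design$seed` and the
#' methylation noise by `seed`, so cohorts with identical designs but
#' different noise realisations share their samples.
#'
#' @inheritParams generate_methylation
#' @param design A [cohort_design()].
#' @return A [cohort_table].
#' @export
simulate_cohort <- function(design = cohort_design(),
                            params = default_cpg_params(), seed = 1L,
                            drift = 0) {
  meta <- sample_cohort_meta(design)
  generate_methylation(meta, params, seed = seed, drift = drift)
}

# per-model defaults for model_faithful_params: anchor CpG plus base
# trajectories keeping the anchor solution inside [0, 100] over ages 19-65
# (the panel defaults put too much of the age signal in high-coefficient
# covariate terms for some models)
.faithful_defaults <- function(name) {
  switch(name,
    Bekaert = list(
      anchor = "ELOVL2_CpG6",
      base = tibble::tribble(
        ~cpg, ~intercept, ~slope,
        "ASPA_CpG1",    75, -0.30,
        "EDARADD_CpG1", 80, -0.35,
        "PDE4C_CpG1",   10,  0.90
      )),
    Park = list(
      anchor = "ELOVL2_CpG1",
      base = tibble::tribble(
        ~cpg, ~intercept, ~slope,
        "CCDC102B_CpG1", 62.7, -0.302,
        "ZNF423_CpG1",   62.3, -0.292
      )),
    Thong = list(
      anchor = "ELOVL2_CpG5",
      base = tibble::tribble(
        ~cpg, ~intercept, ~slope,
        "KLF14_CpG2",  5, 0.05,
        "TRIM59_CpG5", 10, 0.20
      )),
    Weidner = list(
      anchor = "PDE4C_CpG1",
      base = tibble::tribble(
        ~cpg, ~intercept, ~slope,
        "ASPA_CpG1",   62.0, -0.286,
        "ITGA2B_CpG2", 56.4, -0.154
      )),
    ZbiecPiekarska1 = list(
      anchor = "ELOVL2_CpG7",
      base = tibble::tribble(
        ~cpg, ~intercept, ~slope,
        "ELOVL2_CpG5", 35.2, 0.353
      )),
    ZbiecPiekarska2 = list(
      anchor = "KLF14_CpG1",
      base = tibble::tribble(
        ~cpg, ~intercept, ~slope,
        "C1orf132_CpG1", 80, -0.30,
        "ELOVL2_CpG7",   35,  0.357,
        "FHL2_CpG2",     20,  0.339,
        "TRIM59_CpG7",   36,  0.333
      )),
    stop("no default base trajectories for model '", name,
         "'; supply base_params")
  )
}

#' Generation parameters under which a clock is self-consistent
#'
#' Solves one CpG's trajectory (the anchor) so that, applied to the
#' noise-free generator, the clock predicts exactly the chronological age
#' at two anchor ages. For the five linear clocks the whole prediction is
#' then affine in age, so it is exact at every age; for the quadratic
#' Bekaert term the anchor value is obtained by root selection in [0, 100]
#' at each anchor age and interpolated linearly between them, leaving a
#' small bounded interpolation error. Such parameter sets give synthetic
#' cohorts on which predicted age tracks chronological age, so added noise
#' feeds through to prediction error in a controlled way.
#'
#' @param model A [clock_model] or built-in model name.
#' @param anchor Anchor CpG label; must be one of the model's required
#'   CpGs, and must be `ELOVL2_CpG6` for Bekaert (the quadratic term).
#'   Default: a per-model built-in choice.
#' @param age_anchors Two distinct ages (years) at which the clock is made
#'   exact; default `c(25, 60)`.
#' @param base_params Tibble with `cpg`, `intercept`, `slope` covering the
#'   model's non-anchor CpGs; default: built-in trajectories chosen to keep
#'   the anchor solution inside [0, 100].
#' @param anchor_noise_sd Gaussian noise sd placed on the anchor CpG
#'   (default 0; base CpGs are always noise-free under this construction).
#' @return Parameter tibble for [generate_methylation()].
#' @export
model_faithful_params <- function(model, anchor = NULL,
                                  age_anchors = c(25, 60),
                                  base_params = NULL, anchor_noise_sd = 0) {
  model <- resolve_models(model)[[1]]
  stopifnot(length(age_anchors) == 2L, age_anchors[1] != age_anchors[2])
  defaults <- tryCatch(.faithful_defaults(model$name), error = function(e) NULL)
  if (is.null(anchor)) {
    if (is.null(defaults)) stop("anchor must be given for model '",
                                model$name, "'")
    anchor <- defaults$anchor
  }
  if (!anchor %in% model$required_cpgs) {
    stop("anchor ", anchor, " is not a CpG of model ", model$name)
  }
  a_term <- model$terms[model$terms$cpg == anchor, ]
  if (model$name == "Bekaert" && anchor != "ELOVL2_CpG6") {
    stop("for the Bekaert model the anchor must be ELOVL2_CpG6 ",
         "(the quadratic term)")
  }
  if (is.null(base_params)) {
    if (is.null(defaults)) stop("base_params must be given for model '",
                                model$name, "'")
    base_params <- defaults$base
  }
  base_params <- tibble::as_tibble(base_params)
  others <- setdiff(model$required_cpgs, anchor)
  lacking <- setdiff(others, base_params$cpg)
  if (length(lacking) > 0) {
    stop("base_params lack required CpG(s): ",
         paste(lacking, collapse = ", "))
  }
  base_params <- base_params[match(others, base_params$cpg), ]
  # covariate contribution at age t (all non-anchor terms are linear for
  # the built-ins; exponents are honoured anyway)
  o_terms <- model$terms[model$terms$cpg != anchor, ]
  rest_at <- function(t) {
    vals <- base_params$intercept + base_params$slope * t
    model$intercept + sum(o_terms$coefficient * vals^o_terms$exponent)
  }
  solve_anchor <- function(t) {
    target <- (t - rest_at(t)) / a_term$coefficient
    if (a_term$exponent == 1L) {
      v <- target
    } else {
      if (target < 0) {
        stop("no anchor root in [0, 100] at age ", t,
             " (quadratic argument negative); adjust base_params")
      }
      v <- sqrt(target)
    }
    if (v < 0 || v > 100) {
      stop("anchor value ", round(v, 2), " outside [0, 100] at age ", t,
           "; adjust base_params or age_anchors")
    }
    v
  }
  v1 <- solve_anchor(age_anchors[1])
  v2 <- solve_anchor(age_anchors[2])
  b <- (v2 - v1) / (age_anchors[2] - age_anchors[1])
  a <- v1 - b * age_anchors[1]
  dplyr::bind_rows(
    tibble::tibble(cpg = anchor, intercept = a, slope = b,
                   noise_sd = anchor_noise_sd, target_r = NA_real_),
    tibble::tibble(cpg = base_params$cpg, intercept = base_params$intercept,
                   slope = base_params$slope, noise_sd = 0,
                   target_r = NA_real_)
  )
}
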