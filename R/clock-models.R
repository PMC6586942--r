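#' Construct an age prediction clock
#'
#' A clock model maps percent methylation (0-100 scale) at a small set of
#' CpG sites to a predicted chronological age in years via
#' `intercept + sum(coefficient * value^exponent)`. All built-in clocks are
#' linear except the Bekaert model, whose `ELOVL2` CpG 6 term is quadratic.
#'
#' @param name Model name (free text for user-defined clocks).
#' @param intercept Intercept, years.
#' @param terms Data frame with columns `gene`, `index`, `coefficient` and
#'   optionally `exponent` (default 1; only 1 and 2 are allowed).
#' @return An object of class `clock_model` with fields `name`, `intercept`,
#'   `terms` (tibble with a `cpg` label column added) and `required_cpgs`.
#' @seealso [builtin_models()], [predict.clock_model()]
#' @export
clock_model <- function(name, intercept, terms) {
  terms <- tibble::as_tibble(terms)
  if (is.null(terms$exponent)) terms$exponent <- 1L
  stopifnot(
    is.character(name), length(name) == 1L,
    is.numeric(intercept), length(intercept) == 1L,
    all(c("gene", "index", "coefficient") %in% names(terms)),
    all(terms$exponent %in% c(1L, 2L))
  )
  terms$index <- as.integer(terms$index)
  terms$exponent <- as.integer(terms$exponent)
  terms$cpg <- cpg_label(terms$gene, terms$index)
  if (anyDuplicated(terms$cpg)) {
    stop("duplicate CpG terms in model '", name, "'")
  }
  structure(
    list(name = name, intercept = intercept, terms = terms,
         required_cpgs = terms$cpg),
    class = "clock_model"
  )
}

#' @export
print.clock_model <- function(x, ...) {
  cat("<clock_model>", x$name, "\n")
  cat("  intercept:", format(x$intercept, digits = 15), "\n")
  for (i in seq_len(nrow(x$terms))) {
    t <- x$terms[i, ]
    cat(sprintf("  %+.15g * %s%s\n", t$coefficient, t$cpg,
                if (t$exponent == 2L) "^2" else ""))
  }
  invisible(x)
}

#' The six built-in blood-based age prediction clocks
#'
#' Returns the published prediction formulas of Bekaert, Park, Thong,
#' Weidner and Zbiec-Piekarska (models 1 and 2), with coefficients at full
#' published precision. Inputs are percent methylation (0-100); outputs are
#' years, unclamped. The Bekaert model contains a single quadratic term
#' (`ELOVL2` CpG 6 squared); the other five are linear.
#'
#' The Weidner formula circulates in a typographically garbled form; it is
#' encoded here as `38.0 - 0.264*ASPA_CpG1 - 0.237*ITGA2B_CpG2 +
#' 1.647*PDE4C_CpG1`, the reading consistent with the printed
#' coefficient-to-gene order and the model's CpG assignment.
#'
#' @return Named list of six [clock_model] objects, in registry order
#'   Bekaert, Park, Thong, Weidner, ZbiecPiekarska1, ZbiecPiekarska2.
#' @export
#' @examples
#' models <- builtin_models()
#' names(models)
#' models$ZbiecPiekarska1$required_cpgs
builtin_models <- function() {
  term <- function(gene, index, coefficient, exponent = 1L) {
    tibble::tibble(gene = gene, index = index, coefficient = coefficient,
                   exponent = exponent)
  }
  models <- list(
    clock_model("Bekaert", 26.444119, rbind(
      term("ASPA", 1, -0.201902),
      term("EDARADD", 1, -0.239205),
      term("ELOVL2", 6, 0.0063745, 2L),
      term("PDE4C", 1, 0.6352654)
    )),
    clock_model("Park", 39.73167, rbind(
      term("CCDC102B", 1, -0.69994),
      term("ELOVL2", 1, 1.19242),
      term("ZNF423", 1, -0.28914)
    )),
    clock_model("Thong", -20.372, rbind(
      term("ELOVL2", 5, 0.830),
      term("KLF14", 2, 1.723),
      term("TRIM59", 5, 0.715)
    )),
    clock_model("Weidner", 38.0, rbind(
      term("ASPA", 1, -0.264),
      term("ITGA2B", 2, -0.237),
      term("PDE4C", 1, 1.647)
    )),
    clock_model("ZbiecPiekarska1", -42.8393176902677, rbind(
      term("ELOVL2", 5, 0.63266203860581),
      term("ELOVL2", 7, 0.877474742612866)
    )),
    clock_model("ZbiecPiekarska2", 3.26847784751817, rbind(
      term("C1orf132", 1, -0.355450171437202),
      term("ELOVL2", 7, 0.465445549010653),
      term("FHL2", 2, 0.237081243617191),
      term("KLF14", 1, 0.832684435238792),
      term("TRIM59", 7, 0.306488541137007)
    ))
  )
  names(models) <- vapply(models, `[[`, "", "name")
  models
}

#' Resolve model names to clock objects
#'
#' @param models `"all"`, a character vector of built-in model names, a
#'   single [clock_model], or a list of [clock_model] objects.
#' @return Named list of `clock_model` objects in registry order (built-ins)
#'   or given order (user models).
#' @export
resolve_models <- function(models = "all") {
  if (inherits(models, "clock_model")) {
    return(stats::setNames(list(models), models$name))
  }
  if (is.character(models)) {
    builtin <- builtin_models()
    if (identical(models, "all")) return(builtin)
    unknown <- setdiff(models, names(builtin))
    if (length(unknown) > 0) {
      stop("unknown model name(s): ", paste(unknown, collapse = ", "),
           "; built-ins are ", paste(names(builtin), collapse = ", "))
    }
    return(builtin[names(builtin) %in% models])
  }
  stopifnot(is.list(models), all(vapply(models, inherits, TRUE, "clock_model")))
  stats::setNames(models, vapply(models, `[[`, "", "name"))
}

#' Predict age from percent methylation
#'
#' Applies a clock formula to one sample's methylation values. Values must
#' be on the percent scale (0-100); the published coefficients assume it,
#' and beta-scale input (all values <= 1) is rejected rather than silently
#' mis-scaled. The output is raw formula output in years: no clamping and
#' no rounding.
#'
#' @param object A [clock_model].
#' @param methylation Named numeric vector (names are `GENE_CpGk` labels) or
#'   single-row data frame / matrix with such column names.
#' @param ... Unused.
#' @return Predicted age in years (length-1 numeric).
#' @export
#' @examples
#' m <- builtin_models()$Thong
#' predict(m, c(ELOVL2_CpG5 = 60, KLF14_CpG2 = 10, TRIM59_CpG5 = 40))
predict.clock_model <- function(object, methylation, ...) {
  if (is.data.frame(methylation) || is.matrix(methylation)) {
    stopifnot(nrow(methylation) == 1L)
    methylation <- stats::setNames(as.numeric(methylation[1, ]),
                                   colnames(methylation))
  }
  missing_cpgs <- setdiff(object$required_cpgs, names(methylation))
  vals <- methylation[object$terms$cpg]
  missing_cpgs <- union(missing_cpgs, object$terms$cpg[is.na(vals)])
  if (length(missing_cpgs) > 0) {
    stop("model '", object$name, "': missing required CpG(s) ",
         paste(missing_cpgs, collapse = ", "))
  }
  if (any(vals < 0 | vals > 100)) {
    bad <- object$terms$cpg[vals < 0 | vals > 100]
    stop("model '", object$name, "': methylation outside [0, 100] for ",
         paste(bad, collapse = ", "))
  }
  present <- methylation[!is.na(methylation)]
  if (length(present) > 0 && max(present) <= 1 && any(present > 0)) {
    stop("all methylation values are <= 1: input looks beta-scale (0-1); ",
         "clock coefficients expect percent (0-100)")
  }
  unname(object$intercept +
           sum(object$terms$coefficient * vals^object$terms$exponent))
}

#' Apply clocks to a whole cohort
#'
#' Applies each model to every sample of a cohort table. Samples lacking a
#' required CpG for a model are excluded from that model (never imputed),
#' with the reason recorded. Output order is deterministic: input sample
#' order nested within model registry order.
#'
#' @param table A [cohort_table].
#' @param models See [resolve_models()]; default all six built-ins.
#' @return Tibble with columns `sample_id`, `model`, `predicted_age`
#'   (NA when excluded), `excluded` (logical) and `reason`. Predictions
#'   below 0 years are additionally flagged in a `negative` column.
#' @export
predict_cohort <- function(table, models = "all") {
  stopifnot(inherits(table, "cohort_table"))
  models <- resolve_models(models)
  meth <- table$methylation
  if (nrow(meth) > 0) {
    finite <- meth[!is.na(meth)]
    if (length(finite) > 0 && max(finite) <= 1 && any(finite > 0)) {
      stop("cohort methylation maximum is <= 1: input looks beta-scale ",
           "(0-1); clock coefficients expect percent (0-100)")
    }
  }
  out <- lapply(models, function(m) {
    lacking <- setdiff(m$required_cpgs, colnames(meth))
    if (length(lacking) > 0) {
      return(tibble::tibble(
        sample_id = table$samples$sample_id, model = m$name,
        predicted_age = NA_real_, excluded = TRUE,
        reason = paste("cohort lacks column(s):",
                       paste(lacking, collapse = ", "))
      ))
    }
    sub <- meth[, m$terms$cpg, drop = FALSE]
    miss <- is.na(sub)
    excluded <- rowSums(miss) > 0
    pred <- rep(NA_real_, nrow(sub))
    if (any(!excluded)) {
      x <- sub[!excluded, , drop = FALSE]
      pow <- sweep(x, 2, m$terms$exponent, `^`)
      pred[!excluded] <- m$intercept +
        as.numeric(pow %*% m$terms$coefficient)
    }
    reason <- rep(NA_character_, nrow(sub))
    if (any(excluded)) {
      reason[excluded] <- vapply(which(excluded), function(i) {
        paste("missing", paste(m$terms$cpg[miss[i, ]], collapse = ", "))
      }, "")
    }
    tibble::tibble(
      sample_id = table$samples$sample_id, model = m$name,
      predicted_age = pred, excluded = excluded, reason = reason
    )
  })
  res <- dplyr::bind_rows(out)
  res$negative <- !is.na(res$predicted_age) & res$predicted_age < 0
  res
}

#' Read a user-defined clock from a YAML-like key/value file
#'
#' The file format is plain text: a `name:` line, an `intercept:` line, then
#' one `term:` line per CpG with comma-separated `gene, index, coefficient[,
#' exponent]` fields.
#'
#' @param path File path.
#' @return A [clock_model].
#' @export
read_clock_model <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- function(key) {
    hit <- grep(paste0("^", key, ":"), lines, value = TRUE)
    trimws(sub(paste0("^", key, ":"), "", hit))
  }
  name <- kv("name")
  intercept <- as.numeric(kv("intercept"))
  if (length(name) != 1L || length(intercept) != 1L || is.na(intercept)) {
    stop("clock definition needs exactly one 'name:' and one numeric ",
         "'intercept:' line: ", path)
  }
  terms <- lapply(kv("term"), function(x) {
    f <- trimws(strsplit(x, ",")[[1]])
    if (!length(f) %in% c(3L, 4L)) {
      stop("malformed term line (want gene, index, coefficient[, exponent]): ",
           x)
    }
    tibble::tibble(
      gene = f[1], index = as.integer(f[2]), coefficient = as.numeric(f[3]),
      exponent = if (length(f) == 4L) as.integer(f[4]) else 1L
    )
  })
  if (length(terms) == 0) stop("clock definition has no 'term:' lines: ", path)
  clock_model(name, intercept, dplyr::bind_rows(terms))
}
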