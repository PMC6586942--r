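#' Assign cohort age groups
#'
#' Three-group stratification of adult donors: group I (young adults, up to
#' 34 years), group II (middle-aged, 35-49), group III (older adults, 50+).
#' Boundaries are inclusive integer-year cut points; an age of exactly 35
#' falls in group II.
#'
#' @param age Numeric vector of chronological ages in years; must be > 0.
#' @return Factor with levels `I`, `II`, `III`.
#' @export
#' @examples
#' assign_age_group(c(34, 35, 50))
assign_age_group <- function(age) {
  if (!is.numeric(age) || any(is.na(age)) || any(age <= 0)) {
    stop("age must be positive and non-missing")
  }
  cut(age, breaks = c(0, 35, 50, Inf), labels = c("I", "II", "III"),
      right = FALSE)
}

#' Construct a cohort table
#'
#' Couples per-sample metadata (chronological age in years, gender, derived
#' age group) to a samples x CpGs matrix of percent methylation (0-100;
#' `NA` marks missing measurements).
#'
#' @param samples Data frame with columns `sample_id`, `age` and optionally
#'   `gender` (`"M"`, `"F"` or `"unknown"`).
#' @param methylation Numeric matrix or data frame, one row per sample, one
#'   column per CpG; column names are `GENE_CpGk` labels.
#' @return An object of class `cohort_table`: list with `samples` (tibble,
#'   including derived `age_group`), `methylation` (matrix) and `issues`
#'   (tibble of ingestion warnings, see [read_cohort()]).
#' @export
cohort_table <- function(samples, methylation) {
  samples <- tibble::as_tibble(samples)
  stopifnot(all(c("sample_id", "age") %in% names(samples)))
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  }
  if (is.null(samples[["gender"]])) samples$gender <- "unknown"
  samples$gender <- normalize_gender(samples$gender)
  samples$age_group <- assign_age_group(samples$age)

  methylation <- as.matrix(methylation)
  storage.mode(methylation) <- "double"
  if (nrow(methylation) != nrow(samples)) {
    stop("methylation has ", nrow(methylation), " rows but there are ",
         nrow(samples), " samples")
  }
  if (is.null(colnames(methylation)) ||
      anyDuplicated(colnames(methylation))) {
    stop("methylation columns must have unique CpG label names")
  }
  parse_cpg_label(colnames(methylation))  # validates labels
  rownames(methylation) <- samples$sample_id
  bad <- which(!is.na(methylation) &
                 (methylation < 0 | methylation > 100), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    cells <- apply(bad, 1, function(ij) {
      paste0(samples$sample_id[ij[1]], "/", colnames(methylation)[ij[2]],
             " = ", methylation[ij[1], ij[2]])
    })
    stop("methylation outside [0, 100]: ", paste(cells, collapse = "; "))
  }
  structure(
    list(samples = samples, methylation = methylation,
         issues = .empty_issues()),
    class = "cohort_table"
  )
}

#' @export
print.cohort_table <- function(x, ...) {
  cat("<cohort_table> ", nrow(x$samples), " samples x ",
      ncol(x$methylation), " CpGs\n", sep = "")
  tab <- table(x$samples$age_group)
  cat("  age ", min(x$samples$age), "-", max(x$samples$age),
      "; groups I/II/III = ", paste(tab, collapse = "/"),
      "; gender ", sum(x$samples$gender == "F"), " F / ",
      sum(x$samples$gender == "M"), " M\n", sep = "")
  if (nrow(x$issues) > 0) cat("  ", nrow(x$issues), " ingestion issue(s)\n")
  invisible(x)
}

#' @export
dim.cohort_table <- function(x) dim(x$methylation)

normalize_gender <- function(x) {
  x <- tolower(trimws(as.character(x)))
  out <- rep("unknown", length(x))
  out[x %in% c("m", "male", "man", "men")] <- "M"
  out[x %in% c("f", "female", "woman", "women")] <- "F"
  out
}

.empty_issues <- function() {
  tibble::tibble(severity = character(), sample_id = character(),
                 cpg = character(), message = character())
}

.issue <- function(severity, sample_id, cpg, message) {
  tibble::tibble(severity = severity, sample_id = sample_id, cpg = cpg,
                 message = message)
}

#' Read a cohort methylation table
#'
#' Native dialects (`csv`, `tsv`) expect one header row with columns
#' `sample_id`, `age`, `gender` followed by one `GENE_CpGk` column per CpG.
#' The `xlsx` dialect reads the same layout from the first sheet of a
#' workbook (requires the readxl package). Gender tokens `M/F/male/female/
#' man/woman` (case-insensitive) are accepted; anything else becomes
#' `unknown` with a warning-level issue. Unparseable methylation cells
#' become missing with a warning-level issue; values outside [0, 100] are a
#' hard error naming the offending cells. Ages outside 19-65 are accepted
#' but flagged (extrapolation beyond the adult calibration range), and ages
#' of exactly 35 are flagged as sitting on the group I/II boundary.
#'
#' @param path File path.
#' @param dialect `"csv"`, `"tsv"` or `"xlsx"` (default guessed from the
#'   file extension).
#' @return A [cohort_table]; ingestion warnings are in `$issues`.
#' @export
read_cohort <- function(path, dialect = c("auto", "csv", "tsv", "xlsx")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, tsv = "tsv", txt = "tsv", xlsx = "xlsx", "csv")
  }
  if (!file.exists(path)) stop("cohort file not found: ", path)
  raw <- switch(dialect,
    csv = readr::read_csv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE),
    tsv = readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                          progress = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        stop("the xlsx dialect requires the readxl package")
      }
      xl <- readxl::read_excel(path, sheet = 1, col_types = "text")
      tibble::as_tibble(xl)
    }
  )
  names(raw) <- .canonical_column_names(names(raw))
  if (!"age" %in% names(raw)) stop("cohort file has no age column: ", path)
  if (!"sample_id" %in% names(raw)) {
    raw$sample_id <- sprintf("S%03d", seq_len(nrow(raw)))
  }
  issues <- .empty_issues()

  age <- suppressWarnings(as.numeric(raw$age))
  if (any(is.na(age))) {
    stop("unparseable age for sample(s): ",
         paste(raw$sample_id[is.na(age)], collapse = ", "))
  }
  gender_raw <- if ("gender" %in% names(raw)) raw$gender else "unknown"
  gender <- normalize_gender(gender_raw)
  odd <- gender == "unknown" & !tolower(trimws(gender_raw)) %in%
    c("unknown", "na", "")
  if (any(odd)) {
    issues <- dplyr::bind_rows(issues, .issue(
      "warning", raw$sample_id[odd], NA_character_,
      paste0("unrecognised gender token '", gender_raw[odd],
             "'; recorded as unknown")))
  }
  outside <- age < 19 | age > 65
  if (any(outside)) {
    issues <- dplyr::bind_rows(issues, .issue(
      "warning", raw$sample_id[outside], NA_character_,
      paste0("age ", age[outside],
             " outside the 19-65 calibration range (extrapolation)")))
  }
  if (any(age == 35)) {
    issues <- dplyr::bind_rows(issues, .issue(
      "warning", raw$sample_id[age == 35], NA_character_,
      "age exactly 35: on the group I/II boundary, assigned to group II"))
  }

  cpg_cols <- setdiff(names(raw), c("sample_id", "age", "gender"))
  cpg_cols <- cpg_cols[grepl("^[A-Za-z0-9]+_CpG[0-9]+$", cpg_cols)]
  meth <- matrix(NA_real_, nrow(raw), length(cpg_cols),
                 dimnames = list(raw$sample_id, cpg_cols))
  for (cc in cpg_cols) {
    txt <- trimws(raw[[cc]])
    txt[txt %in% c("", "NA", "na", "NaN")] <- NA
    val <- suppressWarnings(as.numeric(txt))
    unparseable <- is.na(val) & !is.na(txt)
    if (any(unparseable)) {
      issues <- dplyr::bind_rows(issues, .issue(
        "warning", raw$sample_id[unparseable], cc,
        paste0("unparseable cell '", txt[unparseable],
               "' treated as missing")))
    }
    meth[, cc] <- val
  }
  tab <- cohort_table(
    tibble::tibble(sample_id = raw$sample_id, age = age, gender = gender),
    meth
  )
  tab$issues <- issues
  tab
}

# map workbook-style headers (e.g. "ELOVL2 (CpG_6)", "Age", "Sex") onto the
# native sample_id / age / gender / GENE_CpGk scheme
.canonical_column_names <- function(nm) {
  out <- nm
  low <- tolower(trimws(nm))
  out[low %in% c("sample_id", "sample id", "sample", "id", "donor")] <-
    "sample_id"
  out[low %in% c("age", "chronological age", "age (years)")] <- "age"
  out[low %in% c("gender", "sex")] <- "gender"
  paren <- regexec("^([A-Za-z0-9]+)[ .]*\\(?CpG[ _]?([0-9]+)\\)?\\.?$",
                   trimws(out))
  for (i in seq_along(out)) {
    m <- regmatches(out[i], paren[i])[[1]]
    if (length(m) == 3L && m[2] %in% panel_genes()) {
      out[i] <- paste0(m[2], "_CpG", m[3])
    }
  }
  out
}

#' Write a cohort table in the native CSV dialect
#'
#' Values are written at full precision so a read/write round trip
#' reproduces the table exactly.
#'
#' @param table A [cohort_table].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  stopifnot(inherits(table, "cohort_table"))
  df <- dplyr::bind_cols(
    table$samples[, c("sample_id", "age", "gender")],
    tibble::as_tibble(table$methylation)
  )
  readr::write_csv(df, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Validate a cohort table against clock requirements
#'
#' Reports, per model, samples that lack a required CpG measurement (those
#' samples are excluded from that model's predictions and metrics) and
#' CpG columns required by a model but absent from the table.
#'
#' @param table A [cohort_table].
#' @param models See [resolve_models()]; `"all"` validates against all six
#'   built-ins and returns the union of the per-model reports.
#' @return Tibble with columns `severity`, `model`, `sample_id`, `cpg`,
#'   `message`; zero rows when the table is complete.
#' @export
validate_cohort <- function(table, models = "all") {
  stopifnot(inherits(table, "cohort_table"))
  models <- resolve_models(models)
  out <- lapply(models, function(m) {
    absent <- setdiff(m$required_cpgs, colnames(table$methylation))
    rows <- list()
    if (length(absent) > 0) {
      rows <- c(rows, list(tibble::tibble(
        severity = "error", model = m$name, sample_id = NA_character_,
        cpg = absent,
        message = paste0("required CpG column ", absent,
                         " absent; model ", m$name,
                         " cannot be applied to any sample"))))
    }
    present <- intersect(m$required_cpgs, colnames(table$methylation))
    if (length(present) > 0) {
      sub <- table$methylation[, present, drop = FALSE]
      miss <- which(is.na(sub), arr.ind = TRUE)
      if (nrow(miss) > 0) {
        rows <- c(rows, list(tibble::tibble(
          severity = "error", model = m$name,
          sample_id = rownames(sub)[miss[, 1]],
          cpg = colnames(sub)[miss[, 2]],
          message = paste0("sample ", rownames(sub)[miss[, 1]],
                           " missing ", colnames(sub)[miss[, 2]],
                           " required by model ", m$name,
                           "; sample excluded from that model"))))
      }
    }
    dplyr::bind_rows(rows)
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0) {
    res <- tibble::tibble(severity = character(), model = character(),
                          sample_id = character(), cpg = character(),
                          message = character())
  }
  res
}
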