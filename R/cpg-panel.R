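#' The 52-CpG pyrosequencing panel
#'
#' The six blood-based age prediction clocks supported by this package draw
#' on 52 CpG sites distributed over 11 gene amplicons. CpGs are identified by
#' gene symbol plus a 1-based within-amplicon index (e.g. `ELOVL2` CpG 6,
#' written `ELOVL2_CpG6` in cohort table headers).
#'
#' `cpg_panel()` returns the full panel together with reference Pearson
#' correlations between percent methylation and chronological age observed
#' in an adult blood cohort (ages 19-65), overall and by gender. These
#' reference magnitudes drive the default targets of the synthetic-cohort
#' generator (see [default_cpg_params()]) and the `in_model` flag marks the
#' 16 distinct CpGs used by at least one of the six clocks.
#'
#' @return A tibble with columns `gene`, `index`, `cpg` (label such as
#'   `"ELOVL2_CpG6"`), `r_all`, `r_men`, `r_women` and `in_model`.
#' @seealso [builtin_models()], [default_cpg_params()]
#' @export
#' @examples
#' panel <- cpg_panel()
#' nrow(panel)                    # 52
#' sum(panel$in_model)            # 16
cpg_panel <- function() {
  ref <- .cpg_reference()
  model_cpgs <- model_cpg_labels()
  tibble::tibble(
    gene = ref$gene,
    index = ref$index,
    cpg = cpg_label(ref$gene, ref$index),
    r_all = ref$r_all,
    r_men = ref$r_men,
    r_women = ref$r_women,
    in_model = cpg_label(ref$gene, ref$index) %in% model_cpgs
  )
}

# reference age-correlation coefficients per CpG (All / Men / Women strata)
.cpg_reference <- function() {
  rows <- list(
    list("ASPA",     c(-0.635, -0.591),
                     c(-0.681, -0.601),
                     c(-0.516, -0.550)),
    list("C1orf132", c(-0.677, -0.700, -0.699),
                     c(-0.743, -0.726, -0.754),
                     c(-0.577, -0.643, -0.597)),
    list("CCDC102B", c(-0.672, -0.573),
                     c(-0.682, -0.537),
                     c(-0.686, -0.638)),
    list("EDARADD",  c(-0.747, -0.675),
                     c(-0.770, -0.677),
                     c(-0.713, -0.658)),
    list("ELOVL2",   c(0.742, 0.790, 0.833, 0.831, 0.785, 0.862, 0.794),
                     c(0.755, 0.799, 0.829, 0.818, 0.769, 0.852, 0.782),
                     c(0.710, 0.763, 0.830, 0.847, 0.805, 0.877, 0.807)),
    list("FHL2",     c(0.795, 0.753, 0.764, 0.782, 0.742, 0.698, 0.626,
                       0.672, 0.660, 0.561),
                     c(0.775, 0.724, 0.722, 0.747, 0.712, 0.652, 0.592,
                       0.652, 0.596, 0.514),
                     c(0.822, 0.791, 0.837, 0.838, 0.780, 0.770, 0.674,
                       0.691, 0.761, 0.634)),
    list("ITGA2B",   c(-0.464, -0.341, -0.325),
                     c(-0.465, -0.359, -0.315),
                     c(-0.421, -0.278, -0.319)),
    list("KLF14",    c(0.768, 0.693, 0.618, 0.499),
                     c(0.765, 0.700, 0.657, 0.480),
                     c(0.789, 0.666, 0.509, 0.514)),
    list("PDE4C",    c(0.757, 0.459, 0.468, 0.296, 0.524, 0.377, 0.429, 0.361),
                     c(0.772, 0.473, 0.518, 0.156, 0.566, 0.342, 0.419, 0.402),
                     c(0.721, 0.392, 0.321, 0.495, 0.467, 0.415, 0.450, 0.245)),
    list("TRIM59",   c(0.570, 0.570, 0.730, 0.695, 0.758, 0.755, 0.739, 0.652),
                     c(0.592, 0.543, 0.695, 0.694, 0.759, 0.729, 0.719, 0.638),
                     c(0.505, 0.631, 0.788, 0.680, 0.748, 0.790, 0.774, 0.672)),
    list("ZNF423",   c(-0.648, -0.551, -0.586),
                     c(-0.670, -0.625, -0.621),
                     c(-0.584, -0.427, -0.495))
  )
  gene <- unlist(lapply(rows, function(x) rep(x[[1]], length(x[[2]]))))
  index <- unlist(lapply(rows, function(x) seq_along(x[[2]])))
  tibble::tibble(
    gene = gene,
    index = as.integer(index),
    r_all = unlist(lapply(rows, `[[`, 2)),
    r_men = unlist(lapply(rows, `[[`, 3)),
    r_women = unlist(lapply(rows, `[[`, 4))
  )
}

#' Gene symbols of the panel
#' @return Character vector of the 11 gene symbols.
#' @export
panel_genes <- function() {
  c("ASPA", "C1orf132", "CCDC102B", "EDARADD", "ELOVL2", "FHL2",
    "ITGA2B", "KLF14", "PDE4C", "TRIM59", "ZNF423")
}

#' Build or parse CpG labels
#'
#' CpG sites are labelled `GENE_CpGk`, e.g. `"ELOVL2_CpG6"`. `cpg_label()`
#' builds labels from gene/index pairs, validating both against the panel;
#' `parse_cpg_label()` inverts it.
#'
#' @param gene Gene symbol(s), one of [panel_genes()].
#' @param index Positive integer within-amplicon CpG number(s) (1-based),
#'   recycled against `gene`.
#' @return `cpg_label()`: character vector of labels. `parse_cpg_label()`:
#'   tibble with columns `gene` and `index`.
#' @export
#' @examples
#' cpg_label("ELOVL2", 6)
#' parse_cpg_label("KLF14_CpG2")
cpg_label <- function(gene, index) {
  n <- max(length(gene), length(index))
  gene <- rep_len(gene, n)
  index <- rep_len(as.integer(index), n)
  bad <- !gene %in% panel_genes()
  if (any(bad)) {
    stop("unknown gene symbol(s): ", paste(unique(gene[bad]), collapse = ", "))
  }
  counts <- .panel_cpg_counts()
  bad_idx <- index < 1L | index > counts[gene]
  if (any(bad_idx)) {
    stop("CpG index out of range for ",
         paste(unique(paste0(gene[bad_idx], " (", index[bad_idx], ")")),
               collapse = ", "))
  }
  paste0(gene, "_CpG", index)
}

#' @rdname cpg_label
#' @param label Character vector of `GENE_CpGk` labels.
#' @export
parse_cpg_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Za-z0-9]+)_CpG([0-9]+)$", label))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) {
    stop("malformed CpG label(s): ", paste(label[bad], collapse = ", "))
  }
  gene <- vapply(m, `[[`, "", 2L)
  index <- as.integer(vapply(m, `[[`, "", 3L))
  cpg_label(gene, index)  # validates
  tibble::tibble(gene = gene, index = index)
}

.panel_cpg_counts <- function() {
  ref <- .cpg_reference()
  vapply(split(ref$index, ref$gene), max, 1L)
}

#' CpGs used by the built-in clocks
#'
#' @return Character vector of the 16 distinct CpG labels appearing in at
#'   least one of the six built-in prediction formulas.
#' @export
model_cpg_labels <- function() {
  models <- builtin_models()
  sort(unique(unlist(lapply(models, function(m) m$terms$cpg))))
}
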