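#' Paired tumor/normal feature-by-sample abundance matrix
#'
#' The substrate of the proteome and metabolome stages: a numeric matrix of
#' feature abundances (rows = features, columns = samples) from a matched
#' cohort, where every patient contributes exactly one tumor and one normal
#' sample. Missing values are `NA` and stay `NA` -- they are never coded as
#' zero, because downstream log transforms would corrupt sentinels.
#'
#' @param values numeric matrix with feature ids as rownames and sample ids
#'   as colnames. `NA` marks a missing (unquantified) cell.
#' @param group character or factor, one of `"tumor"`/`"normal"` per sample,
#'   in column order or named by sample id.
#' @param patient character patient id per sample, in column order or named
#'   by sample id.
#' @param scale scale the values are on: `"log2"` (proteome convention) or
#'   `"linear"` (raw abundances, metabolome convention).
#' @return an object of class `omics_matrix`: a list with elements `values`,
#'   `group` (factor), `patient` (character), `scale`.
#' @examples
#' m <- matrix(rnorm(12, 25), 2, 6,
#'   dimnames = list(c("A", "B"), paste0("S", 1:6)))
#' x <- omics_matrix(m, rep(c("tumor", "normal"), 3),
#'   rep(paste0("P", 1:3), each = 2))
#' n_pairs(x)
#' @export
omics_matrix <- function(values, group, patient, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` needs feature rownames and sample colnames")
  dup <- rownames(values)[duplicated(rownames(values))]
  if (length(dup))
    stop("duplicate feature id(s): ", paste(unique(dup), collapse = ", "))
  group <- align_sample_meta(group, colnames(values), "group")
  patient <- align_sample_meta(patient, colnames(values), "patient")
  group <- factor(as.character(group), levels = c("tumor", "normal"))
  if (anyNA(group))
    stop("`group` must be 'tumor' or 'normal' for every sample")
  for (p in unique(patient)) {
    g <- table(factor(group[patient == p], levels = c("tumor", "normal")))
    if (g[["tumor"]] != 1L || g[["normal"]] != 1L)
      stop("patient '", p, "' is not a complete tumor/normal pair")
  }
  structure(list(values = values, group = group, patient = patient,
                 scale = scale),
            class = "omics_matrix")
}

align_sample_meta <- function(x, samples, what) {
  if (!is.null(names(x))) {
    missing <- setdiff(samples, names(x))
    if (length(missing))
      stop("sample(s) absent from ", what, " map: ",
           paste(missing, collapse = ", "))
    x <- x[samples]
  } else if (length(x) != length(samples)) {
    stop("`", what, "` must have one entry per sample")
  }
  unname(x)
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix: %d features x %d samples (%d pairs), %s scale\n",
              nrow(x$values), ncol(x$values), n_pairs(x), x$scale))
  cat(sprintf("  missing cells: %d (%.1f%%)\n", sum(is.na(x$values)),
              100 * mean(is.na(x$values))))
  invisible(x)
}

#' @rdname omics_matrix
#' @param x an `omics_matrix`
#' @export
n_pairs <- function(x) length(unique(x$patient))

#' @rdname omics_matrix
#' @export
tumor_samples <- function(x) colnames(x$values)[x$group == "tumor"]

#' @rdname omics_matrix
#' @export
normal_samples <- function(x) colnames(x$values)[x$group == "normal"]

#' Values of one group, columns ordered by patient id
#' @param x an `omics_matrix`
#' @param group `"tumor"` or `"normal"`
#' @return numeric matrix (features x patients), colnames = patient ids
#' @export
group_values <- function(x, group = c("tumor", "normal")) {
  group <- match.arg(group)
  keep <- x$group == group
  v <- x$values[, keep, drop = FALSE]
  colnames(v) <- x$patient[keep]
  v[, order(colnames(v)), drop = FALSE]
}

#' Matrix on the linear (raw abundance) scale
#' @param x an `omics_matrix`
#' @return numeric matrix of raw abundances
#' @export
linear_values <- function(x) {
  if (x$scale == "linear") x$values else 2^x$values
}

#' Matrix on the log2 scale
#' @param x an `omics_matrix`
#' @return numeric matrix of log2 abundances
#' @export
log2_values <- function(x) {
  if (x$scale == "log2") x$values else log2(x$values)
}

#' Subset an omics_matrix by features
#' @param x an `omics_matrix`
#' @param features character vector of feature ids (or logical/integer index)
#' @return an `omics_matrix` with the selected rows
#' @export
subset_features <- function(x, features) {
  omics_matrix(x$values[features, , drop = FALSE], x$group, x$patient,
               scale = x$scale)
}

#' Per-feature count of valid (non-missing) values in each group
#' @param x an `omics_matrix`
#' @return integer matrix, one row per feature, columns `tumor` and `normal`
#' @export
valid_counts <- function(x) {
  cbind(tumor  = rowSums(!is.na(x$values[, x$group == "tumor", drop = FALSE])),
        normal = rowSums(!is.na(x$values[, x$group == "normal", drop = FALSE])))
}
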