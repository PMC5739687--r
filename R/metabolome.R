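#' Normalize a targeted-metabolomics matrix
#'
#' Raw peak areas are divided by the tissue mass used per sample, then by
#' the sample's internal-standard response ratio. With unit masses and
#' standards this is the identity; scaling is linear per sample.
#'
#' @param x an [omics_matrix] on the linear scale
#' @param tissue_mass named positive numeric vector (mg per sample)
#' @param internal_standard named positive numeric vector (response ratio
#'   per sample)
#' @return the normalized [omics_matrix]
#' @export
normalize_metabolome <- function(x, tissue_mass = NULL,
                                 internal_standard = NULL) {
  stopifnot(x$scale == "linear")
  v <- x$values
  apply_factor <- function(v, f, what) {
    f <- align_sample_meta(f, colnames(v), what)
    if (any(is.na(f)) || any(f <= 0)) stop("zero or missing ", what)
    sweep(v, 2L, f, "/")
  }
  if (!is.null(tissue_mass)) v <- apply_factor(v, tissue_mass, "tissue mass")
  if (!is.null(internal_standard))
    v <- apply_factor(v, internal_standard, "internal standard")
  omics_matrix(v, x$group, x$patient, scale = "linear")
}

#' Tumor/normal fold changes with below-LOQ flooring
#'
#' Values below the limit of quantification are replaced by the floor
#' before group means are formed, so that a metabolite undetectable in the
#' normal tissue still yields a finite ratio against the background level
#' (the published convention for reduced glutathione). When both group
#' means sit at the floor the fold is 1 and the row is flagged censored.
#'
#' @param x an [omics_matrix] on the linear scale
#' @param floors per-metabolite floor: named numeric vector, or `NULL` to
#'   use the global smallest positive observed value as a common floor
#' @return data.frame with `metabolite`, `mean_tumor`, `mean_normal`,
#'   `fold` (multiplicative tumor/normal), `fold_signed` (negative-fold
#'   convention for down-regulation), `censored`, `floored_normal`,
#'   `floored_tumor` (counts of floored cells)
#' @export
fold_change_with_floor <- function(x, floors = NULL) {
  stopifnot(x$scale == "linear")
  v <- x$values
  if (is.null(floors)) {
    fl <- min(v[!is.na(v) & v > 0])
    floors <- stats::setNames(rep(fl, nrow(v)), rownames(v))
  }
  missing_floor <- setdiff(rownames(v), names(floors))
  if (length(missing_floor))
    stop("no floor defined for metabolite(s): ",
         paste(utils::head(missing_floor, 3), collapse = ", "))
  if (any(floors <= 0)) stop("floors must be positive")
  fl <- floors[rownames(v)]
  below <- sweep(v, 1L, fl, "<")
  floored <- pmax(v, matrix(fl, nrow(v), ncol(v)))
  tum <- floored[, x$group == "tumor", drop = FALSE]
  nor <- floored[, x$group == "normal", drop = FALSE]
  below_t <- below[, x$group == "tumor", drop = FALSE]
  below_n <- below[, x$group == "normal", drop = FALSE]
  mt <- rowMeans(tum, na.rm = TRUE)
  mn <- rowMeans(nor, na.rm = TRUE)
  censored <- abs(mt - fl) < 1e-12 * fl & abs(mn - fl) < 1e-12 * fl
  fold <- ifelse(censored, 1, mt / mn)
  data.frame(metabolite = rownames(v), mean_tumor = unname(mt),
             mean_normal = unname(mn), fold = unname(fold),
             fold_signed = ratio_to_signed(unname(fold)),
             censored = unname(censored),
             floored_normal = unname(rowSums(below_n, na.rm = TRUE)),
             floored_tumor = unname(rowSums(below_t, na.rm = TRUE)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply per-metabolite floors to a linear-scale matrix
#' @param x an [omics_matrix] on the linear scale
#' @param floors named numeric vector of per-metabolite floors (or `NULL`
#'   for the global minimum positive value)
#' @return the floored [omics_matrix]
#' @export
floor_matrix <- function(x, floors = NULL) {
  stopifnot(x$scale == "linear")
  v <- x$values
  if (is.null(floors)) floors <- stats::setNames(
    rep(min(v[!is.na(v) & v > 0]), nrow(v)), rownames(v))
  fl <- floors[rownames(v)]
  if (anyNA(fl)) stop("floors missing for some metabolites")
  omics_matrix(pmax(v, matrix(fl, nrow(v), ncol(v))), x$group, x$patient,
               scale = "linear")
}

#' Full metabolome differential stage
#'
#' Floors the normalized matrix, log2-transforms it, and runs the Welch
#' two-sample test with BH correction at `fdr_level`, additionally gated
#' at nominal `p < p_cutoff` (the metabolome significance rule). Floored
#' fold changes are merged in.
#'
#' @param x normalized [omics_matrix] on the linear scale
#' @param floors per-metabolite floors, see [fold_change_with_floor()]
#' @param fdr_level BH FDR level
#' @param p_cutoff nominal p gate
#' @return data.frame: the [differential_test()] columns plus `fold`,
#'   `fold_signed`, `censored`
#' @export
metabolome_differential <- function(x, floors = NULL, fdr_level = 0.05,
                                    p_cutoff = 0.01) {
  floored <- floor_matrix(x, floors)
  logged <- omics_matrix(log2(floored$values), x$group, x$patient, "log2")
  res <- differential_test(logged, fdr_level = fdr_level,
                           p_cutoff = p_cutoff)
  folds <- fold_change_with_floor(x, floors)
  merge(res, folds[, c("metabolite", "fold", "fold_signed", "censored")],
        by.x = "feature_id", by.y = "metabolite", sort = FALSE)
}

#' Significant-metabolite report table
#'
#' The publication-style summary: significant metabolites sorted by signed
#' fold change descending, with compound-class labels and up/down counts.
#'
#' @param rows output of [metabolome_differential()]
#' @param groups optional data.frame with `metabolite`, `group` compound
#'   classes
#' @return data.frame with `metabolite`, `p_value`, `fold_signed`,
#'   `group`; counts are in `attr(, "n_up")` / `attr(, "n_down")`
#' @export
volcano_table <- function(rows, groups = NULL) {
  sig <- rows[rows$significant, , drop = FALSE]
  out <- data.frame(metabolite = sig$feature_id, p_value = sig$p_value,
                    fold_signed = sig$fold_signed,
                    stringsAsFactors = FALSE)
  out$group <- if (!is.null(groups))
    groups$group[match(out$metabolite, groups$metabolite)]
  else rep(NA_character_, nrow(out))
  out <- out[order(-out$fold_signed), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_up") <- sum(sig$log2fc > 0)
  attr(out, "n_down") <- sum(sig$log2fc < 0)
  out
}
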