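#' Validity filter on quantified features
#'
#' Two published filter modes for a 6+6 paired cohort, generalized to the
#' matrix' group size n:
#' \describe{
#'   \item{`each_group_min3`}{keep features with at least 3 valid values in
#'     each group; no imputation is implied.}
#'   \item{`one_group_full6`}{keep features fully observed (n of n valid) in
#'     at least one group; the missing cells of the other group are meant to
#'     be filled by [impute_gaussian()], rescuing the most regulated
#'     proteins whose abundance fell below the detection limit in one
#'     tissue.}
#' }
#'
#' @param x an [omics_matrix]
#' @param mode filter mode
#' @param min_valid minimum valid count per group for `each_group_min3`
#' @return the filtered [omics_matrix]
#' @export
filter_min_valid <- function(x, mode = c("each_group_min3", "one_group_full6"),
                             min_valid = 3L) {
  mode <- match.arg(mode)
  counts <- valid_counts(x)
  n_t <- sum(x$group == "tumor"); n_n <- sum(x$group == "normal")
  keep <- switch(mode,
    each_group_min3 = counts[, "tumor"] >= min_valid &
                      counts[, "normal"] >= min_valid,
    one_group_full6 = counts[, "tumor"] == n_t | counts[, "normal"] == n_n)
  subset_features(x, which(keep))
}

#' Per-patient compartment mass ratios (mitochondrial vs non-mitochondrial)
#'
#' For each patient, the ratio of total raw-scale abundance (tumor over
#' normal), computed separately over the mitochondrial and the
#' non-mitochondrial compartment. Sums are taken on the linear scale with
#' missing cells contributing 0, matching the "total abundance" reading of
#' mitochondrial mass; the ratio is scale-invariant per patient pair.
#'
#' @param x an [omics_matrix]
#' @param annotation data.frame with columns `feature_id` and `is_mito`
#'   (0/1 or logical). Features absent from the annotation count as
#'   non-mitochondrial (the annotation is a positive list).
#' @return list with `ratios` (data.frame: `patient`, `compartment`,
#'   `ratio`) and `summary` (data.frame: `compartment`, `mean`, `sd`)
#' @export
mito_mass_ratio <- function(x, annotation) {
  v <- linear_values(x)
  is_mito <- rownames(v) %in%
    annotation$feature_id[as.logical(annotation$is_mito)]
  tum <- group_values(omics_matrix(v, x$group, x$patient, "linear"), "tumor")
  nor <- group_values(omics_matrix(v, x$group, x$patient, "linear"), "normal")
  compart <- list(mito = is_mito, non_mito = !is_mito)
  rows <- list()
  for (cp in names(compart)) {
    sel <- compart[[cp]]
    ts <- colSums(tum[sel, , drop = FALSE], na.rm = TRUE)
    ns <- colSums(nor[sel, , drop = FALSE], na.rm = TRUE)
    zero <- names(ns)[ns == 0]
    if (length(zero))
      stop("compartment '", cp, "' has zero total abundance in normal ",
           "sample of patient ", zero[1])
    rows[[cp]] <- data.frame(patient = colnames(tum), compartment = cp,
                             ratio = unname(ts / ns),
                             stringsAsFactors = FALSE)
  }
  ratios <- do.call(rbind, c(rows, make.row.names = FALSE))
  summary <- do.call(rbind, lapply(names(compart), function(cp) {
    r <- ratios$ratio[ratios$compartment == cp]
    data.frame(compartment = cp, mean = mean(r), sd = stats::sd(r))
  }))
  list(ratios = ratios, summary = summary)
}

#' Compartment-stratified regulation thresholds and calls
#'
#' Features are split into mitochondrial and non-mitochondrial sets; within
#' each set a feature counts as regulated only if its log2 fold change
#' exceeds one standard deviation from the set mean (up if
#' `log2fc > mean + sd`, down if `log2fc < mean - sd`, otherwise none). A
#' degenerate set with zero SD yields no calls.
#'
#' @param log2fc named numeric vector of per-feature log2 fold changes
#' @param annotation data.frame with `feature_id`, `is_mito`
#' @param min_size minimum features per compartment (error below)
#' @return list with `thresholds` (data.frame: `compartment`,
#'   `mean_log2fc`, `sd_log2fc`, `up_cutoff`, `down_cutoff`) and `calls`
#'   (data.frame: `feature_id`, `compartment`, `log2fc`, `regulation`)
#' @export
compartment_stats <- function(log2fc, annotation, min_size = 10L) {
  if (is.null(names(log2fc))) stop("`log2fc` must be named by feature id")
  is_mito <- names(log2fc) %in%
    annotation$feature_id[as.logical(annotation$is_mito)]
  compart <- ifelse(is_mito, "mito", "non_mito")
  thr <- list(); calls <- list()
  for (cp in c("mito", "non_mito")) {
    fc <- log2fc[compart == cp]
    if (length(fc) < min_size)
      stop("compartment '", cp, "' has fewer than ", min_size, " features")
    m <- mean(fc); s <- stats::sd(fc)
    thr[[cp]] <- data.frame(compartment = cp, mean_log2fc = m,
                            sd_log2fc = s, up_cutoff = m + s,
                            down_cutoff = m - s)
    reg <- if (s == 0) rep("none", length(fc)) else
      ifelse(fc > m + s, "up", ifelse(fc < m - s, "down", "none"))
    calls[[cp]] <- data.frame(feature_id = names(fc), compartment = cp,
                              log2fc = unname(fc), regulation = reg,
                              stringsAsFactors = FALSE)
  }
  list(thresholds = do.call(rbind, c(thr, make.row.names = FALSE)),
       calls = do.call(rbind, c(calls, make.row.names = FALSE)))
}

#' OXPHOS complex-level summary of log2 fold changes
#'
#' Median log2 fold change per respiratory-chain complex (CI..CIV, ATPase =
#' CV), separately for structural subunits and assembly factors (assembly
#' factors are not part of the final complex and are summarized apart).
#' The qualitative verdict `"CI_down_rest_up"` is attached when the CI
#' subunit median is negative while every other quantified complex has a
#' positive subunit median -- the selective complex-I loss signature.
#'
#' @param log2fc named numeric vector of per-feature log2 fold changes
#' @param annotation data.frame with `feature_id`, `complex` (CI..CV or
#'   empty) and `is_assembly` (0/1)
#' @return data.frame with `complex`, `n_subunits`, `median_subunit_log2fc`,
#'   `n_assembly`, `median_assembly_log2fc`; complexes with no quantified
#'   subunit are reported with `NA` medians. The verdict is in
#'   `attr(, "verdict")` (`NA` if the signature does not hold).
#' @export
oxphos_complex_summary <- function(log2fc, annotation) {
  if (is.null(names(log2fc))) stop("`log2fc` must be named by feature id")
  cx_levels <- c("CI", "CII", "CIII", "CIV", "CV")
  ann <- annotation[!is.na(annotation$complex) &
                      annotation$complex %in% cx_levels, ]
  out <- do.call(rbind, lapply(cx_levels, function(cx) {
    sub <- ann$feature_id[ann$complex == cx & !as.logical(ann$is_assembly)]
    asb <- ann$feature_id[ann$complex == cx & as.logical(ann$is_assembly)]
    sub <- intersect(sub, names(log2fc)); asb <- intersect(asb, names(log2fc))
    data.frame(complex = cx, n_subunits = length(sub),
               median_subunit_log2fc =
                 if (length(sub)) stats::median(log2fc[sub]) else NA_real_,
               n_assembly = length(asb),
               median_assembly_log2fc =
                 if (length(asb)) stats::median(log2fc[asb]) else NA_real_)
  }))
  ci <- out$median_subunit_log2fc[out$complex == "CI"]
  rest <- out$median_subunit_log2fc[out$complex != "CI"]
  rest <- rest[!is.na(rest)]
  verdict <- if (!is.na(ci) && length(rest) && ci < 0 && all(rest > 0))
    "CI_down_rest_up" else NA_character_
  attr(out, "verdict") <- verdict
  out
}

#' Ranking scores for enrichment analysis from group-averaged abundances
#'
#' Per feature, log2 of the tumor group mean over the normal group mean of
#' raw-scale abundances (groups averaged first, then log-transformed).
#'
#' @param x an [omics_matrix]
#' @return named numeric vector of ranking scores
#' @export
ranking_from_matrix <- function(x) {
  v <- linear_values(x)
  tm <- rowMeans(v[, x$group == "tumor", drop = FALSE], na.rm = TRUE)
  nm <- rowMeans(v[, x$group == "normal", drop = FALSE], na.rm = TRUE)
  log2(tm / nm)
}
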