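#' Benjamini-Hochberg step-up adjusted p-values
#'
#' Thin validating wrapper around `stats::p.adjust(method = "BH")`:
#' q_i = min over j with p_(j) >= p_(i) of p_(j) * m / rank(j), capped at 1,
#' returned in the original input order.
#'
#' @param p numeric vector of p-values in \[0,1\]
#' @return q-values in input order
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0,1] and be non-missing")
  stats::p.adjust(p, method = "BH")
}

welch_row <- function(xt, xn) {
  mt <- mean(xt); mn <- mean(xn)
  vt <- stats::var(xt); vn <- stats::var(xn)
  tol <- 1e-12 * max(1, abs(mt), abs(mn))
  if (sqrt(vt / length(xt) + vn / length(xn)) <= tol) {
    # degenerate: (near-)zero variance in both groups
    if (abs(mt - mn) <= tol)
      return(list(t = 0, df = NA_real_, p = 1))
    return(list(t = sign(mt - mn) * Inf, df = NA_real_, p = 0))
  }
  tt <- stats::t.test(xt, xn, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

#' Per-feature Welch two-sample differential test with BH correction
#'
#' For every feature with at least two valid values per group, a Welch
#' (unequal-variance) two-sample t-test on log2 values, tumor vs normal;
#' multiple testing by Benjamini-Hochberg. A feature is significant when
#' `q <= fdr_level` and, if `p_cutoff` is given, additionally
#' `p < p_cutoff` (the gate used for the metabolome stage). Features with
#' fewer than two valid values in a group are skipped (reported via the
#' `"skipped"` attribute). Rows with zero variance in both groups and equal
#' means yield p = 1, not an error.
#'
#' @param x an [omics_matrix] on the log2 scale (linear input is logged)
#' @param fdr_level BH FDR significance level
#' @param p_cutoff optional additional nominal p gate (`NULL` to disable)
#' @param paired use a paired t-test across patient pairs instead of the
#'   default unpaired two-sample test
#' @return data.frame with one row per tested feature: `feature_id`,
#'   `n_tumor`, `n_normal`, `mean_tumor`, `mean_normal`, `log2fc`
#'   (`mean_tumor - mean_normal`), `t_statistic`, `df`, `p_value`,
#'   `q_value`, `significant`, `regulation` (up/down/none)
#' @export
differential_test <- function(x, fdr_level = 0.05, p_cutoff = NULL,
                              paired = FALSE) {
  v <- log2_values(x)
  tum <- v[, x$group == "tumor", drop = FALSE]
  nor <- v[, x$group == "normal", drop = FALSE]
  colnames(tum) <- x$patient[x$group == "tumor"]
  colnames(nor) <- x$patient[x$group == "normal"]
  nor <- nor[, colnames(tum), drop = FALSE]
  ok <- rowSums(!is.na(tum)) >= 2L & rowSums(!is.na(nor)) >= 2L
  skipped <- rownames(v)[!ok]
  if (length(skipped))
    message(length(skipped), " feature(s) skipped (<2 valid values in a group)")
  rows <- lapply(rownames(v)[ok], function(f) {
    xt <- tum[f, ][!is.na(tum[f, ])]
    xn <- nor[f, ][!is.na(nor[f, ])]
    if (paired) {
      both <- intersect(names(xt), names(xn))
      d <- xt[both] - xn[both]
      r <- welch_row(d, rep(0, length(d)))  # one-sample t via two-sample on zeros
      r <- tryCatch({
        tt <- stats::t.test(xt[both], xn[both], paired = TRUE)
        list(t = unname(tt$statistic), df = unname(tt$parameter),
             p = tt$p.value)
      }, error = function(e) r)
    } else {
      r <- welch_row(xt, xn)
    }
    data.frame(feature_id = f, n_tumor = length(xt), n_normal = length(xn),
               mean_tumor = mean(xt), mean_normal = mean(xn),
               log2fc = mean(xt) - mean(xn),
               t_statistic = r$t, df = r$df, p_value = r$p,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  if (nrow(out)) {
    out$q_value <- bh_adjust(out$p_value)
    out$significant <- out$q_value <= fdr_level
    if (!is.null(p_cutoff)) out$significant <- out$significant &
        out$p_value < p_cutoff
    out$regulation <- ifelse(!out$significant, "none",
                             ifelse(out$log2fc > 0, "up", "down"))
  }
  attr(out, "skipped") <- skipped
  out
}

#' Left-censored Gaussian imputation of missing values
#'
#' Standard MNAR replacement for label-free proteomics: per sample column,
#' missing log2 intensities are drawn from a normal distribution narrowed
#' to `width_factor` times the column SD and shifted down by
#' `downshift_factor` column SDs from the column mean. Observed cells are
#' never altered; the draw is deterministic for a fixed seed.
#'
#' @param x an [omics_matrix] on the log2 scale
#' @param width_factor SD shrink factor of the imputation distribution
#' @param downshift_factor downshift in units of the column SD
#' @param seed integer seed
#' @return an [omics_matrix] without missing values
#' @export
impute_gaussian <- function(x, width_factor = 0.3, downshift_factor = 1.8,
                            seed = 1L) {
  stopifnot(x$scale == "log2")
  v <- x$values
  withr::with_seed(seed, {
    for (j in seq_len(ncol(v))) {
      miss <- is.na(v[, j])
      if (!any(miss)) next
      obs <- v[!miss, j]
      if (length(obs) < 2L)
        stop("column '", colnames(v)[j],
             "' has too few observed values to estimate moments")
      v[miss, j] <- stats::rnorm(sum(miss),
                                 mean = mean(obs) - downshift_factor * stats::sd(obs),
                                 sd = width_factor * stats::sd(obs))
    }
  })
  omics_matrix(v, x$group, x$patient, scale = "log2")
}

#' Permutation p-value with the add-one estimator
#'
#' One-sided (or two-sided) Monte-Carlo p-value of an observed statistic
#' against null draws: for direction `"lower"`,
#' p = (1 + #\{null <= observed\}) / (1 + n_draws). The add-one form avoids
#' p = 0.
#'
#' @param observed observed statistic
#' @param null_draws numeric vector of null statistics (>= 100 draws
#'   recommended)
#' @param direction `"lower"` (observed smaller than null is extreme),
#'   `"greater"`, or `"two_sided"` (absolute deviation from the null mean)
#' @return p-value in (0, 1\]
#' @export
permutation_pvalue <- function(observed,
                               null_draws,
                               direction = c("lower", "greater", "two_sided")) {
  direction <- match.arg(direction)
  if (!length(null_draws)) stop("empty null distribution")
  n <- length(null_draws)
  k <- switch(direction,
              lower = sum(null_draws <= observed),
              greater = sum(null_draws >= observed),
              two_sided = {
                ctr <- mean(null_draws)
                sum(abs(null_draws - ctr) >= abs(observed - ctr))
              })
  (1 + k) / (1 + n)
}
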