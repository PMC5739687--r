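#' Heteroplasmic fraction with Wilson 95% interval
#'
#' HF = alt / (alt + ref) from allele depths, with the Wilson score
#' confidence interval (which stays inside \[0,1\] and contains the point
#' estimate even at the boundaries).
#'
#' @param alt_count,ref_count allele depths (vectors allowed); total depth
#'   must be at least 1
#' @param conf confidence level
#' @return data.frame with `hf`, `lower`, `upper`, `depth`
#' @export
heteroplasmic_fraction <- function(alt_count, ref_count, conf = 0.95) {
  n <- alt_count + ref_count
  if (any(is.na(n)) || any(n < 1))
    stop("zero or missing depth: alt + ref must be >= 1")
  p <- alt_count / n
  z <- stats::qnorm(1 - (1 - conf) / 2)
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  # clamp against floating-point drift at p = 0 or 1, where an interval
  # endpoint coincides with the point estimate
  data.frame(hf = p, lower = pmax(0, pmin(center - half, p)),
             upper = pmin(1, pmax(center + half, p)), depth = n)
}

#' Germline/somatic classification from paired heteroplasmic fractions
#'
#' A variant is somatic when the normal-tissue HF is below the detection
#' limit (or the variant is absent from the normal tissue, `NA`); germline
#' when present in both tissues with concordant HF (absolute difference at
#' most `hf_tolerance`); otherwise unclassified.
#'
#' @param hf_tumor,hf_normal heteroplasmic fractions; `hf_normal = NA`
#'   means not detected in the normal tissue
#' @param hf_tolerance concordance tolerance for the germline call
#' @param detection_limit minimum HF regarded as present
#' @return character vector in `{germline, somatic, unclassified}`
#' @export
classify_origin <- function(hf_tumor, hf_normal, hf_tolerance = 0.10,
                            detection_limit = 0.005) {
  stopifnot(length(hf_tumor) == length(hf_normal))
  ifelse(is.na(hf_normal) | hf_normal < detection_limit, "somatic",
         ifelse(abs(hf_tumor - hf_normal) <= hf_tolerance, "germline",
                "unclassified"))
}

#' Pathogenicity prioritization of mtDNA variants
#'
#' Implements the published in-silico prioritization: haplogroup-defining
#' variants are excluded outright; a remaining variant is prioritized when
#' its nucleotide variability is below the variability cutoff (default
#' 0.0026) AND its disease score exceeds the class-specific threshold
#' (0.43 for protein-coding non-synonymous and stop-gain, 0.35 for tRNA,
#' 0.60 for rRNA). Variants of unscored classes (synonymous, D-loop,
#' other non-coding) are never prioritized. The rule is monotone: lowering
#' variability or raising the score never turns a prioritized variant into
#' an excluded one.
#'
#' @param variants data.frame with columns `functional_class`,
#'   `haplogroup_defining`, `nucleotide_variability`, `disease_score`
#'   (the RNA prediction score plays this role for tRNA/rRNA variants)
#' @param thresholds list with `variability_cutoff`, `ds_nonsyn`,
#'   `ds_trna`, `ds_rrna` (defaults from [run_config()])
#' @return the input with added columns `prioritized` (logical) and
#'   `reasons` (semicolon-joined gate results)
#' @export
prioritize_mt <- function(variants, thresholds = run_config()$mtdna) {
  need <- c("functional_class", "haplogroup_defining",
            "nucleotide_variability", "disease_score")
  miss <- setdiff(need, names(variants))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  class_thr <- c(nonsynonymous = thresholds$ds_nonsyn,
                 stop_gain = thresholds$ds_nonsyn,
                 tRNA = thresholds$ds_trna,
                 rRNA = thresholds$ds_rrna)
  n <- nrow(variants)
  prioritized <- logical(n); reasons <- character(n)
  for (i in seq_len(n)) {
    cls <- variants$functional_class[i]
    if (isTRUE(as.logical(variants$haplogroup_defining[i]))) {
      reasons[i] <- "haplogroup-defining (excluded)"
      next
    }
    if (!cls %in% names(class_thr)) {
      reasons[i] <- paste0("class '", cls, "' not scored")
      next
    }
    v <- variants$nucleotide_variability[i]
    s <- variants$disease_score[i]
    if (is.na(s)) stop("missing disease_score for a ", cls, " variant")
    if (is.na(v)) stop("missing nucleotide_variability for a ", cls, " variant")
    thr <- class_thr[[cls]]
    g1 <- v < thresholds$variability_cutoff
    g2 <- s > thr
    prioritized[i] <- g1 && g2
    reasons[i] <- paste0(
      "variability ", signif(v, 3), if (g1) " < " else " >= ",
      thresholds$variability_cutoff, if (g1) " (pass)" else " (fail)", "; ",
      "disease score ", signif(s, 3), if (g2) " > " else " <= ", thr,
      if (g2) " (pass)" else " (fail)")
  }
  variants$prioritized <- prioritized
  variants$reasons <- reasons
  variants
}

#' Tumor/normal mtDNA copy ratio from coverage summaries
#'
#' Per sample, the mitochondrial dose is the mean mtDNA coverage divided
#' by the mean nuclear coverage; per patient pair, the copy ratio is the
#' tumor dose over the normal dose. The cohort mean and SD are reported.
#'
#' @param coverage data.frame with columns `patient`, `tissue`
#'   (`"tumor"`/`"normal"`), `mt_coverage`, `nuclear_coverage`
#' @return list with `pairs` (data.frame: `patient`, `ratio`), `mean`,
#'   `sd`
#' @export
mtdna_copy_ratio <- function(coverage) {
  need <- c("patient", "tissue", "mt_coverage", "nuclear_coverage")
  miss <- setdiff(need, names(coverage))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(coverage$nuclear_coverage <= 0))
    stop("zero nuclear coverage in sample of patient ",
         coverage$patient[coverage$nuclear_coverage <= 0][1])
  if (any(coverage$mt_coverage < 0)) stop("negative mt coverage")
  dose <- coverage$mt_coverage / coverage$nuclear_coverage
  pats <- sort(unique(coverage$patient))
  ratio <- vapply(pats, function(p) {
    d_t <- dose[coverage$patient == p & coverage$tissue == "tumor"]
    d_n <- dose[coverage$patient == p & coverage$tissue == "normal"]
    if (length(d_t) != 1L || length(d_n) != 1L)
      stop("patient '", p, "' must have exactly one tumor and one normal sample")
    d_t / d_n
  }, numeric(1))
  pairs <- data.frame(patient = pats, ratio = unname(ratio),
                      stringsAsFactors = FALSE)
  list(pairs = pairs, mean = mean(pairs$ratio), sd = stats::sd(pairs$ratio))
}
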