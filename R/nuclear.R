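SPECTRUM_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Six-class (pyrimidine-reference) substitution spectrum
#'
#' Collapses the 12 substitution types to the six strand-symmetric
#' pyrimidine-reference classes: purine-reference substitutions are mapped
#' to the reverse complement (G>A counts as C>T, A>G as T>C, ...). Indels
#' (ref or alt not a single base, or `-`) are skipped and counted in the
#' `"skipped"` attribute.
#'
#' @param variants data.frame with columns `ref`, `alt`
#' @return named integer vector over the six classes, with attributes
#'   `total` (SNVs counted) and `skipped` (indels)
#' @export
spectrum_6class <- function(variants) {
  ref <- toupper(as.character(variants$ref))
  alt <- toupper(as.character(variants$alt))
  is_snv <- ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  skipped <- sum(!is_snv)
  ref <- ref[is_snv]; alt <- alt[is_snv]
  if (any(ref == alt)) stop("ref == alt is not a substitution")
  flip <- ref %in% c("A", "G")
  ref[flip] <- unname(MT_COMPLEMENT[ref[flip]])
  alt[flip] <- unname(MT_COMPLEMENT[alt[flip]])
  cls <- factor(paste0(ref, ">", alt), levels = SPECTRUM_CLASSES)
  counts <- table(cls)
  out <- stats::setNames(as.integer(counts), SPECTRUM_CLASSES)
  attr(out, "total") <- sum(out)
  attr(out, "skipped") <- skipped
  out
}

#' Transition/transversion ratio of a six-class spectrum
#'
#' (C>T + T>C) / (C>A + C>G + T>A + T>G). Undefined (error) when the
#' spectrum holds no transversions.
#'
#' @param counts named counts over the six classes (as from
#'   [spectrum_6class()])
#' @return the Ti/Tv ratio
#' @export
titv <- function(counts) {
  counts <- counts[SPECTRUM_CLASSES]
  if (anyNA(counts)) stop("counts must cover the six spectrum classes")
  ti <- counts[["C>T"]] + counts[["T>C"]]
  tv <- sum(counts[c("C>A", "C>G", "T>A", "T>G")])
  if (tv == 0) stop("no transversions: Ti/Tv undefined")
  unname(ti / tv)
}

EFFECT_CLASSES <- c("silent", "missense", "nonsense",
                    "frameshift_del", "frameshift_ins")

#' Per-patient mutation burden and effect-class totals
#'
#' The burden counts tumor-specific non-silent variants per patient
#' (silent variants are excluded); the cohort median and the totals per
#' effect class are reported.
#'
#' @param variants data.frame with columns `patient`, `effect_class`
#'   (silent / missense / nonsense / frameshift_del / frameshift_ins)
#' @return list with `per_patient` (data.frame: `patient`, `burden`),
#'   `median_burden`, `class_totals` (named, all classes), `total`
#' @export
burden_stats <- function(variants) {
  cls <- as.character(variants$effect_class)
  bad <- setdiff(unique(cls), EFFECT_CLASSES)
  if (length(bad))
    stop("unknown effect class(es): ", paste(bad, collapse = ", "))
  totals <- vapply(EFFECT_CLASSES,
                   function(k) sum(cls == k), integer(1))
  nonsilent <- variants[cls != "silent", , drop = FALSE]
  pats <- sort(unique(as.character(variants$patient)))
  burden <- vapply(pats, function(p)
    sum(nonsilent$patient == p), integer(1))
  list(per_patient = data.frame(patient = pats, burden = unname(burden),
                                stringsAsFactors = FALSE),
       median_burden = stats::median(burden),
       class_totals = totals,
       total = sum(totals))
}

#' Exact binomial enrichment test per spectrum class
#'
#' Two-sided exact binomial test of each observed class count against the
#' expectation under baseline class probabilities (default: uniform over
#' the six classes).
#'
#' @param counts named counts over the six classes
#' @param baseline_probs baseline probabilities (must sum to 1)
#' @return data.frame with `class`, `observed`, `expected`, `p_value`,
#'   `direction` (enriched/depleted/none)
#' @export
class_enrichment_test <- function(counts, baseline_probs = rep(1 / 6, 6)) {
  counts <- counts[SPECTRUM_CLASSES]
  if (anyNA(counts)) stop("counts must cover the six spectrum classes")
  if (abs(sum(baseline_probs) - 1) > 1e-8)
    stop("baseline probabilities must sum to 1")
  n <- sum(counts)
  if (n == 0) stop("empty spectrum")
  p <- vapply(seq_along(SPECTRUM_CLASSES), function(i)
    stats::binom.test(counts[[i]], n, baseline_probs[i])$p.value, numeric(1))
  expected <- n * baseline_probs
  data.frame(class = SPECTRUM_CLASSES,
             observed = as.integer(counts), expected = expected,
             p_value = p,
             direction = ifelse(as.integer(counts) > expected, "enriched",
                                ifelse(as.integer(counts) < expected,
                                       "depleted", "none")),
             stringsAsFactors = FALSE)
}

#' Genes covered by copy-number loss segments
#'
#' Interval overlap of gene midpoints with BED-convention (0-based
#' half-open) segments; a gene is lost for a patient when its midpoint lies
#' in one of that patient's loss segments.
#'
#' @param segments data.frame with `chrom`, `start`, `end`, `patient`
#' @param gene_positions data.frame with `feature_id`, `chrom`, `midpoint`
#' @return data.frame with `feature_id`, `patient`
#' @export
cnv_loss_genes <- function(segments, gene_positions) {
  hits <- lapply(seq_len(nrow(segments)), function(i) {
    s <- segments[i, ]
    g <- gene_positions[gene_positions$chrom == s$chrom &
                          gene_positions$midpoint >= s$start &
                          gene_positions$midpoint < s$end, , drop = FALSE]
    if (!nrow(g)) return(NULL)
    data.frame(feature_id = g$feature_id, patient = s$patient,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(feature_id = character(0), patient = character(0))
  unique(out)
}

#' Permutation test of the CNV gene-dose effect on protein abundance
#'
#' Tests whether proteins encoded in lost segments are lower-abundant than
#' expected: the observed statistic is the mean log2 fold change over
#' quantified loss genes; the null is the mean of `n_perm` random
#' equal-size gene draws (without replacement) from all quantified
#' features; the one-sided p-value ("lower than random") uses the add-one
#' permutation estimator.
#'
#' @param log2fc named numeric vector of per-feature log2 fold changes
#' @param loss_genes character vector of gene/feature ids under loss
#' @param n_perm number of permutations (>= 100)
#' @param seed integer seed
#' @return list with `observed`, `null` (numeric vector), `p_value`,
#'   `n_genes` (quantified loss genes used)
#' @export
cnv_dose_test <- function(log2fc, loss_genes, n_perm = 1000L, seed = 1L) {
  if (is.null(names(log2fc))) stop("`log2fc` must be named by feature id")
  if (n_perm < 100L) stop("n_perm must be >= 100")
  genes <- intersect(unique(loss_genes), names(log2fc))
  if (!length(genes))
    stop("no loss gene is among the quantified features")
  observed <- mean(log2fc[genes])
  k <- length(genes)
  null <- withr::with_seed(seed, vapply(seq_len(n_perm), function(b)
    mean(sample(log2fc, k)), numeric(1)))
  list(observed = observed, null = null,
       p_value = permutation_pvalue(observed, null, "lower"),
       n_genes = k)
}
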