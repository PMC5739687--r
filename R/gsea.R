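#' Weighted running-sum enrichment score
#'
#' Kolmogorov-Smirnov-like statistic over a ranked feature list: walking
#' down the ranking, the running sum increases by
#' `|score|^weight / sum(|score of hits|^weight)` at set members and
#' decreases by `1/(N - n_hits)` at non-members; the enrichment score (ES)
#' is the signed maximum deviation from zero. Ties in the ranking are
#' broken by feature id so the statistic is deterministic.
#'
#' @param scores named numeric vector of ranking scores (any order; sorted
#'   decreasing internally)
#' @param gene_set character vector of member feature ids (must intersect
#'   the ranking)
#' @param weight weight exponent on `|score|` (0 = classic unweighted KS,
#'   1 = classic GSEA default)
#' @return list with `es`, `running` (the N-step running sum) and
#'   `hit_positions`
#' @export
enrichment_score <- function(scores, gene_set, weight = 1) {
  s <- sort_ranking(scores)
  hits <- names(s) %in% gene_set
  if (!any(hits)) stop("gene set is disjoint from the ranking")
  w <- abs(s)^weight
  w[!hits] <- 0
  nr <- sum(w[hits])
  if (nr == 0) { w[hits] <- 1; nr <- sum(hits) }  # all hit scores zero
  n_miss <- sum(!hits)
  inc <- ifelse(hits, w / nr, if (n_miss) -1 / n_miss else 0)
  running <- cumsum(inc)
  mx <- max(running); mn <- min(0, running)
  es <- if (mx >= -mn) mx else mn   # ties resolve to the positive deviation
  list(es = es, running = running, hit_positions = which(hits))
}

sort_ranking <- function(scores) {
  if (is.null(names(scores))) stop("ranking scores must be named")
  if (anyNA(scores)) stop("ranking scores must not contain NA")
  scores[order(-scores, names(scores))]
}

# ES from sorted hit positions only (O(k)); equivalent to the running-sum
# definition, used for the permutation null.
es_at_positions <- function(pos, w, n_total) {
  k <- length(pos)
  nr <- sum(w)
  if (nr == 0) { w <- rep(1, k); nr <- k }
  n_miss <- n_total - k
  if (n_miss == 0) return(1)
  hitcum <- cumsum(w) / nr
  miss_before <- (pos - seq_len(k)) / n_miss
  top <- hitcum - miss_before            # running sum just after each hit
  bottom <- c(0, hitcum[-k]) - miss_before  # just before each hit
  mx <- max(top); mn <- min(0, bottom)
  if (mx >= -mn) mx else mn
}

#' Gene set enrichment with gene-set permutation NES and FDR
#'
#' Runs the weighted running-sum statistic for every set of at least
#' `min_size` quantified members, builds a null by drawing random member
#' sets of equal size from the ranking (`n_perm` times), and reports, per
#' set: the normalized enrichment score NES = ES / mean(|null ES| of the
#' same sign), a one-sided nominal p within the same-sign null (add-one
#' estimator), and a permutation FDR q from the pooled normalized null.
#' Gene-set (not phenotype) permutation is used because a 6+6 cohort
#' offers too few phenotype permutations.
#'
#' @param scores named numeric vector of ranking scores (e.g. from
#'   [ranking_from_matrix()])
#' @param sets named list of character vectors (e.g. from [read_gmt()])
#' @param n_perm number of permutations (>= 100)
#' @param seed integer seed
#' @param min_size minimum number of quantified members per set
#' @param weight weight exponent, see [enrichment_score()]
#' @param p_cutoff,fdr_cutoff significance gates on nominal p and FDR q
#' @return data.frame with `set`, `size`, `es`, `nes`, `p_value`,
#'   `fdr_q`, `significant`, `direction`; excluded (undersized) sets are
#'   listed in `attr(, "excluded")`
#' @export
gsea_run <- function(scores, sets, n_perm = 1000L, seed = 1L, min_size = 5L,
                     weight = 1, p_cutoff = 0.01, fdr_cutoff = 0.15) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  s <- sort_ranking(scores)
  n <- length(s)
  w_all <- abs(s)^weight
  sizes <- vapply(sets, function(g) sum(names(s) %in% g), integer(1))
  excluded <- names(sets)[sizes < min_size]
  keep <- names(sets)[sizes >= min_size]
  if (!length(keep)) {
    out <- data.frame(set = character(0))
    attr(out, "excluded") <- excluded
    return(out)
  }
  es_obs <- vapply(keep, function(nm)
    es_at_positions(which(names(s) %in% sets[[nm]]),
                    w_all[names(s) %in% sets[[nm]]], n), numeric(1))
  null_es <- withr::with_seed(seed, {
    lapply(keep, function(nm) {
      k <- sizes[[nm]]
      vapply(seq_len(n_perm), function(b) {
        pos <- sort(sample.int(n, k))
        es_at_positions(pos, w_all[pos], n)
      }, numeric(1))
    })
  })
  names(null_es) <- keep
  norm_one <- function(es, null) {
    mpos <- mean(null[null >= 0]); mneg <- mean(abs(null[null < 0]))
    if (es >= 0) {
      if (!is.finite(mpos) || mpos == 0) return(NA_real_)
      es / mpos
    } else {
      if (!is.finite(mneg) || mneg == 0) return(NA_real_)
      -abs(es) / mneg
    }
  }
  nes <- mapply(norm_one, es_obs, null_es)
  pval <- mapply(function(es, null) {
    same <- if (es >= 0) null[null >= 0] else null[null < 0]
    if (!length(same)) return(1)
    (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
  }, es_obs, null_es)
  # pooled normalized null for the FDR
  null_nes <- unlist(lapply(keep, function(nm) {
    null <- null_es[[nm]]
    vapply(null, norm_one, numeric(1), null = null)
  }))
  null_nes <- null_nes[is.finite(null_nes)]
  fdr_q <- vapply(nes, function(x) {
    if (!is.finite(x)) return(NA_real_)
    if (x >= 0) {
      num_null <- sum(null_nes >= x) / max(1, sum(null_nes >= 0))
      num_obs <- sum(nes >= x, na.rm = TRUE) / max(1, sum(nes >= 0, na.rm = TRUE))
    } else {
      num_null <- sum(null_nes <= x) / max(1, sum(null_nes < 0))
      num_obs <- sum(nes <= x, na.rm = TRUE) / max(1, sum(nes < 0, na.rm = TRUE))
    }
    min(1, num_null / max(num_obs, .Machine$double.eps))
  }, numeric(1))
  out <- data.frame(set = keep, size = unname(sizes[keep]),
                    es = unname(es_obs), nes = unname(nes),
                    p_value = unname(pval), fdr_q = unname(fdr_q),
                    stringsAsFactors = FALSE)
  out$significant <- !is.na(out$nes) & out$p_value <= p_cutoff &
    out$fdr_q <= fdr_cutoff
  out$direction <- ifelse(out$es >= 0, "up", "down")
  out <- out[order(-out$nes), ]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
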