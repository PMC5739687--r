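#' Log-normal draws parameterized by natural-scale mean and SD
#' @param n number of draws
#' @param mean,sd natural-scale mean and standard deviation
#' @return numeric vector with `E[x] = mean`, `SD[x] = sd`
#' @keywords internal
rlnorm_meansd <- function(n, mean, sd) {
  if (sd <= 0) return(rep(mean, n))
  s2 <- log(1 + (sd / mean)^2)
  stats::rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

pair_ids <- function(n) sprintf("P%d", seq_len(n))

make_pair_matrix <- function(values_t, values_n, features, patients, scale) {
  v <- cbind(values_t, values_n)
  colnames(v) <- c(paste0(patients, "_T"), paste0(patients, "_N"))
  rownames(v) <- features
  omics_matrix(v,
               rep(c("tumor", "normal"), each = length(patients)),
               rep(patients, 2), scale = scale)
}

#' Synthetic matched-cohort proteome with MNAR missingness
#'
#' Generates log2 label-free intensities for a paired tumor/normal cohort:
#' per-protein baselines are normal on the log2 scale; each patient draws
#' a mitochondrial mass factor (log-normal around the preset mean 2.22)
#' applied to all mitochondrial proteins in the tumor sample, except the
#' designated complex-I subunits which instead receive the depletion
#' factor (0.35); non-mitochondrial proteins receive the (near-unity)
#' non-mitochondrial factor. Missing-not-at-random cells are then removed
#' with a logistic probability of the true intensity (left-censoring, the
#' structure the downshifted-Gaussian imputation presumes).
#'
#' @param config a [cohort_config()]
#' @param seed integer seed; the same seed reproduces the cohort bit for
#'   bit
#' @return list of class `proteome_cohort` with `matrix` (an
#'   [omics_matrix], log2 scale), `annotation` (`feature_id`, `is_mito`,
#'   `complex`, `is_assembly`) and `truth` (per-patient factors, the
#'   per-protein effect assignment, MNAR threshold)
#' @export
gen_proteome <- function(config = cohort_config(), seed = 1L) {
  cfg <- config$proteome
  np <- config$n_pairs
  n <- cfg$n_proteins
  n_mito <- round(cfg$frac_mito * n)
  if (n_mito < 10)
    stop("frac_mito * n_proteins must be at least 10 for compartment statistics")
  annotation <- proteome_annotation(n, n_mito, cfg$n_ci_subunits)
  patients <- pair_ids(np)
  withr::with_seed(seed, {
    base <- stats::rnorm(n, cfg$base_mean_log2, cfg$base_sd_log2)
    f_mito <- rlnorm_meansd(np, cfg$mito_mass_factor, cfg$mito_mass_sd)
    f_non <- rlnorm_meansd(np, cfg$nonmito_mass_factor, cfg$nonmito_mass_sd)
    is_mito <- as.logical(annotation$is_mito)
    is_ci_sub <- annotation$complex == "CI" & !as.logical(annotation$is_assembly)
    eff <- matrix(0, n, np)
    for (p in seq_len(np)) {
      eff[is_mito, p] <- log2(f_mito[p])
      eff[is_ci_sub, p] <- log2(cfg$ci_depletion_factor)
      eff[!is_mito, p] <- log2(f_non[p])
    }
    noise <- function() matrix(stats::rnorm(n * np, 0, cfg$cv_log2), n, np)
    tum <- base + eff + noise()
    nor <- base + noise()
    x <- make_pair_matrix(tum, nor, annotation$feature_id, patients, "log2")
    if (cfg$mnar_missing$threshold_quantile > 0) {
      thr <- stats::quantile(x$values, cfg$mnar_missing$threshold_quantile)
      p_miss <- stats::plogis(cfg$mnar_missing$steepness * (thr - x$values))
      drop <- matrix(stats::runif(length(p_miss)) < p_miss, nrow(p_miss))
      x$values[drop] <- NA_real_
    } else thr <- NA_real_
  })
  truth <- list(
    patient_factors = data.frame(patient = patients, mito_factor = f_mito,
                                 nonmito_factor = f_non,
                                 stringsAsFactors = FALSE),
    protein_effects = data.frame(
      feature_id = annotation$feature_id,
      compartment = ifelse(is_mito, "mito", "non_mito"),
      effect = ifelse(is_ci_sub, "ci_depleted",
                      ifelse(is_mito, "mito_boost", "nonmito")),
      stringsAsFactors = FALSE),
    ci_depletion_factor = cfg$ci_depletion_factor,
    mito_mass_factor = cfg$mito_mass_factor,
    nonmito_mass_factor = cfg$nonmito_mass_factor,
    mnar_threshold = unname(thr))
  structure(list(matrix = x, annotation = annotation, truth = truth),
            class = "proteome_cohort")
}

proteome_annotation <- function(n, n_mito, n_ci_subunits) {
  stopifnot(n_mito <= n)
  complexes <- c(rep("CI", n_ci_subunits), rep("CI", 8),
                 rep("CII", 4), rep("CIII", 10), rep("CIV", 13),
                 rep("CV", 16), rep(c("CII", "CIII", "CIV", "CV"), each = 2))
  assembly <- c(rep(0L, n_ci_subunits), rep(1L, 8),
                rep(0L, 4 + 10 + 13 + 16), rep(1L, 8))
  n_cx <- length(complexes)
  if (n_cx > n_mito) stop("n_mito too small for the OXPHOS annotation")
  ids_cx <- sprintf("%s_%s%02d", complexes, ifelse(assembly == 1, "ASF", "SUB"),
                    stats::ave(seq_len(n_cx),
                               paste(complexes, assembly), FUN = seq_along))
  ids_mito <- c(ids_cx, sprintf("MITO%04d", seq_len(n_mito - n_cx)))
  ids_other <- sprintf("PROT%04d", seq_len(n - n_mito))
  data.frame(feature_id = c(ids_mito, ids_other),
             is_mito = rep(c(1L, 0L), c(n_mito, n - n_mito)),
             complex = c(complexes, rep(NA_character_, n - n_cx)),
             is_assembly = c(assembly, rep(0L, n - n_cx)),
             stringsAsFactors = FALSE)
}

#' Synthetic targeted-metabolomics cohort with the published effect preset
#'
#' Generates linear-scale abundances for `n_metabolites` metabolites in a
#' paired cohort. Metabolites listed in the effect table carry their
#' published tumor/normal fold change (multiplicative noise, log-normal
#' with the configured CV); all others are null. The below-LOQ metabolite
#' (reduced glutathione) gets normal-tissue values below its limit of
#' quantification and a tumor mean of `fold x LOQ`, so that the floored
#' fold change recovers the published ratio against the background level.
#'
#' @param config a [cohort_config()]
#' @param seed integer seed
#' @return list of class `metabolome_cohort` with `matrix` (linear
#'   scale), `floors` (named per-metabolite LOQ vector), `effect_table`,
#'   and `truth` (`metabolite`, `true_ratio`, `below_loq`)
#' @export
gen_metabolome <- function(config = cohort_config(), seed = 1L) {
  cfg <- config$metabolome
  np <- config$n_pairs
  n <- cfg$n_metabolites
  eff <- cfg$effect_table
  if (!is.null(eff) && nrow(eff) > n)
    stop("effect table references more metabolites than n_metabolites")
  if (is.null(eff))
    eff <- data.frame(metabolite = character(0), fold = numeric(0),
                      below_loq_normal = logical(0))
  n_fill <- n - nrow(eff)
  ids <- c(eff$metabolite, sprintf("metabolite_%03d", seq_len(n_fill)))
  ratio <- c(signed_to_ratio(eff$fold), rep(1, n_fill))
  below <- c(eff$below_loq_normal & cfg$gsh_below_loq_in_normal,
             rep(FALSE, n_fill))
  patients <- pair_ids(np)
  withr::with_seed(seed, {
    base <- stats::rlnorm(n, cfg$base_meanlog, cfg$base_sdlog)
    loq <- base * cfg$loq_fraction
    noise <- function() matrix(rlnorm_meansd(n * np, 1, cfg$cv), n, np)
    nor <- base * noise()
    tum <- base * ratio * noise()
    # below-LOQ metabolites: normals sit under the floor, tumor mean is
    # ratio x floor so the floored ratio recovers the preset fold
    if (any(below)) {
      k <- sum(below)
      nor[below, ] <- loq[below] * 0.3 *
        matrix(rlnorm_meansd(k * np, 1, cfg$cv), k, np)
      tum[below, ] <- loq[below] * ratio[below] *
        matrix(rlnorm_meansd(k * np, 1, cfg$cv), k, np)
    }
    x <- make_pair_matrix(tum, nor, ids, patients, "linear")
  })
  names(loq) <- ids
  truth <- data.frame(metabolite = ids, true_ratio = ratio,
                      below_loq = below, stringsAsFactors = FALSE)
  structure(list(matrix = x, floors = loq, effect_table = eff,
                 truth = truth),
            class = "metabolome_cohort")
}

#' Synthetic mtDNA variant cohort with coverage summaries
#'
#' Generates a paired mtDNA substitution table with the published cohort
#' structure: `n_germline` events present in both tissues at concordant
#' (near-homoplasmic) heteroplasmic fractions, of which a configured
#' fraction is haplogroup-defining; `n_somatic` tumor-only events with HF
#' drawn uniformly from `somatic_hf_range` except `n_homoplasmic_somatic`
#' at HF ~ 1. Functional classes follow the published composition
#' (germline non-haplogroup: 6 non-synonymous / 8 synonymous / 8
#' non-coding; somatic: 35 synonymous / 63 non-synonymous / 19 stop-gain /
#' 78 non-coding, scaled to the configured totals), with positions drawn
#' from the synthetic gene map so that [annotate_mt()] reproduces each
#' intended class. Disease scores and nucleotide variabilities are
#' assigned so that 54/63 somatic non-synonymous variants pass the
#' disease-score threshold and 49 of those lie below the variability
#' cutoff. Per-sample mitochondrial and nuclear mean coverages realize
#' per-pair mtDNA copy ratios log-normal around `copy_ratio_mean`.
#'
#' @param config a [cohort_config()]
#' @param seed integer seed
#' @return list of class `mtdna_cohort` with `variants` (one row per
#'   variant: depths per tissue, annotation fields), `coverage` (per
#'   sample), `haplogroup_sites`, `gene_map`, `genome`, and `truth`
#'   (origins, true HF, true copy ratios)
#' @export
gen_mt_variants <- function(config = cohort_config(), seed = 1L) {
  cfg <- config$mtdna
  np <- config$n_pairs
  map <- toy_mt_gene_map()
  genome <- toy_mt_genome()
  patients <- pair_ids(np)
  withr::with_seed(seed, {
    n_g <- cfg$n_germline
    n_hap <- round(cfg$frac_haplogroup * n_g)
    n_nonhap <- n_g - n_hap
    g_nonsyn <- round(n_nonhap * 6 / 22)
    g_syn <- round(n_nonhap * 8 / 22)
    g_nonc <- n_nonhap - g_nonsyn - g_syn
    g_trna <- min(1L, g_nonc)
    g_dloop <- g_nonc - g_trna
    n_s <- cfg$n_somatic
    s_nonsyn <- round(n_s * 63 / 195)
    s_syn <- round(n_s * 35 / 195)
    s_stop <- round(n_s * 19 / 195)
    s_nonc <- n_s - s_nonsyn - s_syn - s_stop
    s_trna <- min(3L, s_nonc)
    s_rrna <- min(22L, max(0L, s_nonc - s_trna - 1L))
    s_dloop <- max(0L, s_nonc - s_trna - s_rrna)
    hap_classes <- sample(c("synonymous", "dloop"), n_hap, replace = TRUE,
                          prob = c(0.4, 0.6))
    classes <- c(rep("nonsynonymous", g_nonsyn), rep("synonymous", g_syn),
                 rep("dloop", g_dloop), rep("tRNA", g_trna), hap_classes,
                 rep("nonsynonymous", s_nonsyn), rep("synonymous", s_syn),
                 rep("stop_gain", s_stop), rep("dloop", s_dloop),
                 rep("tRNA", s_trna), rep("rRNA", s_rrna))
    origin <- rep(c("germline", "somatic"), c(n_g, n_s))
    hap <- c(rep(FALSE, n_nonhap), rep(TRUE, n_hap), rep(FALSE, n_s))
    loci <- draw_mt_loci(classes, map, genome)
    n_all <- n_g + n_s
    patient <- sample(patients, n_all, replace = TRUE)
    # heteroplasmic fractions
    hf_t <- numeric(n_all); hf_n <- rep(NA_real_, n_all)
    hf_t[origin == "germline"] <- stats::runif(n_g, 0.97, 1.0)
    hf_n[origin == "germline"] <- pmin(1, pmax(
      0, hf_t[origin == "germline"] + stats::runif(n_g, -0.01, 0.01)))
    hf_t[origin == "somatic"] <- stats::runif(
      n_s, cfg$somatic_hf_range[1], cfg$somatic_hf_range[2])
    som_nonsyn_idx <- which(origin == "somatic" &
                              classes == "nonsynonymous")
    if (cfg$n_homoplasmic_somatic > 0 && length(som_nonsyn_idx))
      hf_t[som_nonsyn_idx[seq_len(min(cfg$n_homoplasmic_somatic,
                                      length(som_nonsyn_idx)))]] <- 0.999
    som_trna_idx <- which(origin == "somatic" & classes == "tRNA")
    if (length(som_trna_idx)) hf_t[som_trna_idx[1]] <- 0.57
    # annotation scores
    variability <- stats::runif(n_all, 0.005, 0.3)
    score <- rep(NA_real_, n_all)
    scored <- classes %in% c("nonsynonymous", "stop_gain", "tRNA", "rRNA")
    score[scored] <- stats::runif(sum(scored), 0.05, 0.4)
    # somatic nonsyn: 54/63 above the disease-score threshold, 49 of the
    # 54 below the variability cutoff (published composition, scaled)
    k_pass <- round(length(som_nonsyn_idx) * 54 / 63)
    pass_idx <- som_nonsyn_idx[seq_len(k_pass)]
    score[pass_idx] <- stats::runif(k_pass, 0.45, 0.95)
    k_lowvar <- round(k_pass * 49 / 54)
    variability[pass_idx[seq_len(k_lowvar)]] <-
      stats::runif(k_lowvar, 0, 0.002)
    germ_nonsyn_idx <- which(origin == "germline" &
                               classes == "nonsynonymous" & !hap)
    if (length(germ_nonsyn_idx)) {     # one pathogenic germline nonsyn
      variability[germ_nonsyn_idx[1]] <- 0.00031
      score[germ_nonsyn_idx[1]] <- 0.5
    }
    germ_trna_idx <- which(origin == "germline" & classes == "tRNA" & !hap)
    if (length(germ_trna_idx)) {       # damaging germline tRNA variant
      variability[germ_trna_idx[1]] <- 0
      score[germ_trna_idx[1]] <- 0.65
    }
    som_stop_idx <- which(origin == "somatic" & classes == "stop_gain")
    score[som_stop_idx] <- stats::runif(length(som_stop_idx), 0.5, 0.95)
    variability[som_stop_idx] <- stats::runif(length(som_stop_idx), 0, 0.002)
    if (length(som_trna_idx)) variability[som_trna_idx] <- 0
    dloop_idx <- which(classes == "dloop")
    variability[dloop_idx] <- stats::runif(length(dloop_idx), 0, 0.05)
    # allele depths
    cov_t <- stats::rpois(n_all, cfg$mt_coverage)
    cov_n <- stats::rpois(n_all, cfg$mt_coverage)
    alt_t <- stats::rbinom(n_all, cov_t, hf_t)
    alt_n <- ifelse(is.na(hf_n), 0L, stats::rbinom(n_all, cov_n,
                                                   ifelse(is.na(hf_n), 0, hf_n)))
    variants <- data.frame(
      variant_id = sprintf("v%03d", seq_len(n_all)),
      patient = patient, pos = loci$pos, ref = loci$ref, alt = loci$alt,
      tumor_ref = cov_t - alt_t, tumor_alt = alt_t,
      normal_ref = ifelse(origin == "somatic", cov_n, cov_n - alt_n),
      normal_alt = ifelse(origin == "somatic", 0L, alt_n),
      gene = loci$gene, functional_class = classes,
      haplogroup_defining = hap,
      nucleotide_variability = variability, disease_score = score,
      stringsAsFactors = FALSE)
    # coverage summary realizing the copy-ratio preset
    r_p <- rlnorm_meansd(np, cfg$copy_ratio_mean, cfg$copy_ratio_sd)
    nuc_t <- stats::rnorm(np, cfg$nuclear_coverage, 0.05 * cfg$nuclear_coverage)
    nuc_n <- stats::rnorm(np, cfg$nuclear_coverage, 0.05 * cfg$nuclear_coverage)
    base_dose <- cfg$mt_coverage / cfg$nuclear_coverage
    jitter <- function(k) exp(stats::rnorm(k, 0, 0.02))
    coverage <- rbind(
      data.frame(patient = patients, tissue = "tumor",
                 mt_coverage = nuc_t * base_dose * r_p * jitter(np),
                 nuclear_coverage = nuc_t),
      data.frame(patient = patients, tissue = "normal",
                 mt_coverage = nuc_n * base_dose * jitter(np),
                 nuclear_coverage = nuc_n))
  })
  truth <- list(variants = data.frame(variant_id = variants$variant_id,
                                      origin = origin, true_hf_tumor = hf_t,
                                      true_hf_normal = hf_n,
                                      stringsAsFactors = FALSE),
                copy_ratios = data.frame(patient = patients, ratio = r_p,
                                         stringsAsFactors = FALSE))
  hap_sites <- variants[variants$haplogroup_defining,
                        c("pos", "ref", "alt"), drop = FALSE]
  structure(list(variants = variants, coverage = coverage,
                 haplogroup_sites = hap_sites, gene_map = map,
                 genome = genome, truth = truth),
            class = "mtdna_cohort")
}

# draw distinct loci whose annotation matches each requested class
draw_mt_loci <- function(classes, map, genome) {
  base_at <- function(p) substr(genome, p, p)
  interval_positions <- function(types) {
    sel <- map[map$type %in% types, , drop = FALSE]
    unlist(lapply(seq_len(nrow(sel)),
                  function(i) seq(sel$start[i], sel$end[i])))
  }
  pools <- list()
  # protein classes via rejection against the annotator
  need_protein <- sum(classes %in% c("synonymous", "nonsynonymous",
                                     "stop_gain"))
  if (need_protein) {
    prot_pos <- interval_positions("protein")
    cand_pos <- sample(prot_pos, min(length(prot_pos), 6000L))
    ref <- vapply(cand_pos, base_at, "")
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    ann <- annotate_mt(cand_pos, ref, alt, map, genome)
    for (cl in c("synonymous", "nonsynonymous", "stop_gain"))
      pools[[cl]] <- ann[ann$functional_class == cl, , drop = FALSE]
  }
  for (cl in c("tRNA", "rRNA", "dloop")) {
    if (!any(classes == cl)) next
    type <- c(tRNA = "trna", rRNA = "rrna", dloop = "dloop")[[cl]]
    pos <- sample(interval_positions(type),
                  sum(classes == cl) + 10L, replace = FALSE)
    ref <- vapply(pos, base_at, "")
    alt <- vapply(ref, function(r)
      sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
    gene <- vapply(pos, function(p)
      map$gene[map$start <= p & map$end >= p][1], "")
    pools[[cl]] <- data.frame(pos = pos, ref = ref, alt = alt, gene = gene,
                              functional_class = cl, stringsAsFactors = FALSE)
  }
  taken <- integer(0)
  out <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    pool <- pools[[classes[i]]]
    pool <- pool[!pool$pos %in% taken, , drop = FALSE]
    if (!nrow(pool))
      stop("locus pool exhausted for class ", classes[i])
    row <- pool[sample.int(nrow(pool), 1), , drop = FALSE]
    taken <- c(taken, row$pos)
    out[[i]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Synthetic nuclear somatic variant table
#'
#' Per-patient tumor-specific variant counts are drawn log-normal around
#' the configured median non-silent burden; silent variants are added at
#' the published silent:non-silent ratio; non-silent effect classes follow
#' the published proportions (missense : nonsense : frameshift deletions :
#' frameshift insertions). Substitution classes are multinomial over the
#' six-class spectrum probabilities, each rendered on a random strand
#' (C>T appears as C>T or G>A). Setting `nuclear$n_snv_total` draws a
#' fixed total number of substitutions instead.
#'
#' @param config a [cohort_config()]
#' @param seed integer seed
#' @return list of class `nuclear_cohort` with `variants` (`patient`,
#'   `chrom`, `pos`, `ref`, `alt`, `effect_class`) and `truth`
#' @export
gen_nuclear_variants <- function(config = cohort_config(), seed = 1L) {
  cfg <- config$nuclear
  np <- config$n_pairs
  patients <- pair_ids(np)
  withr::with_seed(seed, {
    if (!is.null(cfg$n_snv_total)) {
      n <- cfg$n_snv_total
      patient <- sample(patients, n, replace = TRUE)
      effect <- sample(c("silent", "missense"), n, replace = TRUE,
                       prob = c(0.5, 0.5))
      snv <- draw_substitutions(n, cfg$spectrum_probs)
      variants <- data.frame(patient = patient,
                             chrom = sample(c(1:22, "X"), n, replace = TRUE),
                             pos = sample.int(1e8, n, replace = TRUE),
                             ref = snv$ref, alt = snv$alt,
                             effect_class = effect,
                             stringsAsFactors = FALSE)
      nonsilent <- tapply(effect != "silent", patient, sum)
    } else {
      rows <- lapply(patients, function(p) {
        n_nonsil <- max(1L, round(cfg$burden_median *
                                    exp(stats::rnorm(1, 0, cfg$burden_sdlog))))
        n_sil <- stats::rpois(1, n_nonsil * cfg$silent_per_nonsilent)
        effect <- c(rep("silent", n_sil),
                    sample(names(cfg$effect_probs), n_nonsil, replace = TRUE,
                           prob = cfg$effect_probs))
        is_fs <- grepl("^frameshift", effect)
        n_snv <- sum(!is_fs)
        ref <- alt <- character(length(effect))
        snv <- draw_substitutions(n_snv, cfg$spectrum_probs)
        ref[!is_fs] <- snv$ref; alt[!is_fs] <- snv$alt
        ref[is_fs] <- ifelse(effect[is_fs] == "frameshift_del", "AT", "A")
        alt[is_fs] <- ifelse(effect[is_fs] == "frameshift_del", "A", "AT")
        data.frame(patient = p,
                   chrom = sample(c(1:22, "X"), length(effect), replace = TRUE),
                   pos = sample.int(1e8, length(effect), replace = TRUE),
                   ref = ref, alt = alt, effect_class = effect,
                   stringsAsFactors = FALSE)
      })
      variants <- do.call(rbind, rows)
      nonsilent <- tapply(variants$effect_class != "silent",
                          variants$patient, sum)
    }
  })
  truth <- list(nonsilent_per_patient = nonsilent,
                spectrum_probs = cfg$spectrum_probs)
  structure(list(variants = variants, truth = truth),
            class = "nuclear_cohort")
}

draw_substitutions <- function(n, spectrum_probs) {
  if (!n) return(list(ref = character(0), alt = character(0)))
  cls <- sample(SPECTRUM_CLASSES, n, replace = TRUE, prob = spectrum_probs)
  ref <- substr(cls, 1, 1); alt <- substr(cls, 3, 3)
  flip <- stats::runif(n) < 0.5           # render on the purine strand
  ref[flip] <- unname(MT_COMPLEMENT[ref[flip]])
  alt[flip] <- unname(MT_COMPLEMENT[alt[flip]])
  list(ref = ref, alt = alt)
}

CHROM_LENGTHS <- stats::setNames(
  c(249, 243, 198, 191, 181, 171, 159, 146, 141, 136, 135, 134, 115, 107,
    102, 90, 83, 80, 59, 64, 47, 51, 155) * 1e6, c(1:22, "X"))

#' Synthetic copy-number losses with a protein dose effect
#'
#' Assigns each protein of a generated proteome cohort a genomic position,
#' applies the configured loss segments per patient (BED convention,
#' overlap within a patient is an error), and adds the dose effect
#' (default -0.5 log2) to the tumor intensities of proteins whose gene
#' midpoint lies in a lost segment of that patient.
#'
#' @param config a [cohort_config()]
#' @param seed integer seed
#' @param proteome a `proteome_cohort` from [gen_proteome()]; generated
#'   with the same config and `seed` when omitted
#' @return list of class `cnv_cohort` with `matrix` (dose-modified log2
#'   [omics_matrix]), `segments`, `gene_positions`, `loss` (`feature_id`,
#'   `patient`), `loss_genes`, and `truth` (`dose_effect_log2`)
#' @export
gen_cnv <- function(config = cohort_config(), seed = 1L, proteome = NULL) {
  if (is.null(proteome)) proteome <- gen_proteome(config, seed)
  cfg <- config$cnv
  x <- proteome$matrix
  patients <- unique(x$patient)
  seg <- cfg$loss_segments
  seg <- seg[seg$patient %in% patients, , drop = FALSE]
  for (key in unique(paste(seg$patient, seg$chrom))) {
    s <- seg[paste(seg$patient, seg$chrom) == key, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)]))
      stop("overlapping loss segments for patient ", s$patient[1],
           " on chromosome ", s$chrom[1])
  }
  ids <- rownames(x$values)
  withr::with_seed(seed + 1L, {
    chrom <- sample(names(CHROM_LENGTHS), length(ids), replace = TRUE,
                    prob = CHROM_LENGTHS / sum(CHROM_LENGTHS))
    midpoint <- floor(stats::runif(length(ids)) * CHROM_LENGTHS[chrom])
  })
  gene_positions <- data.frame(feature_id = ids, chrom = chrom,
                               midpoint = midpoint, stringsAsFactors = FALSE)
  loss <- cnv_loss_genes(seg, gene_positions)
  if (nrow(loss)) {
    tum_cols <- which(x$group == "tumor")
    names(tum_cols) <- x$patient[tum_cols]
    for (i in seq_len(nrow(loss))) {
      j <- tum_cols[[loss$patient[i]]]
      x$values[loss$feature_id[i], j] <-
        x$values[loss$feature_id[i], j] + cfg$dose_effect_log2
    }
  }
  structure(list(matrix = x, segments = seg, gene_positions = gene_positions,
                 loss = loss, loss_genes = unique(loss$feature_id),
                 truth = list(dose_effect_log2 = cfg$dose_effect_log2,
                              loss = loss)),
            class = "cnv_cohort")
}
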