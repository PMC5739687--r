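#' Analysis run configuration
#'
#' Collects the tunable constants of the pipeline: significance gates
#' (BH FDR level 0.05 and the p < 0.01 gate used for the metabolome),
#' proteome validity-filter mode, left-censored imputation parameters,
#' enrichment settings (minimum set size 5), and the mtDNA prioritization
#' thresholds (nucleotide-variability cutoff 0.0026; disease-score
#' thresholds 0.43 / 0.35 / 0.60 for non-synonymous, tRNA and rRNA
#' variants).
#'
#' @param seed integer seed used by randomized stages
#' @param fdr_level BH false-discovery-rate level, in (0,1)
#' @param p_cutoff nominal p-value gate, in (0,1)
#' @param filter_mode proteome validity filter, see [filter_min_valid()]
#' @param imputation list with `width_factor`, `downshift_factor`
#' @param gsea list with `min_size`, `n_perm`, `weight`, `p_cutoff`,
#'   `fdr_cutoff`
#' @param mtdna list with `variability_cutoff`, `ds_nonsyn`, `ds_trna`,
#'   `ds_rrna`, `hf_tolerance`, `detection_limit`
#' @param floor_policy metabolite LOQ floor policy: per-metabolite floors
#'   supplied with the data, or the global minimum positive observed value
#' @return validated list of class `run_config`
#' @export
run_config <- function(seed = 1L,
                       fdr_level = 0.05,
                       p_cutoff = 0.01,
                       filter_mode = c("each_group_min3", "one_group_full6"),
                       imputation = list(width_factor = 0.3,
                                         downshift_factor = 1.8),
                       gsea = list(min_size = 5L, n_perm = 1000L, weight = 1,
                                   p_cutoff = 0.01, fdr_cutoff = 0.15),
                       mtdna = list(variability_cutoff = 0.0026,
                                    ds_nonsyn = 0.43, ds_trna = 0.35,
                                    ds_rrna = 0.60, hf_tolerance = 0.10,
                                    detection_limit = 0.005),
                       floor_policy = c("per_metabolite", "global_min")) {
  cfg <- list(seed = as.integer(seed), fdr_level = fdr_level,
              p_cutoff = p_cutoff, filter_mode = match.arg(filter_mode),
              imputation = imputation, gsea = gsea, mtdna = mtdna,
              floor_policy = match.arg(floor_policy))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  frac <- c(fdr_level = cfg$fdr_level, p_cutoff = cfg$p_cutoff,
            gsea_p = cfg$gsea$p_cutoff, gsea_fdr = cfg$gsea$fdr_cutoff)
  bad <- frac <= 0 | frac >= 1
  if (any(bad))
    stop("fraction(s) outside (0,1): ", paste(names(frac)[bad], collapse = ", "))
  if (cfg$gsea$n_perm < 100L) stop("gsea n_perm must be >= 100")
  thr <- unlist(cfg$mtdna[c("variability_cutoff", "ds_nonsyn", "ds_trna",
                            "ds_rrna")])
  if (any(thr <= 0)) stop("mtdna thresholds must be strictly positive")
  if (cfg$imputation$width_factor <= 0 || cfg$imputation$downshift_factor < 0)
    stop("invalid imputation parameters")
  invisible(cfg)
}

#' Read a run configuration from YAML
#'
#' Keys present in the file override the [run_config()] defaults; absent
#' keys keep them.
#'
#' @param path YAML path
#' @return a `run_config`
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  base <- run_config()
  cfg <- utils::modifyList(unclass(base), user)
  cfg$filter_mode <- match.arg(cfg$filter_mode,
                               c("each_group_min3", "one_group_full6"))
  cfg$floor_policy <- match.arg(cfg$floor_policy,
                                c("per_metabolite", "global_min"))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

#' Synthetic-cohort generator configuration
#'
#' Defaults encode the study conditions the generators emulate: 6 matched
#' tumor/normal pairs; ~2000 proteins of which 25% are mitochondrial, with
#' a per-patient mitochondrial mass gain around 2.22-fold, an unchanged
#' non-mitochondrial compartment (0.97-fold), selective complex-I subunit
#' depletion to 0.35-fold, and left-censored (MNAR) missingness; 159
#' metabolites of which 29 carry the published fold changes (reduced
#' glutathione below LOQ in normals, recovered fold 5413); mtDNA cohorts
#' with 54 germline events (59.3% haplogroup-defining), 195 tumor-specific
#' events with heteroplasmic fractions in 0.006--0.069 (one homoplasmic),
#' and a tumor/normal mtDNA copy ratio around 1.79 (SD 0.64); nuclear SNVs
#' drawn from the published six-class spectrum (400, 426, 1696, 259, 1228,
#' 274) with a median non-silent burden of 78; and chromosome-loss segments
#' imposing a -0.5 log2 protein dose effect.
#'
#' @param n_pairs number of tumor/normal pairs
#' @param proteome,metabolome,mtdna,nuclear,cnv per-stage parameter lists;
#'   entries given here override the preset defaults
#' @return validated list of class `cohort_config`
#' @export
cohort_config <- function(n_pairs = 6L, proteome = list(),
                          metabolome = list(), mtdna = list(),
                          nuclear = list(), cnv = list()) {
  spectrum_counts <- c("C>A" = 400, "C>G" = 426, "C>T" = 1696,
                       "T>A" = 259, "T>C" = 1228, "T>G" = 274)
  def <- list(
    n_pairs = as.integer(n_pairs),
    proteome = list(
      n_proteins = 2000L, frac_mito = 0.25,
      mito_mass_factor = 2.22, mito_mass_sd = 0.4,
      nonmito_mass_factor = 0.97, nonmito_mass_sd = 0.06,
      ci_depletion_factor = 0.35, n_ci_subunits = 40L,
      cv_log2 = 0.5, base_mean_log2 = 25, base_sd_log2 = 2,
      mnar_missing = list(threshold_quantile = 0.10, steepness = 1.0)),
    metabolome = list(
      n_metabolites = 159L, effect_table = metabolite_effect_table(),
      cv = 0.20, gsh_below_loq_in_normal = TRUE,
      base_meanlog = log(1e5), base_sdlog = 1, loq_fraction = 1e-3),
    mtdna = list(
      copy_ratio_mean = 1.79, copy_ratio_sd = 0.64,
      n_germline = 54L, frac_haplogroup = 32 / 54,
      n_somatic = 195L, somatic_hf_range = c(0.006, 0.069),
      n_homoplasmic_somatic = 1L,
      mt_coverage = 2000, nuclear_coverage = 100),
    nuclear = list(
      spectrum_probs = spectrum_counts / sum(spectrum_counts),
      burden_median = 78, burden_sdlog = 0.55,
      effect_probs = c(missense = 760, nonsense = 19,
                       frameshift_del = 11, frameshift_ins = 8) / 798,
      silent_per_nonsilent = 799 / 798,
      n_snv_total = NULL),
    cnv = list(loss_segments = default_loss_segments(),
               dose_effect_log2 = -0.5))
  merge_stage <- function(base, override) {
    for (nm in names(override)) {
      old <- base[[nm]]; new <- override[[nm]]
      if (is.list(old) && is.list(new) &&
          !is.data.frame(old) && !is.data.frame(new))
        base[[nm]] <- utils::modifyList(old, new, keep.null = TRUE)
      else base[nm] <- list(new)   # replaces, and allows setting to NULL
    }
    base
  }
  cfg <- def
  for (stage in c("proteome", "metabolome", "mtdna", "nuclear", "cnv"))
    cfg[[stage]] <- merge_stage(def[[stage]], get(stage))
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' Default chromosome-loss segments of the synthetic cohort
#'
#' Emulates the reported loss pattern: X-chromosome loss in four patients,
#' partial chromosome-1 loss in two, and one patient with additional losses
#' on chromosomes 14, 19, 21 and part of 7. Coordinates are 0-based
#' half-open (BED convention), on a coarse 250 Mb-per-chromosome grid.
#'
#' @return data.frame with columns `chrom`, `start`, `end`, `patient`,
#'   `copy_state`
#' @export
default_loss_segments <- function() {
  seg <- rbind(
    data.frame(chrom = "X", start = 0, end = 155e6,
               patient = c("P1", "P2", "P3", "P4")),
    data.frame(chrom = "1", start = 0, end = 120e6,
               patient = c("P2", "P5")),
    data.frame(chrom = c("14", "19", "21", "7"), start = 0,
               end = c(107e6, 59e6, 47e6, 60e6), patient = "P2"))
  seg$copy_state <- 1L
  seg[, c("chrom", "start", "end", "patient", "copy_state")]
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_pairs >= 2L)
  pr <- cfg$proteome
  if (pr$frac_mito < 0 || pr$frac_mito > 1) stop("frac_mito must be in [0,1]")
  pos <- c(pr$mito_mass_factor, pr$nonmito_mass_factor,
           pr$ci_depletion_factor, pr$cv_log2,
           cfg$mtdna$copy_ratio_mean, cfg$metabolome$cv)
  if (any(pos <= 0)) stop("factors and dispersions must be > 0")
  hf <- cfg$mtdna$somatic_hf_range
  if (length(hf) != 2L || any(hf < 0) || any(hf > 1) || hf[1] > hf[2])
    stop("somatic_hf_range must be an increasing range within [0,1]")
  sp <- cfg$nuclear$spectrum_probs
  if (any(sp < 0)) stop("spectrum_probs must be non-negative")
  if (abs(sum(sp) - 1) > 1e-8)
    stop("spectrum_probs must sum to 1 after normalization")
  et <- cfg$metabolome$effect_table
  if (!is.null(et) && nrow(et) > cfg$metabolome$n_metabolites)
    stop("effect table references more metabolites than n_metabolites")
  invisible(cfg)
}
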