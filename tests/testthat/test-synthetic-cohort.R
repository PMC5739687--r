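test_that("every generator is seed-deterministic", {
  cc <- cohort_config(proteome = list(n_proteins = 400L),
                      mtdna = list(n_germline = 20L, n_somatic = 40L))
  expect_identical(gen_proteome(cc, 5)$matrix$values,
                   gen_proteome(cc, 5)$matrix$values)
  expect_false(identical(gen_proteome(cc, 5)$matrix$values,
                         gen_proteome(cc, 6)$matrix$values))
  expect_identical(gen_metabolome(cc, 5)$matrix$values,
                   gen_metabolome(cc, 5)$matrix$values)
  expect_identical(gen_mt_variants(cc, 5)$variants,
                   gen_mt_variants(cc, 5)$variants)
  expect_identical(gen_nuclear_variants(cc, 5)$variants,
                   gen_nuclear_variants(cc, 5)$variants)
  expect_identical(gen_cnv(cc, 5)$matrix$values, gen_cnv(cc, 5)$matrix$values)
})

test_that("generator truth objects cover every feature exactly once", {
  cc <- cohort_config(proteome = list(n_proteins = 400L))
  pc <- gen_proteome(cc, 2)
  expect_setequal(pc$truth$protein_effects$feature_id,
                  rownames(pc$matrix$values))
  expect_identical(anyDuplicated(pc$truth$protein_effects$feature_id), 0L)
  mc <- gen_metabolome(cc, 2)
  expect_setequal(mc$truth$metabolite, rownames(mc$matrix$values))
  mt <- gen_mt_variants(cc, 2)
  expect_identical(mt$truth$variants$variant_id, mt$variants$variant_id)
})

test_that("a unit-effect proteome yields compartment ratios near 1", {
  # ratios of raw-intensity sums are heavy-tailed per patient, so the null
  # check applies to the cohort mean (narrower baseline spread for stability)
  cc <- cohort_config(proteome = list(
    n_proteins = 2000L, base_sd_log2 = 1.2,
    mito_mass_factor = 1, mito_mass_sd = 0.02,
    nonmito_mass_factor = 1, nonmito_mass_sd = 0.02, ci_depletion_factor = 1,
    mnar_missing = list(threshold_quantile = 0, steepness = 1)))
  for (s in 1:5) {
    pc <- gen_proteome(cc, s)
    m <- mito_mass_ratio(pc$matrix, pc$annotation)$summary
    expect_true(all(abs(m$mean - 1) < 0.05))
  }
})

test_that("proteome config guards fire", {
  expect_error(gen_proteome(cohort_config(proteome = list(
    n_proteins = 100L, frac_mito = 0.05)), 1), "at least 10")
  expect_error(cohort_config(proteome = list(mito_mass_factor = -1)),
               "must be > 0")
})

test_that("metabolome guards: oversized effect table and HF range", {
  expect_error(cohort_config(metabolome = list(n_metabolites = 10L)),
               "more metabolites")
  expect_error(cohort_config(mtdna = list(somatic_hf_range = c(0.5, 1.2))),
               "somatic_hf_range")
})

test_that("GSH preset recovers the published floored fold at one seed", {
  cohort <- gen_metabolome(cohort_config(), seed = 7)
  fc <- fold_change_with_floor(cohort$matrix, cohort$floors)
  gsh <- fc[fc$metabolite == "Reduced glutathione", ]
  expect_equal(gsh$floored_normal, 6)  # all normals below LOQ
  expect_lt(abs(gsh$fold - 5413) / 5413, 0.10)
})

test_that("downstream origin classification recovers the generator truth", {
  cc <- cohort_config(mtdna = list(somatic_hf_range = c(0.05, 0.05),
                                   n_homoplasmic_somatic = 0L))
  cohort <- gen_mt_variants(cc, 3)
  v <- cohort$variants
  hf_t <- heteroplasmic_fraction(v$tumor_alt, v$tumor_ref)$hf
  hf_n <- ifelse(v$normal_alt + v$normal_ref == 0, NA_real_,
                 heteroplasmic_fraction(pmax(v$normal_alt, 0L),
                                        v$normal_ref)$hf)
  called <- classify_origin(hf_t, hf_n)
  truth <- cohort$truth$variants$origin
  som <- truth == "somatic"
  expect_equal(mean(called[som] == "somatic"), 1)
  expect_gt(mean(called[!som] == "germline"), 0.95)
})

test_that("haplogroup fraction zero removes the exclusion gate", {
  cc <- cohort_config(mtdna = list(frac_haplogroup = 0))
  cohort <- gen_mt_variants(cc, 4)
  expect_false(any(cohort$variants$haplogroup_defining))
  pr <- prioritize_mt(cohort$variants)
  expect_false(any(grepl("haplogroup", pr$reasons)))
})

test_that("unit copy-ratio preset gives ratios near 1", {
  cc <- cohort_config(mtdna = list(copy_ratio_mean = 1,
                                   copy_ratio_sd = 0.01))
  cohort <- gen_mt_variants(cc, 5)
  r <- mtdna_copy_ratio(cohort$coverage)
  expect_true(all(abs(r$pairs$ratio - 1) < 0.15))
})

test_that("uniform spectrum gives Ti/Tv near 0.5; printed probs near 2.15", {
  cc_unif <- cohort_config(nuclear = list(
    spectrum_probs = rep(1 / 6, 6), n_snv_total = 6000L))
  sp <- spectrum_6class(gen_nuclear_variants(cc_unif, 6)$variants)
  expect_equal(titv(sp), 0.5, tolerance = 0.07)
  cc_printed <- cohort_config(nuclear = list(n_snv_total = 4283L))
  sp2 <- spectrum_6class(gen_nuclear_variants(cc_printed, 7)$variants)
  expect_identical(attr(sp2, "total"), 4283L)
  expect_equal(titv(sp2), 2924 / 1359, tolerance = 0.15)
})

test_that("default nuclear cohorts carry a plausible non-silent burden", {
  b <- burden_stats(gen_nuclear_variants(cohort_config(), 8)$variants)
  expect_true(b$median_burden > 30 && b$median_burden < 200)
  expect_identical(sort(names(b$class_totals)),
                   sort(c("silent", "missense", "nonsense",
                          "frameshift_del", "frameshift_ins")))
})

test_that("CNV generator applies the dose effect to the right cells", {
  cc <- cohort_config(proteome = list(
    n_proteins = 400L,
    mnar_missing = list(threshold_quantile = 0, steepness = 1)))
  pc <- gen_proteome(cc, 9)
  cv <- gen_cnv(cc, 9, pc)
  expect_gt(length(cv$loss_genes), 0)
  i <- cv$loss[1, ]
  tum_col <- paste0(i$patient, "_T")
  expect_equal(cv$matrix$values[i$feature_id, tum_col],
               pc$matrix$values[i$feature_id, tum_col] - 0.5)
  # untouched patient/feature cells are identical
  other <- setdiff(rownames(pc$matrix$values), cv$loss$feature_id)[1]
  expect_identical(cv$matrix$values[other, ], pc$matrix$values[other, ])
  # no segments -> no loss genes
  cv0 <- gen_cnv(cohort_config(
    proteome = list(n_proteins = 400L),
    cnv = list(loss_segments = default_loss_segments()[0, ])), 9, pc)
  expect_length(cv0$loss_genes, 0)
  # overlapping segments on one patient are rejected
  seg <- data.frame(chrom = "1", start = c(0, 5e7), end = c(1e8, 2e8),
                    patient = "P1", copy_state = 1L)
  expect_error(gen_cnv(cohort_config(
    proteome = list(n_proteins = 400L),
    cnv = list(loss_segments = seg)), 9, pc), "overlapping")
})

test_that("a shared strong dose effect is detected by the permutation test", {
  cc <- cohort_config(
    proteome = list(n_proteins = 600L,
                    mnar_missing = list(threshold_quantile = 0, steepness = 1)),
    cnv = list(dose_effect_log2 = -1,
               loss_segments = data.frame(
                 chrom = "1", start = 0, end = 249e6,
                 patient = sprintf("P%d", 1:6), copy_state = 1L)))
  hits <- 0L
  for (s in 1:10) {
    cv <- gen_cnv(cc, s)
    fc <- stats::setNames(differential_test(cv$matrix)$log2fc,
                          rownames(cv$matrix$values))
    p <- cnv_dose_test(fc, cv$loss_genes, n_perm = 500, seed = s)$p_value
    hits <- hits + (p <= 0.01)
  }
  expect_gte(hits, 9L)
})
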