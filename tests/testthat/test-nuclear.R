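test_that("spectrum collapse maps purine-reference substitutions by
           reverse complement", {
  v <- data.frame(ref = c("G", "A", "C", "T", "G", "A"),
                  alt = c("A", "G", "T", "C", "T", "C"))
  counts <- spectrum_6class(v)
  expect_equal(counts[["C>T"]], 2)  # G>A and C>T
  expect_equal(counts[["T>C"]], 2)  # A>G and T>C
  expect_equal(counts[["C>A"]], 1)  # G>T
  expect_equal(counts[["T>G"]], 1)  # A>C
  expect_error(spectrum_6class(data.frame(ref = "C", alt = "C")),
               "not a substitution")
})

test_that("the printed spectrum fixture totals 4283 and Ti/Tv ~ 2.15", {
  v <- spectrum_fixture(printed_spectrum)
  counts <- spectrum_6class(v)
  expect_identical(unname(counts[names(printed_spectrum)]),
                   unname(printed_spectrum))
  expect_identical(attr(counts, "total"), 4283L)
  expect_equal(titv(counts), 2924 / 1359)
  expect_gte(titv(counts), 2)
})

test_that("spectrum handles empty input and skips indels", {
  empty <- spectrum_6class(data.frame(ref = character(0), alt = character(0)))
  expect_true(all(empty == 0L))
  v <- data.frame(ref = c("C", "AT", "G"), alt = c("T", "A", "GG"))
  counts <- spectrum_6class(v)
  expect_identical(attr(counts, "skipped"), 2L)
  expect_identical(attr(counts, "total"), 1L)
})

test_that("spectrum collapse equals a 12-type brute-force oracle", {
  # explicit enumeration of all 12 substitution types
  oracle_map <- c("C>A" = "C>A", "C>G" = "C>G", "C>T" = "C>T",
                  "T>A" = "T>A", "T>C" = "T>C", "T>G" = "T>G",
                  "G>T" = "C>A", "G>C" = "C>G", "G>A" = "C>T",
                  "A>T" = "T>A", "A>G" = "T>C", "A>C" = "T>G")
  withr::with_seed(17, {
    for (rep in 1:50) {
      types <- sample(names(oracle_map), 200, replace = TRUE)
      v <- data.frame(ref = substr(types, 1, 1), alt = substr(types, 3, 3))
      counts <- spectrum_6class(v)
      expected <- table(factor(unname(oracle_map[types]),
                               levels = names(printed_spectrum)))
      expect_identical(as.integer(counts), as.integer(expected))
      expect_equal(titv(counts),
                   sum(expected[c("C>T", "T>C")]) /
                     sum(expected[c("C>A", "C>G", "T>A", "T>G")]))
    }
  })
})

test_that("Ti/Tv boundary cases", {
  expect_equal(titv(stats::setNames(rep(10L, 6), names(printed_spectrum))),
               0.5)
  only_ti <- stats::setNames(c(0L, 0L, 5L, 0L, 5L, 0L),
                             names(printed_spectrum))
  expect_error(titv(only_ti), "no transversions")
})

test_that("burden statistics use the printed effect-class composition", {
  classes <- rep(c("silent", "missense", "nonsense", "frameshift_del",
                   "frameshift_ins"), c(799, 760, 19, 11, 8))
  v <- data.frame(patient = rep(sprintf("P%d", 1:6), length.out = 1597),
                  effect_class = classes)
  b <- burden_stats(v)
  expect_identical(b$total, 1597L)
  expect_identical(unname(b$class_totals),
                   c(799L, 760L, 19L, 11L, 8L))
  expect_equal(sum(b$per_patient$burden), 1597 - 799)
})

test_that("burden excludes silent variants and is invariant to injecting them", {
  v <- data.frame(patient = "P1", effect_class = rep("missense", 3))
  b <- burden_stats(v)
  expect_equal(b$per_patient$burden, 3)
  expect_equal(b$median_burden, 3)
  more_silent <- rbind(v, data.frame(patient = c("P1", "P2"),
                                     effect_class = "silent"))
  b2 <- burden_stats(more_silent)
  expect_equal(b2$per_patient$burden[b2$per_patient$patient == "P1"], 3)
  expect_equal(b2$median_burden, stats::median(c(3, 0)))
  all_silent <- data.frame(patient = "P1", effect_class = rep("silent", 5))
  expect_equal(burden_stats(all_silent)$per_patient$burden, 0)
  expect_error(burden_stats(data.frame(patient = "P1",
                                       effect_class = "splice")),
               "unknown effect class")
})

test_that("binomial class enrichment detects the printed excess of C>T", {
  at_expectation <- stats::setNames(rep(100L, 6), names(printed_spectrum))
  res <- class_enrichment_test(at_expectation)
  expect_true(all(res$p_value == 1))
  res2 <- class_enrichment_test(printed_spectrum)
  expect_lt(res2$p_value[res2$class == "C>T"], 1e-6)
  expect_identical(res2$direction[res2$class == "C>T"], "enriched")
  expect_identical(res2$direction[res2$class == "T>A"], "depleted")
  expect_lt(res2$p_value[res2$class == "T>A"], 1e-6)
  expect_error(class_enrichment_test(at_expectation, rep(0.2, 6)), "sum to 1")
})

test_that("CNV dose test: degenerate, power and seed-stability behaviour", {
  fc <- withr::with_seed(23, stats::setNames(stats::rnorm(1000, 0, 0.5),
                                             sprintf("g%04d", 1:1000)))
  # loss set = all genes: every null draw equals the observed mean
  all_genes <- cnv_dose_test(fc, names(fc), n_perm = 200, seed = 1)
  expect_equal(all_genes$p_value, 1)
  # strong dose effect on 100 genes is detected
  fc_shift <- fc
  loss <- names(fc)[1:100]
  fc_shift[loss] <- fc_shift[loss] - 1
  hit <- cnv_dose_test(fc_shift, loss, n_perm = 999, seed = 2)
  expect_lte(hit$p_value, 0.005)
  # Monte-Carlo stability across seeds
  p1 <- cnv_dose_test(fc, names(fc)[1:50], n_perm = 400, seed = 5)$p_value
  p1b <- cnv_dose_test(fc, names(fc)[1:50], n_perm = 400, seed = 5)$p_value
  p2 <- cnv_dose_test(fc, names(fc)[1:50], n_perm = 400, seed = 6)$p_value
  expect_identical(p1, p1b)
  expect_lt(abs(p1 - p2), 2 / sqrt(400))
  expect_error(cnv_dose_test(fc, c("nope1", "nope2")), "no loss gene")
})

test_that("CNV dose test p-values are calibrated under the null", {
  hits <- 0L
  for (s in 1:50) {
    fc <- withr::with_seed(3000 + s,
                           stats::setNames(stats::rnorm(400),
                                           sprintf("g%03d", 1:400)))
    loss <- withr::with_seed(4000 + s, sample(names(fc), 40))
    p <- cnv_dose_test(fc, loss, n_perm = 200, seed = s)$p_value
    hits <- hits + (p <= 0.05)
  }
  se <- sqrt(0.05 * 0.95 / 50)
  expect_lte(hits / 50, 0.05 + 3 * se)
})
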