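test_that("heteroplasmic fraction and Wilson interval behave at the edges", {
  expect_equal(heteroplasmic_fraction(10, 90)$hf, 0.10)
  z <- heteroplasmic_fraction(0, 100)
  expect_equal(z$hf, 0)
  expect_equal(z$lower, 0)
  expect_gt(z$upper, 0)
  expect_equal(heteroplasmic_fraction(57, 43)$hf, 0.57)
  expect_error(heteroplasmic_fraction(0, 0), "depth")
  # interval always contains the point estimate, within [0,1]
  grid <- expand.grid(alt = c(0, 1, 5, 50, 100), ref = c(1, 10, 100))
  hf <- heteroplasmic_fraction(grid$alt, grid$ref)
  expect_true(all(hf$lower <= hf$hf & hf$hf <= hf$upper))
  expect_true(all(hf$lower >= 0 & hf$upper <= 1))
})

test_that("Wilson interval matches the prop.test score interval", {
  for (case in list(c(13, 37), c(57, 43), c(2, 998))) {
    ours <- heteroplasmic_fraction(case[1], case[2])
    ref <- stats::prop.test(case[1], sum(case), correct = FALSE)$conf.int
    expect_equal(ours$lower, ref[1], tolerance = 1e-9)
    expect_equal(ours$upper, ref[2], tolerance = 1e-9)
  }
})

test_that("origin classification follows the concordance/detection rules", {
  expect_identical(classify_origin(0.98, 0.99), "germline")
  expect_identical(classify_origin(0.05, 0.0), "somatic")
  expect_identical(classify_origin(1.0, NA), "somatic")   # homoplasmic somatic
  expect_identical(classify_origin(0.50, 0.80), "unclassified")
  expect_identical(classify_origin(c(0.9, 0.03), c(0.85, 0.001)),
                   c("germline", "somatic"))
})

# independent oracle: translate the whole gene with Biostrings and compare
# the affected amino acid
annotate_oracle <- function(pos, ref, alt, map, genome) {
  hit <- map[map$start <= pos & map$end >= pos, , drop = FALSE]
  if (!nrow(hit)) return("other_noncoding")
  g <- hit[1, ]
  if (g$type != "protein")
    return(c(trna = "tRNA", rrna = "rRNA", dloop = "dloop")[[g$type]])
  code <- Biostrings::getGeneticCode("2")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  seq <- substr(genome, g$start, g$end)
  if (g$strand == "-") {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
    idx <- g$end - pos + 1L
    sub <- comp[[alt]]
  } else {
    idx <- pos - g$start + 1L
    sub <- alt
  }
  mut <- seq
  substr(mut, idx, idx) <- sub
  tr <- function(s) as.character(Biostrings::translate(
    Biostrings::DNAString(s), genetic.code = code, no.init.codon = TRUE))
  ci <- ceiling(idx / 3)
  aa_ref <- substr(tr(seq), ci, ci)
  aa_alt <- substr(tr(mut), ci, ci)
  if (aa_ref == aa_alt) "synonymous"
  else if (aa_alt == "*" && aa_ref != "*") "stop_gain"
  else "nonsynonymous"
}

test_that("substitution annotation matches the whole-gene translation oracle", {
  map <- toy_mt_gene_map()
  genome <- toy_mt_genome()
  base_at <- function(p) substr(genome, p, p)
  withr::with_seed(6, {
    pos <- sample.int(16569L, 250)
    ref <- vapply(pos, base_at, "")
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1), "")
  })
  ann <- annotate_mt(pos, ref, alt, map, genome)
  oracle <- vapply(seq_along(pos), function(i)
    annotate_oracle(pos[i], ref[i], alt[i], map, genome), "")
  expect_identical(ann$functional_class, unname(oracle))
  # light-strand gene handled like the oracle over its full length
  nd6 <- 14149:14673
  ref6 <- vapply(nd6, base_at, "")
  alt6 <- ifelse(ref6 == "A", "G", "A")
  ann6 <- annotate_mt(nd6, ref6, alt6, map, genome)
  oracle6 <- vapply(seq_along(nd6), function(i)
    annotate_oracle(nd6[i], ref6[i], alt6[i], map, genome), "")
  expect_identical(ann6$functional_class, unname(oracle6))
  expect_true(all(ann6$gene == "MT-ND6"))
})

test_that("annotation assigns hypervariable D-loop and flags stop gains", {
  map <- toy_mt_gene_map()
  genome <- toy_mt_genome()
  base_at <- function(p) substr(genome, p, p)
  r <- base_at(16100)
  a <- setdiff(c("A", "C", "G", "T"), r)[1]
  expect_identical(annotate_mt(16100, r, a, map, genome)$functional_class,
                   "dloop")
  # a stop-gain substitution exists within MT-ND5 and is classified as such
  found <- NULL
  for (p in 12337:14148) {
    r <- base_at(p)
    for (a in setdiff(c("A", "C", "G", "T"), r)) {
      ann <- annotate_mt(p, r, a, map, genome)
      if (ann$functional_class == "stop_gain") { found <- ann; break }
    }
    if (!is.null(found)) break
  }
  expect_false(is.null(found))
  expect_identical(found$gene, "MT-ND5")
  # reference mismatches and non-substitutions are rejected
  wrong <- setdiff(c("A", "C", "G", "T"), base_at(5000))[1]
  other <- setdiff(c("A", "C", "G", "T"), c(base_at(5000), wrong))[1]
  expect_error(annotate_mt(5000, wrong, other, map, genome), "does not match")
  expect_error(annotate_mt(5000, base_at(5000), base_at(5000), map, genome),
               "not a substitution")
})

test_that("prioritization applies the published gates in order", {
  thr <- run_config()$mtdna
  v <- data.frame(
    functional_class = c("tRNA", "nonsynonymous", "nonsynonymous",
                         "rRNA", "synonymous"),
    haplogroup_defining = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    nucleotide_variability = c(0, 0.00031, 0, 0.001, 0),
    disease_score = c(0.65, 0.5, 0.99, 0.55, NA))
  out <- prioritize_mt(v, thr)
  expect_true(out$prioritized[1])    # tRNA score 0.65 > 0.35
  expect_true(out$prioritized[2])    # conserved nonsyn above 0.43
  expect_false(out$prioritized[3])   # haplogroup gate wins despite scores
  expect_match(out$reasons[3], "haplogroup")
  expect_false(out$prioritized[4])   # rRNA threshold is 0.60
  expect_false(out$prioritized[5])   # synonymous never scored
  v$functional_class[5] <- "nonsynonymous"
  expect_error(prioritize_mt(v, thr), "disease_score")
})

test_that("prioritization is monotone in variability and score", {
  thr <- run_config()$mtdna
  grid <- expand.grid(v = c(0, 0.001, 0.0026, 0.01),
                      s = c(0.2, 0.43, 0.6, 0.9))
  pr <- prioritize_mt(data.frame(
    functional_class = "nonsynonymous", haplogroup_defining = FALSE,
    nucleotide_variability = grid$v, disease_score = grid$s), thr)$prioritized
  for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
    if (grid$v[j] <= grid$v[i] && grid$s[j] >= grid$s[i] && pr[i])
      expect_true(pr[j])
  }
})

test_that("mtDNA copy ratio reproduces coverage arithmetic", {
  cov <- data.frame(patient = c("P1", "P1", "P2", "P2"),
                    tissue = c("tumor", "normal", "tumor", "normal"),
                    mt_coverage = c(400, 200, 300, 300),
                    nuclear_coverage = c(100, 100, 150, 150))
  r <- mtdna_copy_ratio(cov)
  expect_equal(r$pairs$ratio, c(2, 1))
  expect_equal(r$mean, 1.5)
  cov$nuclear_coverage[2] <- 0
  expect_error(mtdna_copy_ratio(cov), "zero nuclear coverage")
})
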