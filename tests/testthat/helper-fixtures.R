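# small in-code fixtures shared across test files

# omics_matrix from explicit tumor/normal matrices (columns = patients)
pair_matrix <- function(tumor, normal, features = NULL, scale = "log2") {
  np <- ncol(tumor)
  if (is.null(features)) features <- sprintf("f%02d", seq_len(nrow(tumor)))
  v <- cbind(tumor, normal)
  rownames(v) <- features
  colnames(v) <- c(sprintf("P%d_T", seq_len(np)), sprintf("P%d_N", seq_len(np)))
  omics_matrix(v, rep(c("tumor", "normal"), each = np),
               rep(sprintf("P%d", seq_len(np)), 2), scale = scale)
}

# vector with exact sample mean m and sample sd s
exact_moments <- function(n, m, s, seed = 1) {
  z <- withr::with_seed(seed, stats::rnorm(n))
  m + s * as.numeric(scale(z))
}

# independent BH oracle: direct minimization over the step-up definition,
# q_(i) = min over j >= i of p_(j) * m / j on the sorted p-values
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  qs <- vapply(seq_len(m), function(i)
    min(1, min(ps[i:m] * m / (i:m))), numeric(1))
  out <- numeric(m)
  out[ord] <- qs
  out
}

# published six-class spectrum counts
printed_spectrum <- c("C>A" = 400L, "C>G" = 426L, "C>T" = 1696L,
                      "T>A" = 259L, "T>C" = 1228L, "T>G" = 274L)

# variant table realizing given six-class counts (half rendered on the
# purine strand)
spectrum_fixture <- function(counts) {
  rows <- lapply(names(counts), function(cl) {
    n <- counts[[cl]]
    ref <- rep(substr(cl, 1, 1), n)
    alt <- rep(substr(cl, 3, 3), n)
    flip <- seq_len(n) %% 2 == 0
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    ref[flip] <- comp[ref[flip]]
    alt[flip] <- comp[alt[flip]]
    data.frame(ref = ref, alt = alt, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
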