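#' Synthetic mitochondrial gene map
#'
#' A toy gene map on the 16,569 bp mitochondrial coordinate system, laid
#' out like the human mtDNA annotation (D-loop with hypervariable regions
#' HV1 at 16024--16383 and HV2 at 57--372, two rRNA genes, tRNA genes, and
#' the 13 OXPHOS protein genes with MT-ND6 on the light strand). Positions
#' of the loci used in worked examples fall inside the right genes
#' (tRNA-Ala covers 5628, MT-CO2 covers 7874, MT-ND6 covers 14568, MT-TP
#' covers 15991). Protein gene lengths are multiples of three; the reading
#' frame starts at `start` on the + strand and at `end` on the - strand.
#' This map is synthetic: interval bounds are simplified, it is not the
#' rCRS annotation.
#'
#' @return data.frame with columns `gene`, `start`, `end` (1-based
#'   inclusive), `type` (protein/trna/rrna/dloop), `strand`
#' @export
toy_mt_gene_map <- function() {
  map <- rbind(
    data.frame(gene = "MT-DLOOP", start = 16024L, end = 16569L,
               type = "dloop", strand = "+"),
    data.frame(gene = "MT-DLOOP", start = 1L, end = 576L,
               type = "dloop", strand = "+"),
    data.frame(gene = "MT-TF",   start = 577L,   end = 647L,   type = "trna", strand = "+"),
    data.frame(gene = "MT-RNR1", start = 648L,   end = 1601L,  type = "rrna", strand = "+"),
    data.frame(gene = "MT-TV",   start = 1602L,  end = 1670L,  type = "trna", strand = "+"),
    data.frame(gene = "MT-RNR2", start = 1671L,  end = 3229L,  type = "rrna", strand = "+"),
    data.frame(gene = "MT-TL1",  start = 3230L,  end = 3306L,  type = "trna", strand = "+"),
    data.frame(gene = "MT-ND1",  start = 3307L,  end = 4263L,  type = "protein", strand = "+"),
    data.frame(gene = "MT-TM",   start = 4402L,  end = 4469L,  type = "trna", strand = "+"),
    data.frame(gene = "MT-ND2",  start = 4470L,  end = 5510L,  type = "protein", strand = "+"),
    data.frame(gene = "MT-TA",   start = 5587L,  end = 5655L,  type = "trna", strand = "+"),
    data.frame(gene = "MT-CO1",  start = 5904L,  end = 7445L,  type = "protein", strand = "+"),
    data.frame(gene = "MT-CO2",  start = 7586L,  end = 8269L,  type = "protein", strand = "+"),
    data.frame(gene = "MT-ATP6", start = 8527L,  end = 9207L,  type = "protein", strand = "+"),
    data.frame(gene = "MT-CO3",  start = 9208L,  end = 9990L,  type = "protein", strand = "+"),
    data.frame(gene = "MT-ND3",  start = 10059L, end = 10403L, type = "protein", strand = "+"),
    data.frame(gene = "MT-ND4",  start = 10760L, end = 12136L, type = "protein", strand = "+"),
    data.frame(gene = "MT-ND5",  start = 12337L, end = 14148L, type = "protein", strand = "+"),
    data.frame(gene = "MT-ND6",  start = 14149L, end = 14673L, type = "protein", strand = "-"),
    data.frame(gene = "MT-CYB",  start = 14747L, end = 15886L, type = "protein", strand = "+"),
    data.frame(gene = "MT-TP",   start = 15956L, end = 16023L, type = "trna", strand = "+"))
  stopifnot(all(map$type != "protein" | (map$end - map$start + 1L) %% 3L == 0L))
  map
}

#' Synthetic mitochondrial reference sequence
#'
#' A seed-deterministic random 16,569-base sequence to pair with
#' [toy_mt_gene_map()] for substitution annotation. Synthetic stand-in:
#' it is not the rCRS sequence, but it exercises the same coordinate
#' system, strand handling and codon arithmetic.
#'
#' @param seed integer seed
#' @return a single character string of length 16,569
#' @export
toy_mt_genome <- function(seed = 16569L) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"),
                                      MT_GENOME_LENGTH, replace = TRUE),
                               collapse = ""))
}

MT_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

revcomp_base <- function(b) unname(MT_COMPLEMENT[b])

#' Functional annotation of mitochondrial substitutions
#'
#' Assigns each substitution a functional class from its gene-map interval:
#' protein-gene substitutions are translated in-frame under the vertebrate
#' mitochondrial genetic code (AGA/AGG are stops, ATA is Met, TGA is Trp;
#' `Biostrings::getGeneticCode("2")`) and classified as `synonymous`,
#' `nonsynonymous`, or `stop_gain`; positions in tRNA/rRNA/D-loop intervals
#' are labelled accordingly; positions outside every interval are
#' `other_noncoding` (not an error). Light-strand genes are translated on
#' the reverse complement with the frame anchored at the gene end.
#'
#' @param pos 1-based position(s) within \[1, 16569\]
#' @param ref,alt reference and alternate bases (A/C/G/T); `ref` must match
#'   the genome
#' @param gene_map gene map as from [toy_mt_gene_map()]
#' @param genome reference sequence string as from [toy_mt_genome()]
#' @return data.frame with `pos`, `ref`, `alt`, `gene`, `functional_class`
#' @export
annotate_mt <- function(pos, ref, alt, gene_map = toy_mt_gene_map(),
                        genome = toy_mt_genome()) {
  check_mt_positions(pos)
  stopifnot(length(pos) == length(ref), length(ref) == length(alt))
  if (any(ref == alt)) stop("ref == alt is not a substitution")
  code <- Biostrings::getGeneticCode("2")
  base_at <- function(p) substr(genome, p, p)
  mism <- vapply(seq_along(pos), function(i) base_at(pos[i]) != ref[i],
                 logical(1))
  if (any(mism))
    stop("ref allele does not match the reference sequence at position ",
         pos[which(mism)[1]])
  one <- function(p, r, a) {
    hit <- which(gene_map$start <= p & gene_map$end >= p)
    if (!length(hit))
      return(c(gene = NA_character_, functional_class = "other_noncoding"))
    g <- gene_map[hit[1], ]
    if (g$type != "protein")
      return(c(gene = g$gene,
               functional_class = c(trna = "tRNA", rrna = "rRNA",
                                    dloop = "dloop")[[g$type]]))
    if (g$strand == "+") {
      off <- p - g$start
      c_start <- g$start + 3L * (off %/% 3L)
      codon <- substr(genome, c_start, c_start + 2L)
      within <- off %% 3L + 1L
      alt_codon <- codon
      substr(alt_codon, within, within) <- a
    } else {
      off <- g$end - p                      # offset on the coding (light) strand
      c_end <- g$end - 3L * (off %/% 3L)    # genomic end of the codon
      fwd <- substr(genome, c_end - 2L, c_end)
      codon <- paste(rev(vapply(strsplit(fwd, "")[[1]], revcomp_base, "")),
                     collapse = "")
      within <- off %% 3L + 1L
      alt_codon <- codon
      substr(alt_codon, within, within) <- revcomp_base(a)
    }
    ref_aa <- code[[codon]]; alt_aa <- code[[alt_codon]]
    cls <- if (ref_aa == alt_aa) "synonymous"
           else if (alt_aa == "*" && ref_aa != "*") "stop_gain"
           else "nonsynonymous"
    c(gene = g$gene, functional_class = cls)
  }
  res <- t(vapply(seq_along(pos), function(i) one(pos[i], ref[i], alt[i]),
                  c(gene = "", functional_class = "")))
  data.frame(pos = pos, ref = ref, alt = alt, gene = res[, "gene"],
             functional_class = res[, "functional_class"],
             stringsAsFactors = FALSE, row.names = NULL)
}
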