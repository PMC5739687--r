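#' Reference effect table for the targeted-metabolomics preset
#'
#' The 29 metabolites reported as significantly regulated between renal
#' oncocytoma and matched kidney tissue, with their published tumor/normal
#' fold changes (down-regulation printed as a negative fold, meaning
#' `-1/fold` on the multiplicative scale) and compound class. Reduced
#' glutathione is flagged `below_loq_normal`: its normal-tissue levels sit
#' below the limit of quantification, so its fold change is built against
#' the background floor.
#'
#' @return data.frame with columns `metabolite`, `fold` (signed, as
#'   printed), `group`, `below_loq_normal`.
#' @export
metabolite_effect_table <- function() {
  aa <- "amino acids, peptides, and analogues"
  sm <- "phosphosphingolipids"
  ac <- "acyl-carnitines"
  nt <- "nucleotides"
  ce <- "ceramides"
  tab <- data.frame(
    metabolite = c(
      "Reduced glutathione", "Oxidized glutathione", "N-Acetylneuraminic acid",
      "Glutaryl-carnitine", "Cervonyl-carnitine", "Arachidyl-carnitine",
      "Sphingomyelin (d16:1/24:1(15Z))", "Sphingomyelin (d18:0/22:0)",
      "Sphingomyelin (d18:1/26:0)", "ADP", "Ceramide (d18:1/14:0)",
      "Sphingomyelin (d18:1/22:0)", "Sphingomyelin (d18:1/26:1(17Z))",
      "ATP", "NAD+", "NADP",
      "L-Threonine", "Ceramide (d18:1/26:1)", "L-Serine",
      "Ceramide (d18:1/25:1)", "L-Alanine", "Beta-Alanine", "Creatinine",
      "Isovaleryl-carnitine", "N-Acetyl-L-glutamic acid", "L-Glutamine",
      "Kynurenic acid", "Hippuric acid", "Guanidoacetic acid"),
    fold = c(5413, 267, 10.44, 4.64, 3.87, 3.76, 2.88, 2.79, 2.60, 2.53,
             2.43, 2.37, 2.26, 2.19, 2.18, 2.16,
             -2.02, -2.28, -2.32, -2.46, -2.51, -3.08, -5.91, -6.34, -9.62,
             -12.22, -13.27, -18.53, -28.46),
    group = c(aa, aa, "sugar acids and derivatives", ac, ac, ac, sm, sm, sm,
              nt, ce, sm, sm, nt, nt, nt,
              aa, ce, aa, ce, aa, aa, "imidazolines", ac, aa, aa,
              "quinoline carboxylic acids", "benzamides", aa),
    stringsAsFactors = FALSE)
  tab$below_loq_normal <- tab$metabolite == "Reduced glutathione"
  tab
}

#' Multiplicative tumor/normal fold from a signed fold change
#'
#' Reporting convention for metabolite tables: down-regulation is printed as
#' a negative fold `-f`, meaning the tumor/normal ratio is `1/f`.
#'
#' @param fold signed fold change(s)
#' @return multiplicative ratio(s) > 0
#' @export
signed_to_ratio <- function(fold) ifelse(fold >= 0, fold, -1 / fold)

#' Signed fold change from a multiplicative ratio
#' @param ratio multiplicative tumor/normal ratio(s)
#' @return signed fold(s): the ratio itself when >= 1, else `-1/ratio`
#' @export
ratio_to_signed <- function(ratio) ifelse(ratio >= 1, ratio, -1 / ratio)
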