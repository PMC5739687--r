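#' Read a feature-by-sample abundance TSV
#'
#' First column is the feature id, remaining columns are numeric abundances;
#' empty cells are missing values and become `NA` (never zero).
#'
#' @param path TSV path
#' @param group_map named character vector, sample id -> `"tumor"`/`"normal"`
#' @param pair_map named character vector, sample id -> patient id
#' @param scale value scale of the file, `"log2"` or `"linear"`
#' @return an [omics_matrix]
#' @export
read_omics_matrix <- function(path, group_map, pair_map,
                              scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  tab <- utils::read.delim(path, check.names = FALSE,
                           colClasses = c("character"), na.strings = "")
  if (ncol(tab) < 2L) stop("matrix TSV needs a feature column plus samples")
  ids <- tab[[1L]]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  suppressWarnings(storage <- matrix(as.numeric(vals), nrow(vals), ncol(vals),
                                     dimnames = list(ids, colnames(vals))))
  bad <- !is.na(vals) & is.na(storage)
  if (any(bad))
    stop("non-numeric cell(s) in ", path, " (e.g. feature '",
         ids[which(bad, arr.ind = TRUE)[1, 1]], "')")
  omics_matrix(storage, group_map[colnames(storage)],
               pair_map[colnames(storage)], scale = scale)
}

#' Write an omics_matrix as TSV (missing cells written empty)
#' @param x an [omics_matrix]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_omics_matrix <- function(x, path) {
  tab <- data.frame(feature_id = rownames(x$values), x$values,
                    check.names = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' members. Duplicate members within a set are collapsed.
#'
#' @param path GMT path
#' @return named list of character vectors with a `description` attribute
#'   per set; empty file gives an empty collection.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    members <- unique(parts[-(1:2)])
    members <- members[nzchar(members)]
    if (length(parts) < 3L || length(members) < 1L)
      stop("GMT set '", parts[1], "' has no members")
    s <- members
    attr(s, "description") <- parts[2]
    sets[[parts[1]]] <- s
  }
  sets
}

#' Write gene sets in GMT format
#' @param sets named list of character vectors (optionally with a
#'   `description` attribute per set)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, unique(as.character(sets[[nm]]))), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

MT_GENOME_LENGTH <- 16569L

#' Read mitochondrial variants from a TSV table
#'
#' Expected columns: `patient`, `pos`, `ref`, `alt`, `tumor_ref`,
#' `tumor_alt`, `normal_ref`, `normal_alt` (allele depths; `NA` depths mean
#' the variant was not assayed in that tissue). Any further columns
#' (annotation such as `disease_score`) are carried through.
#'
#' @param path TSV path
#' @return data.frame of variants, positions 1-based on the 16,569 bp
#'   mitochondrial coordinate system
#' @export
read_mt_variants <- function(path) {
  v <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""))
  need <- c("patient", "pos", "ref", "alt",
            "tumor_ref", "tumor_alt", "normal_ref", "normal_alt")
  miss <- setdiff(need, names(v))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  check_mt_positions(v$pos)
  v
}

check_mt_positions <- function(pos) {
  if (any(pos < 1L | pos > MT_GENOME_LENGTH))
    stop("mtDNA position(s) outside [1, ", MT_GENOME_LENGTH, "]: ",
         paste(utils::head(pos[pos < 1L | pos > MT_GENOME_LENGTH], 3),
               collapse = ", "))
  invisible(pos)
}

#' Read nuclear somatic variants from a TSV table
#'
#' Expected columns: `patient`, `chrom`, `pos`, `ref`, `alt`,
#' `effect_class`.
#'
#' @param path TSV path
#' @return data.frame of variants
#' @export
read_nuclear_variants <- function(path) {
  v <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""))
  need <- c("patient", "chrom", "pos", "ref", "alt", "effect_class")
  miss <- setdiff(need, names(v))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  v
}

#' Read paired-sample variants from a VCF 4.2 file
#'
#' Uses per-sample `AD` (allele depth) fields of a two-sample (tumor,
#' normal) VCF. Multi-allelic rows are not supported.
#'
#' @param path VCF path
#' @param tumor,normal genotype column names of the tumor and normal sample
#' @param patient patient id to assign to all records
#' @return data.frame in the same shape as [read_mt_variants()]
#' @export
read_variants_vcf <- function(path, tumor = "TUMOR", normal = "NORMAL",
                              patient = "P1") {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  ad <- vcfR::extract.gt(vcf, element = "AD")
  for (s in c(tumor, normal))
    if (!s %in% colnames(ad))
      stop("sample '", s, "' (or its AD field) not present in ", path)
  split_ad <- function(col) {
    parts <- strsplit(col, ",", fixed = TRUE)
    if (any(lengths(parts) != 2L & !is.na(col)))
      stop("AD fields must be 'ref,alt' (biallelic)")
    list(ref = as.integer(vapply(parts, `[`, "", 1L)),
         alt = as.integer(vapply(parts, function(p)
           if (length(p) >= 2L) p[2L] else NA_character_, "")))
  }
  tu <- split_ad(ad[, tumor]); no <- split_ad(ad[, normal])
  out <- data.frame(patient = patient, chrom = fix$CHROM,
                    pos = as.integer(fix$POS), ref = fix$REF, alt = fix$ALT,
                    tumor_ref = tu$ref, tumor_alt = tu$alt,
                    normal_ref = no$ref, normal_alt = no$alt,
                    stringsAsFactors = FALSE)
  if (all(out$chrom %in% c("MT", "chrM", "M"))) check_mt_positions(out$pos)
  out
}

#' Write paired-sample variants as a minimal VCF 4.2 file
#' @param variants data.frame as returned by [read_mt_variants()] (a `chrom`
#'   column is optional; defaults to `"MT"`)
#' @param path output path
#' @return `path`, invisibly
#' @export
write_variants_vcf <- function(variants, path) {
  chrom <- if ("chrom" %in% names(variants)) variants$chrom else "MT"
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
              paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                    "INFO", "FORMAT", "TUMOR", "NORMAL", sep = "\t"))
  ad <- function(r, a) ifelse(is.na(r) | is.na(a), ".", paste(r, a, sep = ","))
  body <- paste(chrom, variants$pos, ".", variants$ref, variants$alt, ".",
                "PASS", ".", "AD",
                ad(variants$tumor_ref, variants$tumor_alt),
                ad(variants$normal_ref, variants$normal_alt), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read copy-number segments (BED3 + copy state)
#'
#' BED convention: 0-based half-open intervals. Expected columns `chrom`,
#' `start`, `end`, `patient`, `copy_state`.
#'
#' @param path TSV path
#' @return data.frame of segments
#' @export
read_cnv_segments <- function(path) {
  seg <- utils::read.delim(path, check.names = FALSE)
  need <- c("chrom", "start", "end", "patient", "copy_state")
  miss <- setdiff(need, names(seg))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (any(seg$end <= seg$start)) stop("segments must satisfy start < end")
  seg
}

#' Write a generic results table as TSV
#' @param x data.frame
#' @param path output path
#' @return `path`, invisibly
#' @export
write_results_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
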