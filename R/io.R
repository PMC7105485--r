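# readers/writers for the plain-text interchange formats: dosage TSV
# (canonical), dosage VCF (read via VariantAnnotation, write minimal VCFv4.2),
# phenotype/haplotype TSV, and the summary-statistics dialect.

dosage_header <- function(dm) {
  vt <- attr(dm, "variants")
  if (is.null(vt)) return(colnames(dm))
  paste(vt$variant_id, vt$effect_allele, sep = ":")
}

#' Write a dosage matrix as TSV
#'
#' Canonical interchange layout: rows are samples, the first column is
#' `sample_id`, remaining columns are named `variant_id:effect_allele` and
#' hold expected effect-allele counts in `[0, 2]`.
#'
#' @param dosages Dosage matrix (optionally carrying a `variants` attribute
#'   with effect alleles).
#' @param path Output path.
#' @param comment Optional `#`-prefixed header lines to prepend.
#' @export
write_dosage <- function(dosages, path, comment = NULL) {
  df <- data.frame(sample_id = rownames(dosages) %||%
                     sprintf("S%06d", seq_len(nrow(dosages))),
                   as.data.frame(unclass(dosages)), check.names = FALSE)
  names(df)[-1] <- dosage_header(dosages)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a dosage matrix
#'
#' Reads the canonical TSV layout, or a VCF carrying a per-sample dosage
#' (`DS`) FORMAT field (fractional imputed dosages are legal). Dosages
#' outside `[0, 2]` raise an error naming the offending entry.
#'
#' @param path Input path.
#' @param format `"tsv"` or `"vcf"`.
#' @return Dosage matrix with `variants` attribute (variant_id,
#'   effect_allele); sample order as in the file.
#' @export
read_dosage <- function(path, format = c("tsv", "vcf")) {
  format <- match.arg(format)
  if (format == "vcf") return(read_dosage_vcf(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  ids <- sub(":[^:]*$", "", colnames(m))
  alleles <- sub("^.*:", "", colnames(m))
  alleles[!grepl(":", colnames(m))] <- NA_character_
  validate_dosage_range(m)
  colnames(m) <- ids
  structure(m, variants = data.frame(variant_id = ids, effect_allele = alleles,
                                     stringsAsFactors = FALSE))
}

validate_dosage_range <- function(m) {
  bad <- which(m < -1e-9 | m > 2 + 1e-9, arr.ind = TRUE)
  if (nrow(bad))
    data_error(sprintf("dosage %.4g outside [0, 2] at sample %s, variant %s",
                       m[bad[1, 1], bad[1, 2]],
                       rownames(m)[bad[1, 1]] %||% bad[1, 1],
                       colnames(m)[bad[1, 2]]))
  invisible(m)
}

read_dosage_vcf <- function(path) {
  if (!requireNamespace("VariantAnnotation", quietly = TRUE))
    config_error("reading VCF requires the VariantAnnotation package")
  vcf <- VariantAnnotation::readVcf(path)
  if (!"DS" %in% names(VariantAnnotation::geno(vcf)))
    data_error("VCF lacks a per-sample DS (dosage) FORMAT field")
  ds <- VariantAnnotation::geno(vcf)$DS
  m <- t(matrix(as.numeric(ds), nrow = nrow(ds),
                dimnames = dimnames(ds)[1:2]))
  alt <- as.character(unlist(VariantAnnotation::alt(vcf)))
  validate_dosage_range(m)
  structure(m, variants = data.frame(variant_id = colnames(m),
                                     effect_allele = alt,
                                     stringsAsFactors = FALSE))
}

#' Write a dosage matrix as a minimal VCF with a DS FORMAT field
#'
#' Emits VCFv4.2 with one record per variant on a placeholder contig, the
#' effect allele as ALT, and per-sample expected allele counts in the `DS`
#' genotype field. Intended for round-trip interoperability tests.
#'
#' @param dosages Dosage matrix with a `variants` attribute.
#' @param path Output path.
#' @export
write_dosage_vcf <- function(dosages, path) {
  vt <- attr(dosages, "variants")
  if (is.null(vt)) config_error("dosage matrix lacks variant metadata")
  samples <- rownames(dosages) %||% sprintf("S%06d", seq_len(nrow(dosages)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=1>",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Expected alternate allele dosage\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  for (j in seq_len(ncol(dosages))) {
    ref <- setdiff(c("A", "C", "G", "T"), vt$effect_allele[j])[1]
    writeLines(paste(c("1", j, vt$variant_id[j], ref, vt$effect_allele[j],
                       ".", "PASS", ".", "DS",
                       formatC(dosages[, j], format = "g", digits = 8)),
                     collapse = "\t"), con)
  }
}

#' Write / read phenotype tables
#'
#' TSV with `sample_id`, `status` (0/1) and any further covariate or score
#' columns (PCs, age, sex, `titer_u_ml`, `grs`, `crs`).
#'
#' @param phenotypes Data frame with at least `sample_id` and `status`.
#' @param path File path.
#' @param comment Optional header comment lines.
#' @export
write_phenotypes <- function(phenotypes, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(phenotypes, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(df)))
    data_error("phenotype table needs sample_id and status columns")
  if (!all(df$status %in% 0:1)) data_error("status must be 0/1")
  df
}

#' Write / read phased classical-allele haplotypes
#'
#' Long TSV with columns `sample_id`, `hap` (1/2), `locus`, `allele`.
#'
#' @param haplotypes `n x 2` character matrix of alleles (rownames = sample
#'   ids) or an already-long data frame.
#' @param path File path.
#' @param locus Locus label used when a matrix is supplied.
#' @export
write_haplotypes <- function(haplotypes, path, locus = "DRB1") {
  if (is.matrix(haplotypes)) {
    ids <- rownames(haplotypes) %||% sprintf("S%06d", seq_len(nrow(haplotypes)))
    haplotypes <- data.frame(
      sample_id = rep(ids, 2), hap = rep(1:2, each = nrow(haplotypes)),
      locus = locus, allele = c(haplotypes[, 1], haplotypes[, 2]),
      stringsAsFactors = FALSE)
  }
  utils::write.table(haplotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
}

#' @rdname write_haplotypes
#' @export
read_haplotypes <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("sample_id", "hap", "locus", "allele")
  if (!all(need %in% names(df)))
    data_error(paste("haplotype table needs columns:", paste(need, collapse = ", ")))
  df
}

#' Write / read association summary statistics
#'
#' The interchange dialect has columns `variant_id`, `effect_allele`,
#' `other_allele`, `eaf_cases`, `eaf_controls`, `beta`, `se`, `or`, `ci_low`,
#' `ci_high`, `p`, `n_cases`, `n_controls`, `conditioned_on` (semicolon
#' list). The reader accepts the same dialect, e.g. for meta-analysis of
#' external files.
#'
#' @param stats Data frame in the dialect above.
#' @param path File path.
#' @param comment Optional header comment lines.
#' @export
write_summary_stats <- function(stats, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(stats, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' @rdname write_summary_stats
#' @export
read_summary_stats <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("variant_id", "effect_allele", "beta", "se", "p")
  if (!all(need %in% names(df)))
    data_error(paste("summary statistics need columns:",
                     paste(need, collapse = ", ")))
  df
}

#' Summary-statistics row from an association fit
#'
#' @param fit An `assoc_result` from [fit_additive_logistic()].
#' @param variant_id,effect_allele,other_allele Variant labels.
#' @param eaf_cases,eaf_controls Effect-allele frequencies by status.
#' @return One-row data frame in the summary-statistics dialect.
#' @export
summary_stats_row <- function(fit, variant_id, effect_allele,
                              other_allele = NA, eaf_cases = NA,
                              eaf_controls = NA) {
  data.frame(variant_id = variant_id, effect_allele = effect_allele,
             other_allele = other_allele, eaf_cases = eaf_cases,
             eaf_controls = eaf_controls, beta = fit$beta, se = fit$se,
             or = fit$or_, ci_low = fit$ci95[1], ci_high = fit$ci95[2],
             p = fit$p_wald, n_cases = fit$n_cases,
             n_controls = fit$n_controls,
             conditioned_on = paste(fit$conditioned_on, collapse = ";"),
             stringsAsFactors = FALSE)
}
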