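#' Construct an allele-to-residue lookup table
#'
#' Maps each classical HLA allele (four-digit label) to the amino-acid
#' residue it carries at each polymorphic position of the encoded chain.
#' Every allele must map to exactly one residue per position.
#'
#' @param df Data frame with columns `locus`, `allele`, `position`, `residue`.
#' @return A `residue_table` object.
#' @export
residue_table <- function(df) {
  need <- c("locus", "allele", "position", "residue")
  if (!all(need %in% names(df)))
    config_error(paste("residue table needs columns:", paste(need, collapse = ", ")))
  key <- paste(df$locus, df$allele, df$position)
  if (anyDuplicated(key))
    config_error("each allele must map to exactly one residue per position")
  structure(df[need], class = c("residue_table", "data.frame"))
}

#' Bundled synthetic residue table for DRB1 and DQA1
#'
#' A minimal SYNTHETIC lookup that encodes only the allele/residue pairings
#' relevant to membranous nephropathy risk: DRB1 beta-chain positions 13, 71
#' and 74 (DRB1*1501 carrying 13Arg-71Ala-74Ala, DRB1*0301 carrying
#' 13Ser-71Lys-74Arg, with Arg at 74 the key European risk residue), plus the
#' five mutually correlated DQA1 alpha-chain positions (75, 107, 156, 161,
#' 163) whose haplotype 75Ser-107Ile-156Leu-161Glu-163Ser defines DQA1*0501.
#' It is not an excerpt of the IMGT/HLA catalogue; non-risk alleles carry
#' plausible but synthetic residues.
#'
#' @return A [residue_table()].
#' @export
default_residue_table <- function() {
  drb1 <- rbind(
    c("DRB1*1501", "13", "Arg"), c("DRB1*1501", "71", "Ala"), c("DRB1*1501", "74", "Ala"),
    c("DRB1*0301", "13", "Ser"), c("DRB1*0301", "71", "Lys"), c("DRB1*0301", "74", "Arg"),
    c("DRB1*0405", "13", "His"), c("DRB1*0405", "71", "Arg"), c("DRB1*0405", "74", "Ala"),
    c("DRB1*0701", "13", "Gly"), c("DRB1*0701", "71", "Arg"), c("DRB1*0701", "74", "Gln"),
    c("DRB1*0901", "13", "Phe"), c("DRB1*0901", "71", "Arg"), c("DRB1*0901", "74", "Glu"),
    c("DRB1*1201", "13", "Ser"), c("DRB1*1201", "71", "Arg"), c("DRB1*1201", "74", "Ala"))
  dqa1 <- rbind(
    c("DQA1*0501", "75", "Ser"), c("DQA1*0501", "107", "Ile"),
    c("DQA1*0501", "156", "Leu"), c("DQA1*0501", "161", "Glu"),
    c("DQA1*0501", "163", "Ser"),
    c("DQA1*0101", "75", "Thr"), c("DQA1*0101", "107", "Val"),
    c("DQA1*0101", "156", "Met"), c("DQA1*0101", "161", "Asp"),
    c("DQA1*0101", "163", "Gly"),
    c("DQA1*0301", "75", "Thr"), c("DQA1*0301", "107", "Val"),
    c("DQA1*0301", "156", "Leu"), c("DQA1*0301", "161", "Asp"),
    c("DQA1*0301", "163", "Gly"))
  df <- rbind(
    data.frame(locus = "DRB1", allele = drb1[, 1], position = drb1[, 2],
               residue = drb1[, 3], stringsAsFactors = FALSE),
    data.frame(locus = "DQA1", allele = dqa1[, 1], position = dqa1[, 2],
               residue = dqa1[, 3], stringsAsFactors = FALSE))
  residue_table(df)
}

#' Translate phased classical-allele haplotypes into residue haplotypes
#'
#' Phase is preserved: each chromosome's classical allele is replaced by the
#' residues it carries at every polymorphic position of the locus, giving the
#' phased input required by [conditional_haplotype_test()].
#'
#' @param haplotypes Either an `n x 2` character matrix of classical alleles
#'   (rows = individuals, columns = chromosomes) or a long data frame with
#'   columns `sample_id`, `hap` (1/2), `locus`, `allele`.
#' @param table A [residue_table()].
#' @param locus Locus to translate when `haplotypes` is a long data frame
#'   covering several loci.
#' @return A 3-d character array `[individual, chromosome, position]` of
#'   residues, with position dimnames.
#' @export
assign_residues <- function(haplotypes, table = default_residue_table(),
                            locus = NULL) {
  stopifnot(inherits(table, "residue_table"))
  if (is.data.frame(haplotypes)) {
    if (!is.null(locus)) haplotypes <- haplotypes[haplotypes$locus == locus, ]
    if (length(unique(haplotypes$locus)) != 1L)
      config_error("supply `locus` when the haplotype table covers several loci")
    locus <- haplotypes$locus[1]
    ids <- unique(haplotypes$sample_id)
    hm <- matrix(NA_character_, length(ids), 2,
                 dimnames = list(ids, NULL))
    hm[cbind(match(haplotypes$sample_id, ids), haplotypes$hap)] <- haplotypes$allele
    haplotypes <- hm
  } else {
    locus <- locus %||% unique(table$locus)[1]
  }
  tab <- table[table$locus == locus, ]
  positions <- unique(tab$position)
  alleles <- unique(tab$allele)
  unmapped <- setdiff(unique(as.vector(haplotypes)), alleles)
  if (length(unmapped))
    data_error(paste0("alleles absent from residue table: ",
                      paste(unmapped, collapse = ", ")))
  lut <- matrix(NA_character_, length(alleles), length(positions),
                dimnames = list(alleles, positions))
  lut[cbind(match(tab$allele, alleles), match(tab$position, positions))] <- tab$residue
  if (anyNA(lut))
    config_error("residue table incomplete: every allele needs every position")
  out <- array(NA_character_, c(nrow(haplotypes), 2, length(positions)),
               dimnames = list(rownames(haplotypes), NULL, positions))
  for (k in seq_along(positions)) {
    out[, 1, k] <- lut[haplotypes[, 1], k]
    out[, 2, k] <- lut[haplotypes[, 2], k]
  }
  out
}

#' Per-individual residue dosage at one position
#'
#' Counts, per individual, how many of the two phased chromosomes carry each
#' residue observed at `position`.
#'
#' @param residues Array from [assign_residues()].
#' @param position Position name (character, as in the array dimnames).
#' @return Numeric matrix individuals x residues.
#' @export
residue_dosage <- function(residues, position) {
  r <- residues[, , as.character(position), drop = TRUE]
  lev <- sort(unique(as.vector(r)))
  out <- sapply(lev, function(l) (r[, 1] == l) + (r[, 2] == l))
  colnames(out) <- lev
  out
}

#' Simulate a case-control cohort driven by one multi-allelic locus
#'
#' Haplotypes carrying classical alleles are drawn multinomially at the given
#' control frequencies; disease status follows a prospective logistic model
#' that is additive in allele dosages, with the intercept calibrated exactly
#' to the target prevalence; cases and controls are ascertained to quota.
#'
#' @param allele_freqs Named vector of control haplotype frequencies (sums
#'   to 1).
#' @param allele_log_odds Named vector of per-allele log-odds (reference
#'   alleles 0); names must match `allele_freqs`.
#' @param prevalence Population prevalence.
#' @param n_cases,n_controls Quotas.
#' @param seed Integer seed.
#' @return List with `haplotypes` (`n x 2` character matrix), `dosage`
#'   (individuals x alleles), and `status`.
#' @export
simulate_multiallelic_cohort <- function(allele_freqs, allele_log_odds,
                                         prevalence, n_cases, n_controls,
                                         seed) {
  stopifnot(!is.null(names(allele_freqs)),
            setequal(names(allele_freqs), names(allele_log_odds)))
  if (abs(sum(allele_freqs) - 1) > 1e-8)
    config_error("allele frequencies must sum to 1")
  allele_log_odds <- allele_log_odds[names(allele_freqs)]
  alle <- names(allele_freqs)
  m <- length(alle)
  # exact intercept: enumerate unordered genotypes (HWE)
  gi <- expand.grid(a1 = seq_len(m), a2 = seq_len(m))
  prob <- allele_freqs[gi$a1] * allele_freqs[gi$a2]
  lp <- allele_log_odds[gi$a1] + allele_log_odds[gi$a2]
  f <- function(b0) sum(prob * stats::plogis(b0 + lp)) - prevalence
  b0 <- stats::uniroot(f, c(stats::qlogis(prevalence) - max(abs(lp)) - 1,
                            stats::qlogis(prevalence) + max(abs(lp)) + 1),
                       tol = 1e-12)$root
  need <- c(cases = n_cases, controls = n_controls)
  keep_h <- list(cases = list(), controls = list())
  got <- c(cases = 0L, controls = 0L)
  expected <- n_cases / prevalence
  batch_n <- as.integer(min(2e6, max(5e4, ceiling(expected / 4))))
  max_batches <- ceiling(4 * expected / batch_n) + 10L
  for (batch in seq_len(max_batches)) {
    blk <- local_seed(derive_seed(seed, 100L + batch), {
      h <- matrix(sample.int(m, 2L * batch_n, replace = TRUE,
                             prob = allele_freqs), batch_n, 2)
      st <- stats::rbinom(batch_n, 1L,
                          stats::plogis(b0 + allele_log_odds[h[, 1]] +
                                          allele_log_odds[h[, 2]]))
      list(h = h, st = st)
    })
    for (grp in c("cases", "controls")) {
      idx <- which(blk$st == if (grp == "cases") 1L else 0L)
      idx <- idx[seq_len(min(length(idx), need[[grp]] - got[[grp]]))]
      if (length(idx)) {
        keep_h[[grp]][[length(keep_h[[grp]]) + 1L]] <- blk$h[idx, , drop = FALSE]
        got[[grp]] <- got[[grp]] + length(idx)
      }
    }
    if (all(got >= need)) break
  }
  if (!all(got >= need))
    numeric_error("case/control quota unreachable in bounded draws")
  h <- rbind(do.call(rbind, keep_h$cases), do.call(rbind, keep_h$controls))
  hap <- matrix(alle[h], nrow(h), 2)
  rownames(hap) <- sprintf("S%06d", seq_len(nrow(hap)))
  dosage <- sapply(alle, function(a) (hap[, 1] == a) + (hap[, 2] == a))
  rownames(dosage) <- rownames(hap)
  list(haplotypes = hap, dosage = dosage,
       status = rep(c(1L, 0L), c(n_cases, n_controls)))
}
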