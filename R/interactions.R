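#' Likelihood-ratio test of multiplicative gene-gene interaction
#'
#' Compares the full logistic model with both main effects and the
#' dosage-product interaction term against the reduced model with main
#' effects only (1 df). Ancestry covariates are adjusted for by default; a
#' covariate-free mode is available since the interaction model statement in
#' the source analysis omits covariates.
#'
#' @param dosage_a,dosage_b Additive dosage vectors (variance > 0).
#' @param status 0/1 case status.
#' @param covariates Optional covariate data frame (default-adjusted).
#' @return An `interaction_result`: `beta_interaction`, `se`, `or_`,
#'   `lrt_deviance`, `df = 1`, `p`, `separated`.
#' @export
interaction_lrt <- function(dosage_a, dosage_b, status, covariates = NULL) {
  if (stats::var(dosage_a) == 0 || stats::var(dosage_b) == 0)
    data_error("both dosages must have variance > 0")
  prod_term <- dosage_a * dosage_b
  full <- cbind(a = dosage_a, b = dosage_b, ab = prod_term)
  null <- cbind(a = dosage_a, b = dosage_b)
  res <- lrt_nested(full, null, status, covariates)
  co <- summary(res$full)$coefficients
  beta <- co[".t3", "Estimate"]
  se <- co[".t3", "Std. Error"]
  separated <- !res$full$converged || !res$null$converged ||
    any(!is.finite(stats::coef(res$full))) ||
    any(abs(stats::coef(res$full)) > 15)
  structure(list(
    beta_interaction = beta, se = se, or_ = exp(beta),
    lrt_deviance = res$deviance, df = 1L,
    p = if (separated) NA_real_ else
      stats::pchisq(res$deviance, 1, lower.tail = FALSE),
    separated = separated), class = "interaction_result")
}

#' Pairwise epistasis screen with Bonferroni control
#'
#' Enumerates the lead-SNP-by-HLA-SNP pairs plus any additional shared
#' non-HLA pairs, counts the tests, sets the per-test threshold
#' `family_alpha / n_tests`, and runs [interaction_lrt()] on each pair.
#' Duplicate pairs are deduplicated with a warning.
#'
#' @param dosages Dosage matrix with named columns.
#' @param status 0/1 case status.
#' @param lead_snps Character vector of non-HLA lead SNP ids.
#' @param hla_snps Character vector of independent HLA SNP ids.
#' @param shared_pairs Optional list of `c(a, b)` extra pairs.
#' @param covariates Optional covariate data frame.
#' @param family_alpha Family-wise error target (default 0.05).
#' @return Data frame with one row per pair (`pair`, `beta`, `se`, `p`,
#'   `threshold`, `significant`), with attributes `n_tests` and `threshold`.
#' @export
interaction_screen <- function(dosages, status, lead_snps, hla_snps,
                               shared_pairs = list(), covariates = NULL,
                               family_alpha = 0.05) {
  dosages <- as.matrix(dosages)
  pairs <- c(
    unlist(lapply(lead_snps, function(a) lapply(hla_snps, function(b) c(a, b))),
           recursive = FALSE),
    shared_pairs)
  key <- vapply(pairs, function(p) paste(sort(p), collapse = "|"), "")
  if (anyDuplicated(key)) {
    warning("duplicate interaction pair(s) removed: ",
            paste(unique(key[duplicated(key)]), collapse = ", "))
    pairs <- pairs[!duplicated(key)]
  }
  missing_ids <- setdiff(unique(unlist(pairs)), colnames(dosages))
  if (length(missing_ids))
    data_error(paste0("dosages missing for: ", paste(missing_ids, collapse = ", ")))
  n_tests <- length(pairs)
  thr <- family_alpha / n_tests
  rows <- lapply(pairs, function(p) {
    r <- interaction_lrt(dosages[, p[1]], dosages[, p[2]], status, covariates)
    data.frame(pair = paste(p, collapse = "x"), beta = r$beta_interaction,
               se = r$se, p = r$p, threshold = thr,
               significant = !is.na(r$p) & r$p < thr,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), n_tests = n_tests, threshold = thr)
}

#' Stratified genotype-combination odds-ratio grid
#'
#' Cross-tabulates hard-called genotypes of two variants (dosages rounded to
#' 0/1/2) and reports the crude odds ratio of each cell against a reference
#' cell: `OR = (cases_cell * controls_ref) / (controls_cell * cases_ref)`,
#' with Woolf 95% confidence intervals `exp(log OR +/- 1.96 sqrt(sum 1/n))`.
#' Cells with a zero count in the contrast are flagged and get `NA` (no
#' continuity correction).
#'
#' @param dosage_a,dosage_b Dosage vectors (rounded to hard calls).
#' @param status 0/1 case status.
#' @param reference_cell `c(dosage_a, dosage_b)` of the reference cell
#'   (default double non-carrier `c(0, 0)`); must be non-empty in both cases
#'   and controls.
#' @return Data frame with one row per cell: `dosage_a`, `dosage_b`,
#'   `n_cases`, `n_controls`, `or_`, `ci_low`, `ci_high`, `flagged`.
#' @export
genotype_grid <- function(dosage_a, dosage_b, status,
                          reference_cell = c(0, 0)) {
  da <- pmin(pmax(round(dosage_a), 0), 2)
  db <- pmin(pmax(round(dosage_b), 0), 2)
  status <- as.integer(status)
  grid <- expand.grid(dosage_a = 0:2, dosage_b = 0:2)
  cnt <- function(a, b, st) sum(da == a & db == b & status == st)
  grid$n_cases <- mapply(cnt, grid$dosage_a, grid$dosage_b, 1L)
  grid$n_controls <- mapply(cnt, grid$dosage_a, grid$dosage_b, 0L)
  ref <- grid$dosage_a == reference_cell[1] & grid$dosage_b == reference_cell[2]
  ca_ref <- grid$n_cases[ref]
  co_ref <- grid$n_controls[ref]
  if (ca_ref == 0 || co_ref == 0)
    data_error("reference cell is empty in cases or controls")
  grid$flagged <- (grid$n_cases == 0 | grid$n_controls == 0) & !ref
  lor <- log(grid$n_cases) + log(co_ref) - log(grid$n_controls) - log(ca_ref)
  se <- sqrt(1 / grid$n_cases + 1 / grid$n_controls + 1 / ca_ref + 1 / co_ref)
  grid$or_ <- ifelse(grid$flagged, NA_real_, exp(lor))
  grid$ci_low <- ifelse(grid$flagged, NA_real_, exp(lor - stats::qnorm(0.975) * se))
  grid$ci_high <- ifelse(grid$flagged, NA_real_, exp(lor + stats::qnorm(0.975) * se))
  grid$or_[ref] <- 1
  structure(grid, reference_cell = reference_cell)
}
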