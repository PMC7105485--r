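#' Additive logistic association for a single dosage variant
#'
#' Fits case-control status on allele dosage under additive coding by
#' maximum-likelihood logistic regression, with optional ancestry covariates
#' and a conditioning set of other dosages entered as covariates. Complete or
#' quasi-complete separation is detected (non-convergence or diverging
#' coefficients) and flagged explicitly rather than returned silently.
#'
#' @param dosage Numeric dosage vector in `[0, 2]` (fractional allowed).
#' @param status 0/1 case status.
#' @param covariates Optional data frame / matrix of covariates (e.g. PCs).
#' @param conditioning Optional matrix (or vector) of conditioning dosages.
#' @return An `assoc_result`: `beta`, `se`, `or_`, `ci95`, `p_wald`, `p_lrt`,
#'   `n_cases`, `n_controls`, `df`, `separated`, `conditioned_on`.
#' @export
fit_additive_logistic <- function(dosage, status, covariates = NULL,
                                  conditioning = NULL) {
  status <- as.integer(status)
  if (sum(status == 1) < 1 || sum(status == 0) < 1)
    data_error("need at least one case and one control")
  if (stats::var(dosage) == 0)
    data_error("dosage has zero variance")
  df <- data.frame(.y = status, .d = dosage)
  cond_names <- character()
  if (!is.null(conditioning)) {
    conditioning <- as.matrix(conditioning)
    cond_names <- colnames(conditioning) %||%
      paste0("cond", seq_len(ncol(conditioning)))
    colnames(conditioning) <- make.names(cond_names)
    df <- cbind(df, as.data.frame(conditioning))
  }
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    names(covariates) <- make.names(names(covariates))
    df <- cbind(df, covariates)
  }
  rhs <- setdiff(names(df), ".y")
  full <- suppressWarnings(stats::glm(
    stats::reformulate(rhs, ".y"), family = stats::binomial(), data = df))
  rhs0 <- setdiff(rhs, ".d")
  if (!length(rhs0)) rhs0 <- "1"
  reduced <- suppressWarnings(stats::glm(
    stats::reformulate(rhs0, ".y"), family = stats::binomial(), data = df))
  co <- summary(full)$coefficients
  beta <- co[".d", "Estimate"]
  se <- co[".d", "Std. Error"]
  separated <- !full$converged || !is.finite(beta) || abs(beta) > 15 ||
    !is.finite(se) || se > 100
  dev <- as.numeric(2 * (stats::logLik(full) - stats::logLik(reduced)))
  structure(list(
    beta = beta, se = se, or_ = exp(beta),
    ci95 = exp(beta + c(-1, 1) * stats::qnorm(0.975) * se),
    p_wald = if (separated) NA_real_ else co[".d", "Pr(>|z|)"],
    p_lrt = if (separated) NA_real_ else
      stats::pchisq(dev, df = 1, lower.tail = FALSE),
    deviance = dev, n_cases = sum(status == 1), n_controls = sum(status == 0),
    df = 1L, separated = separated, conditioned_on = cond_names,
    model = full), class = "assoc_result")
}

#' @export
print.assoc_result <- function(x, ...) {
  cat(sprintf("OR = %.3f (95%% CI %.3f-%.3f), beta = %.4f (se %.4f), P = %.3g%s\n",
              x$or_, x$ci95[1], x$ci95[2], x$beta, x$se, x$p_wald,
              if (x$separated) " [SEPARATION]" else ""))
  invisible(x)
}

#' Greedy stepwise conditional scan of a locus
#'
#' At each round every unselected variant is tested conditional on the
#' selected set; the smallest Wald p below `threshold` is added; the scan
#' stops when no variant qualifies. Candidates perfectly collinear with an
#' already-selected variant are skipped (recorded in `skipped`).
#'
#' @param dosages Dosage matrix (individuals x variants, named columns).
#' @param status 0/1 case status.
#' @param covariates Optional covariate data frame.
#' @param threshold Selection p-value threshold (default genome-wide 5e-8).
#' @return List with `steps` (ordered selected ids), `scans` (one data frame
#'   per round: variant_id, beta, se, p), and `skipped`.
#' @export
conditional_scan <- function(dosages, status, covariates = NULL,
                             threshold = 5e-8) {
  dosages <- as.matrix(dosages)
  if (is.null(colnames(dosages)))
    colnames(dosages) <- paste0("v", seq_len(ncol(dosages)))
  selected <- character()
  skipped <- character()
  scans <- list()
  repeat {
    todo <- setdiff(colnames(dosages), c(selected, skipped))
    rows <- lapply(todo, function(v) {
      if (length(selected)) {
        r2 <- suppressWarnings(
          stats::cor(dosages[, v], dosages[, selected, drop = FALSE]))^2
        if (any(is.na(r2)) || any(r2 > 1 - 1e-12)) return(NULL)
      }
      fit <- fit_additive_logistic(
        dosages[, v], status, covariates,
        if (length(selected)) dosages[, selected, drop = FALSE])
      data.frame(variant_id = v, beta = fit$beta, se = fit$se,
                 p = fit$p_wald, separated = fit$separated,
                 stringsAsFactors = FALSE)
    })
    drop_col <- todo[vapply(rows, is.null, TRUE)]
    if (length(drop_col)) {
      message("skipping collinear variant(s): ", paste(drop_col, collapse = ", "))
      skipped <- c(skipped, drop_col)
    }
    scan <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
    scans[[length(scans) + 1L]] <- scan
    ok <- which(!is.na(scan$p) & scan$p < threshold)
    if (!length(ok)) break
    selected <- c(selected, scan$variant_id[ok[which.min(scan$p[ok])]])
  }
  list(steps = selected, scans = scans, skipped = skipped)
}

#' Inverse-variance fixed-effects meta-analysis
#'
#' Combines per-cohort effect estimates with weights `1/se^2`, and reports
#' Cochran's Q heterogeneity statistic with `k - 1` degrees of freedom and
#' `I2 = max(0, (Q - (k-1)) / Q) * 100`.
#'
#' @param beta Numeric vector of per-cohort log-odds estimates.
#' @param se Matching standard errors (finite, positive).
#' @param effect_allele Optional per-cohort effect-allele labels; differing
#'   labels raise a harmonization error.
#' @return A `meta_result` list: `beta_fixed`, `se_fixed`, `p`, `Q`, `q_p`,
#'   `I2`, `k_studies`.
#' @export
meta_fixed <- function(beta, se, effect_allele = NULL) {
  if (length(beta) < 2 || length(beta) != length(se))
    data_error("need >= 2 matched beta/se pairs")
  if (any(!is.finite(se)) || any(se <= 0))
    data_error("standard errors must be finite and positive")
  if (!is.null(effect_allele) && length(unique(effect_allele)) > 1)
    data_error("effect alleles differ across cohorts: harmonize before meta-analysis")
  w <- 1 / se^2
  bf <- sum(w * beta) / sum(w)
  sef <- sqrt(1 / sum(w))
  q <- sum(w * (beta - bf)^2)
  k <- length(beta)
  structure(list(
    beta_fixed = bf, se_fixed = sef,
    p = 2 * stats::pnorm(-abs(bf / sef)),
    Q = q, q_p = stats::pchisq(q, k - 1, lower.tail = FALSE),
    I2 = max(0, (q - (k - 1)) / q) * 100, k_studies = k),
    class = "meta_result")
}

#' Genomic inflation factor
#'
#' `lambda = median(qchisq(p, 1, lower = FALSE)) / qchisq(0.5, 1)`, computed
#' after excluding designated regions (e.g. the HLA and PLA2R loci).
#'
#' @param p_values Vector of association p-values.
#' @param exclude Optional logical vector marking variants to exclude.
#' @return The inflation factor lambda.
#' @export
genomic_lambda <- function(p_values, exclude = NULL) {
  if (!is.null(exclude)) p_values <- p_values[!exclude]
  p_values <- p_values[is.finite(p_values)]
  if (length(p_values) < 100)
    data_error("need >= 100 p-values after exclusion")
  chisq <- stats::qchisq(p_values, df = 1, lower.tail = FALSE)
  stats::median(chisq) / stats::qchisq(0.5, df = 1)
}

#' Quality-control filter for imputed HLA alleles
#'
#' Retains common alleles imputed with high certainty: minor allele frequency
#' strictly greater than `maf_threshold` AND imputation R-squared strictly
#' greater than `r2_threshold` (strict inequalities; an allele at exactly the
#' boundary is dropped). A missing R-squared is an error, never a silent pass.
#'
#' @param alleles Data frame with columns `allele`, `freq`, `r2`.
#' @param maf_threshold,r2_threshold Strict lower bounds (defaults 0.01, 0.8).
#' @return The input with logical `retained` and character `drop_reason`.
#' @export
hla_qc_filter <- function(alleles, maf_threshold = 0.01, r2_threshold = 0.8) {
  need <- c("allele", "freq", "r2")
  if (!all(need %in% names(alleles)))
    config_error(paste("need columns:", paste(need, collapse = ", ")))
  if (anyNA(alleles$r2))
    data_error(paste0("missing imputation R2 for: ",
                      paste(alleles$allele[is.na(alleles$r2)], collapse = ", ")))
  maf <- pmin(alleles$freq, 1 - alleles$freq)
  pass_maf <- maf > maf_threshold
  pass_r2 <- alleles$r2 > r2_threshold
  alleles$retained <- pass_maf & pass_r2
  alleles$drop_reason <- ifelse(alleles$retained, "",
                                ifelse(!pass_maf & !pass_r2, "MAF;R2",
                                       ifelse(!pass_maf, "MAF", "R2")))
  alleles
}

# shared LRT helper: two nested dosage-term models over the same covariates
lrt_nested <- function(full_terms, null_terms, status, covariates) {
  df <- data.frame(.y = as.integer(status))
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    names(covariates) <- make.names(names(covariates))
    df <- cbind(df, covariates)
  }
  add_terms <- function(d, terms, prefix) {
    if (is.null(terms) || ncol(terms) == 0) return(d)
    terms <- as.matrix(terms)
    colnames(terms) <- paste0(prefix, seq_len(ncol(terms)))
    cbind(d, as.data.frame(terms))
  }
  d_full <- add_terms(df, full_terms, ".t")
  d_null <- add_terms(df, null_terms, ".u")
  fit <- function(d) {
    rhs <- setdiff(names(d), ".y")
    if (!length(rhs)) rhs <- "1"
    suppressWarnings(stats::glm(stats::reformulate(rhs, ".y"),
                                family = stats::binomial(), data = d))
  }
  f_full <- fit(d_full)
  f_null <- fit(d_null)
  dev <- as.numeric(2 * (stats::logLik(f_full) - stats::logLik(f_null)))
  list(deviance = max(dev, 0), full = f_full, null = f_null)
}

#' Multi-allelic omnibus likelihood-ratio test
#'
#' Jointly tests all alleles at a multi-allelic locus: the full model carries
#' `m - 1` allele-dosage terms (the most frequent allele omitted as the
#' reference, a determinism choice — the deviance is invariant to which
#' allele is dropped) against a covariate-only reduced model. The deviance
#' `-2 log LR` follows a chi-squared distribution with `m - 1` degrees of
#' freedom. Zero-variance alleles are collapsed into the reference with a
#' warning and the degrees of freedom reduced.
#'
#' @param allele_dosage Matrix individuals x alleles; per-individual dosages
#'   sum to at most 2.
#' @param status 0/1 case status.
#' @param covariates Optional covariate data frame.
#' @return An `omnibus_result`: `deviance`, `df`, `p`, `reference`.
#' @export
omnibus_multiallelic <- function(allele_dosage, status, covariates = NULL) {
  allele_dosage <- as.matrix(allele_dosage)
  if (ncol(allele_dosage) < 2)
    data_error("need >= 2 alleles")
  if (any(rowSums(allele_dosage) > 2 + 1e-8))
    data_error("per-individual allele dosages must sum to <= 2")
  keep <- apply(allele_dosage, 2, stats::var) > 0
  if (!all(keep)) {
    warning("collapsing zero-variance allele(s) into reference: ",
            paste(colnames(allele_dosage)[!keep], collapse = ", "))
    allele_dosage <- allele_dosage[, keep, drop = FALSE]
    if (ncol(allele_dosage) < 2)
      data_error("fewer than 2 variable alleles remain")
  }
  ref <- which.max(colSums(allele_dosage))
  full_terms <- allele_dosage[, -ref, drop = FALSE]
  res <- lrt_nested(full_terms, NULL, status, covariates)
  df <- ncol(full_terms)
  structure(list(deviance = res$deviance, df = df,
                 p = stats::pchisq(res$deviance, df, lower.tail = FALSE),
                 reference = colnames(allele_dosage)[ref]),
            class = "omnibus_result")
}

#' @export
print.omnibus_result <- function(x, ...) {
  cat(sprintf("omnibus LRT: deviance = %.3f, df = %d, P = %.3g (ref %s)\n",
              x$deviance, x$df, x$p, x$reference %||% "-"))
  invisible(x)
}

haplotype_strings <- function(residues, positions) {
  if (!length(positions)) return(NULL)
  h1 <- apply(residues[, 1, as.character(positions), drop = FALSE], 1, paste,
              collapse = "/")
  h2 <- apply(residues[, 2, as.character(positions), drop = FALSE], 1, paste,
              collapse = "/")
  cbind(h1, h2)
}

haplotype_dosage <- function(hapstr) {
  lev <- sort(unique(as.vector(hapstr)))
  out <- sapply(lev, function(l) (hapstr[, 1] == l) + (hapstr[, 2] == l))
  colnames(out) <- lev
  out
}

#' Conditional haplotype test of one amino-acid position
#'
#' Tests whether adding a polymorphic position to an already-conditioned set
#' of positions explains additional risk. The null model carries one dosage
#' term per unique phased haplotype over the conditioned positions; the full
#' model carries the unique haplotypes over the conditioned positions plus
#' the test position. The likelihood-ratio statistic has `k` degrees of
#' freedom, where `k` is the number of additional unique haplotypes the test
#' position creates. With no conditioning this reduces to the `m - 1` df
#' omnibus test of the position's residues.
#'
#' @param residues Phased residue array from [assign_residues()].
#' @param test_position Position to test.
#' @param conditioned_positions Character vector of already-selected
#'   positions (may be empty).
#' @param status 0/1 case status.
#' @param covariates Optional covariate data frame.
#' @return An `omnibus_result` with `df = k`; when the test position creates
#'   no new haplotypes (perfect LD), `df = 0`, `p = NA`, and
#'   `no_new_haplotypes = TRUE`.
#' @export
conditional_haplotype_test <- function(residues, test_position,
                                       conditioned_positions = character(),
                                       status, covariates = NULL) {
  test_position <- as.character(test_position)
  conditioned_positions <- as.character(conditioned_positions)
  if (length(unique(as.vector(residues[, , test_position]))) < 2)
    data_error("test position must have >= 2 residues")
  hs_null <- haplotype_strings(residues, conditioned_positions)
  hs_full <- haplotype_strings(residues, c(conditioned_positions, test_position))
  n_null <- if (is.null(hs_null)) 1L else length(unique(as.vector(hs_null)))
  n_full <- length(unique(as.vector(hs_full)))
  k <- n_full - n_null
  if (k == 0)
    return(structure(list(deviance = 0, df = 0L, p = NA_real_,
                          no_new_haplotypes = TRUE),
                     class = "omnibus_result"))
  drop_ref <- function(d) d[, -which.max(colSums(d)), drop = FALSE]
  full_terms <- drop_ref(haplotype_dosage(hs_full))
  null_terms <- if (is.null(hs_null)) NULL else drop_ref(haplotype_dosage(hs_null))
  res <- lrt_nested(full_terms, null_terms, status, covariates)
  structure(list(deviance = res$deviance, df = k,
                 p = stats::pchisq(res$deviance, k, lower.tail = FALSE),
                 no_new_haplotypes = FALSE),
            class = "omnibus_result")
}

#' Stepwise scan over polymorphic amino-acid positions
#'
#' Greedy forward selection: each round runs [conditional_haplotype_test()]
#' for every unselected polymorphic position conditional on the selected
#' ones, adds the smallest-p position if it falls below `alpha`, and stops at
#' the first round with no qualifying position.
#'
#' @param residues Phased residue array from [assign_residues()].
#' @param status 0/1 case status.
#' @param covariates Optional covariate data frame.
#' @param alpha Stopping threshold (default genome-wide 5e-8; exposed because
#'   no canonical value exists for amino-acid scans).
#' @return List with `selected` (ordered positions) and `rounds` (one data
#'   frame per round: position, deviance, df, p).
#' @export
stepwise_position_scan <- function(residues, status, covariates = NULL,
                                   alpha = 5e-8) {
  positions <- dimnames(residues)[[3]]
  polymorphic <- positions[vapply(positions, function(p)
    length(unique(as.vector(residues[, , p]))) >= 2, TRUE)]
  selected <- character()
  rounds <- list()
  repeat {
    todo <- setdiff(polymorphic, selected)
    if (!length(todo)) break
    tab <- do.call(rbind, lapply(todo, function(p) {
      r <- conditional_haplotype_test(residues, p, selected, status, covariates)
      data.frame(position = p, deviance = r$deviance, df = r$df, p = r$p,
                 stringsAsFactors = FALSE)
    }))
    rounds[[length(rounds) + 1L]] <- tab
    ok <- which(!is.na(tab$p) & tab$p < alpha)
    if (!length(ok)) break
    selected <- c(selected, tab$position[ok[which.min(tab$p[ok])]])
  }
  list(selected = selected, rounds = rounds)
}
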