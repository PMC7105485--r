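#' Published genetic risk score definitions
#'
#' Loads the ethnicity-specific GRS coefficient sets shipped with the
#' package (versioned JSON under `inst/extdata/`): per-allele weights, the
#' dosage-product interaction term, and the control-arm standardization
#' constants, all at full printed precision. The PLA2R1 variant in the score
#' is rs6707458 (the conditionally independent score SNP), not the GWAS top
#' SNP rs17831251.
#'
#' @param ethnicity `"east_asian"` or `"european"`.
#' @param file Optional path to an alternative definitions JSON.
#' @return A `score_definition`: `ethnicity`, `terms` (data frame
#'   `variant_id`, `effect_allele`, `weight`), `interaction_terms`,
#'   `control_mean`, `control_sd`.
#' @export
grs_definition <- function(ethnicity = c("east_asian", "european"),
                           file = NULL) {
  ethnicity <- match.arg(ethnicity)
  file <- file %||% system.file("extdata", "grs_definitions.json",
                                package = "mnarch", mustWork = TRUE)
  defs <- jsonlite::fromJSON(file, simplifyDataFrame = TRUE)
  d <- defs[[ethnicity]]
  if (is.null(d)) config_error(paste("no definition for", ethnicity))
  if (d$control_sd <= 0) config_error("control_sd must be positive")
  structure(list(ethnicity = ethnicity, terms = d$terms,
                 interaction_terms = d$interaction_terms,
                 control_mean = d$control_mean, control_sd = d$control_sd),
            class = "score_definition")
}

#' Compute the standardized genetic risk score
#'
#' Raw score = weighted sum of effect-allele dosages plus weighted dosage
#' products for the interaction terms; standardized score =
#' `(raw - control_mean) / control_sd` with the published control-arm
#' constants. An absent score variant is a hard error (no silent
#' zero-imputation). Missing values (`NA`) within a present variant column
#' are an error by default; `impute_missing = TRUE` substitutes the
#' per-variant sample mean dosage.
#'
#' @param dosages Dosage matrix (individuals x variants, columns named by
#'   `variant_id`), values in `[0, 2]`.
#' @param definition A [grs_definition()].
#' @param impute_missing Mean-impute `NA` dosages instead of erroring.
#' @return Data frame with `grs_raw` and `grs` (standardized), one row per
#'   individual.
#' @export
compute_grs <- function(dosages, definition, impute_missing = FALSE) {
  stopifnot(inherits(definition, "score_definition"))
  dosages <- as.matrix(dosages)
  absent <- setdiff(definition$terms$variant_id, colnames(dosages))
  if (length(absent))
    data_error(paste0("score variants missing from dosage matrix: ",
                      paste(absent, collapse = ", ")))
  if (anyNA(dosages[, definition$terms$variant_id])) {
    if (!impute_missing)
      data_error("NA dosages present (set impute_missing = TRUE to mean-impute)")
    for (v in definition$terms$variant_id) {
      nas <- is.na(dosages[, v])
      if (any(nas)) dosages[nas, v] <- mean(dosages[!nas, v])
    }
  }
  d <- dosages[, definition$terms$variant_id, drop = FALSE]
  if (any(d < -1e-9) || any(d > 2 + 1e-9))
    data_error("dosages must lie in [0, 2]")
  raw <- as.vector(d %*% definition$terms$weight)
  it <- definition$interaction_terms
  for (i in seq_len(NROW(it)))
    raw <- raw + it$weight[i] * dosages[, it$variant_a[i]] * dosages[, it$variant_b[i]]
  data.frame(grs_raw = raw,
             grs = (raw - definition$control_mean) / definition$control_sd)
}

#' Derive the serology weight of the combined risk score
#'
#' Fits the calibration logistic model
#' `status ~ beta1 * GRS + beta2 * ln(titer + offset)` and returns the
#' published weight definition `weight = beta2 / beta1`.
#'
#' @param grs Standardized GRS vector.
#' @param titers Anti-PLA2R titers in U/mL (>= 0).
#' @param status 0/1 case status.
#' @param offset Constant added before the log transform (0.001 U/mL, which
#'   keeps undetectable zero titers finite).
#' @return A `crs_calibration`: `beta1`, `beta2`, `weight`, `offset` (control
#'   standardization constants unset — see [crs_calibration()]).
#' @export
derive_crs_weight <- function(grs, titers, status, offset = 0.001) {
  if (any(titers < 0)) data_error("titers must be >= 0")
  if (stats::var(grs) == 0 || stats::var(log(titers + offset)) == 0)
    data_error("both predictors must have variance > 0")
  fit <- suppressWarnings(stats::glm(
    status ~ grs + log(titers + offset), family = stats::binomial()))
  b <- stats::coef(fit)
  if (abs(b[2]) < 1e-8)
    numeric_error("GRS coefficient is ~0: CRS weight undefined")
  structure(list(beta1 = unname(b[2]), beta2 = unname(b[3]),
                 weight = unname(b[3] / b[2]), offset = offset,
                 control_mean = NA_real_, control_sd = NA_real_),
            class = "crs_calibration")
}

#' Published combined-risk-score calibrations
#'
#' The printed per-ethnicity serology weights and control-arm
#' standardization constants of the combined risk score.
#'
#' @param ethnicity `"east_asian"` or `"european"`.
#' @param file Optional alternative definitions JSON.
#' @return A `crs_calibration`: `weight`, `control_mean`, `control_sd`,
#'   `offset`.
#' @export
crs_calibration <- function(ethnicity = c("east_asian", "european"),
                            file = NULL) {
  ethnicity <- match.arg(ethnicity)
  file <- file %||% system.file("extdata", "grs_definitions.json",
                                package = "mnarch", mustWork = TRUE)
  d <- jsonlite::fromJSON(file)$crs[[ethnicity]]
  structure(list(beta1 = NA_real_, beta2 = NA_real_, weight = d$weight,
                 offset = d$offset, control_mean = d$control_mean,
                 control_sd = d$control_sd),
            class = "crs_calibration")
}

#' Compute the standardized combined risk score
#'
#' `crude = GRS + weight * ln(titer + offset)`, then Z-standardized against
#' the ethnicity-matched control constants:
#' `CRS = (crude - control_mean) / control_sd`. Strictly increasing in titer
#' for positive weights.
#'
#' @param grs Standardized GRS vector.
#' @param titer_u_ml Titers in U/mL (>= 0; negative values error).
#' @param calibration A [crs_calibration()] (or [derive_crs_weight()] result
#'   with control constants filled in).
#' @return Data frame with `crs_crude` and `crs`.
#' @export
compute_crs <- function(grs, titer_u_ml, calibration) {
  stopifnot(inherits(calibration, "crs_calibration"))
  if (any(titer_u_ml < 0)) data_error("negative titer")
  if (!is.finite(calibration$control_mean) || !is.finite(calibration$control_sd))
    config_error("calibration lacks control standardization constants")
  crude <- grs + calibration$weight * log(titer_u_ml + calibration$offset)
  data.frame(crs_crude = crude,
             crs = (crude - calibration$control_mean) / calibration$control_sd)
}

#' Nagelkerke pseudo R-squared
#'
#' `R2 = (1 - exp(2 (LL0 - LL1) / n)) / (1 - exp(2 LL0 / n))` for a fitted
#' logistic model against its null (intercept-only or covariate-only) model
#' over the same outcome vector.
#'
#' @param fitted,null Fitted `glm` objects, or log-likelihood values when `n`
#'   is supplied.
#' @param n Sample size (required when log-likelihoods are passed directly).
#' @return Pseudo R-squared in `[0, 1]`.
#' @export
nagelkerke_r2 <- function(fitted, null, n = NULL) {
  ll1 <- if (inherits(fitted, "glm")) as.numeric(stats::logLik(fitted)) else fitted
  ll0 <- if (inherits(null, "glm")) as.numeric(stats::logLik(null)) else null
  n <- n %||% if (inherits(fitted, "glm")) stats::nobs(fitted) else
    config_error("supply `n` with raw log-likelihoods")
  if (ll1 < ll0 - 1e-8)
    data_error("fitted log-likelihood below null: models are not nested")
  (1 - exp(2 * (ll0 - ll1) / n)) / (1 - exp(2 * ll0 / n))
}

#' Observed-scale to liability-scale heritability
#'
#' `h2_liab = h2_obs * (K (1 - K))^2 / (z^2 P (1 - P))` where `K` is the
#' population prevalence, `P` the sample case proportion, and `z` the
#' standard-normal density at the liability threshold `qnorm(1 - K)`.
#'
#' @param h2_observed Observed-scale heritability (>= 0).
#' @param K Population prevalence.
#' @param P Sample case proportion.
#' @return Liability-scale heritability; values above 1 are retained with a
#'   warning and an `out_of_range` attribute.
#' @export
liability_h2 <- function(h2_observed, K, P) {
  if (h2_observed < 0) data_error("h2_observed must be >= 0")
  check_prob(K, "K"); check_prob(P, "P")
  z <- stats::dnorm(stats::qnorm(1 - K))
  out <- h2_observed * (K * (1 - K))^2 / (z^2 * P * (1 - P))
  if (out > 1) {
    warning("liability-scale heritability exceeds 1; retained and flagged")
    attr(out, "out_of_range") <- TRUE
  }
  out
}
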