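#' AUROC with DeLong or bootstrap confidence interval
#'
#' The area under the ROC curve is computed by the rank (Mann-Whitney)
#' statistic with midrank tie handling, so it equals the probability that a
#' random case outscores a random control with ties counted one half. The
#' default confidence interval is DeLong's; a stratified bootstrap (seeded,
#' 2000 resamples) is available. Constant scores give AUROC 0.5 with a
#' degenerate-CI flag.
#'
#' @param scores Numeric risk scores.
#' @param status 0/1 case status (>= 1 case and >= 1 control).
#' @param ci_method `"delong"` or `"bootstrap"`.
#' @param boot_n,boot_seed Bootstrap resamples and seed.
#' @return A `roc_result`: `auroc`, `ci95`, `points` (fpr, tpr), `n_cases`,
#'   `n_controls`, `degenerate`.
#' @export
auroc <- function(scores, status, ci_method = c("delong", "bootstrap"),
                  boot_n = 2000, boot_seed = 1L) {
  ci_method <- match.arg(ci_method)
  status <- as.integer(status)
  m <- sum(status == 1); n <- sum(status == 0)
  if (m < 1 || n < 1) data_error("need at least one case and one control")
  x <- scores[status == 1]; y <- scores[status == 0]
  auc_of <- function(x, y) {
    r <- rank(c(x, y))
    (sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2) /
      (length(x) * length(y))
  }
  auc <- auc_of(x, y)
  degenerate <- stats::var(scores) == 0
  if (degenerate) {
    ci <- c(NA_real_, NA_real_)
  } else if (ci_method == "delong") {
    # placement values via midranks (O(N log N))
    r_all <- rank(c(x, y))
    v10 <- (r_all[seq_len(m)] - rank(x)) / n
    v01 <- 1 - (r_all[m + seq_len(n)] - rank(y)) / m
    v <- stats::var(v10) / m + stats::var(v01) / n
    ci <- pmin(pmax(auc + c(-1, 1) * stats::qnorm(0.975) * sqrt(v), 0), 1)
  } else {
    boots <- local_seed(boot_seed, replicate(boot_n, {
      auc_of(sample(x, m, replace = TRUE), sample(y, n, replace = TRUE))
    }))
    ci <- unname(stats::quantile(boots, c(0.025, 0.975)))
  }
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(x >= t), 0)
  fpr <- vapply(thr, function(t) mean(y >= t), 0)
  structure(list(auroc = auc, ci95 = ci,
                 points = data.frame(fpr = fpr, tpr = tpr),
                 n_cases = m, n_controls = n, degenerate = degenerate,
                 ci_method = ci_method),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUROC = %.3f (95%% CI %.3f-%.3f), %d cases / %d controls%s\n",
              x$auroc, x$ci95[1], x$ci95[2], x$n_cases, x$n_controls,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' Specificity-targeted cutoff table
#'
#' For each target specificity, selects the smallest score cutoff achieving
#' at least that specificity (predicting positive when `score >= cutoff`)
#' and reports the achieved sensitivity, specificity, and likelihood ratios
#' `LR+ = sens / (1 - spec)` and `LR- = (1 - sens) / spec`.
#'
#' @param scores Numeric risk scores.
#' @param status 0/1 case status.
#' @param specificity_grid Target specificities (default 0.95 to 1.00).
#' @return Data frame of `CutoffRow`s: `target_specificity`, `cutoff`,
#'   `sensitivity`, `specificity`, `lr_pos`, `lr_neg`.
#' @export
cutoff_table <- function(scores, status,
                         specificity_grid = seq(0.95, 1, by = 0.01)) {
  status <- as.integer(status)
  x <- scores[status == 1]; y <- scores[status == 0]
  if (!length(x) || !length(y)) data_error("need cases and controls")
  cand <- sort(unique(scores))
  cand <- c(cand, max(cand) + 1)  # cutoff above all scores: spec 1, sens >= 0
  spec_at <- vapply(cand, function(ct) mean(y < ct), 0)
  sens_at <- vapply(cand, function(ct) mean(x >= ct), 0)
  rows <- lapply(specificity_grid, function(tg) {
    i <- which(spec_at >= tg - 1e-12)[1]
    data.frame(target_specificity = tg, cutoff = cand[i],
               sensitivity = sens_at[i], specificity = spec_at[i],
               lr_pos = sens_at[i] / (1 - spec_at[i]),
               lr_neg = (1 - sens_at[i]) / spec_at[i])
  })
  do.call(rbind, rows)
}

#' Integrated discrimination improvement and continuous NRI
#'
#' `IDI = (mean(p_new - p_old) | events) - (mean(p_new - p_old) | non-events)`
#' (equivalently, the change in discrimination slope). The category-free NRI
#' is `[P(up|event) - P(down|event)] + [P(down|non-event) - P(up|non-event)]`,
#' bounded in `[-2, 2]`.
#'
#' @param p_old,p_new Predicted event probabilities under the old and new
#'   model, in `[0, 1]`.
#' @param status 0/1 event status (needs both classes).
#' @return A `reclass_result`: `idi`, `nri`, and the movement probabilities
#'   `p_up_event`, `p_down_event`, `p_up_nonevent`, `p_down_nonevent`.
#' @export
idi_nri <- function(p_old, p_new, status) {
  check_prob(p_old, "p_old", open = FALSE)
  check_prob(p_new, "p_new", open = FALSE)
  status <- as.integer(status)
  if (!sum(status == 1) || !sum(status == 0))
    data_error("need both events and non-events")
  ev <- status == 1
  d <- p_new - p_old
  idi <- mean(d[ev]) - mean(d[!ev])
  up <- d > 0; down <- d < 0
  res <- list(idi = idi,
              p_up_event = mean(up[ev]), p_down_event = mean(down[ev]),
              p_up_nonevent = mean(up[!ev]), p_down_nonevent = mean(down[!ev]))
  res$nri <- (res$p_up_event - res$p_down_event) +
    (res$p_down_nonevent - res$p_up_nonevent)
  structure(res, class = "reclass_result")
}

#' Decile odds ratios of a risk score
#'
#' Splits the score into deciles (boundaries from the full analyzed sample
#' by default, or from controls only) and fits a logistic regression on
#' decile indicators, reporting each decile's odds ratio with 95% CI in
#' reference to the lowest decile.
#'
#' @param score Numeric risk score.
#' @param status 0/1 case status.
#' @param basis `"all"` (default) or `"controls"`: the sample whose
#'   quantiles define decile boundaries.
#' @param covariates Optional covariate data frame.
#' @return Data frame with one row per decile: `decile`, `n_cases`,
#'   `n_controls`, `or_`, `ci_low`, `ci_high`, `flagged`.
#' @export
decile_or <- function(score, status, basis = c("all", "controls"),
                      covariates = NULL) {
  basis <- match.arg(basis)
  status <- as.integer(status)
  base <- if (basis == "all") score else score[status == 0]
  br <- unique(stats::quantile(base, probs = seq(0, 1, 0.1)))
  if (length(br) < 11)
    warning("tied decile boundaries collapsed; fewer than 10 bins")
  dec <- cut(score, breaks = br, include.lowest = TRUE, labels = FALSE)
  dec[is.na(dec) & score <= br[1]] <- 1L
  dec[is.na(dec) & score >= br[length(br)]] <- length(br) - 1L
  tab <- table(factor(dec), status)
  if (any(tab < 10))
    warning("some deciles hold fewer than 10 individuals")
  df <- data.frame(.y = status, .dec = factor(dec))
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fit <- suppressWarnings(stats::glm(
    stats::reformulate(setdiff(names(df), ".y"), ".y"),
    family = stats::binomial(), data = df))
  co <- summary(fit)$coefficients
  lev <- levels(df$.dec)
  rows <- lapply(seq_along(lev), function(i) {
    d <- lev[i]
    n_ca <- sum(status == 1 & dec == as.integer(d))
    n_co <- sum(status == 0 & dec == as.integer(d))
    if (i == 1)
      return(data.frame(decile = as.integer(d), n_cases = n_ca,
                        n_controls = n_co, or_ = 1, ci_low = NA_real_,
                        ci_high = NA_real_, flagged = FALSE))
    nm <- paste0(".dec", d)
    flagged <- !(nm %in% rownames(co)) || n_ca == 0 || n_co == 0 ||
      !is.finite(co[nm, "Std. Error"]) || co[nm, "Std. Error"] > 100
    b <- if (nm %in% rownames(co)) co[nm, "Estimate"] else NA_real_
    s <- if (nm %in% rownames(co)) co[nm, "Std. Error"] else NA_real_
    data.frame(decile = as.integer(d), n_cases = n_ca, n_controls = n_co,
               or_ = exp(b), ci_low = exp(b - stats::qnorm(0.975) * s),
               ci_high = exp(b + stats::qnorm(0.975) * s), flagged = flagged)
  })
  do.call(rbind, rows)
}

#' Association of the genetic risk score with a clinical trait
#'
#' Linear regression for quantitative traits (optionally natural-log
#' transformed, the convention for proteinuria, eGFR, albumin and antibody
#' titer) or logistic regression for binary traits, with covariate
#' adjustment (age, sex, ancestry as supplied).
#'
#' @param grs Standardized GRS.
#' @param trait Outcome vector.
#' @param family `"linear"` or `"logistic"`.
#' @param covariates Optional covariate data frame.
#' @param transform `"none"` or `"log"` (natural log; non-positive trait
#'   values under `"log"` raise an error naming the offending rows).
#' @return List with `estimate` (slope or log-OR of GRS), `se`, `p`,
#'   `or_` (logistic only), `n`.
#' @export
phenotype_association <- function(grs, trait,
                                  family = c("linear", "logistic"),
                                  covariates = NULL,
                                  transform = c("none", "log")) {
  family <- match.arg(family)
  transform <- match.arg(transform)
  if (transform == "log") {
    bad <- which(trait <= 0)
    if (length(bad))
      data_error(paste0("non-positive trait values under log transform at rows: ",
                        paste(utils::head(bad, 10), collapse = ", ")))
    trait <- log(trait)
  }
  df <- data.frame(.y = trait, .g = grs)
  if (!is.null(covariates)) df <- cbind(df, as.data.frame(covariates))
  fml <- stats::reformulate(setdiff(names(df), ".y"), ".y")
  fit <- if (family == "linear") stats::lm(fml, data = df) else
    suppressWarnings(stats::glm(fml, family = stats::binomial(), data = df))
  co <- summary(fit)$coefficients
  est <- co[".g", 1]; se <- co[".g", 2]; p <- co[".g", 4]
  list(estimate = est, se = se, p = p,
       or_ = if (family == "logistic") exp(est) else NA_real_,
       n = nrow(df))
}
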