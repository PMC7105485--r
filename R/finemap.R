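#' Wakefield approximate Bayes factor
#'
#' Closed-form approximate Bayes factor for association from a GWAS effect
#' estimate and its standard error, under a normal prior with variance `W` on
#' the log-odds effect:
#' `ABF = sqrt(V / (V + W)) * exp(z^2 W / (2 (V + W)))` with `V = se^2` and
#' `z = beta / se`. Oriented so that larger values mean more evidence of
#' association; `W -> 0` gives the vacuous value 1.
#'
#' @param beta Log-odds effect estimate(s).
#' @param se Standard error(s), positive.
#' @param W Prior variance of the effect (default 0.04, i.e. prior SD 0.2 on
#'   the log odds ratio — the convention of the reference implementation).
#' @return Numeric vector of approximate Bayes factors.
#' @export
wakefield_abf <- function(beta, se, W = 0.04) {
  if (any(!is.finite(beta)) || any(!is.finite(se)) || !is.finite(W))
    data_error("non-finite inputs to wakefield_abf")
  if (any(se <= 0) || W <= 0) data_error("se and W must be positive")
  V <- se^2
  z <- beta / se
  sqrt(V / (V + W)) * exp(z^2 * W / (2 * (V + W)))
}

#' 99% credible set under a single causal variant
#'
#' Normalizes Wakefield approximate Bayes factors into per-variant posterior
#' probabilities (`PP_i = ABF_i / sum(ABF)`, assuming exactly one causal
#' variant in the region) and adds variants in decreasing PP order until the
#' cumulative PP strictly exceeds `threshold`. Ties are broken
#' deterministically by `variant_id`.
#'
#' @param beta,se Per-variant effect estimates and standard errors.
#' @param variant_id Variant identifiers (defaults to `v1..vn`).
#' @param W Prior effect variance (see [wakefield_abf()]).
#' @param threshold Cumulative-PP threshold (default 0.99).
#' @return A `credible_set` data frame with `variant_id`, `beta`, `se`,
#'   `abf`, `pp`, `cum_pp`, `in_credible_set`, sorted by decreasing PP.
#' @export
credible_set <- function(beta, se, variant_id = NULL, W = 0.04,
                         threshold = 0.99) {
  if (!length(beta)) data_error("need >= 1 variant")
  variant_id <- variant_id %||% paste0("v", seq_along(beta))
  abf <- wakefield_abf(beta, se, W)
  if (!any(is.finite(abf)) || sum(abf) <= 0)
    numeric_error("all approximate Bayes factors are zero or non-finite")
  pp <- abf / sum(abf)
  ord <- order(-pp, variant_id)
  out <- data.frame(variant_id = variant_id[ord], beta = beta[ord],
                    se = se[ord], abf = abf[ord], pp = pp[ord],
                    stringsAsFactors = FALSE)
  out$cum_pp <- cumsum(out$pp)
  n_in <- match(TRUE, out$cum_pp > threshold, nomatch = nrow(out))
  out$in_credible_set <- as.integer(seq_len(nrow(out)) <= n_in)
  structure(out, class = c("credible_set", "data.frame"),
            threshold = threshold, W = W)
}
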