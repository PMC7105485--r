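#' Specify a simulated biallelic variant
#'
#' A variant is described by its identifier, the effect (risk) allele label,
#' the allele frequency in population controls, and its generative effect on
#' the log-odds scale. In the default cohorts the generative effects are the
#' mutually adjusted per-allele weights of the published genetic risk score,
#' so that fitted logistic coefficients on an ascertained case-control sample
#' recover the score weights.
#'
#' @param variant_id Variant identifier (e.g. an rsID or an HLA allele label).
#' @param effect_allele Label of the counted allele.
#' @param control_allele_freq Effect-allele frequency in population controls,
#'   strictly inside (0, 1).
#' @param log_odds Additive per-allele effect on the log-odds scale.
#' @return A `variant_spec` object (named list).
#' @export
variant_spec <- function(variant_id, effect_allele, control_allele_freq, log_odds) {
  stopifnot(is.character(variant_id), length(variant_id) == 1L,
            is.character(effect_allele), length(effect_allele) == 1L)
  check_prob(control_allele_freq, "control_allele_freq")
  if (!is.numeric(log_odds) || !is.finite(log_odds))
    config_error("`log_odds` must be finite")
  structure(list(variant_id = variant_id, effect_allele = effect_allele,
                 control_allele_freq = control_allele_freq,
                 log_odds = log_odds),
            class = "variant_spec")
}

#' Specify a multiplicative gene-gene interaction
#'
#' The interaction contributes `log_odds * dosage_a * dosage_b` to the
#' generative linear predictor, i.e. a simple product of additive genotype
#' codings.
#'
#' @param variant_a,variant_b Identifiers of the two interacting variants
#'   (must differ, and must be listed in the enclosing [cohort_spec()]).
#' @param log_odds Interaction coefficient per dosage-product unit.
#' @return An `interaction_spec` object.
#' @export
interaction_spec <- function(variant_a, variant_b, log_odds) {
  if (identical(variant_a, variant_b))
    config_error("interaction requires two distinct variants")
  if (!is.numeric(log_odds) || !is.finite(log_odds))
    config_error("`log_odds` must be finite")
  structure(list(variant_a = variant_a, variant_b = variant_b,
                 log_odds = log_odds),
            class = "interaction_spec")
}

#' Specify a case-control cohort to simulate
#'
#' Disease status is generated prospectively from a logistic model whose
#' intercept is calibrated so the population prevalence equals `prevalence`;
#' cases and controls are then ascertained retrospectively until the quotas
#' fill. Odds ratios are invariant to this ascertainment, so fitted logistic
#' coefficients recover the generative `log_odds`.
#'
#' @param ethnicity `"east_asian"` or `"european"` (a label carried through to
#'   score definitions and serology defaults).
#' @param variants List of [variant_spec()] objects.
#' @param interactions Optional list of [interaction_spec()] objects.
#' @param ld_pairs Optional list of `list(variant_a=, variant_b=, r2=)`
#'   entries; the pair is drawn from phased haplotypes with the requested
#'   squared correlation (risk alleles positively associated).
#' @param prevalence Population prevalence K, in (0, 0.5).
#' @param n_cases,n_controls Ascertainment quotas.
#' @param seed Root seed; all stage streams are derived from it.
#' @param n_pcs Number of ancestry principal-component noise covariates to
#'   attach to the phenotype table (standard normal, independent of genotype).
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(ethnicity, variants, interactions = list(),
                        ld_pairs = list(), prevalence = 0.001,
                        n_cases, n_controls, seed, n_pcs = 2L) {
  ethnicity <- match.arg(ethnicity, c("east_asian", "european"))
  if (!length(variants)) config_error("at least one variant is required")
  stopifnot(all(vapply(variants, inherits, TRUE, "variant_spec")))
  stopifnot(all(vapply(interactions, inherits, TRUE, "interaction_spec")))
  if (!(prevalence > 0 && prevalence < 0.5))
    config_error("`prevalence` must be in (0, 0.5)")
  if (n_cases <= 0 || n_controls <= 0) config_error("counts must be positive")
  ids <- vapply(variants, `[[`, "", "variant_id")
  if (anyDuplicated(ids)) config_error("duplicated variant ids")
  refs <- c(unlist(lapply(interactions, function(x) c(x$variant_a, x$variant_b))),
            unlist(lapply(ld_pairs, function(x) c(x$variant_a, x$variant_b))))
  bad <- setdiff(refs, ids)
  if (length(bad))
    config_error(paste0("interaction/ld references not among variants: ",
                        paste(bad, collapse = ", ")))
  structure(list(ethnicity = ethnicity, variants = variants,
                 interactions = interactions, ld_pairs = ld_pairs,
                 prevalence = prevalence, n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls), seed = as.integer(seed),
                 n_pcs = as.integer(n_pcs)),
            class = "cohort_spec")
}

variant_table <- function(spec) {
  data.frame(
    variant_id = vapply(spec$variants, `[[`, "", "variant_id"),
    effect_allele = vapply(spec$variants, `[[`, "", "effect_allele"),
    freq = vapply(spec$variants, `[[`, 0, "control_allele_freq"),
    log_odds = vapply(spec$variants, `[[`, 0, "log_odds"),
    stringsAsFactors = FALSE
  )
}

# ---- linkage disequilibrium haplotypes -------------------------------------

# Haplotype frequencies for two biallelic loci with allele freqs p, q and a
# positive allelic correlation r = +sqrt(r2): f11 = p*q + r*sqrt(p(1-p)q(1-q)).
ld_hap_freqs <- function(p, q, r2) {
  check_prob(p, "p"); check_prob(q, "q"); check_prob(r2, "r2", open = FALSE)
  d_max <- min(p * (1 - q), q * (1 - p))
  r2_max <- d_max^2 / (p * (1 - p) * q * (1 - q))
  d <- sqrt(r2) * sqrt(p * (1 - p) * q * (1 - q))
  f11 <- p * q + d
  if (f11 > min(p, q) + 1e-12 || f11 < max(0, p + q - 1) - 1e-12)
    numeric_error(sprintf(
      "r2 = %.4g infeasible for p = %.4g, q = %.4g (max attainable r2 = %.4g)",
      r2, p, q, r2_max))
  c(`00` = 1 - p - q + f11, `01` = q - f11, `10` = p - f11, `11` = f11)
}

#' Draw a pool of phased two-locus haplotypes with target LD
#'
#' Haplotype frequencies are solved for a single positive allelic correlation
#' `r = +sqrt(r2_target)` (risk alleles positively associated); haplotypes are
#' then drawn multinomially. An unattainable `r2_target` raises an error that
#' reports the attainable maximum.
#'
#' @param p,q Allele frequencies at the two loci.
#' @param r2_target Target squared allelic correlation in `[0, 1]`.
#' @param n_hap Number of haplotypes to draw.
#' @param seed Integer seed.
#' @return An `n_hap x 2` binary matrix; one row per phased haplotype.
#' @export
make_ld_haplotypes <- function(p, q, r2_target, n_hap, seed) {
  f <- ld_hap_freqs(p, q, r2_target)
  local_seed(seed, {
    idx <- sample.int(4L, n_hap, replace = TRUE, prob = f)
    cbind(a = as.integer(idx >= 3L), b = as.integer(idx %% 2L == 0L))
  })
}

# ---- exact genotype-distribution machinery ---------------------------------

hwe_probs <- function(p) c(`0` = (1 - p)^2, `1` = 2 * p * (1 - p), `2` = p^2)

# Joint genotype distribution of an LD pair: convolution of two independent
# haplotypes. Returns 9-row data.frame (da, db, prob).
ld_pair_genotype_probs <- function(p, q, r2) {
  f <- ld_hap_freqs(p, q, r2)
  hap <- cbind(a = c(0, 0, 1, 1), b = c(0, 1, 0, 1))
  out <- matrix(0, 3, 3)
  for (i in 1:4) for (j in 1:4) {
    out[hap[i, 1] + hap[j, 1] + 1, hap[i, 2] + hap[j, 2] + 1] <-
      out[hap[i, 1] + hap[j, 1] + 1, hap[i, 2] + hap[j, 2] + 1] + f[i] * f[j]
  }
  data.frame(da = rep(0:2, 3), db = rep(0:2, each = 3), prob = as.vector(out))
}

# Enumerate the full discrete genotype distribution of a spec as a matrix of
# dosage combinations plus a probability vector. Blocks (independent variants
# and LD pairs) are expanded by an outer product, capped at 2^20 cells.
genotype_distribution <- function(variants, ld_pairs = list()) {
  vt <- if (is.data.frame(variants)) variants else
    variant_table(list(variants = variants))
  ld_ids <- unlist(lapply(ld_pairs, function(x) c(x$variant_a, x$variant_b)))
  blocks <- list()
  for (pr in ld_pairs) {
    pa <- vt$freq[vt$variant_id == pr$variant_a]
    pb <- vt$freq[vt$variant_id == pr$variant_b]
    g <- ld_pair_genotype_probs(pa, pb, pr$r2)
    m <- as.matrix(g[, c("da", "db")])
    colnames(m) <- c(pr$variant_a, pr$variant_b)
    blocks[[length(blocks) + 1L]] <- list(dosage = m, prob = g$prob)
  }
  for (i in seq_len(nrow(vt))) {
    if (vt$variant_id[i] %in% ld_ids) next
    m <- matrix(0:2, ncol = 1, dimnames = list(NULL, vt$variant_id[i]))
    blocks[[length(blocks) + 1L]] <- list(dosage = m, prob = unname(hwe_probs(vt$freq[i])))
  }
  n_cells <- prod(vapply(blocks, function(b) nrow(b$dosage), 0))
  if (n_cells > 2^20) return(NULL)
  dos <- blocks[[1]]$dosage
  prob <- blocks[[1]]$prob
  for (b in blocks[-1]) {
    k <- nrow(b$dosage)
    n0 <- nrow(dos)
    dos <- cbind(dos[rep(seq_len(n0), times = k), , drop = FALSE],
                 b$dosage[rep(seq_len(k), each = n0), , drop = FALSE])
    prob <- prob[rep(seq_len(n0), times = k)] * b$prob[rep(seq_len(k), each = n0)]
  }
  list(dosage = dos, prob = prob)
}

linear_predictor <- function(dosage, vt, interactions) {
  lp <- as.vector(dosage[, vt$variant_id, drop = FALSE] %*% vt$log_odds)
  for (ia in interactions)
    lp <- lp + ia$log_odds * dosage[, ia$variant_a] * dosage[, ia$variant_b]
  lp
}

#' Calibrate the logistic intercept to a target prevalence
#'
#' Finds the intercept `b0` such that the population mean of
#' `plogis(b0 + linear predictor)` equals the prevalence `K`. When the
#' discrete genotype state space is small enough (up to 2^20 cells) the
#' expectation is computed exactly by enumeration; otherwise a fixed-seed
#' Monte-Carlo population of 2e6 individuals is used.
#'
#' @param K Target prevalence in (0, 1).
#' @param variants List of [variant_spec()] (or the variant table of a spec).
#' @param interactions Optional list of [interaction_spec()].
#' @param ld_pairs Optional LD pair list as in [cohort_spec()].
#' @return The intercept on the log-odds scale.
#' @export
calibrate_intercept <- function(K, variants, interactions = list(),
                                ld_pairs = list()) {
  check_prob(K, "K")
  vt <- if (is.data.frame(variants)) variants else
    variant_table(list(variants = variants))
  gd <- genotype_distribution(vt, ld_pairs)
  if (is.null(gd)) {
    spec_like <- list(variants = variants, ld_pairs = ld_pairs)
    dos <- local_seed(20200330, simulate_dosage_block(vt, ld_pairs, 2e6)$dosage)
    lp <- linear_predictor(dos, vt, interactions)
    prob <- rep(1 / nrow(dos), nrow(dos))
  } else {
    lp <- linear_predictor(gd$dosage, vt, interactions)
    prob <- gd$prob
  }
  f <- function(b0) sum(prob * stats::plogis(b0 + lp)) - K
  lo <- stats::qlogis(K) - max(abs(lp)) - 1
  hi <- stats::qlogis(K) + max(abs(lp)) + 1
  if (f(lo) > 0 || f(hi) < 0)
    numeric_error(sprintf(
      "intercept root not bracketed: f(%.3f) = %.3g, f(%.3f) = %.3g",
      lo, f(lo), hi, f(hi)))
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

# Draw one block of genotypes (dosage matrix + phased haplotypes for LD pairs)
# using the current RNG state.
simulate_dosage_block <- function(vt, ld_pairs, n) {
  dos <- matrix(0, n, nrow(vt), dimnames = list(NULL, vt$variant_id))
  haps <- list()
  ld_ids <- unlist(lapply(ld_pairs, function(x) c(x$variant_a, x$variant_b)))
  for (pr in ld_pairs) {
    pa <- vt$freq[vt$variant_id == pr$variant_a]
    pb <- vt$freq[vt$variant_id == pr$variant_b]
    f <- ld_hap_freqs(pa, pb, pr$r2)
    idx <- matrix(sample.int(4L, 2L * n, replace = TRUE, prob = f), n, 2)
    ha <- (idx >= 3L) + 0L
    hb <- (idx %% 2L == 0L) + 0L
    dos[, pr$variant_a] <- rowSums(ha)
    dos[, pr$variant_b] <- rowSums(hb)
    haps[[paste(pr$variant_a, pr$variant_b, sep = "|")]] <-
      list(a = ha, b = hb)
  }
  for (i in seq_len(nrow(vt))) {
    if (vt$variant_id[i] %in% ld_ids) next
    dos[, i] <- stats::rbinom(n, 2L, vt$freq[i])
  }
  list(dosage = dos, haps = haps)
}

#' Simulate genotype dosages for a cohort specification
#'
#' Non-LD variants are drawn as Binomial(2, freq) under Hardy-Weinberg
#' equilibrium; LD pairs are drawn from phased haplotype pools produced by
#' [make_ld_haplotypes()]. Identical spec and seed give bit-identical output.
#'
#' @param spec A [cohort_spec()].
#' @param n Number of individuals.
#' @param seed Integer seed.
#' @return Dosage matrix (`n` x variants) with columns named by `variant_id`,
#'   carrying attributes `variants` (metadata table) and `haplotypes` (phased
#'   0/1 haplotype matrices per LD pair).
#' @export
simulate_genotypes <- function(spec, n, seed) {
  vt <- variant_table(spec)
  blk <- local_seed(seed, simulate_dosage_block(vt, spec$ld_pairs, n))
  structure(blk$dosage, variants = vt, haplotypes = blk$haps)
}

#' Simulate an ascertained case-control cohort
#'
#' Disease status is sampled from the prospective logistic model at the
#' intercept calibrated by [calibrate_intercept()]; batches of population
#' individuals are drawn and retained until the case and control quotas fill.
#'
#' @param spec A [cohort_spec()].
#' @param max_batches Safety cap on population batches before declaring the
#'   quota unreachable.
#' @return An `mn_cohort`: list with `genotypes` (dosage matrix, cases first),
#'   `phenotypes` (`sample_id`, `status`, PCs), `haplotypes` (per LD pair),
#'   `spec`, and the calibrated `intercept`.
#' @export
simulate_case_control <- function(spec, max_batches = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  vt <- variant_table(spec)
  b0 <- calibrate_intercept(spec$prevalence, vt, spec$interactions, spec$ld_pairs)
  need_ca <- spec$n_cases
  need_co <- spec$n_controls
  expected <- need_ca / spec$prevalence
  batch_n <- as.integer(min(2e6, max(5e4, ceiling(expected / 4))))
  if (is.null(max_batches))
    max_batches <- ceiling(4 * expected / batch_n) + 10L
  ca_dos <- list(); co_dos <- list()
  ca_hap <- list(); co_hap <- list()
  got_ca <- 0L; got_co <- 0L
  batch <- 0L
  while (got_ca < need_ca || got_co < need_co) {
    batch <- batch + 1L
    if (batch > max_batches)
      numeric_error(sprintf(
        "case/control quota unreachable within %d batches of %d (have %d/%d cases, %d/%d controls)",
        max_batches, batch_n, got_ca, need_ca, got_co, need_co))
    blk <- local_seed(derive_seed(spec$seed, 100L + batch), {
      b <- simulate_dosage_block(vt, spec$ld_pairs, batch_n)
      lp <- linear_predictor(b$dosage, vt, spec$interactions)
      b$status <- stats::rbinom(batch_n, 1L, stats::plogis(b0 + lp))
      b
    })
    take <- function(idx, need, got) idx[seq_len(min(length(idx), need - got))]
    i_ca <- take(which(blk$status == 1L), need_ca, got_ca)
    i_co <- take(which(blk$status == 0L), need_co, got_co)
    if (length(i_ca)) {
      ca_dos[[length(ca_dos) + 1L]] <- blk$dosage[i_ca, , drop = FALSE]
      ca_hap[[length(ca_hap) + 1L]] <- lapply(blk$haps, lapply, function(m) m[i_ca, , drop = FALSE])
      got_ca <- got_ca + length(i_ca)
    }
    if (length(i_co)) {
      co_dos[[length(co_dos) + 1L]] <- blk$dosage[i_co, , drop = FALSE]
      co_hap[[length(co_hap) + 1L]] <- lapply(blk$haps, lapply, function(m) m[i_co, , drop = FALSE])
      got_co <- got_co + length(i_co)
    }
  }
  genotypes <- rbind(do.call(rbind, ca_dos), do.call(rbind, co_dos))
  n <- nrow(genotypes)
  rownames(genotypes) <- sprintf("S%06d", seq_len(n))
  haps <- NULL
  if (length(spec$ld_pairs)) {
    keys <- names(c(ca_hap, co_hap)[[1]])
    haps <- lapply(stats::setNames(keys, keys), function(k) {
      list(a = do.call(rbind, c(lapply(ca_hap, function(x) x[[k]]$a),
                                lapply(co_hap, function(x) x[[k]]$a))),
           b = do.call(rbind, c(lapply(ca_hap, function(x) x[[k]]$b),
                                lapply(co_hap, function(x) x[[k]]$b))))
    })
  }
  phen <- data.frame(sample_id = rownames(genotypes),
                     status = rep(c(1L, 0L), c(need_ca, need_co)),
                     stringsAsFactors = FALSE)
  if (spec$n_pcs > 0) {
    pcs <- local_seed(derive_seed(spec$seed, 3L),
                      matrix(stats::rnorm(n * spec$n_pcs), n))
    colnames(pcs) <- paste0("PC", seq_len(spec$n_pcs))
    phen <- cbind(phen, as.data.frame(pcs))
  }
  structure(list(genotypes = structure(genotypes, variants = vt),
                 phenotypes = phen, haplotypes = haps, spec = spec,
                 intercept = b0),
            class = "mn_cohort")
}

#' @export
print.mn_cohort <- function(x, ...) {
  cat(sprintf("<mn_cohort> %s: %d cases / %d controls, %d variants\n",
              x$spec$ethnicity, sum(x$phenotypes$status == 1),
              sum(x$phenotypes$status == 0), ncol(x$genotypes)))
  invisible(x)
}

# ---- closed-form raw-score moments and frequency calibration ---------------

#' Closed-form mean and variance of the raw generative score
#'
#' Computes the exact population mean and variance of
#' `sum(w_j d_j) + sum(w_I d_a d_b)` for mutually independent Hardy-Weinberg
#' variants. Used to calibrate unprinted default allele frequencies against
#' the published control-arm score mean and standard deviation.
#'
#' @param variants Variant table (or list of [variant_spec()]).
#' @param interactions List of [interaction_spec()]; pairs must be disjoint.
#' @return Named vector `c(mean, var, sd)`.
#' @export
grs_moments <- function(variants, interactions = list()) {
  vt <- if (is.data.frame(variants)) variants else
    variant_table(list(variants = variants))
  ia_ids <- unlist(lapply(interactions, function(x) c(x$variant_a, x$variant_b)))
  if (anyDuplicated(ia_ids))
    config_error("closed-form moments require disjoint interaction pairs")
  m <- 2 * vt$freq
  v <- 2 * vt$freq * (1 - vt$freq)
  mu <- sum(vt$log_odds * m)
  va <- sum(vt$log_odds^2 * v)
  for (ia in interactions) {
    a <- match(ia$variant_a, vt$variant_id)
    b <- match(ia$variant_b, vt$variant_id)
    e2a <- v[a] + m[a]^2
    e2b <- v[b] + m[b]^2
    mu <- mu + ia$log_odds * m[a] * m[b]
    va <- va + ia$log_odds^2 * (e2a * e2b - m[a]^2 * m[b]^2) +
      2 * ia$log_odds * vt$log_odds[a] * m[b] * v[a] +
      2 * ia$log_odds * vt$log_odds[b] * m[a] * v[b]
  }
  c(mean = mu, var = va, sd = sqrt(va))
}

# Solve the two unprinted East Asian HLA tag-SNP frequencies so that the
# control-arm raw score matches the published control mean and SD exactly
# (two moment equations, two unknowns). Used once to freeze the defaults in
# default_cohort_spec(); kept for transparency and tested against the frozen
# values.
calibrate_ea_hla_freqs <- function(target_mean = 1.6804, target_sd = 1.0033) {
  obj <- function(par) {
    p <- stats::plogis(par)
    sp <- ea_spec_with_freqs(p[1], p[2])
    mo <- grs_moments(variant_table(sp), sp$interactions)
    (mo["mean"] - target_mean)^2 + (mo["sd"] - target_sd)^2
  }
  fit <- stats::optim(stats::qlogis(c(0.2, 0.05)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 5000))
  if (fit$value > 1e-12)
    numeric_error("East Asian frequency calibration did not converge")
  stats::setNames(stats::plogis(fit$par), c("rs9269027", "rs1974461"))
}

ea_spec_with_freqs <- function(p9269027, p1974461,
                               n_cases = 100, n_controls = 100, seed = 1) {
  cohort_spec(
    "east_asian",
    variants = list(
      variant_spec("rs9269027", "A", p9269027, 0.69173),
      variant_spec("rs1974461", "T", p1974461, 1.23685),
      variant_spec("rs6707458", "G", 0.70, 0.36687),
      variant_spec("rs230540", "C", 0.35, 0.25098),
      variant_spec("rs9405192", "G", 0.42, 0.39127)),
    interactions = list(interaction_spec("rs9269027", "rs6707458", 0.48798)),
    prevalence = 0.001, n_cases = n_cases, n_controls = n_controls, seed = seed)
}

#' Default generative cohort specifications
#'
#' East Asian and European specifications whose variants carry the published
#' mutually adjusted score weights as generative effects, the published
#' control allele frequencies where printed, and calibrated defaults where
#' not. The two unprinted East Asian HLA tag-SNP frequencies are calibrated
#' so the control-arm raw score matches the published control mean (1.6804)
#' and SD (1.0033) exactly; for Europeans only the control mean (1.5089) is
#' matched (the printed European SD reflects LD among the HLA tag SNPs which
#' the independent-variant simulator does not model; see the methods
#' vignette).
#'
#' @param ethnicity `"east_asian"` or `"european"`.
#' @param n_cases,n_controls,seed Passed to [cohort_spec()].
#' @param prevalence Population prevalence (default 0.001).
#' @return A `cohort_spec`.
#' @export
default_cohort_spec <- function(ethnicity = c("east_asian", "european"),
                                n_cases, n_controls, seed,
                                prevalence = 0.001) {
  ethnicity <- match.arg(ethnicity)
  if (ethnicity == "east_asian") {
    # frozen output of calibrate_ea_hla_freqs()
    sp <- ea_spec_with_freqs(0.19528599, 0.05070583,
                             n_cases = n_cases, n_controls = n_controls,
                             seed = seed)
    sp$prevalence <- prevalence
    sp
  } else {
    # rs9271541 pinned at the printed DQA1*0501 European control frequency
    # (0.30); rs2858309 fixed at a plausible 0.15; rs9265949 solved so the
    # control raw-score mean equals the printed 1.5089 (frozen value).
    cohort_spec(
      "european",
      variants = list(
        variant_spec("rs9271541", "C", 0.30, 0.34945),
        variant_spec("rs9265949", "T", 0.12726863, 0.67919),
        variant_spec("rs2858309", "C", 0.15, 0.30707),
        variant_spec("rs6707458", "G", 0.61, 0.34601),
        variant_spec("rs230540", "C", 0.32, 0.17450),
        variant_spec("rs9405192", "G", 0.69, 0.18343)),
      interactions = list(interaction_spec("rs9271541", "rs6707458", 0.33782)),
      prevalence = prevalence, n_cases = n_cases, n_controls = n_controls,
      seed = seed)
  }
}

# ---- anti-PLA2R serology ----------------------------------------------------

#' Specify the anti-PLA2R serology generator
#'
#' Case seropositivity follows a logistic model on the standardized GRS;
#' seropositive cases draw titers from a log-normal truncated above the 20
#' U/mL positivity cutoff, seronegative cases from a zero-inflated log-normal
#' below it. Controls exceed 20 U/mL and 2 U/mL at the configured rates,
#' reproducing the 0 / 2 / 20 U/mL clinical banding.
#'
#' @param seropos_intercept,seropos_slope Logistic coefficients of case
#'   seropositivity on the standardized GRS.
#' @param titer_meanlog,titer_sdlog Log-titer distribution of seropositive
#'   cases (U/mL), truncated to `>= 20`.
#' @param control_exceed_rate_20,control_exceed_rate_2 Proportions of controls
#'   with titers above 20 and above 2 U/mL (`rate_20 <= rate_2`).
#' @param zero_fraction Fraction of seronegative titers set to exactly 0.
#' @return A `serology_spec` object.
#' @export
serology_spec <- function(seropos_intercept, seropos_slope,
                          titer_meanlog = log(150), titer_sdlog = 1.2,
                          control_exceed_rate_20 = 0,
                          control_exceed_rate_2 = 0.15,
                          zero_fraction = 0.5) {
  check_prob(control_exceed_rate_20, "control_exceed_rate_20", open = FALSE)
  check_prob(control_exceed_rate_2, "control_exceed_rate_2", open = FALSE)
  if (control_exceed_rate_20 > control_exceed_rate_2)
    config_error("control_exceed_rate_20 must be <= control_exceed_rate_2")
  structure(list(seropos_intercept = seropos_intercept,
                 seropos_slope = seropos_slope,
                 titer_meanlog = titer_meanlog, titer_sdlog = titer_sdlog,
                 control_exceed_rate_20 = control_exceed_rate_20,
                 control_exceed_rate_2 = control_exceed_rate_2,
                 zero_fraction = zero_fraction),
            class = "serology_spec")
}

#' Default serology specifications
#'
#' Calibrated so the 20 U/mL cutoff reproduces the published operating points
#' on cohorts simulated from [default_cohort_spec()]: about 60% sensitivity
#' with 100% specificity in East Asians, and about 54% sensitivity with
#' 99.5% specificity in Europeans (published ranges 51-57% / 99-100%).
#' Intercepts were frozen from an exact enumeration of the case GRS
#' distribution under the default generative model.
#'
#' @param ethnicity `"east_asian"` or `"european"`.
#' @return A `serology_spec`.
#' @export
default_serology_spec <- function(ethnicity = c("east_asian", "european")) {
  ethnicity <- match.arg(ethnicity)
  if (ethnicity == "east_asian") {
    serology_spec(seropos_intercept = -0.70307154, seropos_slope = 0.8,
                  control_exceed_rate_20 = 0, control_exceed_rate_2 = 0.15)
  } else {
    serology_spec(seropos_intercept = -0.49296563, seropos_slope = 0.8,
                  control_exceed_rate_20 = 0.005, control_exceed_rate_2 = 0.15)
  }
}

# Truncated log-normal draws via inverse CDF.
rlnorm_trunc <- function(n, meanlog, sdlog, lower = 0, upper = Inf) {
  lo <- stats::plnorm(lower, meanlog, sdlog)
  hi <- stats::plnorm(upper, meanlog, sdlog)
  stats::qlnorm(stats::runif(n, lo, hi), meanlog, sdlog)
}

#' Simulate serum anti-PLA2R antibody titers
#'
#' Requires the cohort phenotype table to carry a standardized GRS column
#' (`grs`), since case seropositivity depends on it.
#'
#' @param cohort An `mn_cohort` whose `phenotypes` include `grs`.
#' @param serology A [serology_spec()]; defaults to the ethnicity-matched
#'   [default_serology_spec()].
#' @param seed Integer seed (defaults to the cohort's derived serology stream).
#' @return Numeric vector of titers in U/mL (>= 0), aligned with the cohort.
#' @export
simulate_antibody <- function(cohort, serology = NULL, seed = NULL) {
  stopifnot(inherits(cohort, "mn_cohort"))
  if (is.null(cohort$phenotypes$grs))
    data_error("cohort has no `grs` column: compute the GRS first (compute_grs)")
  serology <- serology %||% default_serology_spec(cohort$spec$ethnicity)
  stopifnot(inherits(serology, "serology_spec"))
  seed <- seed %||% derive_seed(cohort$spec$seed, 2L)
  status <- cohort$phenotypes$status
  grs <- cohort$phenotypes$grs
  n <- length(status)
  local_seed(seed, {
    titer <- numeric(n)
    ca <- which(status == 1L)
    p_sero <- stats::plogis(serology$seropos_intercept +
                              serology$seropos_slope * grs[ca])
    sero <- stats::rbinom(length(ca), 1L, p_sero) == 1L
    titer[ca[sero]] <- rlnorm_trunc(sum(sero), serology$titer_meanlog,
                                    serology$titer_sdlog, lower = 20)
    neg <- ca[!sero]
    zero <- stats::runif(length(neg)) < serology$zero_fraction
    titer[neg[zero]] <- 0
    titer[neg[!zero]] <- rlnorm_trunc(sum(!zero), log(5), 1, upper = 20)
    co <- which(status == 0L)
    u <- stats::runif(length(co))
    hi <- u < serology$control_exceed_rate_20
    mid <- !hi & u < serology$control_exceed_rate_2
    lo <- !hi & !mid
    titer[co[hi]] <- rlnorm_trunc(sum(hi), log(40), 0.5, lower = 20)
    titer[co[mid]] <- rlnorm_trunc(sum(mid), log(6), 0.8, lower = 2, upper = 20)
    zero <- stats::runif(sum(lo)) < serology$zero_fraction
    titer[co[lo][zero]] <- 0
    titer[co[lo][!zero]] <- rlnorm_trunc(sum(!zero), log(0.5), 0.8, upper = 2)
    titer
  })
}

# Calibrate the seropositivity intercept so the expected case sensitivity at
# the 20 U/mL cutoff equals `target`, by exact enumeration of the case
# genotype distribution under `spec`. Used once to freeze the defaults.
calibrate_seropos_intercept <- function(spec, definition, slope = 0.8,
                                        target = 0.60) {
  vt <- variant_table(spec)
  gd <- genotype_distribution(vt, spec$ld_pairs)
  lp <- linear_predictor(gd$dosage, vt, spec$interactions)
  b0 <- calibrate_intercept(spec$prevalence, vt, spec$interactions, spec$ld_pairs)
  p_case <- gd$prob * stats::plogis(b0 + lp)
  p_case <- p_case / sum(p_case)
  grs <- compute_grs(gd$dosage, definition)$grs
  f <- function(a) sum(p_case * stats::plogis(a + slope * grs)) - target
  stats::uniroot(f, c(-20, 20), tol = 1e-12)$root
}
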