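test_that("perfect separation is flagged, not silently returned", {
  d <- rep(c(2, 0), each = 100)
  st <- rep(c(1, 0), each = 100)
  fit <- fit_additive_logistic(d, st)
  expect_true(fit$separated)
  expect_true(is.na(fit$p_wald))
  expect_error(fit_additive_logistic(rep(1, 200), st),
               class = "mnarch_data_error")
})

test_that("null fits are calibrated and Wald agrees with LRT", {
  set.seed(101)
  n_rep <- 400
  ok <- logical(n_rep)
  ratio_ok <- logical(n_rep)
  for (i in seq_len(n_rep)) {
    d <- rbinom(2000, 2, 0.3)
    st <- rbinom(2000, 1, 0.3)
    fit <- fit_additive_logistic(d, st)
    ok[i] <- abs(fit$beta) < 3 * fit$se
    ratio_ok[i] <- is.na(fit$p_lrt) ||
      (fit$p_wald / fit$p_lrt < 2 && fit$p_lrt / fit$p_wald < 2)
  }
  expect_gte(mean(ok), 0.99)
  expect_gte(mean(ratio_ok), 0.99)
})

test_that("fitted OR recovers the generative PLA2R1 effect", {
  spec <- cohort_spec("east_asian",
                      list(variant_spec("rs17831251", "C", 0.70, log(2.81))),
                      prevalence = 0.001, n_cases = 3000, n_controls = 3000,
                      seed = 12)
  co <- simulate_case_control(spec)
  fit <- fit_additive_logistic(co$genotypes[, 1], co$phenotypes$status)
  expect_false(fit$separated)
  expect_lt(abs(fit$beta - log(2.81)), 2 * fit$se)
  expect_equal(fit$ci95, exp(fit$beta + c(-1, 1) * qnorm(0.975) * fit$se))
})

test_that("conditional scan isolates causal signals", {
  set.seed(77)
  n <- 6000
  causal <- rbinom(n, 2, 0.3)
  tags <- sapply(1:4, function(i) {
    flip <- runif(n) < 0.15   # imperfect LD copies of the causal variant
    tag <- causal
    tag[flip] <- rbinom(sum(flip), 2, 0.3)
    tag
  })
  dos <- cbind(causal = causal, tags)
  colnames(dos) <- c("causal", paste0("tag", 1:4))
  st <- rbinom(n, 1, plogis(-1.5 + 0.9 * causal))
  sc <- conditional_scan(dos, st, threshold = 5e-8)
  expect_length(sc$steps, 1)
  final <- sc$scans[[length(sc$scans)]]
  expect_true(all(final$p >= 5e-8, na.rm = TRUE))

  # two independent causal variants: both selected, ordered by p
  v1 <- rbinom(n, 2, 0.3); v2 <- rbinom(n, 2, 0.4)
  noise <- rbinom(n, 2, 0.2)
  dos2 <- cbind(v1 = v1, v2 = v2, noise = noise)
  st2 <- rbinom(n, 1, plogis(-2 + 0.8 * v1 + 0.8 * v2))
  sc2 <- conditional_scan(dos2, st2, threshold = 5e-8)
  expect_setequal(sc2$steps, c("v1", "v2"))

  # nothing significant: zero steps, unconditioned scan returned
  st3 <- rbinom(n, 1, 0.3)
  sc3 <- conditional_scan(dos2, st3, threshold = 5e-8)
  expect_length(sc3$steps, 0)
  expect_length(sc3$scans, 1)

  # perfectly collinear duplicate of a selected variant is skipped
  dos4 <- cbind(v1 = v1, v1copy = v1, v2 = v2)
  expect_message(sc4 <- conditional_scan(dos4, st2, threshold = 5e-8),
                 "collinear")
  expect_false("v1copy" %in% sc4$steps)
})

test_that("fixed-effects meta follows the identical-study and hand-computed laws", {
  m <- meta_fixed(c(0.2, 0.2), c(0.1, 0.1))
  expect_equal(m$beta_fixed, 0.2)
  expect_equal(m$se_fixed, 0.1 / sqrt(2), tolerance = 1e-12)
  expect_equal(m$Q, 0)
  expect_equal(m$I2, 0)
  # k identical studies: se/sqrt(k) exactly
  k <- 5
  mk <- meta_fixed(rep(0.3, k), rep(0.07, k))
  expect_equal(mk$se_fixed, 0.07 / sqrt(k), tolerance = 1e-12)

  m2 <- meta_fixed(c(0.2, -0.2), c(0.1, 0.1))
  expect_equal(m2$beta_fixed, 0)
  expect_equal(m2$Q, 8.0, tolerance = 1e-12)
  expect_equal(m2$I2, 87.5, tolerance = 1e-12)

  expect_error(meta_fixed(c(0.1, 0.2), c(0.1, 0.1), effect_allele = c("A", "C")),
               "harmonize", class = "mnarch_data_error")
  expect_error(meta_fixed(0.1, 0.1), class = "mnarch_data_error")
})

test_that("genomic inflation factor behaves as a median chi-square ratio", {
  expect_equal(genomic_lambda(rep(0.5, 200)), 1.0, tolerance = 1e-12)
  # doubling every chi-square doubles lambda
  chi <- qchisq(runif(5000), df = 1)
  p2 <- pchisq(2 * chi, df = 1, lower.tail = FALSE)
  p1 <- pchisq(chi, df = 1, lower.tail = FALSE)
  expect_equal(genomic_lambda(p2) / genomic_lambda(p1), 2, tolerance = 1e-9)
  set.seed(5)
  expect_true(abs(genomic_lambda(runif(10000)) - 1) < 0.05)
  expect_error(genomic_lambda(rep(0.5, 200), exclude = rep(TRUE, 200)),
               class = "mnarch_data_error")
})

test_that("HLA QC filter applies strict printed thresholds", {
  tab <- data.frame(allele = c("a", "b", "c", "d", "e"),
                    freq = c(0.005, 0.3, 0.3, 0.3, 0.995),
                    r2 = c(0.99, 0.79, 0.8, 0.81, 0.99))
  out <- hla_qc_filter(tab)
  expect_equal(out$retained, c(FALSE, FALSE, FALSE, TRUE, FALSE))
  expect_equal(out$drop_reason[1], "MAF")   # freq 0.005
  expect_equal(out$drop_reason[2], "R2")    # r2 0.79
  expect_equal(out$drop_reason[3], "R2")    # boundary r2 = 0.8 dropped
  expect_equal(out$drop_reason[5], "MAF")   # MAF uses the minor allele
  tab$r2[1] <- NA
  expect_error(hla_qc_filter(tab), class = "mnarch_data_error")
})

test_that("omnibus test reduces to the biallelic LRT and ignores the reference", {
  set.seed(202)
  co <- simulate_multiallelic_cohort(
    c(A = 0.6, B = 0.4), c(A = 0, B = 0.5),
    prevalence = 0.05, n_cases = 500, n_controls = 500, seed = 9)
  om <- omnibus_multiallelic(co$dosage, co$status)
  fit <- fit_additive_logistic(co$dosage[, "B"], co$status)
  expect_equal(om$df, 1L)
  expect_equal(om$deviance, fit$deviance, tolerance = 1e-8)

  co5 <- simulate_multiallelic_cohort(
    c(A = 0.4, B = 0.3, C = 0.2, D = 0.1),
    c(A = 0, B = 0.3, C = 0.5, D = 0),
    prevalence = 0.05, n_cases = 600, n_controls = 600, seed = 10)
  om_ref <- omnibus_multiallelic(co5$dosage, co5$status)
  # manual oracle: drop a DIFFERENT allele column; deviance must be identical
  dev_manual <- sapply(colnames(co5$dosage), function(drop) {
    f1 <- glm(co5$status ~ co5$dosage[, setdiff(colnames(co5$dosage), drop)],
              family = binomial())
    f0 <- glm(co5$status ~ 1, family = binomial())
    as.numeric(2 * (logLik(f1) - logLik(f0)))
  })
  expect_true(all(abs(dev_manual - om_ref$deviance) < 1e-8))
  expect_equal(om_ref$df, 3L)

  dz <- cbind(co5$dosage, Z = 0)
  expect_warning(omz <- omnibus_multiallelic(dz, co5$status), "zero-variance")
  expect_equal(omz$df, 3L)
})

test_that("omnibus type-I error is nominal under the null", {
  set.seed(303)
  n_rep <- 1000
  rej <- logical(n_rep)
  freqs <- c(A = 0.4, B = 0.3, C = 0.2, D = 0.1)
  for (i in seq_len(n_rep)) {
    h <- matrix(sample(names(freqs), 2 * 400, TRUE, prob = freqs), 400, 2)
    dos <- sapply(names(freqs), function(a) rowSums(h == a))
    st <- rbinom(400, 1, 0.4)
    rej[i] <- omnibus_multiallelic(dos, st)$p < 0.05
  }
  b <- binom_bounds99(0.05, n_rep)
  expect_gt(mean(rej), b[1])
  expect_lt(mean(rej), b[2])
})
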