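ea_def <- grs_definition("east_asian")
eu_def <- grs_definition("european")

dos_row <- function(def, values = 0) {
  ids <- def$terms$variant_id
  m <- matrix(values, nrow = 1, ncol = length(ids), dimnames = list("s1", ids))
  m
}

test_that("GRS substitution matches independent hand arithmetic", {
  # all dosages zero
  expect_equal(compute_grs(dos_row(ea_def), ea_def)$grs,
               (0 - 1.6804) / 1.0033, tolerance = 1e-9)
  expect_equal(round(compute_grs(dos_row(ea_def), ea_def)$grs, 4), -1.6749)
  expect_equal(compute_grs(dos_row(eu_def), eu_def)$grs,
               (0 - 1.5089) / 0.8202, tolerance = 1e-9)
  expect_equal(round(compute_grs(dos_row(eu_def), eu_def)$grs, 4), -1.8397)
  # dosage 2 at the two interacting variants: raw includes the product term
  m <- dos_row(ea_def)
  m[, c("rs9269027", "rs6707458")] <- 2
  out <- compute_grs(m, ea_def)
  expect_equal(out$grs_raw, 0.69173 * 2 + 0.36687 * 2 + 0.48798 * 4,
               tolerance = 1e-12)
  expect_equal(out$grs_raw, 4.06912, tolerance = 1e-9)
  expect_equal(round(out$grs, 4), 2.3809)
})

test_that("GRS is linear and matches a term-by-term oracle", {
  set.seed(51)
  n <- 200
  m <- matrix(runif(n * 5, 0, 2), n,
              dimnames = list(NULL, ea_def$terms$variant_id))
  out <- compute_grs(m, ea_def)
  oracle <- sapply(seq_len(n), function(i) {
    raw <- sum(ea_def$terms$weight * m[i, ea_def$terms$variant_id])
    it <- ea_def$interaction_terms
    for (k in seq_len(nrow(it)))
      raw <- raw + it$weight[k] * m[i, it$variant_a[k]] * m[i, it$variant_b[k]]
    unname(raw)
  })
  expect_equal(out$grs_raw, oracle, tolerance = 1e-12)
})

test_that("standardization against recomputed control constants is exact", {
  co <- ea_test_cohort()
  raw <- co$phenotypes$grs_raw
  ctrl <- raw[co$phenotypes$status == 0]
  std <- (raw - mean(ctrl)) / sd(ctrl)
  expect_equal(mean(std[co$phenotypes$status == 0]), 0, tolerance = 1e-12)
  expect_equal(sd(std[co$phenotypes$status == 0]), 1, tolerance = 1e-12)
  # simulator tie-in: control-arm raw SD within 5% of the printed 1.0033
  expect_lt(abs(sd(ctrl) - 1.0033) / 1.0033, 0.05)
})

test_that("missing variants and NA dosages are hard errors", {
  m <- dos_row(ea_def)[, -1, drop = FALSE]
  expect_error(compute_grs(m, ea_def), "rs9269027",
               class = "mnarch_data_error")
  m2 <- dos_row(ea_def)
  m2[1, 2] <- NA
  expect_error(compute_grs(m2, ea_def), class = "mnarch_data_error")
  expect_equal(compute_grs(rbind(m2, dos_row(ea_def, 1)), ea_def,
                           impute_missing = TRUE)$grs_raw[1],
               compute_grs(dos_row(ea_def, c(0, 1, 0, 0, 0)), ea_def)$grs_raw)
  m3 <- dos_row(ea_def, 2.5)
  expect_error(compute_grs(m3, ea_def), class = "mnarch_data_error")
})

test_that("CRS weight derivation behaves across constructed regimes", {
  set.seed(52)
  n <- 6000
  grs <- rnorm(n)
  x <- rnorm(n)                      # stand-in for ln(titer + offset)
  titer <- exp(x) - 0.001
  titer[titer < 0] <- 0
  lx <- log(titer + 0.001)
  # equal generative coefficients -> weight ~ 1
  st <- rbinom(n, 1, plogis(-0.5 + 0.7 * grs + 0.7 * lx))
  cal <- derive_crs_weight(grs, titer, st)
  expect_equal(cal$weight, 1, tolerance = 0.15)
  # titer unrelated to status -> weight ~ 0
  st0 <- rbinom(n, 1, plogis(-0.5 + 0.7 * grs))
  cal0 <- derive_crs_weight(grs, titer, st0)
  expect_lt(abs(cal0$weight), 0.1)
  expect_error(derive_crs_weight(grs, titer - 1, st),
               class = "mnarch_data_error")
})

test_that("derive_crs_weight recovers the published weight as generative truth", {
  # parameter-recovery oracle: simulate case status FROM the calibration
  # model (beta1 = 1, beta2 = 1.7712, so weight = 1.7712) and re-derive.
  # The default serology world itself cannot reproduce the published
  # calibration: the printed control CRS moments imply a control titer
  # distribution inconsistent with the printed 2 U/mL band specificities
  # (see the methods vignette), so on the default cohort only the sign and
  # rough magnitude of the weight are asserted below.
  set.seed(54)
  n <- 8000
  grs <- rnorm(n)
  titer <- ifelse(runif(n) < 0.4, 0, rlnorm(n, log(5), 1.5))
  lt <- log(titer + 0.001)
  # beta1 = 0.4, beta2 = 0.4 * 1.7712: weight = beta2 / beta1 = 1.7712
  st <- rbinom(n, 1, plogis(-0.5 + 0.4 * grs + 0.4 * 1.7712 * (lt - mean(lt))))
  cal <- derive_crs_weight(grs, titer, st)
  expect_lt(abs(cal$weight - 1.7712) / 1.7712, 0.25)

  co <- ea_test_cohort()
  cal_def <- derive_crs_weight(co$phenotypes$grs, co$phenotypes$titer_u_ml,
                               co$phenotypes$status)
  expect_gt(cal_def$weight, 0.25)
  expect_lt(cal_def$weight, 1.7712 * 2)
})

test_that("CRS scoring matches hand arithmetic on the printed constants", {
  ea <- crs_calibration("east_asian")
  out <- compute_crs(0, 0, ea)
  expect_equal(out$crs_crude, 1.7712 * log(0.001), tolerance = 1e-12)
  expect_equal(out$crs, (1.7712 * log(0.001) - 0.3724) / 2.7503,
               tolerance = 1e-12)
  eu <- crs_calibration("european")
  out2 <- compute_crs(1.0, 100, eu)
  expect_equal(out2$crs_crude, 1 + 0.4829 * log(100.001), tolerance = 1e-9)
  expect_equal(round(out2$crs, 4),
               round((1 + 0.4829 * log(100.001) + 1.4982) / 1.4354, 4))
  # weight = 0: CRS is affine in GRS alone
  cal0 <- ea; cal0$weight <- 0
  g <- c(-1, 0, 2)
  expect_equal(compute_crs(g, c(0, 50, 300), cal0)$crs,
               (g - ea$control_mean) / ea$control_sd)
  # strictly increasing in titer for positive weight
  tt <- c(0, 1, 5, 20, 100)
  expect_true(all(diff(compute_crs(rep(0, 5), tt, ea)$crs) > 0))
  expect_error(compute_crs(0, -1, ea), class = "mnarch_data_error")
})

test_that("Nagelkerke pseudo R2 spans its closed-form limits", {
  set.seed(53)
  st <- rbinom(500, 1, 0.4)
  null <- glm(st ~ 1, family = binomial())
  expect_equal(nagelkerke_r2(null, null), 0, tolerance = 1e-12)
  x <- ifelse(st == 1, 1, -1) + rnorm(500, 0, 1e-3)  # ~perfect predictor
  full <- suppressWarnings(glm(st ~ x, family = binomial()))
  expect_gt(nagelkerke_r2(full, null), 0.99)
  expect_error(nagelkerke_r2(null, full), class = "mnarch_data_error")
})

test_that("GRS explains roughly a third of disease risk in the default world", {
  co <- ea_test_cohort()
  st <- co$phenotypes$status
  full <- glm(st ~ co$phenotypes$grs, family = binomial())
  null <- glm(st ~ 1, family = binomial())
  r2 <- nagelkerke_r2(full, null)
  expect_gt(r2, 0.32 - 0.08)
  expect_lt(r2, 0.32 + 0.08)
})

test_that("liability-scale transformation matches closed-form evaluations", {
  # K = P: factor reduces to K(1-K)/z^2
  z <- dnorm(qnorm(1 - 0.001))
  expect_equal(liability_h2(0.005, 0.001, 0.001),
               0.005 * 0.001 * 0.999 / z^2, tolerance = 1e-12)
  expect_equal(liability_h2(0.005, 0.001, 0.001), 0.44, tolerance = 0.005)
  expect_equal(liability_h2(1.0, 0.001, 0.337),
               (0.001 * 0.999)^2 / (z^2 * 0.337 * 0.663), tolerance = 1e-12)
  expect_equal(liability_h2(1.0, 0.001, 0.337), 0.394, tolerance = 0.002)
  expect_warning(out <- liability_h2(5, 0.001, 0.337), "exceeds 1")
  expect_true(isTRUE(attr(out, "out_of_range")))
})
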