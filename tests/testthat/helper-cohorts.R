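# shared fixtures, built in code; the moderate default cohort is simulated
# once per test run and reused by several files
ea_cohort_cache <- new.env(parent = emptyenv())

ea_test_cohort <- function() {
  if (is.null(ea_cohort_cache$cohort)) {
    # 1:2 case:control, mirroring the discovery design
    spec <- default_cohort_spec("east_asian", n_cases = 4000,
                                n_controls = 8000, seed = 20260911)
    co <- simulate_case_control(spec)
    sc <- compute_grs(co$genotypes, grs_definition("east_asian"))
    co$phenotypes$grs_raw <- sc$grs_raw
    co$phenotypes$grs <- sc$grs
    co$phenotypes$titer_u_ml <- simulate_antibody(co)
    ea_cohort_cache$cohort <- co
  }
  ea_cohort_cache$cohort
}

# binomial 99% bounds around a nominal rate for a type-I calibration check
binom_bounds99 <- function(alpha, n_reps) {
  alpha + c(-1, 1) * stats::qnorm(0.995) * sqrt(alpha * (1 - alpha) / n_reps)
}
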