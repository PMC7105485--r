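# mnarch

Genetic architecture of membranous nephropathy: cohort simulation,
association testing, HLA fine-mapping, and combined genetic-serologic risk
scores.

## The problem

Primary membranous nephropathy (MN) is a rare autoimmune kidney disease
driven largely by autoantibodies against the podocyte antigen PLA2R. Its
genetic architecture is unusual: a handful of common alleles — *PLA2R1*,
*NFKB1*, *IRF4*, and ethnicity-specific classical HLA alleles
(DRB1\*15:01 in East Asians, DQA1\*05:01 in Europeans, DRB1\*03:01 in both) —
plus a strong PLA2R1-by-HLA interaction jointly explain roughly a third of
disease risk. That makes a simple genetic risk score (GRS) clinically
interesting: combined with the serum anti-PLA2R ELISA titer it can classify
cases that serology alone misses.

`mnarch` packages that entire analysis as tested, seedable code for
methodologists and statistical geneticists: every stage runs on simulated
cohorts whose statistical structure matches the published effect sizes,
allele frequencies, and serology operating points, so estimator behaviour
can be validated end-to-end without any consortium data.

## The models

**Generative cohort.** Disease status follows a prospective logistic
liability model over allele dosages $d_{ij} \in [0,2]$,

$$\operatorname{logit} P(Y_i=1) = \beta_0 + \textstyle\sum_j w_j d_{ij} +
\sum_{(a,b)} w_{ab} d_{ia} d_{ib},$$

with the intercept calibrated exactly (by enumeration of the discrete
genotype distribution) to a population prevalence of $K = 0.001$, and cases
and controls ascertained retrospectively to quota. Odds ratios are invariant
to this ascertainment, so fitted logistic coefficients recover the
generative weights — the backbone of the test suite.

**Risk scores.** The East Asian GRS, for example, is

$$\mathrm{GRS}_i = \big[\,0.69173\,d_{\mathrm{rs9269027}} +
1.23685\,d_{\mathrm{rs1974461}} + 0.36687\,d_{\mathrm{rs6707458}} +
0.25098\,d_{\mathrm{rs230540}} + 0.39127\,d_{\mathrm{rs9405192}} +
0.48798\,d_{\mathrm{rs9269027}} d_{\mathrm{rs6707458}} - 1.6804\,\big] /
1.0033,$$

and the combined risk score adds a weighted log-titer term,
$\mathrm{CRS}_i \propto \mathrm{GRS}_i + w \ln(\alpha\mathrm{PLA2R}_i +
0.001)$, Z-standardized against ethnicity-matched control constants. All
constants ship at full printed precision in versioned JSON.

**Statistics.** Additive dosage logistic regression with separation
flagging; greedy stepwise conditioning; inverse-variance fixed-effects
meta-analysis with Cochran's Q and $I^2$; genomic inflation $\lambda$;
multi-allelic HLA omnibus LRTs ($m-1$ df) and phased conditional
amino-acid haplotype tests ($k$ df for the $k$ new haplotypes a position
creates); Wakefield approximate Bayes factors and 99% credible sets;
pairwise epistasis LRTs with Bonferroni control (0.05/18); AUROC with
DeLong CIs, specificity-targeted cutoff tables with likelihood ratios,
IDI/NRI, decile odds ratios, Nagelkerke pseudo-$R^2$, and the
liability-scale heritability transformation.

## Worked example

```r
library(mnarch)

spec   <- default_cohort_spec("east_asian", n_cases = 2000,
                              n_controls = 4000, seed = 1)
cohort <- simulate_case_control(spec)
#> <mn_cohort> east_asian: 2000 cases / 4000 controls, 5 variants

scores <- compute_grs(cohort$genotypes, grs_definition("east_asian"))
cohort$phenotypes$grs <- scores$grs
sd(scores$grs_raw[cohort$phenotypes$status == 0])
#> [1] 1.0137   # simulated control-arm raw GRS SD vs published 1.0033

cohort$phenotypes$titer_u_ml <- simulate_antibody(cohort)
auroc(cohort$phenotypes$grs, cohort$phenotypes$status)
#> AUROC = 0.809 (95% CI 0.797-0.821), 2000 cases / 4000 controls

cutoff_table(cohort$phenotypes$titer_u_ml, cohort$phenotypes$status, 1.0)
#>   target_specificity cutoff sensitivity specificity lr_pos lr_neg
#> 1                  1 20.039       0.599           1    Inf  0.401

decile_or(cohort$phenotypes$grs, cohort$phenotypes$status)$or_[10]
#> [1] 96.9     # top vs bottom GRS decile
```

The GRS AUROC (0.81) matches the published East Asian discovery value of
0.80, the ELISA cutoff table reproduces the published 60% sensitivity /
100% specificity operating point at 20 U/mL, and individuals in the top GRS
decile carry a many-tens-fold odds of disease relative to the bottom decile.

Single-variant recovery — a simulated *PLA2R1* cohort at the published
East Asian control frequency (0.70) and odds ratio (2.81):

```r
spec <- cohort_spec("east_asian",
  variants = list(variant_spec("rs17831251", "C", 0.70, log(2.81))),
  prevalence = 0.001, n_cases = 3000, n_controls = 3000, seed = 2)
co  <- simulate_case_control(spec)
fit_additive_logistic(co$genotypes[, 1], co$phenotypes$status)
#> OR = 2.674 (95% CI 2.430-2.941), beta = 0.9834 (se 0.0486), P = 6.87e-91
```

## Pipeline and CLI

`run_pipeline()` executes simulate → score → serology → CRS → association →
conditioning → epistasis screen → credible set → diagnostics from a JSON
configuration (demo in `inst/extdata/demo_config.json`), writing commented
TSVs. A thin command-line front end lives at `inst/cli/mnarch.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","mnarch.R",package="mnarch"))')" \
  run --config inst/extdata/demo_config.json --out results/
```

Exit codes: 0 success, 2 configuration error, 3 data error, 4 numerical
failure.

## Documentation

The methods vignette (`vignettes/mnarch-methods.Rmd`) records the generative
model, every calibrated default and why, the degrees-of-freedom accounting
of the HLA tests, numerical choices, and what the simulator deliberately
does not emulate.
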