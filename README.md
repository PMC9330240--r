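# metpgx

Pharmacogenetic analysis of glycemic response to metformin in type 2
diabetes mellitus (T2DM): candidate-variant association testing on
responder/non-responder cohorts, and a permutation-based machine-learning
framework designed for small, heavily imbalanced clinical samples.

Metformin is the first-line oral hypoglycemic agent in T2DM, yet the
glucose-lowering response varies widely between patients. Part of that
variability is genetic: variants in the transporter and signalling genes
*SLC22A1* (OCT1, hepatic metformin uptake), *SLC47A1* (MATE1), *SLC2A2*
(GLUT2) and *ATM* have been repeatedly implicated. `metpgx` implements the
two analysis layers such studies need:

1. **Single-variant association.** For each candidate SNP, responders and
   non-responders (crossed with monotherapy-only membership into four group
   pairings, p1–p4) are compared at genotype and allele level by the
   two-sided Fisher exact test on 2×2 tables, with the cross-product odds
   ratio and Woolf 95% CI
   (`exp(log OR ± 1.96·√(1/a + 1/b + 1/c + 1/d))`, Haldane–Anscombe +0.5
   correction at zero cells). Genotype distributions are checked by the
   exact Hardy–Weinberg equilibrium test (conditional on allele counts),
   and cohort minor-allele frequencies can be compared against
   user-supplied reference panel counts. No multiplicity correction gates
   significance (a Bonferroni column is reported for information).

2. **Balanced-resampling prediction.** With ~250 responders (cases) and
   ~44 non-responders (controls), a naive fit is dominated by the majority
   class. The framework instead repeats, over many replicates: draw 44
   cases at random, combine them with *all* 44 controls into a balanced
   88-sample training set; fit logistic regression or the L1-penalized
   (Lasso) logistic model (penalty grid 0.00068–0.125, chosen by internal
   CV); then score the model twice —
   * stratified four-fold cross-validated AUC (Mann–Whitney form,
     fold-averaged), and
   * **case-shuffling AUC**: 44 *unseen* cases combined with the *same* 44
     controls.

   Because the controls are reused between training and validation, the
   case-shuffling estimate is optimistic: on pure noise it averages well
   above 0.5 while CV stays at chance. The package therefore ships a noise
   calibration (`noise_calibration()`) that measures this corrected
   baseline, and a permutation-averaged variable importance: per replicate
   the absolute coefficient statistic is scaled so the top feature reads
   100, then averaged across replicates with a t-based 95% CI.

A synthetic cohort generator (`generate_cohort()`) reproduces the study
conditions — phenotype means/SDs, 31% male, ~44/297 non-responders,
Hardy–Weinberg genotypes at the five candidate SNPs, and a logistic
response model with effects planted on male sex, rs12208357 minor-allele
count, familial T2DM background and waist–hip ratio — so the entire
pipeline is testable without patient data.

## Worked example

```r
library(metpgx)

# published allele-level table: T/C counts in responders vs non-responders
tab <- matrix(c(36, 470, 15, 73), 2, byrow = TRUE,
              dimnames = list(c("responders", "non_responders"), c("T", "C")))
fisher_exact_two_sided(tab)
#> [1] 0.00593469
odds_ratio_ci(tab[2:1, ])$or     # odds of T in non-responders vs responders
#> [1] 2.682648
```

The T allele is significantly enriched in non-responders (p = 0.0059,
OR ≈ 2.68). The same machinery runs end-to-end on a synthetic cohort:

```r
cohort <- generate_cohort(sim_config(seed = 1))
table(cohort$response)
#> non_responder     responder
#>            46           253

scan <- run_association_scan(cohort, default_variants())
subset(scan, variant == "rs12208357" & comparison == "p1" &
         level %in% c("allele:T", "genotype:TT"),
       select = c(level, a, b, c, d, p, or))
#>          level  a   b  c  d          p        or
#> 43 genotype:TT  1 252  2 44 0.06281191 11.454545
#> 45    allele:T 26 480 13 79 0.00422802  3.037975
```

The generator planted a negative rs12208357 effect, and the scan recovers
the allele-level enrichment (p = 0.0042, OR ≈ 3.0 with non-responders in
the numerator). Fitting the four-feature model (sex, rs12208357, familial
background, WHR) with the balanced-resampling framework:

```r
fm <- encode_features(cohort, feature_preset("four"))
nctrl <- sum(fm$y == 0)
spec <- resampling_spec(n_cases_train = nctrl, n_controls = nctrl,
                        n_replicates = 200, model = "logistic", seed = 7)
rr <- run_replicates(fm, spec)
unlist(rr$summary[c("median_cv_auc", "median_shuffle_auc")])
#>      median_cv_auc median_shuffle_auc
#>          0.5576432          0.6098771
```

The median case-shuffling AUC (0.61) must be read against the noise
baseline of that metric (≈0.53–0.60 depending on model size, see
`noise_calibration()`), not against 0.5; the cross-validated estimate
(0.56) is the unbiased one.

## Analysis workflow

The `analysis/` directory holds numbered drivers that run the full study
sequence on the synthetic cohort and write their tables and figures under
`results/`:

```sh
Rscript analysis/01_simulate_cohort.R            # cohort.tsv
Rscript analysis/02_single_variant_association.R # HWE + four-group scans
Rscript analysis/03_noise_calibration.R          # baseline calibration
Rscript analysis/04_model_comparison.R           # model presets + importance
```

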