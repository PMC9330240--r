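test_that("two-sided Fisher p-values match brute-force margin enumeration", {
  # exhaustive over all tables with both row margins <= 8
  for (r1 in 1:8) for (a in 0:r1) for (r2 in 1:8) for (cc in 0:r2) {
    tab <- matrix(c(a, r1 - a, cc, r2 - cc), 2L, 2L, byrow = TRUE)
    if (any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_two_sided(tab), oracle_fisher_p(tab),
                 tolerance = 1e-12)
  }
  # random tables with margins up to 30
  set.seed(404)
  for (i in 1:200) {
    r1 <- sample(30, 1); r2 <- sample(30, 1)
    tab <- matrix(c(a <- sample(0:r1, 1), r1 - a,
                    cc <- sample(0:r2, 1), r2 - cc), 2L, 2L, byrow = TRUE)
    if (any(colSums(tab) == 0)) next
    expect_equal(fisher_exact_two_sided(tab), oracle_fisher_p(tab),
                 tolerance = 1e-12)
  }
})

test_that("Fisher test honours its symmetries and degenerate contracts", {
  expect_equal(fisher_exact_two_sided(matrix(c(5, 5, 5, 5), 2)), 1)
  expect_equal(fisher_exact_two_sided(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  tab <- matrix(c(7, 2, 3, 9), 2, byrow = TRUE)
  expect_equal(fisher_exact_two_sided(tab), fisher_exact_two_sided(t(tab)))
  expect_equal(fisher_exact_two_sided(tab),
               fisher_exact_two_sided(tab[2:1, 2:1]))
  expect_warning(p <- fisher_exact_two_sided(matrix(c(3, 0, 5, 0), 2,
                                                    byrow = TRUE)),
                 "degenerate")
  expect_equal(p, 1)
  expect_error(fisher_exact_two_sided(matrix(c(-1, 2, 3, 4), 2)),
               "non-negative")
})

test_that("odds ratios use the cross-product with Woolf intervals", {
  # published allele table, non-responders in the first row
  res <- odds_ratio_ci(matrix(c(15, 73, 36, 470), 2, byrow = TRUE))
  expect_equal(res$or, (15 * 470) / (73 * 36), tolerance = 1e-12)
  expect_false(res$corrected)
  expect_lt(res$ci_lower, res$or); expect_gt(res$ci_upper, res$or)
  flat <- odds_ratio_ci(matrix(c(1, 1, 1, 1), 2))
  expect_equal(flat$or, 1)
  expect_true(flat$ci_lower < 1 && flat$ci_upper > 1)
  zero <- odds_ratio_ci(matrix(c(0, 10, 5, 5), 2, byrow = TRUE))
  expect_true(zero$corrected)
  expect_true(is.finite(zero$or) && zero$or > 0)
})

test_that("exact HWE test matches direct enumeration for all counts up to n = 50", {
  for (n in c(1:12, 20, 35, 50)) {
    for (n_het in 0:n) for (n_minor_hom in 0:(n - n_het)) {
      cnt <- c(n - n_het - n_minor_hom, n_het, n_minor_hom)
      expect_equal(hwe_exact_test(cnt),
                   oracle_hwe_p(cnt[1], cnt[2], cnt[3]),
                   tolerance = 1e-12)
    }
  }
})

test_that("HWE test flags heterozygote deficits and passes degenerate inputs", {
  expect_equal(hwe_exact_test(c(25, 50, 25)), 1)
  expect_lt(hwe_exact_test(c(50, 0, 50)), 1e-3)
  expect_equal(hwe_exact_test(c(10, 0, 0)), 1)
  expect_error(hwe_exact_test(c(-1, 2, 3)), "non-negative")
})

test_that("contingency construction reproduces the published allele table", {
  coh <- table3_cohort()
  v <- rs12208357_spec()
  tab <- build_contingency(coh, v, "p1", "allele:T")
  expect_equal(unclass(tab), matrix(c(36, 470, 15, 73), 2, byrow = TRUE),
               ignore_attr = TRUE)
  tab_c <- build_contingency(coh, v, "p2", "allele:C")
  expect_equal(unclass(tab_c), matrix(c(218, 20, 73, 15), 2, byrow = TRUE),
               ignore_attr = TRUE)
  tt <- build_contingency(coh, v, "p1", "genotype:TT")
  expect_equal(unclass(tt), matrix(c(2, 251, 3, 41), 2, byrow = TRUE),
               ignore_attr = TRUE)
})

test_that("contingency construction enforces group and category contracts", {
  coh <- table3_cohort()
  v <- rs12208357_spec()
  no_mono_nr <- coh[!(coh$response == "non_responder" &
                        coh$therapy == "monotherapy"), ]
  expect_error(build_contingency(no_mono_nr, v, "p4", "allele:T"),
               "empty group.*non_responders_mono")
  no_tt <- coh[coh$rs12208357 != 2L, ]
  expect_warning(tab <- build_contingency(no_tt, v, "p1", "genotype:TT"),
                 "absent")
  expect_equal(sum(tab[, 1]), 0)
  # missing genotypes are excluded row-wise
  coh2 <- coh
  coh2$rs12208357[coh2$subject_id %in% coh2$subject_id[1:5]] <- NA
  tab2 <- build_contingency(coh2, v, "p1", "allele:T")
  expect_equal(sum(tab2), sum(tab2), tolerance = 0)
  expect_equal(sum(tab2[1, ]) + sum(tab2[2, ]), 2 * (nrow(coh) - 5))
})

test_that("the association scan reproduces the published headline p-values", {
  scan <- run_association_scan(table3_cohort(), rs12208357_spec())
  expect_equal(nrow(scan), 4 * 5)
  get_p <- function(comp, lev)
    scan$p[scan$comparison == comp & scan$level == lev]
  expect_equal(round(get_p("p1", "allele:T"), 4), 0.0059)
  expect_equal(round(get_p("p2", "allele:T"), 4), 0.0418)
  expect_equal(round(get_p("p1", "genotype:TT"), 4), 0.0246)
  # T allele enriched in non-responders: oriented OR above 1
  expect_gt(scan$or[scan$comparison == "p1" & scan$level == "allele:T"], 1)
})

test_that("a scan over identical group distributions yields p = 1 throughout", {
  block <- data.frame(
    response = rep(c("responder", "non_responder"), each = 40),
    therapy = rep(c("monotherapy", "combination"), times = 40),
    rs12208357 = rep(rep(c(0L, 1L, 2L, 0L), times = c(4, 3, 1, 2)),
                     length.out = 80)
  )
  # identical genotype vectors in both groups by construction
  block$rs12208357 <- rep(rep(c(0L, 1L, 2L, 0L), times = c(4, 3, 1, 2)), 2)[1:80]
  block$rs12208357[block$response == "non_responder"] <-
    block$rs12208357[block$response == "responder"]
  scan <- run_association_scan(block, rs12208357_spec(),
                               comparisons = "p1")
  expect_true(all(scan$p == 1))
})

test_that("scan output is combinatorially complete and deterministically ordered", {
  coh <- small_cohort(seed = 21, n = 200)
  v2 <- default_variants()[1:2, ]
  scan <- run_association_scan(coh, v2)
  expect_equal(nrow(scan), 2 * 4 * 5)
  expect_equal(scan$variant, rep(v2$dbsnp_id, each = 20))
  expect_identical(scan, run_association_scan(coh, v2))
  # allele-level column sums equal twice the genotyped group sizes
  al <- scan[scan$level == "allele:C" & scan$variant == "rs11212617", ]
  gt <- scan[scan$level == "genotype:AA" & scan$variant == "rs11212617", ]
  expect_equal(al$n_group1, 2 * gt$n_group1)
  expect_equal(al$n_group2, 2 * gt$n_group2)
})

test_that("stratified scans run per stratum and compare strata within non-responders", {
  coh <- small_cohort(seed = 31, n = 400)
  v <- rs12208357_spec()
  res <- stratified_scan(coh, v, stratum = "sex")
  expect_named(res$within, c("female", "male"))
  expect_equal(nrow(res$within$male), 5L)
  expect_true(all(c("stratum_a", "stratum_b", "p") %in%
                    names(res$between_nonresponders)))
  expect_error(stratified_scan(coh, v, stratum = "no_such_column"),
               "not found")
  # identical genotype distributions between strata -> between-stratum p = 1
  coh2 <- coh
  nr <- which(coh2$response == "non_responder")
  coh2$sex[nr] <- rep(c("male", "female"), length.out = length(nr))
  coh2$rs12208357[nr] <- rep(c(0L, 0L, 1L, 1L), length.out = length(nr))
  male_g <- sort(coh2$rs12208357[nr][coh2$sex[nr] == "male"])
  female_g <- sort(coh2$rs12208357[nr][coh2$sex[nr] == "female"])
  if (identical(male_g, female_g)) {
    res2 <- stratified_scan(coh2, v, stratum = "sex")
    expect_true(all(res2$between_nonresponders$p == 1))
  }
})

test_that("MAF comparison against reference counts behaves at the extremes", {
  expect_equal(compare_maf(c(36, 470), c(36, 470))$p, 1)
  expect_lt(compare_maf(c(0, 100), c(50, 50))$p, 1e-3)
  eq <- compare_maf(c(10, 90), c(20, 180))
  expect_equal(eq$p, 1, tolerance = 1e-12)
  expect_equal(eq$maf_cohort, 0.1)
  expect_equal(eq$maf_reference, 0.1)
  expect_error(compare_maf(c(0, 0), c(5, 5)), "positive allele total")
})

test_that("null cohorts keep the p1 allele test at its nominal type-I level", {
  # no genetic effect: response depends only on non-genetic features
  null_model <- list(intercept = qlogis(253 / 297),
                     coef = c(sex_male = 0))
  v <- rs12208357_spec()
  rejected <- vapply(1:400, function(s) {
    cfg <- sim_config(seed = 7000 + s, response_model = null_model)
    coh <- generate_cohort(cfg)
    tab <- build_contingency(coh, v, "p1", "allele:T")
    fisher_exact_two_sided(tab) <= 0.05
  }, logical(1))
  expect_lt(mean(rejected), 0.055 + 2 * sqrt(0.05 * 0.95 / 400))
})

test_that("the HWE scan covers every variant and group", {
  coh <- small_cohort(seed = 41, n = 300)
  hw <- hwe_scan(coh, default_variants())
  expect_equal(nrow(hw), 5 * 3)
  expect_true(all(hw$p_hwe > 0 & hw$p_hwe <= 1))
  totals <- hw$n_hom_major + hw$n_het + hw$n_hom_minor
  expect_true(all(totals[hw$group == "all"] == 300))
  expect_true(all(totals[hw$group == "responders"] ==
                    sum(coh$response == "responder")))
})
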