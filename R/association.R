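#' Construct a validated 2x2 contingency table
#'
#' @param counts 2x2 matrix (or length-4 vector, row-major) of non-negative
#'   integer counts; rows are groups, columns category present/absent.
#' @param row_labels,col_labels Character labels of length 2.
#' @return Matrix of class `contingency_table`.
#' @export
contingency_table <- function(counts,
                              row_labels = c("group1", "group2"),
                              col_labels = c("present", "absent")) {
  if (!is.matrix(counts)) counts <- matrix(counts, 2L, 2L, byrow = TRUE)
  if (!all(dim(counts) == 2L)) domain_error("counts must be 2x2")
  if (any(counts < 0)) domain_error("counts must be non-negative")
  if (any(abs(counts - round(counts)) > 1e-8))
    domain_error("counts must be integers")
  if (any(rowSums(counts) == 0))
    domain_error("each row needs at least one positive count")
  dimnames(counts) <- list(row_labels, col_labels)
  structure(counts, class = c("contingency_table", "matrix"))
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Standard two-sided convention: the p-value sums, over all tables with the
#' observed margins, the hypergeometric probabilities not exceeding that of
#' the observed table. Degenerate tables with a zero column margin carry no
#' information about association and return p = 1 with a warning.
#'
#' @param table A 2x2 count matrix (coerced via [contingency_table()]).
#' @return The two-sided p-value in `(0, 1]`.
#' @export
fisher_exact_two_sided <- function(table) {
  tab <- contingency_table(unclass(table))
  if (any(colSums(tab) == 0)) {
    warning("degenerate table: a zero column margin; returning p = 1")
    return(1)
  }
  stats::fisher.test(matrix(as.numeric(tab), 2L, 2L))$p.value
}

#' Odds ratio with Woolf 95% confidence interval
#'
#' Cross-product odds ratio `(a*d)/(b*c)` for a 2x2 table `[[a,b],[c,d]]`
#' with the Woolf logit interval
#' `exp(log(OR) +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`. When any cell is zero
#' the Haldane-Anscombe correction (+0.5 to every cell) is applied and
#' flagged.
#'
#' @param table 2x2 count matrix.
#' @param alpha Two-sided error rate for the interval (default 0.05).
#' @return List: `or`, `ci_lower`, `ci_upper`, `corrected` (logical).
#' @export
odds_ratio_ci <- function(table, alpha = 0.05) {
  tab <- contingency_table(unclass(table))
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  corrected <- any(c(a, b, cc, d) == 0)
  if (corrected) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  or <- (a * d) / (b * cc)
  z <- stats::qnorm(1 - alpha / 2)
  se <- sqrt(1 / a + 1 / b + 1 / cc + 1 / d)
  list(or = or,
       ci_lower = exp(log(or) - z * se),
       ci_upper = exp(log(or) + z * se),
       corrected = corrected)
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact test conditional on the observed allele counts: enumerates every
#' heterozygote count compatible with the allele totals, computes each
#' configuration's probability under random mating by the standard
#' recurrence, and sums the probabilities not exceeding that of the observed
#' configuration.
#'
#' @param genotype_counts Length-3 vector `(n_AA, n_Aa, n_aa)` of major
#'   homozygote, heterozygote and minor homozygote counts.
#' @return Exact p-value in `(0, 1]`.
#' @export
hwe_exact_test <- function(genotype_counts) {
  g <- as.numeric(genotype_counts)
  if (length(g) != 3L || any(g < 0) || any(abs(g - round(g)) > 1e-8))
    domain_error("genotype_counts must be three non-negative integers")
  n <- sum(g)
  if (n < 1) domain_error("at least one subject required")
  n_ab <- round(g[2])
  n_a <- round(2 * g[3] + g[2])   # minor allele count
  n_b <- round(2 * g[1] + g[2])
  rare <- min(n_a, n_b)
  common <- max(n_a, n_b)
  if (rare == 0) return(1)
  # heterozygote count has the parity of the rare allele count
  hets <- seq(rare %% 2, rare, by = 2L)
  hom_rare <- (rare - hets) / 2
  hom_common <- (common - hets) / 2
  # unnormalized log-probabilities via the recurrence
  # P(h + 2) / P(h) = 4 * hom_rare(h) * hom_common(h) / ((h + 2) * (h + 1))
  logp <- numeric(length(hets))
  for (i in seq_along(hets)[-1]) {
    h <- hets[i - 1L]
    logp[i] <- logp[i - 1L] +
      log(4) + log(hom_rare[i - 1L]) + log(hom_common[i - 1L]) -
      log(h + 2) - log(h + 1)
  }
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  obs <- p[match(n_ab, hets)]
  if (is.na(obs)) domain_error("heterozygote count incompatible with alleles")
  sum(p[p <= obs * (1 + 1e-12)])
}

# Internal: subject masks for the four responder/non-responder pairings.
# p1: responders (any therapy)  vs non-responders (any therapy)
# p2: responders (monotherapy)  vs non-responders (any therapy)
# p3: responders (any therapy)  vs non-responders (monotherapy)
# p4: responders (monotherapy)  vs non-responders (monotherapy)
comparison_groups <- function(cohort, comparison) {
  resp <- cohort$response == "responder"
  mono <- cohort$therapy == "monotherapy"
  switch(comparison,
    p1 = list(g1 = resp,        g2 = !resp,
              labels = c("responders", "non_responders")),
    p2 = list(g1 = resp & mono, g2 = !resp,
              labels = c("responders_mono", "non_responders")),
    p3 = list(g1 = resp,        g2 = !resp & mono,
              labels = c("responders", "non_responders_mono")),
    p4 = list(g1 = resp & mono, g2 = !resp & mono,
              labels = c("responders_mono", "non_responders_mono")),
    config_error("comparison must be one of p1, p2, p3, p4")
  )
}

#' Build a responder/non-responder contingency table for one variant
#'
#' Rows are the two patient groups of the requested comparison (responder
#' group first); columns count the requested category versus all others.
#' At genotype level the category is one genotype class (e.g. `"TT"`) against
#' the rest; at allele level each genotyped subject contributes two allele
#' observations. Subjects with a missing genotype at the variant are excluded
#' row-wise.
#'
#' @param cohort Cohort data frame with `response`, `therapy` and a genotype
#'   column named by the variant's dbSNP id.
#' @param variant One row of the variant registry.
#' @param comparison `"p1"`, `"p2"`, `"p3"` or `"p4"`: responders
#'   (any therapy / monotherapy only) against non-responders (any therapy /
#'   monotherapy only), in the order p1 = all-vs-all, p2 = mono-vs-all,
#'   p3 = all-vs-mono, p4 = mono-vs-mono.
#' @param level `"genotype:<class>"` (e.g. `"genotype:TT"`) or
#'   `"allele:<base>"` (e.g. `"allele:T"`).
#' @return A [contingency_table()].
#' @export
build_contingency <- function(cohort, variant, comparison, level) {
  if (!all(c("response", "therapy") %in% names(cohort)))
    config_error("cohort must contain 'response' and 'therapy' columns")
  vid <- variant$dbsnp_id
  if (!vid %in% names(cohort))
    config_error("cohort lacks genotype column '", vid, "'")
  keep <- !is.na(cohort[[vid]])
  grp <- comparison_groups(cohort[keep, , drop = FALSE], comparison)
  g <- cohort[[vid]][keep]
  if (!sum(grp$g1))
    stop("empty group after filtering: ", grp$labels[1L],
         " (variant ", vid, ", comparison ", comparison, ")")
  if (!sum(grp$g2))
    stop("empty group after filtering: ", grp$labels[2L],
         " (variant ", vid, ", comparison ", comparison, ")")
  parts <- strsplit(level, ":", fixed = TRUE)[[1L]]
  if (length(parts) != 2L || !parts[1L] %in% c("genotype", "allele"))
    config_error("level must be 'genotype:<class>' or 'allele:<base>'")
  classes <- genotype_classes(variant)
  if (parts[1L] == "genotype") {
    cls <- parts[2L]
    if (!cls %in% classes)
      config_error("unknown genotype class '", cls, "' for ", vid)
    count_of <- as.integer(names(classes)[match(cls, classes)])
    in_cat <- g == count_of
    counts <- matrix(c(sum(in_cat & grp$g1), sum(!in_cat & grp$g1),
                       sum(in_cat & grp$g2), sum(!in_cat & grp$g2)),
                     2L, 2L, byrow = TRUE)
    col_labels <- c(cls, paste0("not_", cls))
  } else {
    base <- parts[2L]
    if (!base %in% c(variant$major_allele, variant$minor_allele))
      config_error("unknown allele '", base, "' for ", vid)
    # allele count per subject for the requested base
    n_base <- if (base == variant$minor_allele) g else 2L - g
    counts <- matrix(c(sum(n_base[grp$g1]), sum((2L - n_base)[grp$g1]),
                       sum(n_base[grp$g2]), sum((2L - n_base)[grp$g2])),
                     2L, 2L, byrow = TRUE)
    col_labels <- c(base,
                    setdiff(c(variant$major_allele, variant$minor_allele),
                            base))
  }
  if (any(colSums(counts) == 0))
    warning("category '", level, "' absent in both groups for ", vid)
  contingency_table(counts, row_labels = grp$labels, col_labels = col_labels)
}

# Internal: deterministic level list for one variant: the three genotype
# classes (by minor-allele count) then the two alleles (major, minor).
variant_levels <- function(variant) {
  c(paste0("genotype:", unname(genotype_classes(variant))),
    paste0("allele:", c(variant$major_allele, variant$minor_allele)))
}

#' Single-variant association scan
#'
#' For every variant x comparison (p1-p4) x level (three genotype classes and
#' both alleles): builds the contingency table, runs the two-sided Fisher
#' exact test and computes the odds ratio with Woolf 95% CI. The odds ratio
#' is oriented as odds(category in non-responders) / odds(category in
#' responders), so OR > 1 means the category is enriched among
#' non-responders. A Bonferroni-adjusted p-value over the scan is reported
#' for information only; the significance convention of the analysis is the
#' unadjusted p <= 0.05.
#'
#' @param cohort Cohort data frame.
#' @param variants Variant registry data frame.
#' @param comparisons Subset of `c("p1","p2","p3","p4")`.
#' @return Data frame ordered by (variant, comparison, level) with the
#'   table cells `a,b,c,d` (responder-group row first), group sizes,
#'   `p`, `or`, `ci_lower`, `ci_upper`, `or_corrected`, `p_bonferroni`.
#' @export
run_association_scan <- function(cohort, variants,
                                 comparisons = c("p1", "p2", "p3", "p4")) {
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    v <- variants[i, , drop = FALSE]
    for (comp in comparisons) {
      for (lev in variant_levels(v)) {
        tab <- suppressWarnings(build_contingency(cohort, v, comp, lev))
        p <- suppressWarnings(fisher_exact_two_sided(tab))
        # orient OR with non-responders in the numerator
        orc <- odds_ratio_ci(tab[c(2L, 1L), ])
        rows[[length(rows) + 1L]] <- data.frame(
          variant = v$dbsnp_id, gene = v$gene, comparison = comp,
          level = lev,
          a = tab[1, 1], b = tab[1, 2], c = tab[2, 1], d = tab[2, 2],
          n_group1 = sum(tab[1, ]), n_group2 = sum(tab[2, ]),
          p = p, or = orc$or, ci_lower = orc$ci_lower,
          ci_upper = orc$ci_upper, or_corrected = orc$corrected,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

#' Sex-stratified (or any-stratum) association scan
#'
#' Runs the responder versus non-responder comparison within each level of a
#' categorical stratum column, and additionally compares the strata to each
#' other within the non-responder group (e.g. T-allele frequency in male
#' versus female non-responders).
#'
#' @param cohort Cohort data frame.
#' @param variants Variant registry.
#' @param stratum Name of a categorical cohort column with >= 2 levels.
#' @return List with `within` (named list of scan data frames, one per
#'   stratum level) and `between_nonresponders` (data frame of pairwise
#'   stratum comparisons within non-responders).
#' @export
stratified_scan <- function(cohort, variants, stratum = "sex") {
  if (!stratum %in% names(cohort))
    config_error("stratum column '", stratum, "' not found in cohort")
  levs <- sort(unique(stats::na.omit(cohort[[stratum]])))
  if (length(levs) < 2L)
    config_error("stratum column must have >= 2 levels")
  within <- list()
  for (lv in levs) {
    sub <- cohort[cohort[[stratum]] == lv, , drop = FALSE]
    if (nrow(sub) < 2L) {
      warning("stratum level '", lv, "' has < 2 subjects; skipped")
      next
    }
    within[[as.character(lv)]] <-
      run_association_scan(sub, variants, comparisons = "p1")
  }
  # between-stratum comparisons within non-responders
  nonresp <- cohort[cohort$response == "non_responder", , drop = FALSE]
  rows <- list()
  pairs <- utils::combn(as.character(levs), 2L, simplify = FALSE)
  for (pr in pairs) {
    for (i in seq_len(nrow(variants))) {
      v <- variants[i, , drop = FALSE]
      vid <- v$dbsnp_id
      keep <- !is.na(nonresp[[vid]]) & nonresp[[stratum]] %in% pr
      g <- nonresp[[vid]][keep]
      s <- nonresp[[stratum]][keep]
      if (sum(s == pr[1L]) < 1L || sum(s == pr[2L]) < 1L) next
      for (lev in variant_levels(v)) {
        parts <- strsplit(lev, ":", fixed = TRUE)[[1L]]
        if (parts[1L] == "genotype") {
          classes <- genotype_classes(v)
          cnt <- as.integer(names(classes)[match(parts[2L], classes)])
          x1 <- sum(g[s == pr[1L]] == cnt); n1 <- sum(s == pr[1L])
          x2 <- sum(g[s == pr[2L]] == cnt); n2 <- sum(s == pr[2L])
          tab <- matrix(c(x1, n1 - x1, x2, n2 - x2), 2L, 2L, byrow = TRUE)
        } else {
          nb <- if (parts[2L] == v$minor_allele) g else 2L - g
          tab <- matrix(c(sum(nb[s == pr[1L]]), sum((2L - nb)[s == pr[1L]]),
                          sum(nb[s == pr[2L]]), sum((2L - nb)[s == pr[2L]])),
                        2L, 2L, byrow = TRUE)
        }
        p <- suppressWarnings(fisher_exact_two_sided(tab))
        rows[[length(rows) + 1L]] <- data.frame(
          variant = vid, stratum_a = pr[1L], stratum_b = pr[2L],
          level = lev, a = tab[1, 1], b = tab[1, 2],
          c = tab[2, 1], d = tab[2, 2], p = p, stringsAsFactors = FALSE
        )
      }
    }
  }
  list(within = within,
       between_nonresponders = if (length(rows)) do.call(rbind, rows)
                               else NULL)
}

#' Compare a cohort's minor allele frequency with reference counts
#'
#' Two-sided Fisher's exact test on the 2x2 allele-count table formed by the
#' cohort's and a user-supplied reference population's (minor, major) allele
#' counts. No live database is queried; reference counts are an input.
#'
#' @param cohort_allele_counts Length-2 vector `(minor, major)`.
#' @param reference_allele_counts Length-2 vector `(minor, major)`.
#' @return List: `p`, `maf_cohort`, `maf_reference`.
#' @export
compare_maf <- function(cohort_allele_counts, reference_allele_counts) {
  co <- as.numeric(cohort_allele_counts)
  re <- as.numeric(reference_allele_counts)
  if (any(c(co, re) < 0)) domain_error("allele counts must be non-negative")
  if (sum(co) < 1 || sum(re) < 1)
    domain_error("each population needs a positive allele total")
  tab <- matrix(c(co, re), 2L, 2L, byrow = TRUE)
  list(p = fisher_exact_two_sided(tab),
       maf_cohort = co[1L] / sum(co),
       maf_reference = re[1L] / sum(re))
}

#' Hardy-Weinberg check across the cohort and response groups
#'
#' Runs the exact HWE test per variant in the whole cohort and within
#' responders and non-responders separately.
#'
#' @param cohort Cohort data frame.
#' @param variants Variant registry.
#' @return Data frame: variant, group, genotype counts, HWE p-value.
#' @export
hwe_scan <- function(cohort, variants) {
  groups <- list(all = rep(TRUE, nrow(cohort)),
                 responders = cohort$response == "responder",
                 non_responders = cohort$response == "non_responder")
  rows <- list()
  for (i in seq_len(nrow(variants))) {
    vid <- variants$dbsnp_id[i]
    for (gn in names(groups)) {
      g <- cohort[[vid]][groups[[gn]]]
      g <- g[!is.na(g)]
      cnt <- c(sum(g == 0L), sum(g == 1L), sum(g == 2L))
      rows[[length(rows) + 1L]] <- data.frame(
        variant = vid, group = gn,
        n_hom_major = cnt[1L], n_het = cnt[2L], n_hom_minor = cnt[3L],
        p_hwe = if (sum(cnt) >= 1) hwe_exact_test(cnt) else NA_real_,
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}
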