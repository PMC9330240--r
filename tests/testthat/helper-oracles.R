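# Independent oracles used to cross-check the package's statistics.

# Two-sided Fisher p by brute-force enumeration of all 2x2 tables with the
# observed margins, summing hypergeometric probabilities not exceeding the
# observed table's (with the conventional 1e-7 relative tie guard).
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + cc; n <- a + b + cc + d
  lo <- max(0L, r1 + c1 - n); hi <- min(r1, c1)
  as <- lo:hi
  probs <- stats::dhyper(as, c1, n - c1, r1)
  p_obs <- probs[match(a, as)]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact Hardy-Weinberg p by direct log-factorial evaluation of the
# Levene-Haldane conditional distribution of the heterozygote count.
oracle_hwe_p <- function(n_aa_major, n_het, n_aa_minor) {
  n <- n_aa_major + n_het + n_aa_minor
  na <- 2 * n_aa_minor + n_het   # minor allele total
  nb <- 2 * n_aa_major + n_het
  if (min(na, nb) == 0) return(1)
  hets <- seq(min(na, nb) %% 2, min(na, nb), by = 2)
  logp <- vapply(hets, function(h) {
    hom_minor <- (na - h) / 2
    hom_major <- (nb - h) / 2
    lfactorial(n) - lfactorial(hom_major) - lfactorial(h) -
      lfactorial(hom_minor) + h * log(2) +
      lfactorial(na) + lfactorial(nb) - lfactorial(2 * n)
  }, numeric(1))
  p <- exp(logp - max(logp)); p <- p / sum(p)
  obs <- p[match(n_het, hets)]
  sum(p[p <= obs * (1 + 1e-12)])
}

# AUC by exhaustive concordant/discordant pair counting.
oracle_auc_pairs <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (x in cases) for (y in controls) {
    tot <- tot + (x > y) + 0.5 * (x == y)
  }
  tot / (length(cases) * length(controls))
}
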