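# Fixtures built in code.

# Cohort whose rs12208357 genotype distribution reproduces the published
# four-group frequency table of the study the pipeline emulates:
# responders (monotherapy)      CC 100, CT 18, TT 1
# responders (combination)      CC 119, CT 14, TT 1
# non-responders (monotherapy)  CC  11, CT  1, TT 0
# non-responders (combination)  CC  21, CT  8, TT 3
# giving responders 253 (alleles C 470 / T 36; mono C 218 / T 20) and
# non-responders 44 (C 73 / T 15; mono C 23 / T 1).
table3_cohort <- function() {
  block <- function(response, therapy, g0, g1, g2) {
    data.frame(
      response = response, therapy = therapy,
      rs12208357 = rep(c(0L, 1L, 2L), times = c(g0, g1, g2)),
      stringsAsFactors = FALSE
    )
  }
  coh <- rbind(
    block("responder", "monotherapy", 100, 18, 1),
    block("responder", "combination", 119, 14, 1),
    block("non_responder", "monotherapy", 11, 1, 0),
    block("non_responder", "combination", 21, 8, 3)
  )
  coh$subject_id <- sprintf("T%03d", seq_len(nrow(coh)))
  coh
}

rs12208357_spec <- function() {
  v <- default_variants()
  v[v$dbsnp_id == "rs12208357", , drop = FALSE]
}

# Small synthetic cohort for structural tests.
small_cohort <- function(seed = 1, n = 120, ...) {
  generate_cohort(sim_config(n_subjects = n, seed = seed, ...))
}

# Pure-noise feature matrix with the study's class structure.
noise_fm <- function(n_cases, n_controls, k, seed) {
  n <- n_cases + n_controls
  x <- metpgx:::with_seed(seed, matrix(stats::rnorm(n * k), n, k))
  colnames(x) <- paste0("noise_", seq_len(k))
  structure(list(
    x = x, y = c(rep(1L, n_cases), rep(0L, n_controls)),
    feature_names = colnames(x),
    continuous = stats::setNames(rep(TRUE, k), colnames(x)),
    n_dropped = 0L
  ), class = "feature_matrix")
}
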