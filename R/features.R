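#' Feature presets for the predictive models
#'
#' Named sets of predictor columns mirroring the model families compared in
#' the analysis: the single associated variant, all five SNPs, the
#' eleven-parameter model (everything except the glycemic traits, which
#' partly define the outcome), the four headline features, and the full
#' thirteen-variable set used as a positive control.
#'
#' @param name One of `"rs12208357"`, `"all_snps"`, `"eleven"`, `"four"`,
#'   `"full13"`.
#' @return Character vector of feature names.
#' @export
feature_preset <- function(name = c("rs12208357", "all_snps", "eleven",
                                    "four", "full13")) {
  name <- match.arg(name)
  snps <- default_variants()$dbsnp_id
  pheno <- c("sex", "age", "bmi", "whr", "creatinine", "family_history")
  glycemic <- c("fbg", "hba1c")
  switch(name,
    rs12208357 = "rs12208357",
    all_snps   = snps,
    eleven     = c(snps, pheno),
    four       = c("sex", "rs12208357", "family_history", "whr"),
    full13     = c(snps, pheno, glycemic)
  )
}

#' Encode a cohort as a numeric feature matrix
#'
#' Sex and familial background become 0/1 indicators (male = 1, history
#' present = 1); SNP genotypes are already minor-allele counts; continuous
#' traits are passed through unscaled. Standardization of the continuous
#' columns is deliberately deferred to the resampling loop, where scaling
#' parameters are estimated on each training draw only and then applied to
#' its validation data (leakage guard). Subjects with any missing encoded
#' feature or missing label are dropped and counted.
#'
#' @param cohort Cohort data frame.
#' @param feature_set Character vector of cohort feature names (see
#'   [feature_preset()]).
#' @return List of class `feature_matrix`: `x` (numeric matrix), `y`
#'   (integer labels, 1 = responder/case), `feature_names`, `continuous`
#'   (logical per column, eligible for standardization), `n_dropped`.
#' @export
encode_features <- function(cohort, feature_set) {
  unknown <- setdiff(feature_set, names(cohort))
  if (length(unknown))
    config_error("unknown feature(s): ", paste(unknown, collapse = ", "))
  n <- nrow(cohort)
  cols <- list()
  continuous <- logical(0)
  for (f in feature_set) {
    v <- cohort[[f]]
    if (f == "sex") {
      cols[["sex"]] <- as.numeric(v == "male")
      continuous["sex"] <- FALSE
    } else if (f == "family_history") {
      cols[["family_history"]] <- as.numeric(v)
      continuous["family_history"] <- FALSE
    } else if (grepl("^rs[0-9]+$", f)) {
      g <- as.numeric(v)
      if (any(!is.na(g) & !g %in% c(0, 1, 2)))
        config_error("genotype column '", f, "' has values outside {0,1,2}")
      cols[[f]] <- g
      continuous[f] <- FALSE
    } else {
      cols[[f]] <- as.numeric(v)
      continuous[f] <- TRUE
    }
  }
  x <- do.call(cbind, cols)
  y <- as.integer(cohort$response == "responder")
  keep <- stats::complete.cases(x) & !is.na(y)
  structure(list(
    x = x[keep, , drop = FALSE],
    y = y[keep],
    feature_names = colnames(x),
    continuous = continuous,
    n_dropped = n - sum(keep)
  ), class = "feature_matrix")
}

#' Pearson collinearity screen of the predictors
#'
#' Computes the feature-by-feature Pearson correlation matrix and flags
#' pairs whose absolute correlation exceeds the threshold; zero-variance
#' columns make the correlation undefined and are flagged as such.
#'
#' @param fm A [encode_features()] result.
#' @param threshold Absolute correlation flag threshold (default 0.5).
#' @return List: `r` (correlation matrix, unit diagonal), `flagged` (data
#'   frame of feature pairs with |r| > threshold), `zero_variance`
#'   (character vector of degenerate columns).
#' @export
correlation_screen <- function(fm, threshold = 0.5) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (nrow(fm$x) < 3L) domain_error("need >= 3 subjects for correlations")
  sds <- apply(fm$x, 2L, stats::sd)
  zero_var <- colnames(fm$x)[sds == 0]
  r <- suppressWarnings(stats::cor(fm$x))
  diag(r) <- 1
  flagged <- NULL
  nm <- colnames(r)
  for (i in seq_len(ncol(r) - 1L)) {
    for (j in seq.int(i + 1L, ncol(r))) {
      if (!is.na(r[i, j]) && abs(r[i, j]) > threshold) {
        flagged <- rbind(flagged, data.frame(
          feature_a = nm[i], feature_b = nm[j], r = r[i, j],
          stringsAsFactors = FALSE
        ))
      }
    }
  }
  list(r = r, flagged = flagged, zero_variance = zero_var)
}
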