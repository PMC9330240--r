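#' Default Lasso penalty grid
#'
#' Twenty log-spaced penalty values spanning the tuning range 0.00068 to
#' 0.125 (endpoints included).
#'
#' @return Ascending numeric vector of length 20.
#' @export
lambda_grid_default <- function() {
  exp(seq(log(0.00068), log(0.125), length.out = 20L))
}

#' Balanced-resampling specification
#'
#' Parameters of the permutation-based training/validation framework for the
#' imbalanced responder/non-responder cohort: at each replicate a random set
#' of `n_cases_train` cases is drawn (without replacement) and combined with
#' the full, fixed set of `n_controls` controls into a balanced training set;
#' performance is measured by stratified `cv_folds`-fold cross-validated AUC
#' and by case-shuffling AUC on held-out cases combined with the same
#' controls.
#'
#' @param n_cases_train Cases drawn per replicate (default 44).
#' @param n_controls Controls, all of which enter every training set
#'   (default 44).
#' @param n_replicates Number of resampling replicates (default 1000).
#' @param cv_folds Cross-validation folds (default 4).
#' @param model `"logistic"` (maximum-likelihood fit) or `"lasso"`
#'   (L1-penalized logistic with internal CV penalty selection).
#' @param lambda_grid Ascending positive penalty grid for the Lasso.
#' @param feature_set Optional character vector restricting the features.
#' @param seed Master seed; each replicate derives its own stream.
#' @return Validated list of class `resampling_spec`.
#' @export
resampling_spec <- function(n_cases_train = 44L, n_controls = 44L,
                            n_replicates = 1000L, cv_folds = 4L,
                            model = c("logistic", "lasso"),
                            lambda_grid = lambda_grid_default(),
                            feature_set = NULL, seed = 1L) {
  model <- match.arg(model)
  if (n_replicates < 1L) domain_error("n_replicates must be >= 1")
  if (n_cases_train < cv_folds)
    domain_error("n_cases_train must be >= cv_folds")
  if (is.unsorted(lambda_grid) || any(lambda_grid <= 0))
    domain_error("lambda_grid must be ascending and positive")
  structure(list(
    n_cases_train = as.integer(n_cases_train),
    n_controls = as.integer(n_controls),
    n_replicates = as.integer(n_replicates),
    cv_folds = as.integer(cv_folds), model = model,
    lambda_grid = lambda_grid, feature_set = feature_set,
    seed = as.integer(seed)
  ), class = "resampling_spec")
}

#' Area under the ROC curve (Mann-Whitney form)
#'
#' `P(score_case > score_control) + 0.5 * P(equal)`, computed from mid-ranks
#' so ties are handled exactly.
#'
#' @param scores Numeric scores (any monotone transform of risk).
#' @param labels Binary labels, 1 = case.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L)
    domain_error("AUC undefined: both classes must be present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Draw one balanced training set
#'
#' Samples `n_cases_train` cases without replacement and combines them with
#' all `n_controls` controls; the remaining cases form the pool from which
#' the case-shuffling validation set is later drawn.
#'
#' @param fm A [encode_features()] result.
#' @param spec A [resampling_spec()].
#' @param replicate_seed Seed for this replicate's draw.
#' @return List: `train_idx` (cases first, then controls), `case_pool`,
#'   `control_idx`.
#' @export
draw_balanced_training <- function(fm, spec, replicate_seed) {
  cases <- which(fm$y == 1L)
  controls <- which(fm$y == 0L)
  if (length(cases) < spec$n_cases_train)
    stop("insufficient cases: need ", spec$n_cases_train, ", have ",
         length(cases))
  if (length(controls) != spec$n_controls)
    stop("control set must hold exactly ", spec$n_controls,
         " subjects (all controls enter every training set), have ",
         length(controls))
  train_cases <- with_seed(replicate_seed,
                           sample(cases, spec$n_cases_train))
  list(train_idx = c(train_cases, controls),
       case_pool = setdiff(cases, train_cases),
       control_idx = controls)
}

# Internal: standardization parameters for the continuous columns, estimated
# on the training rows only.
fit_scaler <- function(x, continuous) {
  idx <- which(continuous[colnames(x)])
  center <- rep(0, ncol(x)); scale <- rep(1, ncol(x))
  names(center) <- names(scale) <- colnames(x)
  for (j in idx) {
    center[j] <- mean(x[, j])
    s <- stats::sd(x[, j])
    scale[j] <- if (is.na(s) || s == 0) 1 else s
  }
  list(center = center, scale = scale)
}

apply_scaler <- function(x, scaler) {
  sweep(sweep(x, 2L, scaler$center, "-"), 2L, scaler$scale, "/")
}

# Internal: stratified fold assignment with reseeded retry if any fold lacks
# both classes (possible only in tiny degenerate inputs).
stratified_folds <- function(y, k, seed) {
  for (attempt in seq_len(10L)) {
    fold <- integer(length(y))
    s <- derive_seed(seed, "fold_attempt", attempt)
    fold <- with_seed(s, {
      for (cls in unique(y)) {
        idx <- which(y == cls)
        fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
      }
      fold
    })
    ok <- all(vapply(seq_len(k),
                     function(f) length(unique(y[fold == f])) == 2L,
                     logical(1L)))
    if (ok) return(fold)
  }
  stop("could not build folds containing both classes in 10 attempts")
}

# Internal: logistic fit on a plain matrix via glm.fit, with coefficient
# standard errors for the importance statistic. Aliased (NA) coefficients
# from separation/collinearity are treated as zero with zero importance.
fit_logistic <- function(x, y) {
  xd <- cbind(`(Intercept)` = 1, x)
  fit <- suppressWarnings(
    stats::glm.fit(xd, y, family = stats::binomial())
  )
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  p <- fit$rank
  piv <- fit$qr$pivot[seq_len(p)]
  covmat <- chol2inv(fit$qr$qr[seq_len(p), seq_len(p), drop = FALSE])
  se <- rep(NA_real_, ncol(xd))
  se[piv] <- sqrt(diag(covmat))
  tstat <- abs(cf / se)
  tstat[!is.finite(tstat)] <- 0
  list(type = "logistic",
       a0 = cf[1L], beta = cf[-1L],
       importance_stat = tstat[-1L],
       n_selected = NA_integer_, lambda = NA_real_,
       converged = fit$converged)
}

# Internal: Lasso logistic fit with penalty selected by internal stratified
# CV maximizing held-out AUC; ties broken toward the larger (sparser)
# penalty. glmnet needs >= 2 columns, so single-feature designs are padded
# with a constant column that can never be selected.
fit_lasso <- function(x, y, spec, seed) {
  padded <- ncol(x) < 2L
  xg <- if (padded) cbind(x, `.pad` = 0) else x
  grid_desc <- rev(spec$lambda_grid)
  fold <- stratified_folds(y, spec$cv_folds, derive_seed(seed, "lambda_cv"))
  cvauc <- matrix(NA_real_, spec$cv_folds, length(spec$lambda_grid))
  for (f in seq_len(spec$cv_folds)) {
    m <- glmnet::glmnet(xg[fold != f, , drop = FALSE], y[fold != f],
                        family = "binomial", lambda = grid_desc,
                        standardize = TRUE)
    pr <- stats::predict(m, xg[fold == f, , drop = FALSE],
                         s = spec$lambda_grid)
    for (j in seq_along(spec$lambda_grid)) {
      cvauc[f, j] <- auc(pr[, j], y[fold == f])
    }
  }
  mean_auc <- colMeans(cvauc)
  best <- max(which(mean_auc >= max(mean_auc) - 1e-12))
  lam <- spec$lambda_grid[best]
  m <- glmnet::glmnet(xg, y, family = "binomial", lambda = grid_desc,
                      standardize = TRUE)
  cf <- as.numeric(stats::coef(m, s = lam))
  beta <- cf[-1L]
  names(beta) <- colnames(xg)
  if (padded) beta <- beta[colnames(x)]
  # importance: coefficient magnitude on the standardized-predictor scale
  sds <- apply(x, 2L, stats::sd)
  stat <- abs(beta) * ifelse(sds > 0, sds, 0)
  list(type = "lasso",
       a0 = cf[1L], beta = beta,
       importance_stat = stat,
       n_selected = sum(beta != 0),
       lambda = lam, internal_cv_auc = mean_auc[best],
       converged = TRUE)
}

#' Fit the replicate model on a balanced training set
#'
#' @param x Numeric training matrix (continuous columns already standardized
#'   with training-set statistics).
#' @param y Binary labels, 1 = case; both classes must be present.
#' @param spec A [resampling_spec()].
#' @param seed Seed for the Lasso's internal penalty-selection folds.
#' @return List of class `metpgx_fit` with intercept `a0`, coefficient
#'   vector `beta`, the per-feature importance statistic, and for the Lasso
#'   the selected penalty and nonzero count.
#' @export
fit_model <- function(x, y, spec, seed = spec$seed) {
  if (length(unique(y)) < 2L)
    stop("training set contains a single class")
  fit <- if (spec$model == "logistic") fit_logistic(x, y)
         else fit_lasso(x, y, spec, seed)
  class(fit) <- "metpgx_fit"
  fit
}

#' Linear predictor of a fitted replicate model
#'
#' @param fit A `metpgx_fit`.
#' @param x Matrix on the same scale as the training data.
#' @return Numeric scores (log-odds scale).
#' @export
predict_fit <- function(fit, x) {
  drop(fit$a0 + x %*% fit$beta)
}

#' Stratified k-fold cross-validated AUC
#'
#' Assigns stratified folds, refits the model on each complement, computes
#' the AUC on each held-out fold and returns the average across folds.
#' Fold-wise averaging (rather than pooling out-of-fold scores) keeps the
#' null expectation at 0.5 regardless of model complexity: pooled scores
#' from independently fitted folds carry fold-specific calibration shifts
#' that systematically depress the pooled AUC on null data. For the Lasso
#' the refits use the penalty supplied in `lambda` (the replicate's selected
#' penalty).
#'
#' @param x,y Training matrix and labels.
#' @param spec A [resampling_spec()].
#' @param seed Fold-assignment seed.
#' @param lambda Fixed penalty for Lasso refits (ignored for logistic).
#' @return AUC in `[0, 1]`.
#' @export
cv_auc <- function(x, y, spec, seed, lambda = NULL) {
  if (min(table(y)) < spec$cv_folds)
    domain_error("need >= cv_folds subjects per class")
  fold <- stratified_folds(y, spec$cv_folds, seed)
  fold_aucs <- numeric(spec$cv_folds)
  for (f in seq_len(spec$cv_folds)) {
    tr <- fold != f
    if (spec$model == "logistic") {
      m <- fit_logistic(x[tr, , drop = FALSE], y[tr])
      scores <- predict_fit(structure(m, class = "metpgx_fit"),
                            x[!tr, , drop = FALSE])
    } else {
      padded <- ncol(x) < 2L
      xg <- if (padded) cbind(x, `.pad` = 0) else x
      m <- glmnet::glmnet(xg[tr, , drop = FALSE], y[tr],
                          family = "binomial",
                          lambda = rev(spec$lambda_grid),
                          standardize = TRUE)
      scores <- as.numeric(
        stats::predict(m, xg[!tr, , drop = FALSE], s = lambda)
      )
    }
    fold_aucs[f] <- auc(scores, y[!tr])
  }
  mean(fold_aucs)
}

#' Case-shuffling validation AUC
#'
#' Draws `n_cases_train` unseen cases from the pool (disjoint from the
#' training cases by construction), combines them with the same fixed
#' controls used in training, and evaluates the already-fitted model on this
#' set. Because the controls are reused between training and validation this
#' estimate is optimistic for overfitted models; its noise baseline is
#' therefore above 0.5 and must be calibrated (see [noise_calibration()]).
#'
#' @param fit A `metpgx_fit`.
#' @param fm The full [encode_features()] result.
#' @param case_pool Indices of cases not used in training.
#' @param control_idx Indices of the controls (as used in training).
#' @param scaler The training-set scaler (from the replicate).
#' @param spec A [resampling_spec()].
#' @param seed Validation-draw seed.
#' @return AUC in `[0, 1]`.
#' @export
case_shuffle_auc <- function(fit, fm, case_pool, control_idx, scaler,
                             spec, seed) {
  if (length(case_pool) < spec$n_cases_train)
    stop("case pool (", length(case_pool), ") smaller than the ",
         spec$n_cases_train, " validation cases required")
  val_cases <- with_seed(seed, sample(case_pool, spec$n_cases_train))
  idx <- c(val_cases, control_idx)
  xv <- apply_scaler(fm$x[idx, , drop = FALSE], scaler)
  auc(predict_fit(fit, xv), fm$y[idx])
}

#' Run the full permutation-based resampling loop
#'
#' For each of `n_replicates` replicates: draw a balanced training set,
#' standardize its continuous columns on the training rows, fit the model,
#' and record training AUC, stratified `cv_folds`-fold CV AUC, case-shuffling
#' validation AUC, the coefficient vector and the importance statistic.
#' Fully reproducible from `spec$seed`.
#'
#' @param fm A [encode_features()] result (optionally restricted by
#'   `spec$feature_set`).
#' @param spec A [resampling_spec()].
#' @return List of class `metpgx_replicates`: `replicates` (per-replicate
#'   data frame), `coefficients` and `importance_stat` (replicate x feature
#'   matrices), `importance` (the profile from [variable_importance()] when
#'   at least 2 replicates were run), and `summary` (means and medians of
#'   every metric).
#' @export
run_replicates <- function(fm, spec) {
  stopifnot(inherits(fm, "feature_matrix"), inherits(spec, "resampling_spec"))
  if (!is.null(spec$feature_set)) {
    keep <- spec$feature_set
    unknown <- setdiff(keep, colnames(fm$x))
    if (length(unknown))
      config_error("feature_set names absent from matrix: ",
                   paste(unknown, collapse = ", "))
    fm$x <- fm$x[, keep, drop = FALSE]
    fm$feature_names <- keep
  }
  nfeat <- ncol(fm$x)
  R <- spec$n_replicates
  res <- data.frame(replicate_id = seq_len(R), train_auc = NA_real_,
                    cv_auc = NA_real_, shuffle_auc = NA_real_,
                    n_selected = NA_integer_, lambda = NA_real_)
  coefs <- matrix(NA_real_, R, nfeat, dimnames = list(NULL, colnames(fm$x)))
  stats_m <- coefs
  for (i in seq_len(R)) {
    rs <- derive_seed(spec$seed, "replicate", i)
    draw <- draw_balanced_training(fm, spec, rs)
    xtr_raw <- fm$x[draw$train_idx, , drop = FALSE]
    scaler <- fit_scaler(xtr_raw, fm$continuous)
    xtr <- apply_scaler(xtr_raw, scaler)
    ytr <- fm$y[draw$train_idx]
    fit <- fit_model(xtr, ytr, spec, seed = derive_seed(rs, "fit"))
    res$train_auc[i] <- auc(predict_fit(fit, xtr), ytr)
    res$cv_auc[i] <- cv_auc(xtr, ytr, spec, seed = derive_seed(rs, "cv"),
                            lambda = fit$lambda)
    res$shuffle_auc[i] <- case_shuffle_auc(fit, fm, draw$case_pool,
                                           draw$control_idx, scaler, spec,
                                           seed = derive_seed(rs, "val"))
    res$n_selected[i] <- fit$n_selected
    res$lambda[i] <- fit$lambda
    coefs[i, ] <- fit$beta
    stats_m[i, ] <- fit$importance_stat
  }
  importance <- if (R >= 2L) variable_importance(stats_m) else NULL
  summary <- list(
    model = spec$model, n_replicates = R,
    mean_train_auc = mean(res$train_auc),
    mean_cv_auc = mean(res$cv_auc),
    median_cv_auc = stats::median(res$cv_auc),
    mean_shuffle_auc = mean(res$shuffle_auc),
    median_shuffle_auc = stats::median(res$shuffle_auc),
    mean_n_selected = if (spec$model == "lasso") mean(res$n_selected)
                      else NA_real_,
    median_n_selected = if (spec$model == "lasso")
                          stats::median(res$n_selected) else NA_real_
  )
  structure(list(replicates = res, coefficients = coefs,
                 importance_stat = stats_m, importance = importance,
                 summary = summary, spec = spec),
            class = "metpgx_replicates")
}

#' Permutation-averaged scaled variable importance
#'
#' Within each replicate the absolute importance statistic (coefficient
#' t-statistic for logistic fits; standardized coefficient magnitude for the
#' Lasso) is scaled linearly so the largest feature scores 100. The profile
#' is the per-feature mean of these scaled values across replicates with a
#' t-based 95% confidence interval; features never selected stay at 0.
#'
#' @param stat_matrix Replicate x feature matrix of non-negative statistics
#'   (or a `metpgx_replicates` object).
#' @return Data frame: `feature`, `mean_importance`, `ci_lower`, `ci_upper`,
#'   `prop_selected`, sorted by decreasing mean importance.
#' @export
variable_importance <- function(stat_matrix) {
  if (inherits(stat_matrix, "metpgx_replicates"))
    stat_matrix <- stat_matrix$importance_stat
  if (nrow(stat_matrix) < 2L)
    domain_error("need >= 2 replicates for confidence intervals")
  row_max <- apply(stat_matrix, 1L, max)
  scaled <- 100 * sweep(stat_matrix, 1L, ifelse(row_max > 0, row_max, Inf),
                        "/")
  n <- nrow(scaled)
  mu <- colMeans(scaled)
  se <- apply(scaled, 2L, stats::sd) / sqrt(n)
  tq <- stats::qt(0.975, df = n - 1L)
  out <- data.frame(
    feature = colnames(stat_matrix),
    mean_importance = mu,
    ci_lower = mu - tq * se,
    ci_upper = mu + tq * se,
    prop_selected = colMeans(stat_matrix > 0),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out[order(-out$mean_importance), , drop = FALSE]
}

#' Nonzero-coefficient counts along the Lasso path
#'
#' Diagnostic for the penalty grid: fits the L1-penalized logistic model on
#' one fixed training set and reports how many features carry a nonzero
#' coefficient at each penalty value.
#'
#' @param x,y Training matrix and binary labels.
#' @param lambda_grid Ascending positive penalty grid.
#' @return Integer vector of nonzero counts, named by penalty value.
#' @export
lasso_path_nnz <- function(x, y, lambda_grid = lambda_grid_default()) {
  padded <- ncol(x) < 2L
  xg <- if (padded) cbind(x, `.pad` = 0) else x
  m <- glmnet::glmnet(xg, y, family = "binomial",
                      lambda = rev(lambda_grid), standardize = TRUE)
  nnz <- vapply(lambda_grid, function(l) {
    beta <- as.numeric(stats::coef(m, s = l))[-1L]
    if (padded) beta <- beta[seq_len(ncol(x))]
    sum(beta != 0)
  }, numeric(1L))
  stats::setNames(as.integer(nnz), signif(lambda_grid, 4L))
}

#' Noise-baseline calibration of the validation metrics
#'
#' Replaces the predictors by pure standard-normal noise while keeping the
#' study's class structure (a large case pool, a small fixed control set) and
#' runs the full replicate loop for each number of noise features. The mean
#' CV AUC should sit at 0.5 for any number of noise features; the
#' case-shuffling AUC exceeds 0.5 because the controls are reused between
#' training and validation, and its noise mean is the corrected baseline
#' against which real models must be read; the training AUC grows with the
#' number of noise features (overfitting).
#'
#' @param n_noise Integer vector of noise-feature counts (default 1:13).
#' @param spec A [resampling_spec()] (its `model`, replicate count and seed
#'   are used).
#' @param n_cases Size of the case pool (default 253).
#' @param n_controls Number of controls (default `spec$n_controls`).
#' @param fresh_noise If `TRUE` (default) the noise cohort is redrawn at
#'   every replicate, so the calibration integrates over noise realizations
#'   and estimates the expected null baseline; within a replicate the
#'   subjects' noise values are of course shared between training and
#'   validation, preserving the control-reuse mechanism. With `FALSE` a
#'   single fixed noise cohort per feature count is resampled throughout,
#'   in which case the result inherits the idiosyncrasies of that one draw
#'   (a spurious signal in the 44 fixed controls shifts every replicate).
#' @return Data frame with one row per noise-feature count: mean and median
#'   CV, case-shuffling and training AUC across replicates.
#' @export
noise_calibration <- function(n_noise = 1:13, spec = resampling_spec(),
                              n_cases = 253L, n_controls = spec$n_controls,
                              fresh_noise = TRUE) {
  make_fm <- function(k, seed) {
    n <- n_cases + n_controls
    x <- with_seed(seed,
                   matrix(stats::rnorm(n * k), n, k,
                          dimnames = list(NULL, paste0("noise_", seq_len(k)))))
    structure(list(
      x = x, y = c(rep(1L, n_cases), rep(0L, n_controls)),
      feature_names = colnames(x),
      continuous = stats::setNames(rep(TRUE, k), colnames(x)),
      n_dropped = 0L
    ), class = "feature_matrix")
  }
  rows <- list()
  for (k in n_noise) {
    spec_k <- spec
    spec_k$feature_set <- NULL
    if (fresh_noise) {
      reps <- vector("list", spec$n_replicates)
      spec_k$n_replicates <- 1L
      for (i in seq_len(spec$n_replicates)) {
        fm <- make_fm(k, derive_seed(spec$seed, "noise_features", k, i))
        spec_k$seed <- derive_seed(spec$seed, "noise_run", k, i)
        reps[[i]] <- run_replicates(fm, spec_k)$replicates
      }
      rep_tab <- do.call(rbind, reps)
    } else {
      fm <- make_fm(k, derive_seed(spec$seed, "noise_features", k))
      spec_k$seed <- derive_seed(spec$seed, "noise_run", k)
      rep_tab <- run_replicates(fm, spec_k)$replicates
    }
    rows[[length(rows) + 1L]] <- data.frame(
      n_noise = k,
      mean_cv_auc = mean(rep_tab$cv_auc),
      median_cv_auc = stats::median(rep_tab$cv_auc),
      mean_shuffle_auc = mean(rep_tab$shuffle_auc),
      median_shuffle_auc = stats::median(rep_tab$shuffle_auc),
      mean_train_auc = mean(rep_tab$train_auc)
    )
  }
  do.call(rbind, rows)
}
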