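test_that("Mann-Whitney AUC equals exhaustive pair counting", {
  expect_equal(auc(c(0.9, 0.4, 0.6), c(1, 0, 1)), 1)
  expect_equal(auc(rep(2, 6), c(1, 1, 1, 0, 0, 0)), 0.5)
  expect_equal(auc(1:6, c(0, 0, 0, 1, 1, 1)), 1)
  expect_error(auc(1:4, c(1, 1, 1, 1)), "both classes")
  set.seed(88)
  for (n in 2:10) {
    for (i in 1:30) {
      labels <- sample(c(0, 1), n, replace = TRUE)
      if (length(unique(labels)) < 2) next
      scores <- sample(1:4, n, replace = TRUE) + sample(c(0, 0.5), n, TRUE)
      expect_equal(auc(scores, labels), oracle_auc_pairs(scores, labels),
                   tolerance = 1e-12)
    }
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(99)
  scores <- rnorm(60)
  labels <- rbinom(60, 1, 0.4)
  expect_equal(auc(scores, labels),
               as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                              levels = c(0, 1),
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("balanced draws use all controls and return the case pool", {
  fm <- noise_fm(253, 44, 3, seed = 5)
  spec <- resampling_spec(n_replicates = 1)
  d <- draw_balanced_training(fm, spec, replicate_seed = 17)
  expect_length(d$train_idx, 88L)
  expect_length(d$case_pool, 209L)
  expect_setequal(d$control_idx, which(fm$y == 0))
  expect_identical(d, draw_balanced_training(fm, spec, replicate_seed = 17))
  # boundary: exactly 2 * 44 cases
  fm88 <- noise_fm(88, 44, 2, seed = 6)
  d88 <- draw_balanced_training(fm88, spec, 1)
  expect_length(d88$case_pool, 44L)
  fm43 <- noise_fm(100, 43, 2, seed = 7)
  expect_error(draw_balanced_training(fm43, spec, 1), "43")
})

test_that("stratified folds partition both classes evenly", {
  y <- c(rep(1L, 44), rep(0L, 43))  # 87 subjects, one dropped
  fold <- metpgx:::stratified_folds(y, 4L, seed = 3)
  expect_setequal(as.numeric(table(fold)), c(22, 22, 22, 21))
  for (f in 1:4) expect_length(unique(y[fold == f]), 2L)
})

test_that("logistic fits on noise stay null; planted effects are recovered", {
  spec <- resampling_spec(n_replicates = 1, model = "logistic")
  cvs <- coefs <- numeric(40)
  for (i in 1:40) {
    fm <- noise_fm(44, 44, 1, seed = 100 + i)
    fit <- fit_model(fm$x, fm$y, spec)
    coefs[i] <- fit$beta[1]
    cvs[i] <- cv_auc(fm$x, fm$y, spec, seed = 200 + i)
  }
  expect_lt(abs(mean(coefs)), 0.15)
  expect_lt(abs(mean(cvs) - 0.5), 0.05)
  # deterministic label = f(feature) separates perfectly in CV
  x <- matrix(c(rnorm(44, 3), rnorm(44, -3)), ncol = 1)
  y <- as.integer(x[, 1] > 0)
  expect_gt(cv_auc(x, y, spec, seed = 1), 0.99)
  expect_error(fit_model(x, rep(1L, 88), spec), "single class")
})

test_that("the Lasso zeroes weak predictors at the grid maximum and selects strong ones", {
  spec <- resampling_spec(n_replicates = 1, model = "lasso", seed = 4)
  # grid maximum on standard-normal noise: intercept-only model
  fm <- noise_fm(44, 44, 8, seed = 300)
  nnz <- lasso_path_nnz(fm$x, fm$y)
  expect_equal(unname(nnz[length(nnz)]), 0L)
  expect_true(all(diff(nnz) <= 0))  # sparsity monotone in the penalty
  # a strong planted effect is selected in (nearly) every replicate
  hits <- vapply(1:20, function(i) {
    x <- metpgx:::with_seed(400 + i, matrix(rnorm(88 * 5), 88, 5))
    colnames(x) <- paste0("f", 1:5)
    y <- metpgx:::with_seed(500 + i,
                            rbinom(88, 1, plogis(2 * x[, 1])))
    if (length(unique(y)) < 2) return(NA)
    fit <- fit_model(x, y, spec, seed = 600 + i)
    fit$beta[["f1"]] != 0
  }, logical(1))
  expect_gte(mean(hits, na.rm = TRUE), 0.95)
})

test_that("case-shuffling validation scores held-out cases against reused controls", {
  fm <- noise_fm(253, 44, 2, seed = 8)
  spec <- resampling_spec(n_replicates = 1)
  d <- draw_balanced_training(fm, spec, 9)
  scaler <- metpgx:::fit_scaler(fm$x[d$train_idx, ], fm$continuous)
  # constant model scores everything identically -> AUC 0.5
  const <- structure(list(a0 = 1, beta = c(noise_1 = 0, noise_2 = 0)),
                     class = "metpgx_fit")
  expect_equal(case_shuffle_auc(const, fm, d$case_pool, d$control_idx,
                                scaler, spec, seed = 11), 0.5)
  expect_error(case_shuffle_auc(const, fm, d$case_pool[1:10], d$control_idx,
                                scaler, spec, seed = 11), "pool")
  # a model aligned with the true class structure reaches AUC 1
  fm2 <- fm
  fm2$x[, 1] <- fm2$y * 10
  d2 <- draw_balanced_training(fm2, spec, 9)
  sc2 <- list(center = c(0, 0), scale = c(1, 1))
  names(sc2$center) <- names(sc2$scale) <- colnames(fm2$x)
  sep <- structure(list(a0 = 0, beta = c(noise_1 = 1, noise_2 = 0)),
                   class = "metpgx_fit")
  expect_equal(case_shuffle_auc(sep, fm2, d2$case_pool, d2$control_idx,
                                sc2, spec, seed = 12), 1)
})

test_that("the replicate loop is reproducible and summarizes its metrics", {
  fm <- noise_fm(120, 30, 3, seed = 13)
  spec <- resampling_spec(n_cases_train = 30, n_controls = 30,
                          n_replicates = 5, seed = 77)
  a <- run_replicates(fm, spec)
  b <- run_replicates(fm, spec)
  expect_identical(a$replicates, b$replicates)
  expect_identical(a$coefficients, b$coefficients)
  one <- run_replicates(fm, resampling_spec(n_cases_train = 30,
                                            n_controls = 30,
                                            n_replicates = 1, seed = 77))
  expect_equal(one$summary$mean_cv_auc, one$replicates$cv_auc[1])
  expect_equal(one$summary$median_shuffle_auc, one$replicates$shuffle_auc[1])
  expect_true(all(a$replicates$cv_auc >= 0 & a$replicates$cv_auc <= 1))
})

test_that("stronger planted effects raise CV AUC and the feature's importance", {
  run_at <- function(beta) {
    fm <- noise_fm(150, 40, 4, seed = 21)
    # plant the effect as a mean shift of feature 1 in the cases
    fm$x[, 1] <- fm$x[, 1] + beta * fm$y
    spec <- resampling_spec(n_cases_train = 40, n_controls = 40,
                            n_replicates = 30, seed = 23)
    rr <- run_replicates(fm, spec)
    imp <- rr$importance
    list(cv = rr$summary$median_cv_auc,
         imp1 = imp$mean_importance[imp$feature == "noise_1"])
  }
  weak <- run_at(0.3); strong <- run_at(1.5)
  expect_gt(strong$cv, weak$cv)
  expect_gt(strong$imp1, weak$imp1)
})

test_that("importance scaling pins the dominant feature at 100", {
  stat <- rbind(c(5, 0.1, 0), c(4, 0.2, 0), c(6, 0.05, 0))
  colnames(stat) <- c("a", "b", "c")
  prof <- variable_importance(stat)
  expect_equal(prof$mean_importance[prof$feature == "a"], 100)
  expect_lt(prof$mean_importance[prof$feature == "b"], 5)
  expect_equal(prof$mean_importance[prof$feature == "c"], 0)
  expect_equal(prof$prop_selected[prof$feature == "c"], 0)
  expect_true(all(prof$ci_lower <= prof$ci_upper))
})

test_that("two equally strong independent features earn equal mean importance", {
  fm <- noise_fm(160, 40, 2, seed = 31)
  fm$x[, 1] <- fm$x[, 1] + 0.8 * fm$y
  fm$x[, 2] <- fm$x[, 2] + 0.8 * fm$y
  spec <- resampling_spec(n_cases_train = 40, n_controls = 40,
                          n_replicates = 60, seed = 33)
  rr <- run_replicates(fm, spec)
  imp <- rr$importance$mean_importance
  expect_lt(abs(imp[1] - imp[2]), 12)
})

test_that("noise baselines separate as expected: shuffle above CV, both near chance", {
  spec <- resampling_spec(n_replicates = 150, model = "logistic", seed = 55)
  nc <- noise_calibration(n_noise = 3, spec)
  expect_gte(nc$mean_shuffle_auc - nc$mean_cv_auc, 0)
  expect_lte(nc$mean_shuffle_auc - nc$mean_cv_auc, 0.1)
  expect_true(nc$mean_cv_auc > 0.45 && nc$mean_cv_auc < 0.60)
  expect_true(nc$mean_shuffle_auc > 0.45 && nc$mean_shuffle_auc < 0.60)
  expect_gt(nc$mean_train_auc, nc$mean_cv_auc)
})

test_that("causal features outrank noise features on average in the default cohort", {
  coh <- generate_cohort(sim_config(seed = 61))
  fm <- encode_features(coh, feature_preset("full13"))
  nctrl <- sum(fm$y == 0)
  spec <- resampling_spec(n_cases_train = nctrl, n_controls = nctrl,
                          n_replicates = 60, model = "lasso", seed = 62)
  rr <- run_replicates(fm, spec)
  imp <- rr$importance
  causal <- c("sex", "rs12208357", "family_history", "whr")
  m_causal <- mean(imp$mean_importance[imp$feature %in% causal])
  m_null <- mean(imp$mean_importance[!imp$feature %in% causal])
  expect_gt(m_causal, m_null)
})
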