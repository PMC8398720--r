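test_that("screening thresholds are inclusive at 60/10/10", {
  expect_true(screen_positive(scale_scores(60, 0, 0), "SAD"))
  expect_false(screen_positive(scale_scores(59, 0, 0), "SAD"))
  expect_true(screen_positive(scale_scores(0, 10, 0), "GAD"))
  expect_false(screen_positive(scale_scores(0, 9, 0), "GAD"))
  expect_true(screen_positive(scale_scores(0, 0, 10), "MDD"))
  expect_false(screen_positive(scale_scores(0, 0, 9), "MDD"))
})

test_that("subjects with four or more missing features are excluded", {
  set.seed(701)
  X <- matrix(rnorm(10 * 8), 10, dimnames = list(NULL, pheno_features()))
  X[1, 1:4] <- NA  # exactly 4 missing -> out
  X[2, 1:3] <- NA  # 3 missing -> retained
  feats <- data.frame(subject_id = sprintf("S%02d", 1:10), X,
                      check.names = FALSE)
  y <- rep(c(TRUE, FALSE), 5)
  inp <- build_model_input(feats, y)
  expect_equal(inp$n_excluded, 1)
  expect_identical(inp$excluded_ids, "S01")
  expect_true("S02" %in% inp$subject_id)
  expect_equal(nrow(inp$X), 9)

  # degenerate cohorts are fatal with a diagnostic
  expect_error(build_model_input(feats, rep(TRUE, 10)), "single class")
  Xall <- X; Xall[, 1:4] <- NA
  fall <- data.frame(subject_id = feats$subject_id, Xall, check.names = FALSE)
  expect_error(build_model_input(fall, y), "left after")
})

test_that("preprocessing is fitted on training rows only", {
  X <- matrix(c(1, 2, 3, 10, 20, 30), 3,
              dimnames = list(NULL, c("a", "b")))
  pp <- fit_preprocess(X)
  expect_equal(unname(pp$mean), c(2, 20))
  expect_equal(unname(pp$sd), c(1, 10))
  expect_equal(unname(pp$median), c(2, 20))

  # training data standardizes to mean 0 sd 1
  Z <- apply_preprocess(pp, X)
  expect_equal(unname(colMeans(Z)), c(0, 0))
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1))

  # held-out data generally does not (no-leakage witness)
  set.seed(702)
  Xte <- matrix(rnorm(20, mean = 5), 10, 2)
  Zte <- apply_preprocess(pp, Xte)
  expect_gt(abs(mean(Zte[, 1])), 0.5)

  # impute-then-scale order: missing -> median -> 0 after centering
  Xm <- matrix(c(NA, 2, 3), 1)
  pp2 <- list(mean = c(2, 0, 0), sd = c(1, 1, 1), median = c(2, 0, 0))
  expect_equal(apply_preprocess(pp2, Xm)[1, 1], 0)
  expect_equal(apply_preprocess(pp2, matrix(c(3, 0, 0), 1))[1, 1], 1)
})

test_that("zero-variance and all-missing training features are handled", {
  X <- cbind(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_warning(pp <- fit_preprocess(X), "zero-variance")
  expect_equal(unname(apply_preprocess(pp, X)[, "a"]), c(0, 0, 0))
  Xna <- cbind(a = c(NA_real_, NA, NA), b = c(1, 2, 3))
  expect_error(fit_preprocess(Xna), "missing in all training rows")
})

test_that("logistic fit recovers signs, shrinks under the null, matches IRLS", {
  set.seed(703)
  # null: permuted labels, large n -> coefficients near zero
  X <- matrix(rnorm(2000 * 3), 2000, dimnames = list(NULL, c("a", "b", "c")))
  y <- runif(2000) < 0.5
  m0 <- fit_logistic(X, y)
  expect_lt(max(abs(m0$coefficients)), 0.15)
  expect_identical(m0$method, "mle")

  # a single strong positive feature gets a positive coefficient
  x1 <- rnorm(400)
  y1 <- runif(400) < plogis(2 * x1)
  m1 <- fit_logistic(cbind(s = x1), y1)
  expect_gt(m1$coefficients[["s"]], 0)

  # small non-separable fixture matches an independent IRLS oracle
  xf <- c(1, 2, 3, 4)
  yf <- c(0, 1, 0, 1)
  mf <- fit_logistic(cbind(x = xf), yf)
  bo <- oracle_irls_logistic(xf, yf)
  expect_equal(mf$intercept, bo[1], tolerance = 1e-8)
  expect_equal(mf$coefficients[["x"]], bo[2], tolerance = 1e-8)
})

test_that("separated data falls back to a weak ridge with a warning", {
  x <- c(-2, -1, 1, 2)
  y <- c(0, 0, 1, 1)
  expect_warning(m <- fit_logistic(cbind(x = x), y), "ridge")
  expect_identical(m$method, "ridge")
  expect_true(is.finite(m$coefficients[["x"]]))
  expect_gt(m$coefficients[["x"]], 0)
})

test_that("auroc implements the Mann-Whitney pair formulation", {
  expect_equal(auroc(c(1, 2, 3, 10, 11), c(F, F, F, T, T)), 1.0)
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(F, F, T, T)),
               oracle_auroc(c(0.1, 0.4, 0.35, 0.8), c(F, F, T, T)))
  set.seed(704)
  for (i in 1:5) {
    s <- sample(round(runif(30), 2))  # duplicates induce ties
    l <- runif(30) < 0.4
    if (length(unique(l)) < 2) next
    expect_equal(auroc(s, l), oracle_auroc(s, l), tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(auroc(exp(3 * s), l), auroc(s, l), tolerance = 1e-12)
  }
  expect_true(is.na(auroc(1:4, rep(TRUE, 4))))
})

test_that("repeated 5x20 CV yields 100 AUROCs from near-equal stratified folds", {
  fc <- simulate_feature_cohort(n = 84, seed = 705)
  inp <- build_model_input(fc$features, fc$labels$MDD)
  cv <- repeated_kfold_cv(inp, k = 5, r = 20, seed = 1)
  expect_length(cv$aurocs, 100)
  expect_true(all(cv$aurocs >= 0 & cv$aurocs <= 1))
  expect_setequal(unique(cv$fold_sizes), c(16, 17))
  # reproducible from the seed
  cv2 <- repeated_kfold_cv(inp, k = 5, r = 20, seed = 1)
  expect_identical(cv$aurocs, cv2$aurocs)
  # too few positives for stratification is fatal
  tiny <- list(X = inp$X[1:10, ], y = c(TRUE, rep(FALSE, 9)))
  expect_error(repeated_kfold_cv(tiny, k = 5, r = 1, seed = 1),
               "infeasible")
})

test_that("each fold's AUROC comes from a model untouched by its test subjects", {
  fc <- simulate_feature_cohort(n = 60, effects = default_effects(),
                                seed = 706)
  inp <- build_model_input(fc$features, fc$labels$SAD)
  cv <- repeated_kfold_cv(inp, k = 5, r = 2, seed = 3, details = TRUE)
  # recompute fold 2 of repeat 1 by hand from the recorded assignment
  f <- cv$folds[, 1]
  tr <- f != 2
  pp <- fit_preprocess(inp$X[tr, , drop = FALSE])
  m <- suppressWarnings(
    fit_logistic(apply_preprocess(pp, inp$X[tr, , drop = FALSE]),
                 inp$y[tr]))
  p <- predict_logistic(m, apply_preprocess(pp, inp$X[!tr, , drop = FALSE]))
  expect_equal(auroc(p, inp$y[!tr]), cv$aurocs[2], tolerance = 1e-12)

  # corrupting held-out rows cannot change the training-side fit
  Xc <- inp$X
  Xc[!tr, ] <- Xc[!tr, ] + 100
  ppc <- fit_preprocess(Xc[tr, , drop = FALSE])
  expect_identical(ppc, pp)
})

test_that("the corrected resampled t-test matches its closed form", {
  # null identity: all fold AUROCs at 0.5
  tt0 <- corrected_resampled_ttest(rep(0.5, 100), k = 5, r = 20)
  expect_equal(tt0$t, 0)
  expect_equal(tt0$p_one_tailed, 1)
  expect_equal(tt0$df, 99)

  set.seed(707)
  a <- rnorm(100, 0.6, 0.13)
  tt <- corrected_resampled_ttest(a, k = 5, r = 20)
  d <- a - 0.5
  expect_equal(tt$t, mean(d) / sqrt((1 / 100 + 1 / 4) * var(d)),
               tolerance = 1e-12)
  expect_equal(tt$p_one_tailed, pt(tt$t, 99, lower.tail = FALSE),
               tolerance = 1e-15)

  # degenerate variance cases
  expect_warning(ttv <- corrected_resampled_ttest(rep(0.7, 100), k = 5, r = 20),
                 "zero variance")
  expect_equal(ttv$p_one_tailed, 0)
})

test_that("auroc agrees with an established ROC implementation", {
  set.seed(708)
  s <- rnorm(60)
  l <- runif(60) < plogis(s)
  if (length(unique(l)) == 2) {
    ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(l, s,
                                                           direction = "<"))))
    expect_equal(auroc(s, l), ref, tolerance = 1e-12)
  }
})

test_that("full-data model recovers injected coefficient directions", {
  set.seed(709)
  fc <- simulate_feature_cohort(n = 300, effects = default_effects(),
                                seed = 710)
  inp <- build_model_input(fc$features, fc$labels$MDD)
  full <- suppressWarnings(fit_full_model(inp))
  expect_length(full$coefficients, 8)
  expect_named(full$coefficients, pheno_features())
  # dominant injected MDD effects: speech and exits protective
  expect_lt(full$coefficients[["speech_presence"]], 0)
  expect_lt(full$coefficients[["exits_from_home"]], 0)

  # null cohort: all coefficients small
  fcn <- simulate_feature_cohort(n = 800, seed = 711)
  inpn <- build_model_input(fcn$features, fcn$labels$MDD)
  fn <- suppressWarnings(fit_full_model(inpn))
  expect_lt(max(abs(fn$coefficients)), 0.35)
})
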