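# Screening from scale scores, preprocessing, logistic model fitting,
# AUROC, repeated stratified k-fold cross-validation, and the corrected
# resampled t-test.

#' Screen a subject for one disorder
#'
#' Fixed inclusive thresholds on the exit scale scores: LSAS >= 60 for
#' SAD, GAD-7 >= 10 for GAD, PHQ-8 >= 10 for MDD.
#'
#' @param scores A [scale_scores()] object (or list with `lsas`, `gad7`,
#'   `phq8`).
#' @param disorder One of `"SAD"`, `"GAD"`, `"MDD"`.
#' @param thresholds Named list of thresholds (see [default_config()]).
#' @return Logical: positive screen.
#' @export
#' @examples
#' screen_positive(scale_scores(60, 3, 4), "SAD")  # TRUE
#' screen_positive(scale_scores(59, 3, 4), "SAD")  # FALSE
screen_positive <- function(scores, disorder,
                            thresholds = default_config()$screening) {
  disorder <- match.arg(disorder, names(.PHENO_DISORDERS))
  instrument <- .PHENO_DISORDERS[[disorder]]
  scores[[instrument]] >= thresholds[[instrument]]
}

#' Screening labels for a cohort
#'
#' @param cohort List of [subject_record()]s.
#' @param config Analysis configuration.
#' @return Data frame `subject_id`, the three scale scores, and logical
#'   columns `SAD`, `GAD`, `MDD`.
#' @export
screening_labels <- function(cohort, config = default_config()) {
  out <- data.frame(
    subject_id = vapply(cohort, `[[`, character(1), "subject_id"),
    lsas = vapply(cohort, function(r) r$scores$lsas, integer(1)),
    gad7 = vapply(cohort, function(r) r$scores$gad7, integer(1)),
    phq8 = vapply(cohort, function(r) r$scores$phq8, integer(1)),
    stringsAsFactors = FALSE)
  for (d in names(.PHENO_DISORDERS)) {
    out[[d]] <- vapply(seq_len(nrow(out)), function(i) {
      screen_positive(out[i, ], d, config$screening)
    }, logical(1))
  }
  out
}

#' Screening prevalence summary
#'
#' @param labels Output of [screening_labels()] (or any data frame with
#'   logical `SAD`, `GAD`, `MDD` columns).
#' @return Data frame `disorder`, `n`, `positives`, `percent`.
#' @export
screening_summary <- function(labels) {
  do.call(rbind, lapply(names(.PHENO_DISORDERS), function(d) {
    data.frame(disorder = d, n = nrow(labels),
               positives = sum(labels[[d]]),
               percent = round(100 * mean(labels[[d]]), 1))
  }))
}

#' Assemble the modeling input for one disorder
#'
#' Subjects with four or more missing features are considered to have
#' insufficient data and are excluded before any modeling; subjects with
#' one to three missing features are retained (their gaps are median-
#' imputed inside each training fold later).
#'
#' @param features Feature data frame from [extract_cohort_features()].
#' @param labels Logical label vector aligned with `features` rows.
#' @param max_missing Exclusion threshold (inclusive; default 4).
#' @return List: `X` (subjects x 8 matrix with `NA`s), `y`, `subject_id`,
#'   `excluded_ids`, `n_excluded`.
#' @export
build_model_input <- function(features, labels, max_missing = 4L) {
  X <- as.matrix(features[, .PHENO_FEATURES, drop = FALSE])
  stopifnot(nrow(X) == length(labels))
  miss <- rowSums(is.na(X))
  keep <- miss < max_missing
  if (sum(keep) < 2) {
    stop(sprintf("only %d subject(s) left after the >=%d-missing-feature exclusion",
                 sum(keep), max_missing), call. = FALSE)
  }
  y <- as.logical(labels[keep])
  if (length(unique(y)) < 2) {
    stop("all retained subjects screen in a single class; cannot model",
         call. = FALSE)
  }
  ids <- if ("subject_id" %in% names(features)) {
    features$subject_id
  } else {
    as.character(seq_len(nrow(X)))
  }
  list(X = X[keep, , drop = FALSE], y = y, subject_id = ids[keep],
       excluded_ids = ids[!keep], n_excluded = sum(!keep))
}

#' Fit preprocessing parameters on training rows
#'
#' Per-feature mean, standard deviation, and median over the non-missing
#' training values only, so held-out subjects never leak into the
#' preprocessing.
#'
#' @param X Training feature matrix (may contain `NA`).
#' @return List of named vectors `mean`, `sd`, `median`.
#' @export
fit_preprocess <- function(X) {
  stopifnot(nrow(X) >= 2)
  all_na <- colSums(!is.na(X)) == 0
  if (any(all_na)) {
    stop("feature(s) missing in all training rows: ",
         paste(colnames(X)[all_na], collapse = ", "), call. = FALSE)
  }
  m <- apply(X, 2, mean, na.rm = TRUE)
  s <- apply(X, 2, sd, na.rm = TRUE)
  s[is.na(s)] <- 0
  if (any(s == 0)) {
    warning("zero-variance training feature(s): ",
            paste(colnames(X)[s == 0], collapse = ", "),
            "; scaled column(s) will be all zero", call. = FALSE)
  }
  md <- apply(X, 2, median, na.rm = TRUE)
  list(mean = m, sd = s, median = md)
}

#' Apply preprocessing: impute, then scale
#'
#' Missing values become the training median; every feature is then
#' centered on the training mean and divided by the training SD
#' (zero-variance features map to all-zero columns).
#'
#' @param params Output of [fit_preprocess()].
#' @param X Feature matrix to transform.
#' @return Numeric matrix with no missing values.
#' @export
apply_preprocess <- function(params, X) {
  X <- as.matrix(X)
  for (j in seq_len(ncol(X))) {
    X[is.na(X[, j]), j] <- params$median[j]
  }
  s <- ifelse(params$sd == 0, 1, params$sd)
  out <- sweep(sweep(X, 2, params$mean, "-"), 2, s, "/")
  out[, params$sd == 0] <- 0
  out
}

.ridge_irls <- function(Xd, y, lambda, maxit = 100, tol = 1e-10) {
  p <- ncol(Xd)
  pen <- diag(c(0, rep(lambda, p - 1)), p)  # intercept unpenalized
  beta <- numeric(p)
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    beta_new <- solve(crossprod(Xd, w * Xd) + pen, crossprod(Xd, w * z))
    delta <- max(abs(beta_new - beta))
    beta <- drop(beta_new)
    if (delta < tol) break
  }
  beta
}

#' Fit an unpenalized logistic regression
#'
#' Maximum-likelihood logistic fit of `y` on (already standardized)
#' features `X`. The method interprets raw standardized coefficients, so
#' no regularization is applied; if the fit is (quasi-)separated or fails
#' to converge, a weak ridge penalty (`ridge_lambda`, default 1e-4) is
#' used instead and a warning is emitted.
#'
#' @param X Numeric feature matrix (no `NA`).
#' @param y Logical (or 0/1) outcome with both classes present.
#' @param ridge_lambda Fallback ridge penalty.
#' @return List: `intercept`, `coefficients` (named per feature),
#'   `method` (`"mle"` or `"ridge"`).
#' @export
fit_logistic <- function(X, y, ridge_lambda = 1e-4) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(unique(y)) < 2) stop("both classes must be present", call. = FALSE)
  Xd <- cbind(`(Intercept)` = 1, X)
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm.fit(Xd, y, family = stats::binomial(),
                   control = list(maxit = 100)),
    warning = function(w) {
      if (grepl("0 or 1|converge|separat", conditionMessage(w))) sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (sep || !fit$converged || anyNA(fit$coefficients)) {
    warning("separation or non-convergence in logistic fit; ",
            "falling back to ridge (lambda = ", ridge_lambda, ")",
            call. = FALSE)
    beta <- .ridge_irls(Xd, y, ridge_lambda)
    method <- "ridge"
  } else {
    beta <- fit$coefficients
    method <- "mle"
  }
  cf <- beta[-1]
  names(cf) <- colnames(X)
  list(intercept = unname(beta[1]), coefficients = cf, method = method)
}

#' Predicted probabilities from a fitted logistic model
#'
#' @param model Output of [fit_logistic()].
#' @param X Standardized feature matrix.
#' @return Vector of probabilities.
#' @export
predict_logistic <- function(model, X) {
  drop(plogis(model$intercept + as.matrix(X) %*% model$coefficients))
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a random positive
#' outscores a random negative, counting ties as one half (midranks).
#'
#' @param scores Numeric prediction scores.
#' @param labels Logical labels.
#' @return AUROC in `[0, 1]`; `NA` if either class is absent.
#' @export
auroc <- function(scores, labels) {
  labels <- as.logical(labels)
  npos <- sum(labels)
  nneg <- sum(!labels)
  if (npos == 0 || nneg == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels]) - npos * (npos + 1) / 2) / (npos * nneg)
}

# Stratified fold assignment with fold totals as equal as possible:
# sizes are floor(n/k) or floor(n/k)+1, positives spread so every fold
# holds both classes whenever npos >= k and nneg >= k.
.make_folds <- function(y, k, stratified = TRUE) {
  n <- length(y)
  if (!stratified) {
    return(sample(rep(seq_len(k), length.out = n)))
  }
  pos <- which(y)
  neg <- which(!y)
  if (length(pos) < k || length(neg) < k) {
    stop(sprintf("stratified %d-fold assignment infeasible: %d positives, %d negatives",
                 k, length(pos), length(neg)), call. = FALSE)
  }
  totals <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) totals[sample.int(k, extra)] <- totals[1] + 1
  cp <- rep(length(pos) %/% k, k)
  rp <- length(pos) %% k
  if (rp > 0) {
    # give positive remainders to the largest folds (random among ties)
    ord <- order(-totals, sample.int(k))
    cp[ord[seq_len(rp)]] <- cp[ord[seq_len(rp)]] + 1
  }
  cn <- totals - cp
  if (any(cn < 0)) stop("fold assignment infeasible", call. = FALSE)
  fold <- integer(n)
  fold[sample(pos)] <- rep(seq_len(k), times = cp)
  fold[sample(neg)] <- rep(seq_len(k), times = cn)
  fold
}

#' Repeated stratified k-fold cross-validation of the screening model
#'
#' For each of `r` repeats, subjects are randomly partitioned into `k`
#' near-equal stratified folds; for each fold, preprocessing (median
#' imputation + scaling) and the logistic model are fitted on the other
#' `k - 1` folds only, and the held-out subjects' predicted probabilities
#' are scored by AUROC. Returns all `k * r` fold-level AUROCs; fully
#' reproducible from `seed`.
#'
#' @param input Model input from [build_model_input()].
#' @param k Folds per repeat (default 5).
#' @param r Repeats (default 20).
#' @param seed Integer seed for the fold assignments.
#' @param stratified Preserve class proportions per fold (default TRUE).
#' @param ridge_lambda Separation fallback penalty for the fold fits.
#' @param details Also return the fold assignment matrix (subjects x r).
#' @return List of class `cv_result`: `aurocs` (length `k * r`, fold
#'   varying fastest), `fold_sizes`, `k`, `r`, `n`, and optionally
#'   `folds`.
#' @export
repeated_kfold_cv <- function(input, k = 5L, r = 20L, seed = NULL,
                              stratified = TRUE, ridge_lambda = 1e-4,
                              details = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  X <- input$X
  y <- input$y
  aurocs <- numeric(k * r)
  fold_sizes <- integer(0)
  folds <- if (details) matrix(NA_integer_, nrow(X), r) else NULL
  idx <- 0L
  for (rep_i in seq_len(r)) {
    f <- .make_folds(y, k, stratified)
    if (details) folds[, rep_i] <- f
    fold_sizes <- c(fold_sizes, tabulate(f, k))
    for (fold_i in seq_len(k)) {
      tr <- f != fold_i
      pp <- fit_preprocess(X[tr, , drop = FALSE])
      model <- suppressWarnings(
        fit_logistic(apply_preprocess(pp, X[tr, , drop = FALSE]), y[tr],
                     ridge_lambda))
      p <- predict_logistic(model, apply_preprocess(pp, X[!tr, , drop = FALSE]))
      idx <- idx + 1L
      aurocs[idx] <- auroc(p, y[!tr])
    }
  }
  structure(list(aurocs = aurocs, fold_sizes = fold_sizes, k = k, r = r,
                 n = nrow(X), folds = folds), class = "cv_result")
}

#' Corrected resampled t-test for repeated k-fold CV performance
#'
#' Tests whether the mean fold-level AUROC exceeds `null_value` (0.5, an
#' uninformative model). Because the `k * r` resampled models share
#' training data, the naive variance of the mean is deflated; the
#' corrected statistic inflates it by the train/test overlap term:
#' \deqn{t = \bar d / \sqrt{(1/(kr) + n_{test}/n_{train})\, s_d^2}}
#' with `d_j = AUROC_j - null_value`, `df = k r - 1`, and a one-tailed
#' upper p-value. The train/test ratio uses the equal-fold approximation
#' `1/(k - 1)`; with the default 5x20 design the bracket is
#' `(1/100 + 1/4)`.
#'
#' @param aurocs The `k * r` fold-level AUROCs.
#' @param null_value Null performance (default 0.5).
#' @param k,r Cross-validation design.
#' @param test_train_ratio Overlap ratio; default `1/(k-1)`.
#' @return List `t`, `df`, `p_one_tailed`, `mean`, `sd`.
#' @export
corrected_resampled_ttest <- function(aurocs, null_value = 0.5, k = 5L,
                                      r = 20L,
                                      test_train_ratio = 1 / (k - 1)) {
  stopifnot(length(aurocs) == k * r)
  d <- aurocs - null_value
  m <- mean(d)
  v <- var(d)
  df <- k * r - 1
  if (v == 0) {
    if (m == 0) {
      t <- 0
      p <- 1
    } else {
      warning("zero variance with nonzero mean difference; p = 0",
              call. = FALSE)
      t <- sign(m) * Inf
      p <- if (m > 0) 0 else 1
    }
  } else {
    t <- m / sqrt((1 / (k * r) + test_train_ratio) * v)
    p <- pt(t, df, lower.tail = FALSE)
  }
  list(t = t, df = df, p_one_tailed = p, mean = mean(aurocs), sd = sd(aurocs))
}

#' Full-data logistic model with x-standardized coefficients
#'
#' Fits preprocessing and the logistic model on all included subjects of
#' one disorder. Because every feature is scaled to mean 0, SD 1, the
#' coefficient magnitudes are comparable across features; a negative
#' coefficient means the feature is associated with decreased odds of a
#' positive screen.
#'
#' @param input Model input from [build_model_input()].
#' @param ridge_lambda Separation fallback penalty.
#' @return List: `intercept`, `coefficients` (8, named), `preprocess`,
#'   `method`.
#' @export
fit_full_model <- function(input, ridge_lambda = 1e-4) {
  pp <- fit_preprocess(input$X)
  model <- fit_logistic(apply_preprocess(pp, input$X), input$y, ridge_lambda)
  c(model, list(preprocess = pp))
}
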