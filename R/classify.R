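# Cross-validated logistic-regression discrimination with a permutation-based
# empirical chance level. The patient class (MCI) is the positive class, so
# sensitivity = correctly identified patients.

# Bare IRLS ridge-logistic fit on a design matrix WITHOUT intercept column
# (added here). Returns coefficients c(intercept, slopes) and diagnostics.
fit_irls <- function(x, y, ridge = 1e-6, max_iter = 50, tol = 1e-8) {
  x <- cbind(1, x)
  p <- ncol(x)
  beta <- numeric(p)
  pen <- diag(c(0, rep(ridge, p - 1)), p)
  dev_old <- Inf
  dev <- Inf
  converged <- FALSE
  iter <- 0
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    xtw <- t(x * w)
    beta_new <- tryCatch(
      solve(xtw %*% x + pen, xtw %*% z),
      error = function(e) NULL
    )
    if (is.null(beta_new)) break
    beta <- drop(beta_new)
    dev <- -2 * sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
    if (abs(dev_old - dev) < tol * (abs(dev) + 1)) {
      converged <- TRUE
      break
    }
    dev_old <- dev
  }
  list(beta = beta, converged = converged, n_iter = iter, deviance = dev)
}

#' Fit a ridge-stabilised logistic regression
#'
#' Maximum-likelihood fit by iteratively reweighted least squares with a small
#' L2 penalty on the slopes for stability. Under perfect separation the
#' unpenalised likelihood diverges; if the fit has not converged at the
#' default ridge, it is retried with a 1000-fold larger penalty and flagged.
#'
#' @param x numeric feature matrix (subjects x features).
#' @param labels two-level factor/character vector, or 0/1.
#' @param positive the positive-class label (default `"MCI"`); ignored for
#'   0/1 input.
#' @param ridge L2 penalty on the slopes (default 1e-6).
#' @return object of class `pli_logistic` with `coefficients`, `converged`,
#'   `ridge_fallback`, `ridge`, `n_iter`, `feature_names`, `positive`.
#' @export
fit_logistic <- function(x, labels, positive = "MCI", ridge = 1e-6) {
  x <- as.matrix(x)
  y <- as_binary(labels, positive)
  if (length(unique(y)) < 2 || min(table(y)) < 2) {
    abort("Need at least 2 subjects in each class.")
  }
  if (any(!is.finite(x))) abort("Feature matrix must not contain missing values.")
  fit <- fit_irls(x, y, ridge)
  fallback <- FALSE
  if (!fit$converged) {
    fit <- fit_irls(x, y, ridge * 1000)
    fallback <- TRUE
    ridge <- ridge * 1000
  }
  nms <- colnames(x) %||% paste0("x", seq_len(ncol(x)))
  structure(
    list(
      coefficients = setNames(fit$beta, c("(Intercept)", nms)),
      converged = fit$converged,
      ridge_fallback = fallback,
      ridge = ridge,
      n_iter = fit$n_iter,
      deviance = fit$deviance,
      feature_names = nms,
      positive = positive
    ),
    class = "pli_logistic"
  )
}

as_binary <- function(labels, positive) {
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(as.numeric(labels))
  as.numeric(labels == positive)
}

#' @export
predict.pli_logistic <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  eta <- drop(cbind(1, as.matrix(newdata)) %*% object$coefficients)
  if (type == "response") plogis(eta) else eta
}

#' @export
print.pli_logistic <- function(x, ...) {
  cat("<pli_logistic> ridge =", x$ridge,
      if (x$ridge_fallback) "(fallback)", "\n")
  print(round(x$coefficients, 4))
  invisible(x)
}

#' @export
tidy.pli_logistic <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients), estimate = unname(x$coefficients))
}

#' @export
glance.pli_logistic <- function(x, ...) {
  tibble::tibble(
    deviance = x$deviance, n_iter = x$n_iter,
    converged = x$converged, ridge = x$ridge
  )
}

#' ROC curve and AUC by threshold sweep
#'
#' The AUC equals the Mann-Whitney U statistic divided by `n1 * n0`, with
#' tied scores counted 1/2 (computed via mid-ranks); the ROC points come from
#' sweeping the decision threshold over the unique scores.
#'
#' @param scores numeric classifier scores (higher = more positive).
#' @param labels class labels.
#' @param positive positive-class label.
#' @return list with `auc` and `points` (tibble of fpr, tpr, threshold,
#'   monotone non-decreasing in both coordinates).
#' @export
roc_auc <- function(scores, labels, positive = "MCI") {
  y <- as_binary(labels, positive)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) abort("Both classes must be present.")
  r <- rank(scores)  # mid-ranks: ties count 1/2 in the U statistic
  auc <- (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  points <- tibble::tibble(
    threshold = c(Inf, thr),
    tpr = vapply(c(Inf, thr), function(t) sum(scores >= t & y == 1) / n1, 0),
    fpr = vapply(c(Inf, thr), function(t) sum(scores >= t & y == 0) / n0, 0)
  )
  list(auc = auc, points = points)
}

# Stratified fold assignment: within each class, subjects are shuffled and
# dealt round-robin into k folds.
stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  withr::with_seed(as.integer(seed), {
    for (cl in unique(y)) {
      idx <- which(y == cl)
      if (length(idx) < k && length(idx) < 2) abort("Too few subjects for stratified folds.")
      folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
  })
  folds
}

# Internal lean CV: pooled held-out probabilities and accuracy only.
cv_probs <- function(x, y, k, seed, ridge) {
  folds <- stratified_folds(y, k, seed)
  probs <- numeric(length(y))
  for (f in unique(folds)) {
    tr <- folds != f
    if (length(unique(y[tr])) < 2) abort("A training fold lost one class entirely.")
    mu <- colMeans(x[tr, , drop = FALSE])
    sg <- apply(x[tr, , drop = FALSE], 2, sd)
    sg[sg == 0] <- 1
    xtr <- sweep(sweep(x[tr, , drop = FALSE], 2, mu), 2, sg, "/")
    xte <- sweep(sweep(x[!tr, , drop = FALSE], 2, mu), 2, sg, "/")
    fit <- fit_irls(xtr, y[tr], ridge)
    if (!fit$converged) fit <- fit_irls(xtr, y[tr], ridge * 1000)
    probs[!tr] <- plogis(drop(cbind(1, xte) %*% fit$beta))
  }
  list(probs = probs, folds = folds)
}

#' Stratified k-fold cross-validated classification
#'
#' Features are z-scored with training-fold statistics only (no leakage);
#' confusion-matrix metrics (accuracy, sensitivity, specificity, precision,
#' F1, as percentages) are computed from the single confusion matrix pooled
#' over all held-out folds at a 0.5 probability threshold, and the AUC from
#' the pooled held-out probabilities.
#'
#' @param x numeric feature matrix (subjects x features).
#' @param labels two-level labels.
#' @param k number of folds (default 10).
#' @param seed integer seed for the fold shuffle.
#' @param positive positive-class label (default `"MCI"`).
#' @param ridge see [fit_logistic()].
#' @return object of class `classifier_report`.
#' @export
cross_validate <- function(x, labels, k = 10, seed = 1L, positive = "MCI",
                           ridge = 1e-6) {
  x <- as.matrix(x)
  y <- as_binary(labels, positive)
  if (min(table(y)) < 2) abort("Need at least 2 subjects per class.")
  if (any(!is.finite(x))) abort("Feature matrix must not contain missing values.")
  k <- min(k, min(table(y)))
  cv <- cv_probs(x, y, k, seed, ridge)
  pred <- as.numeric(cv$probs > 0.5)

  tp <- sum(pred == 1 & y == 1); tn <- sum(pred == 0 & y == 0)
  fp <- sum(pred == 1 & y == 0); fn <- sum(pred == 0 & y == 1)
  precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  recall <- tp / (tp + fn)
  f1 <- if (!is.na(precision) && precision + recall > 0) {
    2 * precision * recall / (precision + recall)
  } else {
    NA_real_
  }
  roc <- roc_auc(cv$probs, y, positive = 1)

  per_fold <- tibble::tibble(fold = cv$folds, prob = cv$probs, truth = y) |>
    dplyr::group_by(.data$fold) |>
    dplyr::summarise(
      n = dplyr::n(),
      accuracy = 100 * mean((.data$prob > 0.5) == (.data$truth == 1)),
      .groups = "drop"
    )

  structure(
    list(
      metrics = tibble::tibble(
        accuracy = 100 * (tp + tn) / length(y),
        specificity = 100 * tn / (tn + fp),
        sensitivity = 100 * recall,
        precision = 100 * precision,
        f1 = 100 * f1,
        auc = roc$auc
      ),
      confusion = matrix(c(tp, fn, fp, tn), 2, 2,
                         dimnames = list(pred = c("pos", "neg"), truth = c("pos", "neg"))),
      roc_points = roc$points,
      predictions = tibble::tibble(
        fold = cv$folds, prob = cv$probs,
        truth = ifelse(y == 1, positive, paste0("not_", positive))
      ),
      per_fold = per_fold,
      empirical_chance_level = NA_real_,
      n_permutations = NA_integer_,
      k = k,
      seed = as.integer(seed),
      positive = positive
    ),
    class = "classifier_report"
  )
}

#' Permutation-based empirical chance level
#'
#' Repeats the full cross-validated classification with labels permuted
#' uniformly at random and returns the given percentile of the null accuracy
#' distribution. An observed accuracy above the 95th percentile is
#' significant at p < 0.05.
#'
#' @inheritParams cross_validate
#' @param n_permutations number of label permutations (default 5000).
#' @param percentile percentile of the null distribution to report
#'   (default 95).
#' @return list with `chance_level` (percent) and `null_accuracies`.
#' @export
empirical_chance_level <- function(x, labels, n_permutations = 5000,
                                   percentile = 95, k = 10, seed = 1L,
                                   positive = "MCI", ridge = 1e-6) {
  if (n_permutations < 100) abort("`n_permutations` must be >= 100.")
  x <- as.matrix(x)
  y <- as_binary(labels, positive)
  k <- min(k, min(table(y)))
  accs <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_permutations), function(i) {
      yp <- sample(y)
      fold_seed <- sample.int(2147483646L, 1)
      cv <- cv_probs(x, yp, k, fold_seed, ridge)
      100 * mean((cv$probs > 0.5) == (yp == 1))
    }, 0)
  })
  list(
    chance_level = unname(quantile(accs, percentile / 100)),
    null_accuracies = accs
  )
}

#' Evaluate a classifier with its empirical chance level
#'
#' Convenience wrapper: [cross_validate()] plus [empirical_chance_level()]
#' stored in one report.
#'
#' @inheritParams empirical_chance_level
#' @export
evaluate_classifier <- function(x, labels, k = 10, n_permutations = 5000,
                                percentile = 95, seed = 1L, positive = "MCI",
                                ridge = 1e-6) {
  seeds <- derive_seeds(seed, 2)
  rep <- cross_validate(x, labels, k, seeds[1], positive, ridge)
  ecl <- empirical_chance_level(x, labels, n_permutations, percentile, k,
                                seeds[2], positive, ridge)
  rep$empirical_chance_level <- ecl$chance_level
  rep$n_permutations <- as.integer(n_permutations)
  rep$seed <- as.integer(seed)
  rep
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("<classifier_report> %d-fold CV, positive class = %s\n",
              x$k, x$positive))
  m <- x$metrics
  cat(sprintf(
    "  accuracy %.2f%%  specificity %.2f%%  sensitivity %.2f%%  AUC %.3f\n",
    m$accuracy, m$specificity, m$sensitivity, m$auc
  ))
  if (!is.na(x$empirical_chance_level)) {
    cat(sprintf("  empirical chance level (%d permutations): %.2f%%\n",
                x$n_permutations, x$empirical_chance_level))
  }
  invisible(x)
}

#' @export
tidy.classifier_report <- function(x, ...) {
  x$per_fold
}

#' @export
glance.classifier_report <- function(x, ...) {
  dplyr::mutate(
    x$metrics,
    empirical_chance_level = x$empirical_chance_level,
    n_folds = x$k,
    n_permutations = x$n_permutations,
    seed = x$seed
  )
}

#' Build the classifier feature matrix from connectivity results
#'
#' @param conn connectivity tibble from [cohort_connectivity()].
#' @param cohort cohort tibble (for subject order and labels).
#' @param feature_set `"global_pairs8"` (global alpha PLI plus the eight
#'   pairs of [default_alpha_pairs()], when all labels exist),
#'   `"global"` (global alpha PLI only) or `"all_pairs"` (every channel
#'   pair).
#' @param band band to draw features from (default `"alpha"`).
#' @return list with `x` (matrix, rownames = subject ids) and `labels`.
#' @export
pli_features <- function(conn, cohort,
                         feature_set = c("global_pairs8", "global", "all_pairs"),
                         band = "alpha") {
  feature_set <- match.arg(feature_set)
  cb <- dplyr::filter(conn, .data$band == !!band)
  cb <- cb[match(cohort$subject_id, cb$subject_id), ]
  if (any(is.na(cb$subject_id))) abort("Connectivity results missing for some subjects.")
  g <- matrix(cb$global_pli, ncol = 1, dimnames = list(cohort$subject_id, "global_alpha_pli"))
  x <- switch(feature_set,
    global = g,
    global_pairs8 = {
      p8 <- t(vapply(cb$matrix, function(m) {
        e <- extract_pairs(m)
        setNames(e$pli, e$pair)
      }, numeric(8)))
      rownames(p8) <- cohort$subject_id
      cbind(g, p8)
    },
    all_pairs = {
      ap <- t(vapply(cb$matrix, function(m) {
        td <- tidy(m)
        setNames(td$pli, paste0(td$chan_1, "-", td$chan_2))
      }, numeric(choose(length(cb$matrix[[1]]$channel_labels), 2))))
      rownames(ap) <- cohort$subject_id
      ap
    }
  )
  list(x = x, labels = cohort$group)
}
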