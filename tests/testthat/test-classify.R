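# Logistic regression, cross-validation, ROC/AUC, permutation chance level.

test_that("logistic fit recovers the log odds ratio of a binary feature", {
  # cell counts (a, b) for x=1, (c, d) for x=0 -> slope = log(ad / bc)
  a <- 18; b <- 6; c <- 7; d <- 19
  x <- matrix(c(rep(1, a + b), rep(0, c + d)), ncol = 1)
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  fit <- fit_logistic(x, y)
  expect_equal(unname(fit$coefficients[2]), log(a * d / (b * c)), tolerance = 1e-4)
  expect_equal(unname(fit$coefficients[1]), log(c / d), tolerance = 1e-4)
})

test_that("uninformative features give near-zero slopes and the base-rate intercept", {
  withr::with_seed(1, {
    x <- matrix(rnorm(60), ncol = 1)
    y <- rep(c(1, 0), times = c(20, 40))
  })
  fit <- fit_logistic(x, y)
  # intercept-only MLE: log(n1/n0); the weak feature shifts it only slightly
  expect_equal(unname(fit$coefficients[1]), log(20 / 40), tolerance = 0.25)
  expect_lt(abs(fit$coefficients[2]), 0.6)
})

test_that("IRLS agrees with glm on a well-conditioned problem", {
  withr::with_seed(2, {
    x <- matrix(rnorm(200 * 2), ncol = 2)
    p <- plogis(0.5 + x %*% c(1, -0.7))
    y <- rbinom(200, 1, p)
  })
  fit <- fit_logistic(x, y, ridge = 1e-10)
  ref <- stats::glm(y ~ x, family = stats::binomial())
  expect_equal(unname(fit$coefficients), unname(stats::coef(ref)),
               tolerance = 1e-4)
})

test_that("duplicated feature columns do not change the predictions", {
  withr::with_seed(3, {
    x <- matrix(rnorm(80), ncol = 1)
    y <- rbinom(80, 1, plogis(1.2 * x))
  })
  f1 <- fit_logistic(x, y, ridge = 1e-4)
  f2 <- fit_logistic(cbind(x, x), y, ridge = 1e-4)
  expect_equal(predict(f1, x), predict(f2, cbind(x, x)), tolerance = 1e-5)
})

test_that("perfect separation is handled via the ridge penalty", {
  x <- matrix(c(-(10:1), 1:10) / 10, ncol = 1)
  y <- rep(c(0, 1), each = 10)
  fit <- fit_logistic(x, y)
  expect_true(all(is.finite(fit$coefficients)))
  expect_true(all((predict(fit, x) > 0.5) == (y == 1)))
})

test_that("AUC equals the brute-force concordant-pair count, ties at 1/2", {
  pair_count_auc <- function(scores, y) {
    pos <- scores[y == 1]; neg <- scores[y == 0]
    total <- 0
    for (p in pos) for (q in neg) {
      total <- total + (p > q) + 0.5 * (p == q)
    }
    total / (length(pos) * length(neg))
  }
  withr::with_seed(4, {
    for (i in 1:25) {
      n <- sample(6:20, 1)
      y <- c(1, 0, rbinom(n - 2, 1, 0.5))
      scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
      expect_identical(roc_auc(scores, y, positive = 1)$auc,
                       pair_count_auc(scores, y))
    }
  })
  expect_identical(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1), positive = 1)$auc, 1)
  expect_identical(roc_auc(rep(1, 10), rep(c(0, 1), 5), positive = 1)$auc, 0.5)
  expect_error(roc_auc(1:4, rep(1, 4), positive = 1), "Both classes")
})

test_that("AUC agrees with pROC on a random instance", {
  skip_if_not_installed("pROC")
  withr::with_seed(5, {
    y <- rbinom(50, 1, 0.5)
    s <- rnorm(50) + y
  })
  ours <- roc_auc(s, y, positive = 1)$auc
  ref <- as.numeric(suppressMessages(pROC::auc(y, s, direction = "<")))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("ROC points are monotone from (0,0) to (1,1)", {
  withr::with_seed(6, { y <- rbinom(40, 1, 0.5); s <- rnorm(40) + 0.8 * y })
  pts <- roc_auc(s, y, positive = 1)$points
  expect_true(all(diff(pts$fpr) >= 0))
  expect_true(all(diff(pts$tpr) >= 0))
  expect_identical(c(pts$fpr[1], pts$tpr[1]), c(0, 0))
  expect_identical(c(max(pts$fpr), max(pts$tpr)), c(1, 1))
})

test_that("cross-validation is reproducible, stratified, and self-consistent", {
  withr::with_seed(7, {
    x <- matrix(rnorm(60 * 3), ncol = 3)
    labels <- rep(c("MCI", "NC"), each = 30)
    x[labels == "MCI", 1] <- x[labels == "MCI", 1] + 1.5
  })
  r1 <- cross_validate(x, labels, k = 10, seed = 99)
  r2 <- cross_validate(x, labels, k = 10, seed = 99)
  expect_identical(glance(r1), glance(r2))

  # stratification: every fold contains both classes
  folds <- r1$predictions$fold
  per_fold <- table(folds, r1$predictions$truth)
  expect_true(all(per_fold > 0))

  # metric consistency from the pooled confusion matrix
  cm <- r1$confusion
  m <- r1$metrics
  expect_equal(m$accuracy, 100 * (cm[1, 1] + cm[2, 2]) / sum(cm))
  prec <- cm[1, 1] / sum(cm[1, ]); rec <- cm[1, 1] / sum(cm[, 1])
  expect_equal(m$f1, 100 * 2 * prec * rec / (prec + rec))
  expect_true(all(unlist(m[, 1:5]) >= 0 & unlist(m[, 1:5]) <= 100))
})

test_that("a linearly separable feature is classified perfectly", {
  x <- matrix(c(seq(1, 2, length.out = 15), seq(5, 6, length.out = 15)), ncol = 1)
  labels <- rep(c("NC", "MCI"), each = 15)
  rep <- cross_validate(x, labels, k = 5, seed = 1)
  expect_identical(rep$metrics$accuracy, 100)
  expect_identical(rep$metrics$auc, 1)
})

test_that("label-independent features hover at 50% accuracy on average", {
  withr::with_seed(8, {
    accs <- vapply(1:40, function(i) {
      x <- matrix(rnorm(40), ncol = 1)
      labels <- rep(c("MCI", "NC"), each = 20)
      cross_validate(x, labels, k = 5, seed = i)$metrics$accuracy
    }, 0)
  })
  se <- sd(accs) / sqrt(length(accs))
  expect_lt(abs(mean(accs) - 50), 4 * se)
})

test_that("chance level is reproducible and beaten by separable data", {
  x <- matrix(c(seq(1, 2, length.out = 15), seq(5, 6, length.out = 15)), ncol = 1)
  labels <- rep(c("NC", "MCI"), each = 15)
  e1 <- empirical_chance_level(x, labels, n_permutations = 150, seed = 3, k = 5)
  e2 <- empirical_chance_level(x, labels, n_permutations = 150, seed = 3, k = 5)
  expect_identical(e1$chance_level, e2$chance_level)
  expect_length(e1$null_accuracies, 150)
  obs <- cross_validate(x, labels, k = 5, seed = 3)$metrics$accuracy
  expect_gt(obs, e1$chance_level)
  expect_error(empirical_chance_level(x, labels, n_permutations = 50), ">= 100")
})

test_that("evaluate_classifier attaches the chance level to the report", {
  withr::with_seed(9, {
    x <- matrix(rnorm(30), ncol = 1)
    labels <- rep(c("MCI", "NC"), each = 15)
  })
  rep <- evaluate_classifier(x, labels, k = 5, n_permutations = 120, seed = 4)
  g <- glance(rep)
  expect_false(is.na(g$empirical_chance_level))
  expect_identical(g$n_permutations, 120L)
  expect_identical(nrow(tidy(rep)), 5L)
})

test_that("feature construction matches the requested feature set", {
  v <- random_pli_values(62, seed = 10)
  conn <- tibble::tibble(
    subject_id = c("s1", "s2"), band = "alpha",
    matrix = list(fixture_pli_matrix(v, montage_10_20(62)),
                  fixture_pli_matrix(v / 2, montage_10_20(62))),
    global_pli = c(global_pli(v), global_pli(v / 2))
  )
  cohort <- tibble::tibble(subject_id = c("s1", "s2"), group = c("MCI", "NC"))
  fg <- pli_features(conn, cohort, "global")
  expect_identical(dim(fg$x), c(2L, 1L))
  f9 <- pli_features(conn, cohort, "global_pairs8")
  expect_identical(dim(f9$x), c(2L, 9L))
  expect_identical(colnames(f9$x)[1], "global_alpha_pli")
  fa <- pli_features(conn, cohort, "all_pairs")
  expect_identical(dim(fa$x), c(2L, 1891L))
  expect_identical(fg$labels, c("MCI", "NC"))
})
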