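test_that("mean prediction error is the average absolute difference", {
  expect_equal(mpe(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mpe(c(2, 2, 2), c(0, 2, 4)), 4 / 3)
  # the uniform guesser on all-2 labels has expectation 1.2
  expect_equal(mean(random_expected_error(rep(2, 10))), 1.2)
})

test_that("wilcoxon exact p-values match full sign enumeration", {
  # all-positive differences of distinct magnitude: p = 2/2^5
  w <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(w$p_value, 0.0625)
  expect_equal(w$statistic, 15)
  expect_equal(w$method, "exact")
  # identical vectors degenerate to p = 1 with a warning
  expect_warning(w0 <- wilcoxon_signed_rank(1:4, 1:4), "zero")
  expect_equal(w0$p_value, 1)
  # property: exact equals 2^n brute force, including ties and zeros
  set.seed(13)
  for (rep in 1:25) {
    n <- sample(4:12, 1)
    a <- sample(0:4, n, replace = TRUE)
    b <- sample(0:4, n, replace = TRUE)
    if (all(a == b)) next
    expect_equal(
      wilcoxon_signed_rank(a, b)$p_value,
      brute_force_wilcoxon(a - b),
      tolerance = 1e-12
    )
  }
})

test_that("normal approximation tracks the exact test at n = 20", {
  set.seed(17)
  for (rep in 1:10) {
    a <- rnorm(20)
    b <- rnorm(20)
    pe <- wilcoxon_signed_rank(a, b, exact_limit = 25)$p_value
    pa <- wilcoxon_signed_rank(a, b, exact_limit = 5)$p_value
    expect_lt(abs(pa - pe), 0.01)
  }
})

test_that("pratt zero handling keeps zeros in the ranking", {
  a <- c(3, 3, 3, 5, 6)
  b <- c(3, 3, 3, 1, 1)
  wd <- wilcoxon_signed_rank(a, b, zero_method = "drop")
  wp <- wilcoxon_signed_rank(a, b, zero_method = "pratt")
  expect_equal(wd$n, 2)
  expect_equal(wp$n, 2)
  expect_gt(wp$statistic, wd$statistic) # zeros push ranks upward
})

test_that("bonferroni adjustment divides alpha by the comparison count", {
  expect_equal(bonferroni_alpha(0.05, 4), 0.0125)
  expect_equal(bonferroni_alpha(0.05, 1), 0.05)
  expect_equal(bonferroni_alpha(0.01, 5), 0.002)
})

test_that("comparison report flags exactly the sub-threshold p-values", {
  set.seed(23)
  base <- abs(rnorm(40))
  errs <- list(
    ref = base,
    worse = base + rexp(40), # clearly worse
    same = base # p = 1 territory
  )
  suppressWarnings(cmp <- compare_models(errs, reference = "ref"))
  expect_s3_class(cmp, "trust_comparison")
  expect_equal(attr(cmp, "alpha_adj"), 0.05 / 2)
  df <- as.data.frame(cmp)
  expect_equal(df$significant, !is.na(df$p_value) & df$p_value < 0.025)
  expect_true(df$significant[df$model == "worse"])
  expect_false(df$significant[df$model == "same"])
})

test_that("confusion matrix tallies true-by-predicted counts", {
  res <- list(folds = data.frame(truth = c(0, 2, 2, 4), pred = c(0, 2, 4, 2)))
  cm <- confusion_matrix(res)
  expect_equal(dim(cm), c(5, 5))
  expect_equal(sum(cm), 4)
  expect_equal(cm["2", "2"], 1L)
  expect_equal(cm["2", "4"], 1L)
  expect_equal(cm["4", "2"], 1L)
  expect_equal(unname(rowSums(cm)), c(1L, 0L, 2L, 0L, 1L))
  # all-correct -> diagonal
  res <- list(folds = data.frame(truth = 0:4, pred = 0:4))
  expect_equal(confusion_matrix(res), diag(1L, 5),
    ignore_attr = TRUE
  )
})

test_that("the a priori constant is optimal, hence at most the random error", {
  # min over constants <= mean over constants = uniform-guesser error,
  # so the dataset-level a priori model never loses to random guessing
  set.seed(29)
  for (rep in 1:20) {
    y <- sample(0:4, sample(8:40, 1), replace = TRUE)
    g <- apriori_predict(y)
    errs <- sapply(0:4, function(c) mean(abs(y - c)))
    expect_equal(mean(abs(y - g)), min(errs))
    expect_lte(mean(abs(y - g)), mean(random_expected_error(y)))
  }
})

test_that("nested cross-validation respects its contract on a small dataset", {
  d <- generate_dataset(
    generator_config(n_dyads = 6, seed = 41, signal = 1)
  )
  grid <- svm_config(cost = c(2, 8), gamma = 2^c(-5, -3))
  res <- nested_loocv(d, "svm-d", config = grid)
  expect_s3_class(res, "nested_cv_result")
  expect_equal(nrow(res$folds), n_examples(d))
  expect_equal(res$mpe, mean(res$folds$abs_error))
  expect_true(all(res$folds$pred %in% 0:4))
  expect_true(all(res$folds$cost %in% grid$cost))
  expect_true(all(res$folds$gamma %in% grid$gamma))
  # svm-s arm ranks features per fold and runs the same protocol
  res_s <- nested_loocv(d, "svm-s", config = svm_config(cost = 2, gamma = 2^-5), rank_k = 5)
  expect_equal(nrow(res_s$folds), n_examples(d))
  expect_true(all(res_s$folds$abs_error >= 0 & res_s$folds$abs_error <= 4))
})

test_that("altering a held-out label cannot change that fold's trained model", {
  d <- generate_dataset(generator_config(n_dyads = 5, seed = 43))
  fm <- feature_matrix(d, "domain")
  x <- as.matrix(fm[, grep("^x", names(fm))])
  y <- fm$tokens_given
  grid <- svm_config(cost = 2, gamma = 2^-5)
  i <- 3
  f1 <- trustcues:::.outer_fold(x, y, i, grid)
  y2 <- y
  y2[i] <- (y[i] + 2) %% 5 # corrupt only the held-out label
  f2 <- trustcues:::.outer_fold(x, y2, i, grid)
  expect_identical(serialize(f1$model$fit$SV, NULL), serialize(f2$model$fit$SV, NULL))
  expect_identical(f1$model$fit$coefs, f2$model$fit$coefs)
  expect_identical(f1$model$fit$rho, f2$model$fit$rho)
  expect_identical(f1$cost, f2$cost)
  expect_identical(f1$gamma, f2$gamma)
  expect_identical(f1$scaling, f2$scaling)
  expect_identical(f1$pred, f2$pred) # same model, same prediction
})

test_that("ablation with an empty exclusion reproduces the full run exactly", {
  d <- generate_dataset(generator_config(n_dyads = 5, seed = 47))
  grid <- svm_config(cost = 2, gamma = 2^-5)
  ab <- ablate_categories(
    d,
    exclusions = list(full = character(0), duration = "duration"),
    config = grid
  )
  full_run <- nested_loocv(d, "svm-d", config = grid)
  expect_equal(ab$mpe[ab$exclusion == "full"], full_run$mpe)
  expect_equal(ab$n_features, c(42L, 30L)) # duration removes 12 slots
  expect_error(
    ablate_categories(d,
      exclusions = list(all = c("self", "partner", "diff")),
      config = grid
    ),
    "removes all features"
  )
})
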