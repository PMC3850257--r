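#' SVM hyper-parameter grid
#'
#' The cost parameter C trades training error against margin width, and
#' the Gaussian-kernel bandwidth gamma sets the smoothness of the class
#' boundary.  Defaults follow the usual dyadic grid
#' \eqn{C \in \{2^{-5}, 2^{-3}, \dots, 2^{15}\}},
#' \eqn{\gamma \in \{2^{-15}, 2^{-13}, \dots, 2^{3}\}}, which contains
#' the optima typically selected on this problem (C = 8, gamma = 0.031;
#' C = 2, gamma = 0.125).
#'
#' @param cost Positive vector of candidate C values.
#' @param gamma Positive vector of candidate gamma values.
#' @return A list of class `svm_config`.
#' @export
svm_config <- function(cost = 2^seq(-5, 15, by = 2),
                       gamma = 2^seq(-15, 3, by = 2)) {
  stopifnot(length(cost) > 0, length(gamma) > 0, all(cost > 0), all(gamma > 0))
  structure(list(cost = sort(cost), gamma = sort(gamma)), class = "svm_config")
}

#' Scale features to [-1, +1] using training-set bounds
#'
#' Each column is mapped affinely so the training minimum hits -1 and the
#' training maximum +1; constant columns map to 0.  The apply set is
#' transformed with the training map only, so its values may fall outside
#' the bounds -- the held-out example never influences the scaling.
#'
#' @param x_train Numeric training matrix.
#' @param x_apply Optional matrix to transform with the training map.
#' @return List with `train`, `apply` (or `NULL`), and the per-column
#'   `min` and `max` used.
#' @examples
#' scale_features(matrix(c(0, 5, 10), ncol = 1))$train
#' @export
scale_features <- function(x_train, x_apply = NULL) {
  x_train <- as.matrix(x_train)
  lo <- apply(x_train, 2, min)
  hi <- apply(x_train, 2, max)
  map <- function(m) {
    m <- as.matrix(m)
    out <- matrix(0, nrow(m), ncol(m), dimnames = dimnames(m))
    for (j in seq_len(ncol(m))) {
      if (hi[j] > lo[j]) {
        out[, j] <- 2 * (m[, j] - lo[j]) / (hi[j] - lo[j]) - 1
      }
    }
    out
  }
  list(
    train = map(x_train),
    apply = if (is.null(x_apply)) NULL else map(x_apply),
    min = lo, max = hi
  )
}

#' Fit the Gaussian-kernel SVM trust predictor
#'
#' A C-classification SVM with radial kernel over the token-giving
#' classes 0..4, multi-class by one-vs-one voting (the LIBSVM scheme).
#' A single-class training set yields a degenerate model that always
#' predicts that class.  Inputs are expected to be scaled already (see
#' [scale_features()]); no internal rescaling is done.
#'
#' @param x Numeric feature matrix.
#' @param y Integer labels in 0..4.
#' @param cost,gamma SVM hyper-parameters.
#' @return Object of class `trust_svm`.
#' @export
fit_svm <- function(x, y, cost = 1, gamma = 1 / ncol(x)) {
  x <- as.matrix(x)
  y <- as.integer(y)
  stopifnot(all(y %in% 0:4), nrow(x) == length(y))
  if (length(unique(y)) == 1L) {
    return(structure(
      list(constant = y[1], cost = cost, gamma = gamma),
      class = "trust_svm"
    ))
  }
  fit <- e1071::svm(
    x = x, y = factor(y, levels = 0:4), type = "C-classification",
    kernel = "radial", cost = cost, gamma = gamma, scale = FALSE
  )
  structure(list(fit = fit, cost = cost, gamma = gamma), class = "trust_svm")
}

#' @export
predict.trust_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$constant)) {
    return(rep(object$constant, nrow(newdata)))
  }
  as.integer(as.character(stats::predict(object$fit, newdata)))
}

#' @export
print.trust_svm <- function(x, ...) {
  if (!is.null(x$constant)) {
    cat("<trust_svm> degenerate single-class model, predicts", x$constant, "\n")
  } else {
    cat(
      "<trust_svm> radial kernel, cost =", x$cost, ", gamma =", x$gamma,
      ",", nrow(x$fit$SV), "support vectors\n"
    )
  }
  invisible(x)
}

#' A priori (error-minimizing constant) prediction
#'
#' Ignores all features and predicts the single class that minimizes the
#' mean absolute error against the training labels; ties favor the
#' smaller class.  On the study's token distribution this is two tokens.
#'
#' @param train_labels Integer labels in 0..4.
#' @return The minimizing class (integer).
#' @examples
#' apriori_predict(c(2, 2, 2, 4))
#' @export
apriori_predict <- function(train_labels) {
  stopifnot(length(train_labels) > 0, all(train_labels %in% 0:4))
  errs <- vapply(0:4, function(g) mean(abs(train_labels - g)), numeric(1))
  (0:4)[which.min(errs)]
}

#' Expected absolute error of the uniform random guesser
#'
#' The random baseline guesses 0..4 uniformly; its expected absolute
#' error for a true label `y` is `mean(abs(0:4 - y))` (so 1.2 at y = 2
#' and 2.0 at the extremes).  A sampled variant is available for
#' simulation-style use.
#'
#' @param y Integer label(s) in 0..4 (vectorized).
#' @param n_samples If non-`NULL`, draw this many uniform guesses per
#'   label and return the empirical mean error instead of the analytic
#'   expectation.
#' @param seed Optional seed for the sampled variant.
#' @return Numeric expected (or sampled mean) absolute error per label.
#' @examples
#' random_expected_error(2) # 1.2
#' @export
random_expected_error <- function(y, n_samples = NULL, seed = NULL) {
  stopifnot(all(y %in% 0:4))
  if (is.null(n_samples)) {
    return(vapply(y, function(yy) mean(abs(0:4 - yy)), numeric(1)))
  }
  if (!is.null(seed)) set.seed(seed)
  vapply(y, function(yy) {
    mean(abs(sample(0:4, n_samples, replace = TRUE) - yy))
  }, numeric(1))
}

#' Human-baseline prediction errors
#'
#' Each participant predicted how many tokens their partner would give;
#' the absolute discrepancy between that prediction and the partner's
#' actual gift measures how accurately people judge a stranger's
#' trustworthiness.  Participants without a recorded prediction are
#' excluded (their count is attached as attribute `n_missing`).
#'
#' @param dataset A [trust_dataset()].
#' @return Named numeric vector of absolute errors, one per participant
#'   with a prediction; attribute `n_missing` counts exclusions.
#' @export
human_baseline_errors <- function(dataset) {
  oc <- dataset$outcomes
  partner_given <- vapply(seq_len(nrow(oc)), function(i) {
    j <- oc$session_id == oc$session_id[i] &
      oc$participant_id != oc$participant_id[i]
    oc$tokens_given[j]
  }, numeric(1))
  err <- abs(oc$tokens_predicted - partner_given)
  names(err) <- oc$participant_id
  keep <- !is.na(err)
  structure(err[keep], n_missing = sum(!keep))
}
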