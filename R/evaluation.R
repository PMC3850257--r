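#' Mean prediction error
#'
#' The single evaluation metric: the average absolute difference between
#' predicted and true token-giving labels, in tokens (range 0--4).
#'
#' @param preds,truth Equal-length numeric vectors.
#' @return The mean absolute error.
#' @examples
#' mpe(c(2, 2, 2), c(0, 2, 4)) # 4/3
#' @export
mpe <- function(preds, truth) {
  stopifnot(length(preds) == length(truth))
  mean(abs(preds - truth))
}

# one outer fold of the nested protocol: rank (optionally), scale, tune
# (C, gamma) by inner leave-one-out MPE, refit, predict the held-out row.
# The held-out example influences nothing but its own recorded error.
.outer_fold <- function(x, y, i, config, rank_k = NULL) {
  tr <- setdiff(seq_len(nrow(x)), i)
  xtr <- x[tr, , drop = FALSE]
  ytr <- y[tr]
  keep <- seq_len(ncol(x))
  if (!is.null(rank_k)) {
    keep <- selected_features(rank_features(xtr, ytr, k = rank_k))
  }
  sc <- scale_features(xtr[, keep, drop = FALSE], x[i, keep, drop = FALSE])
  xs <- sc$train
  n_tr <- nrow(xs)
  best <- NULL
  # grids ascend, so scanning order implements the smallest-C-then-gamma
  # tie-break (prefer the least over-fitting winner)
  for (cost in config$cost) {
    for (gamma in config$gamma) {
      errs <- numeric(n_tr)
      for (j in seq_len(n_tr)) {
        m <- fit_svm(xs[-j, , drop = FALSE], ytr[-j], cost = cost, gamma = gamma)
        errs[j] <- abs(predict(m, xs[j, , drop = FALSE]) - ytr[j])
      }
      inner <- mean(errs)
      if (is.null(best) || inner < best$inner_mpe - 1e-12) {
        best <- list(cost = cost, gamma = gamma, inner_mpe = inner)
      }
    }
  }
  model <- fit_svm(xs, ytr, cost = best$cost, gamma = best$gamma)
  list(
    pred = predict(model, sc$apply),
    cost = best$cost, gamma = best$gamma, inner_mpe = best$inner_mpe,
    model = model, features = keep, scaling = sc[c("min", "max")]
  )
}

.nested_loocv_xy <- function(x, y, config, rank_k = NULL, arm = "svm-d",
                             progress = FALSE) {
  m <- nrow(x)
  if (m < 3) stop("nested leave-one-out needs at least 3 examples")
  rows <- vector("list", m)
  for (i in seq_len(m)) {
    f <- .outer_fold(x, y, i, config, rank_k = rank_k)
    rows[[i]] <- data.frame(
      fold = i, truth = y[i], pred = f$pred,
      abs_error = abs(f$pred - y[i]), cost = f$cost, gamma = f$gamma
    )
    if (progress && i %% 10 == 0) message("outer fold ", i, "/", m)
  }
  folds <- do.call(rbind, rows)
  structure(
    list(folds = folds, mpe = mean(folds$abs_error), arm = arm, m = m),
    class = "nested_cv_result"
  )
}

#' Nested leave-one-out cross-validation of the SVM trust predictor
#'
#' The outer loop removes one participant at a time for unbiased
#' assessment; with the remainder, the inner loop leave-one-out
#' grid-searches (C, gamma) by inner mean prediction error, the winner is
#' refit on the whole remainder, and the held-out participant is
#' predicted.  Feature scaling, ranking (for the standard-selection arm),
#' and tuning all use the outer-training fold only, so no information
#' leaks from the held-out example.  Ties in the grid search prefer the
#' smallest C, then the smallest gamma.
#'
#' @param dataset A [trust_dataset()].
#' @param arm `"svm-d"` (domain-knowledge features) or `"svm-s"` (naive
#'   features narrowed by per-fold variable ranking).
#' @param config An [svm_config()] grid.
#' @param rank_k Number of top-ranked features kept in the `svm-s` arm.
#' @param include_templates For `svm-d`: include the template slots
#'   x31..x42 (the final 42-feature model) or only x1..x30.
#' @param seed Unused by the deterministic SVM path; accepted for
#'   interface uniformity and set if non-`NULL`.
#' @param progress Emit a message every 10 outer folds.
#' @return An object of class `nested_cv_result`: per-fold predictions,
#'   absolute errors and chosen hyper-parameters (`$folds`), the overall
#'   `$mpe`, and the `$arm`.
#' @export
nested_loocv <- function(dataset, arm = c("svm-d", "svm-s"),
                         config = svm_config(), rank_k = 10,
                         include_templates = TRUE, seed = NULL,
                         progress = FALSE) {
  arm <- match.arg(arm)
  if (!is.null(seed)) set.seed(seed)
  fm <- feature_matrix(
    dataset,
    set = if (arm == "svm-d") "domain" else "naive",
    include_templates = include_templates
  )
  drop_cols <- c("session_id", "participant_id", "tokens_given")
  x <- as.matrix(fm[, setdiff(names(fm), drop_cols), drop = FALSE])
  y <- fm$tokens_given
  res <- .nested_loocv_xy(
    x, y, config,
    rank_k = if (arm == "svm-s") rank_k else NULL,
    arm = arm, progress = progress
  )
  res$participant_id <- fm$participant_id
  res
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(
    "<nested_cv_result> arm =", x$arm, ", m =", x$m,
    ", MPE =", round(x$mpe, 4), "\n"
  )
  hp <- unique(x$folds[, c("cost", "gamma")])
  cat("chosen hyper-parameters across folds:\n")
  print(hp, row.names = FALSE)
  invisible(x)
}

#' Per-fold a priori baseline errors
#'
#' Evaluates the error-minimizing constant predictor under the same
#' leave-one-out protocol as the SVM: for each held-out participant the
#' constant is chosen from the remaining labels only.
#'
#' @param y Integer labels in 0..4.
#' @return Numeric vector of absolute errors, one per example.
#' @export
apriori_loocv_errors <- function(y) {
  vapply(seq_along(y), function(i) {
    abs(apriori_predict(y[-i]) - y[i])
  }, numeric(1))
}

#' Confusion matrix of a cross-validation result
#'
#' @param result A `nested_cv_result` (or any list with a `$folds` data
#'   frame holding `truth` and `pred`).
#' @return A 5x5 integer matrix, rows = true class 0..4, columns =
#'   predicted class; row sums equal the class counts.
#' @export
confusion_matrix <- function(result) {
  f <- result$folds
  tab <- table(
    factor(f$truth, levels = 0:4),
    factor(f$pred, levels = 0:4)
  )
  m <- matrix(as.integer(tab), 5, 5,
    dimnames = list(true = 0:4, predicted = 0:4)
  )
  m
}

#' Wilcoxon signed-rank test on paired prediction errors
#'
#' Two-sided test of whether two models' per-participant absolute errors
#' differ.  Zero differences are dropped by default (their count is
#' reported; the Pratt variant keeps them in the ranking).  For up to
#' `exact_limit` nonzero pairs the p-value is exact, computed from the
#' full distribution of the signed-rank statistic over all sign
#' assignments (midranks make this valid under ties); beyond that a
#' normal approximation with continuity and tie correction is used.
#'
#' @param errors_a,errors_b Equal-length paired error vectors.
#' @param zero_method `"drop"` (classic) or `"pratt"`.
#' @param exact_limit Largest number of nonzero pairs for the exact
#'   distribution.
#' @return List of class `wilcoxon_signed_rank`: `statistic` (W+, the sum
#'   of ranks of positive differences), `p_value`, `n` (nonzero pairs),
#'   `n_zero`, and `method`.
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))$p_value # 0.0625
#' @export
wilcoxon_signed_rank <- function(errors_a, errors_b,
                                 zero_method = c("drop", "pratt"),
                                 exact_limit = 25) {
  stopifnot(length(errors_a) == length(errors_b))
  zero_method <- match.arg(zero_method)
  d <- errors_a - errors_b
  n_zero <- sum(d == 0)
  if (zero_method == "drop") {
    dnz <- d[d != 0]
    r <- rank(abs(dnz))
  } else {
    r_all <- rank(abs(d))
    dnz <- d[d != 0]
    r <- r_all[d != 0]
  }
  n <- length(dnz)
  if (n == 0) {
    warning("all paired differences are zero; p = 1")
    return(structure(
      list(statistic = 0, p_value = 1, n = 0, n_zero = n_zero,
           method = "degenerate"),
      class = "wilcoxon_signed_rank"
    ))
  }
  w <- sum(r[dnz > 0])
  if (n <= exact_limit) {
    # exact null distribution of 2*W via subset-sum convolution over the
    # doubled (integer) midranks
    r2 <- as.integer(round(2 * r))
    total <- sum(r2)
    f <- numeric(total + 1)
    f[1] <- 1
    for (ri in r2) {
      g <- f
      g[(ri + 1):(total + 1)] <- g[(ri + 1):(total + 1)] + f[1:(total + 1 - ri)]
      f <- g
    }
    f <- f / 2^n
    w2 <- as.integer(round(2 * w))
    p_le <- sum(f[1:(w2 + 1)])
    p_ge <- sum(f[(w2 + 1):(total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    method <- "exact"
  } else {
    mu <- sum(r) / 2
    sigma <- sqrt(sum(r^2) / 4)
    z <- (w - mu - 0.5 * sign(w - mu)) / sigma
    p <- 2 * stats::pnorm(-abs(z))
    method <- "normal approximation"
  }
  structure(
    list(statistic = w, p_value = p, n = n, n_zero = n_zero, method = method),
    class = "wilcoxon_signed_rank"
  )
}

#' @export
print.wilcoxon_signed_rank <- function(x, ...) {
  cat(
    "Wilcoxon signed-rank (", x$method, "): W+ =", x$statistic,
    ", n =", x$n, "(", x$n_zero, "zeros ),",
    "p =", signif(x$p_value, 4), "\n"
  )
  invisible(x)
}

#' Bonferroni-adjusted significance level
#'
#' @param alpha Family-wise significance level.
#' @param n_comparisons Number of pairwise comparisons.
#' @return `alpha / n_comparisons` (0.05 over 4 comparisons gives 0.0125).
#' @examples
#' bonferroni_alpha(0.05, 4)
#' @export
bonferroni_alpha <- function(alpha, n_comparisons) {
  stopifnot(alpha > 0, n_comparisons >= 1)
  alpha / n_comparisons
}

#' Compare models on paired per-participant errors
#'
#' Builds the standard comparison table: each model's mean prediction
#' error, and a Wilcoxon signed-rank test of the reference model against
#' every other, flagged at the Bonferroni-adjusted level.
#'
#' @param errors Named list of equal-length paired absolute-error
#'   vectors, one per model.
#' @param reference Name of the reference model (default: first).
#' @param alpha Family-wise significance level before adjustment.
#' @param ... Passed to [wilcoxon_signed_rank()].
#' @return Object of class `trust_comparison`: a data frame with columns
#'   `model`, `mpe`, `p_value`, `significant`, plus attributes
#'   `alpha_adj` and `reference`.
#' @export
compare_models <- function(errors, reference = names(errors)[1],
                           alpha = 0.05, ...) {
  stopifnot(is.list(errors), !is.null(names(errors)), reference %in% names(errors))
  lens <- lengths(errors)
  stopifnot(length(unique(lens)) == 1)
  others <- setdiff(names(errors), reference)
  alpha_adj <- bonferroni_alpha(alpha, max(1, length(others)))
  rows <- data.frame(
    model = c(reference, others),
    mpe = vapply(errors[c(reference, others)], mean, numeric(1)),
    p_value = c(NA_real_, vapply(others, function(mn) {
      wilcoxon_signed_rank(errors[[reference]], errors[[mn]], ...)$p_value
    }, numeric(1))),
    stringsAsFactors = FALSE
  )
  rows$significant <- !is.na(rows$p_value) & rows$p_value < alpha_adj
  ord <- c(1, 1 + order(rows$mpe[-1]))
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  structure(rows,
    class = c("trust_comparison", "data.frame"),
    alpha_adj = alpha_adj, reference = reference
  )
}

#' @export
print.trust_comparison <- function(x, ...) {
  cat(
    "Model comparison (reference:", attr(x, "reference"),
    "; adjusted alpha =", attr(x, "alpha_adj"), ")\n"
  )
  df <- as.data.frame(x)
  df$mpe <- round(df$mpe, 3)
  df$p_value <- signif(df$p_value, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

# expand exclusion tokens ("self:duration", "duration", "partner") into slots
.exclusion_slots <- function(tokens) {
  whos <- c("self", "partner", "diff")
  types <- c("frequency", "duration", "joint", "template")
  slots <- integer(0)
  for (tok in tokens) {
    if (grepl(":", tok, fixed = TRUE)) {
      parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
      slots <- c(slots, feature_slots(who = parts[1], type = parts[2]))
    } else if (tok %in% types) {
      slots <- c(slots, feature_slots(type = tok))
    } else if (tok %in% whos) {
      slots <- c(slots, feature_slots(who = tok))
    } else {
      stop("unknown exclusion token: ", tok)
    }
  }
  sort(unique(slots))
}

#' Feature-category ablation
#'
#' Re-runs the nested cross-validation of the full 42-feature domain
#' model with chosen feature categories removed, to measure each
#' category's contribution to performance.  Exclusions are described by
#' tokens combining a role (`self`, `partner`, `diff`) and/or a type
#' (`frequency`, `duration`, `joint`, `template`), e.g. `"duration"`
#' removes x5..x8, x15..x18 and x25..x28, while `"partner:frequency"`
#' removes x11..x14.  An empty exclusion reproduces the full-model run
#' exactly.
#'
#' @param dataset A [trust_dataset()].
#' @param exclusions Named list of character vectors of tokens; an
#'   unnamed entry `character(0)` denotes the full model.
#' @param config An [svm_config()].
#' @param seed Optional seed (the SVM path is deterministic).
#' @return A data frame with one row per exclusion set: `exclusion`,
#'   `n_features`, `mpe`; attribute `results` keeps the full
#'   `nested_cv_result` objects.
#' @export
ablate_categories <- function(dataset,
                              exclusions = list(
                                full = character(0),
                                duration = "duration",
                                frequency = "frequency",
                                joint = "joint",
                                template = "template",
                                partner = "partner",
                                self = "self"
                              ),
                              config = svm_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fm <- feature_matrix(dataset, set = "domain", include_templates = TRUE)
  drop_cols <- c("session_id", "participant_id", "tokens_given")
  x_full <- as.matrix(fm[, setdiff(names(fm), drop_cols), drop = FALSE])
  y <- fm$tokens_given
  if (is.null(names(exclusions))) names(exclusions) <- seq_along(exclusions)
  results <- list()
  rows <- list()
  for (nm in names(exclusions)) {
    drop <- .exclusion_slots(exclusions[[nm]])
    keep <- setdiff(seq_len(ncol(x_full)), drop)
    if (length(keep) == 0) stop("exclusion '", nm, "' removes all features")
    res <- .nested_loocv_xy(
      x_full[, keep, drop = FALSE], y, config,
      arm = paste0("svm-d/", nm)
    )
    results[[nm]] <- res
    rows[[nm]] <- data.frame(
      exclusion = nm, n_features = length(keep), mpe = res$mpe,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "results") <- results
  out
}
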