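#' Variable-ranking feature selection
#'
#' Scores each feature by the absolute value of its Pearson correlation
#' with the number of tokens given and ranks features by decreasing
#' score.  Constant (zero-variance) features are uninformative by
#' construction and receive score 0; ties are broken by feature index so
#' the ordering is deterministic.  Within the nested cross-validation
#' protocol the ranking is computed on the outer-training fold only,
#' before the inner tuning loop, so the held-out example never influences
#' the selection.
#'
#' @param x Numeric feature matrix (or data frame), one row per example.
#' @param y Numeric labels (tokens given).
#' @param k Number of features to retain (capped at the total).
#' @return An object of class `ranked_features`: list with `ranking`
#'   (feature indices, best first), `scores` (absolute correlations in
#'   ranking order), `k`, and `names`.
#' @examples
#' x <- cbind(a = c(1, 2, 3, 4), b = c(4, 4, 4, 4))
#' rank_features(x, c(0, 1, 2, 4), k = 1)
#' @export
rank_features <- function(x, y, k = 10) {
  x <- as.matrix(x)
  if (nrow(x) < 3) stop("need at least 3 examples to rank features")
  if (length(unique(y)) < 2) stop("need at least 2 distinct label values")
  sdx <- apply(x, 2, stats::sd)
  scores <- rep(0, ncol(x))
  ok <- sdx > 0
  if (any(ok)) {
    scores[ok] <- abs(suppressWarnings(stats::cor(x[, ok, drop = FALSE], y)))
  }
  scores[is.na(scores)] <- 0
  ord <- order(-scores, seq_along(scores))
  k <- min(as.integer(k), ncol(x))
  structure(
    list(
      ranking = ord, scores = scores[ord], k = k,
      names = colnames(x)[ord]
    ),
    class = "ranked_features"
  )
}

#' @export
print.ranked_features <- function(x, ...) {
  cat("<ranked_features> top", x$k, "of", length(x$ranking), "features\n")
  top <- seq_len(min(x$k, length(x$ranking)))
  nm <- if (is.null(x$names)) x$ranking else x$names
  print(stats::setNames(round(x$scores[top], 4), nm[top]))
  invisible(x)
}

#' Retained feature indices
#'
#' @param ranked A [rank_features()] result.
#' @return The indices of the top `k` features.
#' @export
selected_features <- function(ranked) {
  stopifnot(inherits(ranked, "ranked_features"))
  ranked$ranking[seq_len(ranked$k)]
}
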