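#' Discrete-observation hidden Markov model
#'
#' A discrete HMM over the eight trust-related cues: initial-state
#' probabilities `pi` = P(s0), a state-transition matrix `A` =
#' P(s_t | s_{t-1}), and an emission matrix `B` = P(o_t | s_t) over the
#' symbol alphabet.  Rows must sum to one within 1e-9.
#'
#' @param pi Numeric vector of initial-state probabilities.
#' @param A Square transition matrix, rows summing to 1.
#' @param B Emission matrix, `n_states` rows by `length(alphabet)`
#'   columns, rows summing to 1.
#' @param alphabet Character vector of observation symbols (default the
#'   eight-cue trust alphabet).
#' @return Object of class `discrete_hmm`.
#' @examples
#' h <- discrete_hmm(
#'   pi = c(1, 0), A = matrix(c(.9, .1, .2, .8), 2, byrow = TRUE),
#'   B = matrix(rep(1 / 8, 16), 2)
#' )
#' forward_loglik(h, c("smiling", "arms crossed"))
#' @export
discrete_hmm <- function(pi, A, B, alphabet = trust_cue_alphabet()) {
  A <- as.matrix(A)
  B <- as.matrix(B)
  n <- length(pi)
  stopifnot(
    nrow(A) == n, ncol(A) == n, nrow(B) == n,
    ncol(B) == length(alphabet)
  )
  if (abs(sum(pi) - 1) > 1e-9 || any(abs(rowSums(A) - 1) > 1e-9) ||
    any(abs(rowSums(B) - 1) > 1e-9)) {
    stop("pi and all rows of A and B must sum to 1 (tolerance 1e-9)")
  }
  if (any(pi < 0) || any(A < 0) || any(B < 0)) stop("negative probabilities")
  structure(
    list(pi = as.numeric(pi), A = A, B = B, alphabet = alphabet,
         n_states = n),
    class = "discrete_hmm"
  )
}

#' @export
print.discrete_hmm <- function(x, ...) {
  cat(
    "<discrete_hmm>", x$n_states, "states over",
    length(x$alphabet), "symbols\n"
  )
  invisible(x)
}

.obs_index <- function(hmm, seq) {
  if (inherits(seq, "sign_sequence")) seq <- seq$symbols
  obs <- match(seq, hmm$alphabet)
  if (anyNA(obs)) {
    stop("symbol(s) outside the model alphabet: ",
         paste(unique(seq[is.na(obs)]), collapse = ", "))
  }
  obs
}

#' Forward-algorithm log-likelihood
#'
#' Computes log P(sequence | model) by the scaled forward recursion, so
#' long sequences do not underflow.  The empty sequence has probability
#' one (log-likelihood 0).
#'
#' @param hmm A [discrete_hmm()].
#' @param seq Character vector of symbols (or a `sign_sequence`).
#' @return The log-likelihood (a non-positive number).
#' @export
forward_loglik <- function(hmm, seq) {
  obs <- .obs_index(hmm, seq)
  n_t <- length(obs)
  if (n_t == 0) return(0)
  alpha <- hmm$pi * hmm$B[, obs[1]]
  ll <- 0
  for (t in seq_len(n_t)[-1]) {
    ct <- sum(alpha)
    if (ct == 0) return(-Inf)
    ll <- ll + log(ct)
    alpha <- as.numeric(crossprod(alpha / ct, hmm$A)) * hmm$B[, obs[t]]
  }
  ct <- sum(alpha)
  if (ct == 0) return(-Inf)
  ll + log(ct)
}

# scaled forward-backward for one sequence; returns sufficient statistics
.fb_stats <- function(hmm, obs) {
  n <- hmm$n_states
  n_t <- length(obs)
  alpha <- matrix(0, n, n_t)
  beta <- matrix(0, n, n_t)
  cs <- numeric(n_t)
  a <- hmm$pi * hmm$B[, obs[1]]
  cs[1] <- sum(a)
  alpha[, 1] <- a / cs[1]
  if (n_t > 1) {
    for (t in 2:n_t) {
      a <- as.numeric(crossprod(alpha[, t - 1], hmm$A)) * hmm$B[, obs[t]]
      cs[t] <- sum(a)
      alpha[, t] <- a / cs[t]
    }
  }
  beta[, n_t] <- 1
  if (n_t > 1) {
    for (t in (n_t - 1):1) {
      beta[, t] <- hmm$A %*% (hmm$B[, obs[t + 1]] * beta[, t + 1]) / cs[t + 1]
    }
  }
  gam <- alpha * beta
  gam <- sweep(gam, 2, colSums(gam), "/")
  xi_sum <- matrix(0, n, n)
  if (n_t > 1) {
    for (t in 1:(n_t - 1)) {
      xi <- (alpha[, t] %o% (hmm$B[, obs[t + 1]] * beta[, t + 1])) * hmm$A /
        cs[t + 1]
      xi_sum <- xi_sum + xi / sum(xi)
    }
  }
  b_num <- matrix(0, n, ncol(hmm$B))
  for (t in seq_len(n_t)) b_num[, obs[t]] <- b_num[, obs[t]] + gam[, t]
  list(
    loglik = sum(log(cs)), gamma1 = gam[, 1], xi_sum = xi_sum, b_num = b_num,
    gamma_sum = rowSums(gam),
    gamma_sum_trans = if (n_t > 1) rowSums(gam[, 1:(n_t - 1), drop = FALSE]) else numeric(n)
  )
}

.random_hmm <- function(n_states, alphabet) {
  norm <- function(v) v / sum(v)
  pi <- norm(stats::runif(n_states, 0.1, 1))
  A <- t(apply(matrix(stats::runif(n_states^2, 0.1, 1), n_states), 1, norm))
  B <- t(apply(
    matrix(stats::runif(n_states * length(alphabet), 0.1, 1), n_states), 1, norm
  ))
  if (n_states == 1) {
    A <- matrix(1, 1, 1)
    B <- matrix(norm(stats::runif(length(alphabet), 0.1, 1)), 1)
  }
  discrete_hmm(pi, A, B, alphabet)
}

# raise entries to the floor and renormalize the remaining mass over the
# unfloored entries, so the floor holds exactly after normalization
.floor_renorm <- function(m, floor) {
  fix_row <- function(v) {
    v <- v / sum(v)
    low <- v < floor
    if (!any(low)) return(v)
    if (all(low)) return(rep(1 / length(v), length(v)))
    v[low] <- floor
    v[!low] <- v[!low] * (1 - floor * sum(low)) / sum(v[!low])
    v
  }
  if (is.matrix(m)) t(apply(m, 1, fix_row)) else fix_row(m)
}

#' Baum-Welch (EM) training of a discrete HMM
#'
#' Fits initial, transition, and emission probabilities to a collection
#' of observation sequences by expectation maximization, summing expected
#' sufficient statistics across sequences.  The total log-likelihood is
#' non-decreasing across iterations; training stops when its relative
#' improvement drops below `tol` or after `max_iter` iterations.  A small
#' probability floor is applied to every parameter after each M-step (and
#' renormalized) so unseen symbols cannot drive held-out log-likelihoods
#' to minus infinity.
#'
#' @param sequences List of character vectors of symbols (empty sequences
#'   are dropped; at least one non-empty sequence is required).
#' @param n_states Number of hidden states.
#' @param seed Optional seed for the random initialization.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @param floor Probability floor.
#' @param alphabet Observation alphabet.
#' @param init Optional `discrete_hmm` to initialize from (overrides the
#'   random initialization).
#' @return A `discrete_hmm` with attributes `loglik` (final total
#'   log-likelihood), `loglik_trace`, `iterations`, and `converged`.
#' @export
baum_welch <- function(sequences, n_states, seed = NULL, tol = 1e-4,
                       max_iter = 500, floor = 1e-6,
                       alphabet = trust_cue_alphabet(), init = NULL) {
  if (!is.list(sequences)) sequences <- list(sequences)
  sequences <- Filter(length, sequences)
  if (length(sequences) == 0) stop("all sequences are empty")
  if (!is.null(seed)) set.seed(seed)
  hmm <- if (is.null(init)) .random_hmm(n_states, alphabet) else init
  stopifnot(hmm$n_states == n_states)
  obs_list <- lapply(sequences, function(s) .obs_index(hmm, s))
  trace <- numeric(0)
  prev <- -Inf
  converged <- FALSE
  iter <- 0
  while (iter < max_iter) {
    iter <- iter + 1
    stats_all <- lapply(obs_list, function(o) .fb_stats(hmm, o))
    ll <- sum(vapply(stats_all, `[[`, numeric(1), "loglik"))
    trace <- c(trace, ll)
    pi_new <- Reduce(`+`, lapply(stats_all, `[[`, "gamma1"))
    a_num <- Reduce(`+`, lapply(stats_all, `[[`, "xi_sum"))
    b_num <- Reduce(`+`, lapply(stats_all, `[[`, "b_num"))
    pi_new <- .floor_renorm(pi_new / length(obs_list), floor)
    a_den <- rowSums(a_num)
    a_new <- hmm$A
    ok <- a_den > 0
    if (any(ok)) a_new[ok, ] <- a_num[ok, , drop = FALSE] / a_den[ok]
    a_new <- .floor_renorm(a_new, floor)
    b_den <- rowSums(b_num)
    b_new <- hmm$B
    ok <- b_den > 0
    if (any(ok)) b_new[ok, ] <- b_num[ok, , drop = FALSE] / b_den[ok]
    b_new <- .floor_renorm(b_new, floor)
    hmm <- discrete_hmm(pi_new, a_new, b_new, alphabet)
    if (is.finite(prev) && abs(ll - prev) < tol * (abs(prev) + 1e-10)) {
      converged <- TRUE
      break
    }
    prev <- ll
  }
  attr(hmm, "loglik") <- trace[length(trace)]
  attr(hmm, "loglik_trace") <- trace
  attr(hmm, "iterations") <- iter
  attr(hmm, "converged") <- converged
  hmm
}

#' Simulate an observation sequence from a trained HMM
#'
#' Draws a state path from the initial and transition distributions, then
#' an observation from each visited state's emission distribution.
#'
#' @param object A [discrete_hmm()].
#' @param nsim Sequence length.
#' @param seed Optional seed.
#' @param ... Unused.
#' @return Character vector of `nsim` symbols.
#' @export
simulate.discrete_hmm <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  if (nsim == 0) return(character(0))
  states <- integer(nsim)
  states[1] <- sample.int(object$n_states, 1, prob = object$pi)
  if (nsim > 1) {
    for (t in 2:nsim) {
      states[t] <- sample.int(object$n_states, 1,
        prob = object$A[states[t - 1], ]
      )
    }
  }
  vapply(states, function(s) {
    object$alphabet[sample.int(ncol(object$B), 1, prob = object$B[s, ])]
  }, character(1))
}

#' Classify a cue sequence as low or high trust
#'
#' Scores the sequence under both class-conditional models and returns
#' the class whose model assigns the higher log-likelihood; ties
#' (including the empty sequence) go to `"low"`, the majority class.
#'
#' @param pair An `hmm_pair` from [select_hmm_pair()], or any list with
#'   elements `hmm_low` and `hmm_high`.
#' @param seq Character vector of symbols (or `sign_sequence`).
#' @return `"low"` or `"high"`.
#' @export
classify_sequence <- function(pair, seq) {
  ll_low <- forward_loglik(pair$hmm_low, seq)
  ll_high <- forward_loglik(pair$hmm_high, seq)
  if (ll_high > ll_low) "high" else "low"
}

#' Train and select class-conditional HMMs by leave-one-out accuracy
#'
#' Trains one HMM on the cue sequences of participants who gave
#' `low_label` tokens (the modal, lower-trust group) and another on those
#' who gave `high_label`, over `n_runs` random configurations: each run
#' draws the state counts uniformly from `state_range` and fresh random
#' initial parameters.  A run's quality is its leave-one-out
#' classification accuracy -- each participant's sequence is removed from
#' its class's training set, the class models are retrained, and the
#' held-out sequence is classified by [classify_sequence()].  The best
#' run's configuration is refit on all data and returned.  Participants
#' with empty trust-cue sequences are excluded from training and counted.
#'
#' @param dataset A [trust_dataset()].
#' @param n_runs Number of random configurations.
#' @param state_range Candidate numbers of hidden states.
#' @param seed Optional seed for the whole search.
#' @param low_label,high_label Token counts defining the two classes.
#' @param tol,max_iter,floor Passed to [baum_welch()].
#' @param verbose Report per-run accuracy.
#' @return Object of class `hmm_pair`: `hmm_low`, `hmm_high`, `accuracy`,
#'   `hits`, `misses`, `majority_rate`, `n_states` (named vector),
#'   `n_low`, `n_high`, `n_empty`.
#' @export
select_hmm_pair <- function(dataset, n_runs = 100, state_range = 2:8,
                            seed = NULL, low_label = 2, high_label = 4,
                            tol = 1e-4, max_iter = 500, floor = 1e-6,
                            verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  oc <- dataset$outcomes
  seqs <- list()
  labels <- character(0)
  n_empty <- 0
  for (i in seq_len(nrow(oc))) {
    y <- oc$tokens_given[i]
    if (!(y %in% c(low_label, high_label))) next
    rec <- participant_record(dataset, oc$participant_id[i], oc$session_id[i])
    s <- extract_sign_sequence(rec)$symbols
    if (length(s) == 0) {
      n_empty <- n_empty + 1
      next
    }
    seqs[[length(seqs) + 1]] <- s
    labels <- c(labels, if (y == low_label) "low" else "high")
  }
  n_low <- sum(labels == "low")
  n_high <- sum(labels == "high")
  if (n_low < 2 || n_high < 2) {
    stop("each class needs at least 2 usable (non-empty) sequences")
  }
  m <- length(seqs)
  best <- NULL
  for (run in seq_len(n_runs)) {
    ns_low <- if (length(state_range) == 1) state_range else sample(state_range, 1)
    ns_high <- if (length(state_range) == 1) state_range else sample(state_range, 1)
    init_low <- .random_hmm(ns_low, trust_cue_alphabet())
    init_high <- .random_hmm(ns_high, trust_cue_alphabet())
    train <- function(idx, init) {
      baum_welch(seqs[idx],
        n_states = init$n_states, tol = tol,
        max_iter = max_iter, floor = floor, init = init
      )
    }
    # models trained on a full class serve every fold that holds out a
    # member of the *other* class
    full_low <- train(which(labels == "low"), init_low)
    full_high <- train(which(labels == "high"), init_high)
    hits <- 0
    for (i in seq_len(m)) {
      if (labels[i] == "low") {
        pair_i <- list(
          hmm_low = train(setdiff(which(labels == "low"), i), init_low),
          hmm_high = full_high
        )
      } else {
        pair_i <- list(
          hmm_low = full_low,
          hmm_high = train(setdiff(which(labels == "high"), i), init_high)
        )
      }
      if (classify_sequence(pair_i, seqs[[i]]) == labels[i]) hits <- hits + 1
    }
    acc <- hits / m
    if (verbose) {
      message(
        "run ", run, ": states (", ns_low, ",", ns_high, ") accuracy ",
        round(acc, 3)
      )
    }
    if (is.null(best) || acc > best$accuracy) {
      best <- list(
        accuracy = acc, hits = hits,
        hmm_low = full_low, hmm_high = full_high,
        n_states = c(low = ns_low, high = ns_high)
      )
    }
  }
  structure(
    list(
      hmm_low = best$hmm_low, hmm_high = best$hmm_high,
      accuracy = best$accuracy, hits = best$hits, misses = m - best$hits,
      majority_rate = max(n_low, n_high) / m,
      n_states = best$n_states, n_low = n_low, n_high = n_high,
      n_empty = n_empty
    ),
    class = "hmm_pair"
  )
}

#' @export
print.hmm_pair <- function(x, ...) {
  cat(
    "<hmm_pair> states (low, high) = (", x$n_states["low"], ",",
    x$n_states["high"], "); LOOCV accuracy ", round(100 * x$accuracy),
    "% (", x$hits, " hits, ", x$misses, " misses) vs majority ",
    round(100 * x$majority_rate), "%\n",
    sep = ""
  )
  invisible(x)
}

#' Simulate both class models and sign their outputs
#'
#' Draws one observation sequence from each of the low- and high-trust
#' models and maps the cues to +/- signs, supporting qualitative
#' inspection of the temporal patterns each model has learned (e.g. the
#' longer runs of consecutive low-trust cues typical of the low model).
#'
#' @param pair An `hmm_pair`.
#' @param length Sequence length to simulate.
#' @param seed Optional seed.
#' @return List of two `sign_sequence` objects, `low` and `high`.
#' @export
simulate_and_sign <- function(pair, length = 20, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  mk <- function(hmm) {
    sym <- simulate.discrete_hmm(hmm, nsim = length)
    structure(list(symbols = sym, signs = cue_signs(sym)),
      class = "sign_sequence"
    )
  }
  list(low = mk(pair$hmm_low), high = mk(pair$hmm_high))
}

#' Serialize an HMM to/from JSON
#'
#' @param hmm A [discrete_hmm()].
#' @param path JSON file path.
#' @return `write_hmm()` returns `path` invisibly; `read_hmm()` returns
#'   the reconstructed `discrete_hmm`.
#' @export
write_hmm <- function(hmm, path) {
  jsonlite::write_json(
    list(
      pi = hmm$pi, A = hmm$A, B = hmm$B, alphabet = hmm$alphabet,
      format_version = 1L
    ),
    path,
    digits = NA, auto_unbox = TRUE
  )
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  discrete_hmm(obj$pi, obj$A, obj$B, alphabet = obj$alphabet)
}
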