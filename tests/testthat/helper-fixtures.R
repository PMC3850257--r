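# hand-built fixtures used across test files

# one dyad with known, hand-enumerable cue intervals
make_toy_session_frames <- function() {
  iv <- rbind(
    # participant a: 2 face touching, 1 arms crossed, 1 smiling
    data.frame(
      session_id = "s1", participant_id = "a",
      category = c("touch", "touch", "arms", "mouth"),
      cue = c("face touching", "face touching", "arms crossed", "smiling"),
      start_s = c(10, 40, 0, 100), stop_s = c(20, 45, 30, 115)
    ),
    # participant b: 1 leaning backward, 1 hand touching, 2 smiling
    data.frame(
      session_id = "s1", participant_id = "b",
      category = c("lean", "touch", "mouth", "mouth"),
      cue = c("leaning backward", "hand touching", "smiling", "smiling"),
      start_s = c(5, 50, 60, 90), stop_s = c(35, 55, 70, 95)
    )
  )
  oc <- data.frame(
    session_id = "s1", participant_id = c("a", "b"),
    tokens_given = c(2L, 4L), tokens_predicted = c(3L, 2L)
  )
  list(intervals = iv, outcomes = oc)
}

make_toy_dataset <- function() {
  f <- make_toy_session_frames()
  trust_dataset(f$intervals, f$outcomes, duration_s = 300)
}

# dataset whose two members of each session mirror each other exactly
make_mirrored_dataset <- function() {
  f <- make_toy_session_frames()
  iv_a <- f$intervals[f$intervals$participant_id == "a", ]
  iv_b <- iv_a
  iv_b$participant_id <- "b"
  trust_dataset(rbind(iv_a, iv_b), f$outcomes, duration_s = 300)
}

# build a participant record directly from a cue sequence with unit spacing
record_from_cues <- function(cues, gap = 10, dur = 5, duration_s = 300) {
  voc <- cue_vocabulary()
  starts <- seq(0, by = gap, length.out = length(cues))
  iv <- data.frame(
    session_id = "s", participant_id = "p",
    category = voc$category[match(cues, voc$cue)],
    cue = cues, start_s = starts, stop_s = starts + dur
  )
  list(
    session_id = "s", participant_id = "p", partner_id = "q",
    duration_s = duration_s, intervals = iv,
    tokens_given = 2L, tokens_predicted = NA_integer_
  )
}

# independent brute-force window enumeration (oracle for template counts)
brute_count_templates <- function(signs, patterns) {
  counts <- stats::setNames(integer(length(patterns)), patterns)
  if (length(signs) >= 3) {
    for (i in 1:(length(signs) - 2)) {
      w <- paste(signs[i:(i + 2)], collapse = "")
      if (w %in% patterns) counts[w] <- counts[w] + 1L
    }
  }
  counts
}

# brute-force HMM likelihood by summing over all state paths
brute_force_loglik <- function(hmm, symbols) {
  obs <- match(symbols, hmm$alphabet)
  n_t <- length(obs)
  if (n_t == 0) return(0)
  n <- hmm$n_states
  paths <- expand.grid(rep(list(seq_len(n)), n_t))
  total <- 0
  for (r in seq_len(nrow(paths))) {
    s <- as.integer(paths[r, ])
    p <- hmm$pi[s[1]] * hmm$B[s[1], obs[1]]
    if (n_t > 1) {
      for (t in 2:n_t) {
        p <- p * hmm$A[s[t - 1], s[t]] * hmm$B[s[t], obs[t]]
      }
    }
    total <- total + p
  }
  log(total)
}

# brute-force exact two-sided Wilcoxon signed-rank p over all 2^n signs
brute_force_wilcoxon <- function(d) {
  dnz <- d[d != 0]
  n <- length(dnz)
  r <- rank(abs(dnz))
  w_obs <- sum(r[dnz > 0])
  ws <- vapply(0:(2^n - 1), function(mask) {
    sel <- as.logical(bitwAnd(mask, 2^(0:(n - 1))))
    sum(r[sel])
  }, numeric(1))
  p_le <- mean(ws <= w_obs + 1e-9)
  p_ge <- mean(ws >= w_obs - 1e-9)
  min(1, 2 * min(p_le, p_ge))
}

# tiny deterministic random hmm helper
random_test_hmm <- function(n_states, alphabet = trust_cue_alphabet()) {
  norm <- function(v) v / sum(v)
  pi <- norm(runif(n_states, 0.05, 1))
  A <- t(apply(matrix(runif(n_states^2, 0.05, 1), n_states), 1, norm))
  B <- t(apply(matrix(runif(n_states * length(alphabet), 0.05, 1), n_states),
    1, norm
  ))
  if (n_states == 1) {
    A <- matrix(1, 1, 1)
    B <- matrix(norm(runif(length(alphabet), 0.05, 1)), 1)
  }
  discrete_hmm(pi, A, B, alphabet)
}
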