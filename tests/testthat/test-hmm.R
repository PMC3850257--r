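test_that("hmm construction enforces stochasticity", {
  expect_error(
    discrete_hmm(c(0.5, 0.4), diag(2), matrix(1 / 8, 2, 8)),
    "sum to 1"
  )
  h <- discrete_hmm(c(1, 0), diag(2), matrix(1 / 8, 2, 8))
  expect_s3_class(h, "discrete_hmm")
  expect_error(forward_loglik(h, "eye contact"), "alphabet")
})

test_that("forward log-likelihood has its closed forms", {
  # 1-state uniform emission: every length-9 sequence has p = (1/8)^9
  h <- discrete_hmm(1, matrix(1, 1, 1), matrix(1 / 8, 1, 8))
  seq9 <- rep(c("smiling", "arms crossed", "face touching"), 3)
  expect_equal(forward_loglik(h, seq9), 9 * log(1 / 8))
  # empty sequence has log-probability 0
  expect_equal(forward_loglik(h, character(0)), 0)
})

test_that("forward algorithm equals brute-force path enumeration", {
  set.seed(101)
  for (rep in 1:60) {
    ns <- sample(1:3, 1)
    h <- random_test_hmm(ns)
    len <- sample(1:6, 1)
    symbols <- sample(trust_cue_alphabet(), len, replace = TRUE)
    expect_equal(
      forward_loglik(h, symbols),
      brute_force_loglik(h, symbols),
      tolerance = 1e-10
    )
  }
})

test_that("baum-welch with one state recovers pooled symbol frequencies", {
  seqs <- list(
    c("smiling", "smiling", "arms crossed"),
    c("face touching", "smiling")
  )
  h <- baum_welch(seqs, n_states = 1, seed = 1)
  emp <- table(factor(unlist(seqs), levels = trust_cue_alphabet())) / 5
  expect_equal(as.numeric(h$B), as.numeric(emp), tolerance = 1e-4)
})

test_that("baum-welch log-likelihood is monotone and rows stay stochastic", {
  set.seed(103)
  seqs <- lapply(1:8, function(i) {
    sample(trust_cue_alphabet(), sample(10:25, 1), replace = TRUE)
  })
  for (ns in c(2, 4)) {
    h <- baum_welch(seqs, n_states = ns, seed = ns, max_iter = 80)
    tr <- attr(h, "loglik_trace")
    expect_true(all(diff(tr) >= -1e-8))
    expect_equal(sum(h$pi), 1, tolerance = 1e-9)
    expect_equal(unname(rowSums(h$A)), rep(1, ns), tolerance = 1e-9)
    expect_equal(unname(rowSums(h$B)), rep(1, ns), tolerance = 1e-9)
    expect_true(all(h$B >= 1e-6 - 1e-12))
  }
  expect_error(baum_welch(list(character(0)), 2), "empty")
})

test_that("training is reproducible under a seed", {
  set.seed(104)
  seqs <- lapply(1:5, function(i) sample(trust_cue_alphabet(), 15, replace = TRUE))
  h1 <- baum_welch(seqs, n_states = 3, seed = 9)
  h2 <- baum_welch(seqs, n_states = 3, seed = 9)
  expect_identical(h1$A, h2$A)
  expect_identical(h1$B, h2$B)
})

test_that("simulation respects degenerate chains, seeds, and stationarity", {
  # a deterministic cycle forces its sequence
  h <- discrete_hmm(
    pi = c(1, 0),
    A = matrix(c(0, 1, 1, 0), 2, byrow = TRUE),
    B = rbind(
      c(1, rep(0, 7)), # always "smiling"
      c(rep(0, 6), 1, 0) # always "arms crossed"
    )
  )
  expect_equal(
    simulate(h, nsim = 4, seed = 1),
    c("smiling", "arms crossed", "smiling", "arms crossed")
  )
  expect_equal(simulate(h, nsim = 0), character(0))
  expect_identical(simulate(h, 10, seed = 2), simulate(h, 10, seed = 2))
  # long-run symbol frequencies approach the stationary mixture
  set.seed(105)
  h2 <- random_test_hmm(2)
  ev <- eigen(t(h2$A))
  stat <- Re(ev$vectors[, which.min(abs(ev$values - 1))])
  stat <- stat / sum(stat)
  expected <- as.numeric(stat %*% h2$B)
  sym <- simulate(h2, nsim = 20000, seed = 6)
  emp <- as.numeric(table(factor(sym, levels = h2$alphabet))) / 20000
  expect_equal(emp, expected, tolerance = 0.02)
})

test_that("classification picks the larger log-likelihood, ties to low", {
  set.seed(107)
  low <- discrete_hmm(1, matrix(1), matrix(c(rep(0.05, 4), rep(0.2, 4))[
    match(trust_cue_alphabet(), c(high_trust_cues(), low_trust_cues()))
  ], 1))
  high <- discrete_hmm(1, matrix(1), matrix(c(rep(0.2, 4), rep(0.05, 4))[
    match(trust_cue_alphabet(), c(high_trust_cues(), low_trust_cues()))
  ], 1))
  pair <- list(hmm_low = low, hmm_high = high)
  expect_equal(classify_sequence(pair, rep("face touching", 6)), "low")
  expect_equal(classify_sequence(pair, rep("smiling", 6)), "high")
  # identical models tie on everything -> low; empty sequence ties -> low
  pair2 <- list(hmm_low = low, hmm_high = low)
  expect_equal(classify_sequence(pair2, rep("smiling", 4)), "low")
  expect_equal(classify_sequence(pair, character(0)), "low")
})

test_that("class-conditional selection beats the majority rate on separated data", {
  # two clearly distinct generating regimes via the synthetic generator
  d <- generate_dataset(generator_config(
    n_dyads = 14, seed = 109, signal = 1,
    label_dist = c(0, 0, 0.6, 0, 0.4), partner_coupling = 0
  ))
  pair <- select_hmm_pair(
    d,
    n_runs = 3, state_range = 2:3, seed = 11, max_iter = 40
  )
  expect_s3_class(pair, "hmm_pair")
  expect_gt(pair$accuracy, pair$majority_rate)
  expect_equal(pair$hits + pair$misses, pair$n_low + pair$n_high)
  expect_equal(pair$accuracy, pair$hits / (pair$hits + pair$misses))
})

test_that("simulate_and_sign maps degenerate emissions to pure sign runs", {
  all_smile <- discrete_hmm(1, matrix(1), {
    b <- matrix(0, 1, 8)
    b[1, match("smiling", trust_cue_alphabet())] <- 1
    b
  })
  all_face <- discrete_hmm(1, matrix(1), {
    b <- matrix(0, 1, 8)
    b[1, match("face touching", trust_cue_alphabet())] <- 1
    b
  })
  sim <- simulate_and_sign(
    list(hmm_low = all_face, hmm_high = all_smile),
    length = 6, seed = 3
  )
  expect_equal(sim$low$signs, rep("-", 6))
  expect_equal(sim$high$signs, rep("+", 6))
})

test_that("hmm json round trip preserves parameters", {
  set.seed(111)
  h <- random_test_hmm(3)
  p <- withr::local_tempfile(fileext = ".json")
  write_hmm(h, p)
  h2 <- read_hmm(p)
  expect_equal(h2$pi, h$pi)
  expect_equal(unname(h2$A), unname(h$A), tolerance = 1e-12)
  expect_equal(unname(h2$B), unname(h$B), tolerance = 1e-12)
  expect_equal(h2$alphabet, h$alphabet)
})
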