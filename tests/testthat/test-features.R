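test_that("cue frequency and duration fraction match direct enumeration", {
  d <- make_toy_dataset()
  a <- participant_record(d, "a")
  expect_equal(cue_frequency(a, "face touching"), 2)
  expect_equal(cue_frequency(a, "head nodding"), 0)
  expect_error(cue_frequency(a, "eyebrow raise"), "unknown cue")
  # smiling held 15 s of 300 s -> 5% of the interaction
  expect_equal(cue_duration_fraction(a, "smiling"), 0.05)
  expect_equal(cue_duration_fraction(a, "leaning backward"), 0)
  # a cue spanning the full session counts once but fills the duration
  full <- record_from_cues("arms crossed")
  full$intervals$start_s <- 0
  full$intervals$stop_s <- 300
  expect_equal(cue_frequency(full, "arms crossed"), 1)
  expect_equal(cue_duration_fraction(full, "arms crossed"), 1)
})

test_that("domain features match hand enumeration of the toy session", {
  d <- make_toy_dataset()
  sess <- dyad_session(d, "s1")
  x <- extract_table1_features(sess, "a")
  expect_length(x, 30)
  # self (a): face touching 2 (15 s), arms crossed 1 (30 s),
  # leaning backward 0, hand touching 0; order: ft, ac, lb, ht
  expect_equal(unname(x[1:4]), c(2, 1, 0, 0))
  expect_equal(unname(x[5:8]), c(15, 30, 0, 0) / 300)
  expect_equal(unname(x["x9"]), mean(x[1:4]), ignore_attr = TRUE)
  expect_equal(unname(x["x10"]), mean(x[5:8]), ignore_attr = TRUE)
  # partner (b): leaning backward 1 (30 s), hand touching 1 (5 s)
  expect_equal(unname(x[11:14]), c(0, 0, 1, 1))
  expect_equal(unname(x[15:18]), c(0, 0, 30, 5) / 300)
  expect_equal(unname(x[21:30]), unname(x[1:10] - x[11:20]))
  # swapping roles swaps blocks and negates the differences
  xb <- extract_table1_features(sess, "b")
  expect_equal(unname(xb[1:10]), unname(x[11:20]))
  expect_equal(unname(xb[11:20]), unname(x[1:10]))
  expect_equal(unname(xb[21:30]), unname(-x[21:30]))
})

test_that("mirrored partners zero out every difference slot", {
  d <- make_mirrored_dataset()
  sess <- dyad_session(d, "s1")
  x <- extract_table1_features(sess, "a")
  expect_equal(unname(x[21:30]), rep(0, 10))
  t12 <- extract_template_features(sess, "a")
  expect_equal(unname(t12[9:12]), rep(0, 4))
})

test_that("sign sequences order trust-cue onsets and map their polarity", {
  hi <- record_from_cues(c(
    "smiling", "smiling", "face touching", "smiling", "smiling",
    "hand touching", "arms in lap", "arms crossed", "arms in lap"
  ))
  expect_equal(
    extract_sign_sequence(hi)$signs,
    c("+", "+", "-", "+", "+", "-", "+", "-", "+")
  )
  lo <- record_from_cues(c(
    "smiling", "arms crossed", "face touching", "hand touching", "smiling",
    "face touching", "arms crossed", "smiling", "smiling"
  ))
  expect_equal(
    extract_sign_sequence(lo)$signs,
    c("+", "-", "-", "-", "+", "-", "-", "+", "+")
  )
  # non-trust cues yield an empty sequence
  none <- record_from_cues(c("head nodding", "eye contact", "laughing"))
  expect_length(extract_sign_sequence(none)$signs, 0)
})

test_that("template counts equal independent window enumeration", {
  signs <- c("+", "-", "-", "-", "+", "-", "-", "+", "+")
  lo <- count_templates(signs, "low")
  expect_equal(
    lo,
    c("---" = 1L, "--+" = 2L, "-+-" = 1L, "+--" = 2L)
  )
  expect_equal(count_templates(c("+", "-"), "low"), brute_count_templates(c("+", "-"), low_templates()))
  expect_equal(
    count_templates(c("+", "+", "+"), "high"),
    c("+++" = 1L, "++-" = 0L, "+-+" = 0L, "-++" = 0L)
  )
  # property: counts match the brute-force oracle, and low+high counts
  # partition all windows: total = max(L - 2, 0)
  set.seed(42)
  for (rep in 1:30) {
    n <- sample(0:12, 1)
    signs <- sample(c("+", "-"), n, replace = TRUE)
    lo <- count_templates(signs, "low")
    hi <- count_templates(signs, "high")
    expect_equal(lo, brute_count_templates(signs, low_templates()))
    expect_equal(hi, brute_count_templates(signs, high_templates()))
    expect_equal(sum(lo) + sum(hi), max(length(signs) - 2, 0))
  }
})

test_that("feature matrices have the documented shapes and symmetries", {
  d <- generate_dataset(generator_config(n_dyads = 4, seed = 31))
  fm <- feature_matrix(d, "domain")
  expect_equal(ncol(fm) - 3, 42) # 30 + 12 model features
  fm30 <- feature_matrix(d, "domain", include_templates = FALSE)
  expect_equal(ncol(fm30) - 3, 30)
  nv <- feature_matrix(d, "naive")
  expect_equal(ncol(nv) - 3, 42) # 2 x 21 cues
  # a's partner block equals b's self block within each session
  for (sid in session_ids(d)) {
    sess <- dyad_session(d, sid)
    xa <- extract_table1_features(sess, "a")
    xb <- extract_table1_features(sess, "b")
    expect_equal(unname(xa[11:20]), unname(xb[1:10]))
  }
  # duration fractions bounded
  dur_cols <- paste0("x", c(5:8, 15:18))
  expect_true(all(fm[, dur_cols] >= 0 & fm[, dur_cols] <= 1))
})

test_that("row order of the interval table does not change features", {
  d <- make_toy_dataset()
  f <- make_toy_session_frames()
  set.seed(1)
  shuffled <- trust_dataset(
    f$intervals[sample(nrow(f$intervals)), ], f$outcomes
  )
  s1 <- dyad_session(d, "s1")
  s2 <- dyad_session(shuffled, "s1")
  expect_equal(
    extract_table1_features(s1, "a"),
    extract_table1_features(s2, "a")
  )
  expect_equal(
    extract_sign_sequence(s1$a)$symbols,
    extract_sign_sequence(s2$a)$symbols
  )
})

test_that("feature slot map partitions all 42 slots", {
  all_slots <- sort(unique(c(
    feature_slots(type = "frequency"), feature_slots(type = "duration"),
    feature_slots(type = "joint"), feature_slots(type = "template")
  )))
  expect_equal(all_slots, 1:42)
  expect_equal(feature_slots(type = "duration"), c(5:8, 15:18, 25:28))
  expect_equal(feature_slots(who = "partner", type = "frequency"), 11:14)
  expect_equal(length(feature_slots(who = "self")), 14)
})
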