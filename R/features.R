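#' Cue frequency and duration measures
#'
#' `cue_frequency()` counts how many times a participant emitted a cue
#' (one arms-crossed interval spanning the whole session still counts as
#' one emission).  `cue_duration_fraction()` measures how long the cue was
#' held as a fraction of the interaction, which captures prevalence that
#' the frequency misses.
#'
#' @param record A participant record from [participant_record()].
#' @param cue A cue label from [cue_vocabulary()].
#' @param duration_s Session duration in seconds; defaults to the
#'   record's own duration.
#' @return `cue_frequency()`: an integer count; `cue_duration_fraction()`:
#'   a fraction in `[0, 1]`.
#' @examples
#' d <- generate_dataset(generator_config(n_dyads = 1, seed = 1))
#' r <- participant_record(d, d$outcomes$participant_id[1])
#' cue_frequency(r, "smiling")
#' cue_duration_fraction(r, "smiling")
#' @export
cue_frequency <- function(record, cue) {
  .check_cues(cue)
  sum(record$intervals$cue == cue)
}

#' @rdname cue_frequency
#' @export
cue_duration_fraction <- function(record, cue, duration_s = record$duration_s) {
  .check_cues(cue)
  stopifnot(duration_s > 0)
  iv <- record$intervals
  iv <- iv[iv$cue == cue, , drop = FALSE]
  if (any(iv$stop_s > duration_s)) {
    stop("interval exceeds session duration")
  }
  sum(iv$stop_s - iv$start_s) / duration_s
}

# feature block for one record: freq, dur over the four low-trust cues,
# plus the two joint means
.low_cue_block <- function(record) {
  cues <- low_trust_cues()
  fr <- vapply(cues, function(cc) cue_frequency(record, cc), numeric(1))
  du <- vapply(cues, function(cc) cue_duration_fraction(record, cc), numeric(1))
  c(fr, du, mean(fr), mean(du))
}

#' Domain-knowledge features (slots x1..x30)
#'
#' The 30-feature set built from the four low-trust cues: the
#' participant's own frequencies (`x1..x4`, ordered face touching, arms
#' crossed, leaning backward, hand touching), duration fractions
#' (`x5..x8`), and their joint means (`x9`, `x10`); the partner's
#' analogues (`x11..x20`); and the self-minus-partner differences
#' (`x21..x30`).  Swapping `who` swaps the self/partner blocks and
#' negates the differences.
#'
#' @param session A session from [dyad_session()].
#' @param who `"a"` or `"b"`: which member is "self".
#' @return Named numeric vector `x1..x30`.
#' @export
extract_table1_features <- function(session, who = c("a", "b")) {
  who <- match.arg(who)
  self <- session[[who]]
  partner <- session[[if (who == "a") "b" else "a"]]
  s <- .low_cue_block(self)
  p <- .low_cue_block(partner)
  out <- c(s, p, s - p)
  names(out) <- paste0("x", 1:30)
  out
}

#' Order a participant's trust-cue events into a signed sequence
#'
#' Restricts the record to the eight trust-related cues and orders their
#' onsets by start time (ties broken by the canonical alphabet order,
#' then stop time), mapping each event to `+` (high-trust cue) or `-`
#' (low-trust cue).
#'
#' @param record A participant record.
#' @return An object of class `sign_sequence`: list with character
#'   vectors `symbols` (cue labels) and `signs` (`"+"`/`"-"`), possibly
#'   empty.
#' @export
extract_sign_sequence <- function(record) {
  iv <- record$intervals
  iv <- iv[iv$cue %in% trust_cue_alphabet(), , drop = FALSE]
  ord <- order(iv$start_s, match(iv$cue, trust_cue_alphabet()), iv$stop_s)
  iv <- iv[ord, , drop = FALSE]
  structure(
    list(symbols = iv$cue, signs = if (nrow(iv)) cue_signs(iv$cue) else character()),
    class = "sign_sequence"
  )
}

#' @export
print.sign_sequence <- function(x, ...) {
  cat("<sign_sequence> length", length(x$signs), "\n")
  if (length(x$signs) > 0) cat(paste(x$signs, collapse = " "), "\n")
  invisible(x)
}

#' Length-3 sign templates
#'
#' The four low-trust templates are the length-3 sign patterns with a
#' majority of `-` symbols; the high-trust templates have a majority of
#' `+`.  Counted over overlapping windows they profile the neighbors of
#' each cue, capturing runs such as the frequent consecutive low-trust
#' cues characteristic of low-trust interactions.
#'
#' @return Character vector of four patterns.
#' @examples
#' low_templates()
#' @export
low_templates <- function() {
  c("---", "--+", "-+-", "+--")
}

#' @rdname low_templates
#' @export
high_templates <- function() {
  c("+++", "++-", "+-+", "-++")
}

#' Count template occurrences in a sign sequence
#'
#' Slides a window of three signs along the sequence (step 1, windows
#' overlap) and counts exact matches of each template of the requested
#' polarity.  Sequences shorter than three signs yield all zeros.
#'
#' @param x A [extract_sign_sequence()] result, or a character vector of
#'   `"+"`/`"-"` signs.
#' @param polarity `"low"` or `"high"`.
#' @return Named integer vector of four counts.
#' @examples
#' count_templates(c("+", "-", "-", "-", "+", "-", "-", "+", "+"), "low")
#' @export
count_templates <- function(x, polarity = c("low", "high")) {
  polarity <- match.arg(polarity)
  signs <- if (inherits(x, "sign_sequence")) x$signs else x
  stopifnot(all(signs %in% c("+", "-")))
  pats <- if (polarity == "low") low_templates() else high_templates()
  n <- length(signs)
  counts <- stats::setNames(integer(length(pats)), pats)
  if (n >= 3) {
    windows <- paste0(
      signs[1:(n - 2)], signs[2:(n - 1)], signs[3:n]
    )
    tab <- table(windows)
    hit <- intersect(pats, names(tab))
    counts[hit] <- as.integer(tab[hit])
  }
  counts
}

#' Sequence-template features (slots x31..x42)
#'
#' Twelve features: the frequencies of the four low-trust templates in
#' the participant's own sign sequence (`x31..x34`), in their partner's
#' (`x35..x38`), and the self-minus-partner differences (`x39..x42`,
#' which may be negative).
#'
#' @inheritParams extract_table1_features
#' @return Named numeric vector `x31..x42`.
#' @export
extract_template_features <- function(session, who = c("a", "b")) {
  who <- match.arg(who)
  self <- session[[who]]
  partner <- session[[if (who == "a") "b" else "a"]]
  s <- count_templates(extract_sign_sequence(self), "low")
  p <- count_templates(extract_sign_sequence(partner), "low")
  out <- c(s, p, s - p)
  names(out) <- paste0("x", 31:42)
  out
}

#' Naive full feature extraction (42 features)
#'
#' The uninformed feature set: frequency and duration fraction of each of
#' the 21 originally coded cues for the participant alone, with no
#' domain-knowledge narrowing.  This is the candidate pool for
#' variable-ranking selection (the standard-selection SVM arm).
#'
#' @inheritParams extract_table1_features
#' @return Named numeric vector of 42 features
#'   (`freq_<cue>`, `dur_<cue>`).
#' @export
extract_naive_features <- function(session, who = c("a", "b")) {
  who <- match.arg(who)
  self <- session[[who]]
  voc <- cue_vocabulary()
  cues <- voc$cue[voc$phase2]
  fr <- vapply(cues, function(cc) cue_frequency(self, cc), numeric(1))
  du <- vapply(cues, function(cc) cue_duration_fraction(self, cc), numeric(1))
  key <- gsub(" ", "_", cues)
  stats::setNames(c(fr, du), c(paste0("freq_", key), paste0("dur_", key)))
}

#' Build the feature matrix for a whole dataset
#'
#' One row per participant.  The `"domain"` set holds the 30
#' domain-knowledge features plus (by default) the 12 low-trust template
#' features, i.e. the final 42-feature model input; the `"naive"` set
#' holds the 42 frequency/duration features of the 21 coded cues.
#'
#' @param dataset A [trust_dataset()].
#' @param set `"domain"` or `"naive"`.
#' @param include_templates For the domain set, append `x31..x42`.
#' @return A data frame with columns `session_id`, `participant_id`, the
#'   features, and `tokens_given`.
#' @examples
#' d <- generate_dataset(generator_config(n_dyads = 2, seed = 1))
#' dim(feature_matrix(d))
#' @export
feature_matrix <- function(dataset, set = c("domain", "naive"),
                           include_templates = TRUE) {
  set <- match.arg(set)
  rows <- list()
  for (sid in session_ids(dataset)) {
    sess <- dyad_session(dataset, sid)
    for (who in c("a", "b")) {
      feats <- if (set == "domain") {
        f <- extract_table1_features(sess, who)
        if (include_templates) f <- c(f, extract_template_features(sess, who))
        f
      } else {
        extract_naive_features(sess, who)
      }
      rec <- sess[[who]]
      rows[[length(rows) + 1]] <- data.frame(
        session_id = sid, participant_id = rec$participant_id,
        t(feats), tokens_given = rec$tokens_given,
        stringsAsFactors = FALSE, check.names = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature-slot map for the domain model
#'
#' Maps the role (`self`, `partner`, `diff`) and type (`frequency`,
#' `duration`, `joint`, `template`) of each of the 42 domain-model
#' feature slots, for use in category ablation.
#'
#' @param who Optional role filter.
#' @param type Optional type filter.
#' @return Integer vector of slot indices into `x1..x42`.
#' @examples
#' feature_slots(type = "duration") # x5..x8, x15..x18, x25..x28
#' @export
feature_slots <- function(who = NULL, type = NULL) {
  map <- data.frame(
    slot = 1:42,
    who = rep(
      c("self", "partner", "diff", "self", "partner", "diff"),
      c(10, 10, 10, 4, 4, 4)
    ),
    type = c(
      rep(c(
        rep("frequency", 4), rep("duration", 4), rep("joint", 2)
      ), 3),
      rep("template", 12)
    ),
    stringsAsFactors = FALSE
  )
  keep <- rep(TRUE, 42)
  if (!is.null(who)) {
    who <- match.arg(who, c("self", "partner", "diff"))
    keep <- keep & map$who == who
  }
  if (!is.null(type)) {
    type <- match.arg(type, c("frequency", "duration", "joint", "template"))
    keep <- keep & map$type == type
  }
  map$slot[keep]
}
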