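#' Assemble a validated trust dataset
#'
#' A trust dataset holds the timed nonverbal-cue annotations and Give-Some
#' Game outcomes for a collection of dyadic sessions.  Times are seconds
#' from session start and intervals are half-open `[start_s, stop_s)`, so
#' intervals of cues in the same category may touch but never overlap.
#'
#' @param intervals Data frame with columns `session_id`, `participant_id`,
#'   `category`, `cue`, `start_s`, `stop_s`; one row per coded cue
#'   occurrence.
#' @param outcomes Data frame with columns `session_id`, `participant_id`,
#'   `tokens_given` (integer 0--4, the class label) and optionally
#'   `tokens_predicted` (integer 0--4 or `NA`; the participant's guess of
#'   what their partner will give).  Exactly two participants per session.
#' @param duration_s Session duration in seconds (default 300, a 5-minute
#'   conversation).
#' @return An object of class `trust_dataset`: a list with elements
#'   `intervals`, `outcomes` and `duration_s`.
#' @examples
#' iv <- data.frame(
#'   session_id = "s1", participant_id = c("a", "b"),
#'   category = "mouth", cue = "smiling", start_s = 0, stop_s = 15
#' )
#' oc <- data.frame(
#'   session_id = "s1", participant_id = c("a", "b"),
#'   tokens_given = c(2L, 4L), tokens_predicted = c(2L, 2L)
#' )
#' d <- trust_dataset(iv, oc)
#' n_examples(d)
#' @export
trust_dataset <- function(intervals, outcomes, duration_s = 300) {
  if (is.null(intervals)) {
    intervals <- data.frame(
      session_id = character(), participant_id = character(),
      category = character(), cue = character(),
      start_s = numeric(), stop_s = numeric(), stringsAsFactors = FALSE
    )
  }
  intervals <- as.data.frame(intervals, stringsAsFactors = FALSE)
  outcomes <- as.data.frame(outcomes, stringsAsFactors = FALSE)
  if (!"tokens_predicted" %in% names(outcomes)) {
    outcomes$tokens_predicted <- NA_integer_
  }
  outcomes$tokens_given <- as.integer(outcomes$tokens_given)
  outcomes$tokens_predicted <- as.integer(outcomes$tokens_predicted)
  x <- structure(
    list(
      intervals = .order_intervals(intervals),
      outcomes = outcomes[order(outcomes$session_id, outcomes$participant_id), ,
        drop = FALSE
      ],
      duration_s = duration_s
    ),
    class = "trust_dataset"
  )
  rownames(x$intervals) <- NULL
  rownames(x$outcomes) <- NULL
  validate_dataset(x)
  x
}

# canonical deterministic row order: session, participant, start, cue
.order_intervals <- function(iv) {
  iv[order(iv$session_id, iv$participant_id, iv$start_s, iv$cue), , drop = FALSE]
}

#' Validate a trust dataset
#'
#' Checks every structural invariant: known cue labels with matching
#' categories, interval bounds inside `[0, duration_s]`, mutual exclusivity
#' of same-category intervals per participant, two distinct participants
#' per session, and token counts in 0--4.
#'
#' @param x A [trust_dataset()].
#' @return `x`, invisibly; otherwise an error describing the violation.
#' @export
validate_dataset <- function(x) {
  stopifnot(inherits(x, "trust_dataset"))
  iv <- x$intervals
  oc <- x$outcomes
  need_iv <- c("session_id", "participant_id", "category", "cue", "start_s", "stop_s")
  if (!all(need_iv %in% names(iv))) {
    stop("interval table must have columns: ", paste(need_iv, collapse = ", "))
  }
  if (!all(c("session_id", "participant_id", "tokens_given") %in% names(oc))) {
    stop("outcomes table must have columns session_id, participant_id, tokens_given")
  }
  .check_cues(iv$cue)
  voc <- cue_vocabulary()
  want_cat <- voc$category[match(iv$cue, voc$cue)]
  bad_cat <- which(iv$category != want_cat)
  if (length(bad_cat) > 0) {
    stop(
      "category mismatch for cue '", iv$cue[bad_cat[1]], "': got '",
      iv$category[bad_cat[1]], "', vocabulary says '", want_cat[bad_cat[1]], "'"
    )
  }
  if (any(is.na(iv$start_s)) || any(is.na(iv$stop_s))) {
    stop("interval times must not be missing")
  }
  if (any(iv$start_s < 0) || any(iv$stop_s > x$duration_s) ||
    any(iv$start_s >= iv$stop_s)) {
    stop(
      "intervals must satisfy 0 <= start_s < stop_s <= ", x$duration_s,
      " (session duration)"
    )
  }
  # category mutual exclusivity per participant (half-open intervals)
  if (nrow(iv) > 0) {
    key <- split(
      seq_len(nrow(iv)),
      list(iv$session_id, iv$participant_id, iv$category),
      drop = TRUE
    )
    for (idx in key) {
      if (length(idx) < 2) next
      o <- idx[order(iv$start_s[idx])]
      if (any(iv$start_s[o][-1] < iv$stop_s[o][-length(o)])) {
        stop(
          "overlapping intervals within category '", iv$category[o[1]],
          "' for participant '", iv$participant_id[o[1]], "' in session '",
          iv$session_id[o[1]], "'"
        )
      }
    }
  }
  # outcomes: labels present and in range, two distinct participants/session
  if (any(is.na(oc$tokens_given))) stop("missing tokens_given label")
  if (!all(oc$tokens_given %in% 0:4)) stop("tokens_given must be in 0..4")
  tp <- oc$tokens_predicted[!is.na(oc$tokens_predicted)]
  if (!all(tp %in% 0:4)) stop("tokens_predicted must be in 0..4 or NA")
  per <- table(oc$session_id)
  if (any(per != 2)) {
    stop(
      "each session needs exactly two participant records; offending: ",
      paste(names(per)[per != 2], collapse = ", ")
    )
  }
  dup <- tapply(oc$participant_id, oc$session_id, function(p) anyDuplicated(p) > 0)
  if (any(dup)) stop("participant ids within a session must be distinct")
  # every participant with intervals must have an outcomes row
  known <- paste(oc$session_id, oc$participant_id)
  orphan <- setdiff(unique(paste(iv$session_id, iv$participant_id)), known)
  if (length(orphan) > 0) {
    stop("intervals for participants without outcomes: ", paste(orphan, collapse = "; "))
  }
  invisible(x)
}

#' @export
print.trust_dataset <- function(x, ...) {
  cat(
    "<trust_dataset> ", length(unique(x$outcomes$session_id)), " sessions, ",
    nrow(x$outcomes), " participants, ", nrow(x$intervals),
    " cue intervals, duration ", x$duration_s, " s\n",
    sep = ""
  )
  invisible(x)
}

#' Number of labeled participant examples
#'
#' @param x A [trust_dataset()].
#' @return Integer: one example per participant (two per session).
#' @export
n_examples <- function(x) {
  stopifnot(inherits(x, "trust_dataset"))
  nrow(x$outcomes)
}

#' Extract one participant's record
#'
#' @param x A [trust_dataset()].
#' @param participant_id Participant identifier.
#' @param session_id Optional session identifier (needed only if the
#'   participant id is not unique across sessions).
#' @return A list with elements `session_id`, `participant_id`,
#'   `partner_id`, `duration_s`, `intervals` (this participant's rows),
#'   `tokens_given`, `tokens_predicted`.
#' @export
participant_record <- function(x, participant_id, session_id = NULL) {
  oc <- x$outcomes
  hit <- oc$participant_id == participant_id
  if (!is.null(session_id)) hit <- hit & oc$session_id == session_id
  if (sum(hit) == 0) stop("no such participant: ", participant_id)
  if (sum(hit) > 1) stop("ambiguous participant id; supply session_id")
  row <- oc[hit, ]
  sid <- row$session_id
  partner <- oc$participant_id[oc$session_id == sid &
    oc$participant_id != participant_id]
  iv <- x$intervals
  list(
    session_id = sid,
    participant_id = participant_id,
    partner_id = partner,
    duration_s = x$duration_s,
    intervals = iv[iv$session_id == sid & iv$participant_id == participant_id, ,
      drop = FALSE
    ],
    tokens_given = row$tokens_given,
    tokens_predicted = row$tokens_predicted
  )
}

#' Extract one dyadic session
#'
#' @param x A [trust_dataset()].
#' @param session_id Session identifier.
#' @return A list with elements `session_id`, `duration_s`, and the two
#'   participant records `a` and `b` (in sorted participant-id order).
#' @export
dyad_session <- function(x, session_id) {
  pids <- sort(x$outcomes$participant_id[x$outcomes$session_id == session_id])
  if (length(pids) != 2) stop("no such session: ", session_id)
  list(
    session_id = session_id,
    duration_s = x$duration_s,
    a = participant_record(x, pids[1], session_id),
    b = participant_record(x, pids[2], session_id)
  )
}

#' Session identifiers in a dataset
#' @param x A [trust_dataset()].
#' @return Character vector of session ids.
#' @export
session_ids <- function(x) {
  unique(x$outcomes$session_id)
}

#' Read annotated interactions from CSV
#'
#' Reads an interval table (one row per coded cue occurrence) and the game
#' outcomes, either from a sidecar outcomes CSV or from `tokens_given` /
#' `tokens_predicted` columns embedded in the interval table, and returns a
#' validated dataset.  Row order in the files does not affect the result.
#'
#' @param path CSV with columns `session_id`, `participant_id`, `category`,
#'   `cue`, `start_s`, `stop_s`, and optionally embedded outcome columns.
#' @param outcomes_path Optional sidecar CSV with columns `session_id`,
#'   `participant_id`, `tokens_given`, `tokens_predicted`.
#' @param duration_s Session duration in seconds.
#' @return A [trust_dataset()].
#' @seealso [write_annotations()]
#' @export
read_annotations <- function(path, outcomes_path = NULL, duration_s = 300) {
  iv <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(outcomes_path)) {
    oc <- utils::read.csv(outcomes_path, stringsAsFactors = FALSE)
  } else {
    if (!"tokens_given" %in% names(iv)) {
      stop(
        "no outcomes: supply outcomes_path or embed tokens_given ",
        "in the interval table"
      )
    }
    oc <- unique(iv[, intersect(
      c("session_id", "participant_id", "tokens_given", "tokens_predicted"),
      names(iv)
    )])
    if (anyDuplicated(oc[, c("session_id", "participant_id")]) > 0) {
      stop("embedded outcomes differ across rows of one participant")
    }
  }
  iv <- iv[, c(
    "session_id", "participant_id", "category", "cue",
    "start_s", "stop_s"
  )]
  trust_dataset(iv, oc, duration_s = duration_s)
}

#' Write annotated interactions to CSV
#'
#' Writes the interval table and the outcomes table with a deterministic
#' row ordering (session, participant, start time, cue), so equal datasets
#' always serialize to byte-identical files.  `read_annotations()` on the
#' result reconstructs the dataset exactly.
#'
#' @param x A [trust_dataset()].
#' @param path Destination CSV for the interval table.
#' @param outcomes_path Destination CSV for the outcomes table; default
#'   replaces the extension of `path` with `_outcomes.csv`.
#' @return Invisibly, the two paths written.
#' @export
write_annotations <- function(x, path, outcomes_path = NULL) {
  validate_dataset(x)
  if (is.null(outcomes_path)) {
    outcomes_path <- paste0(sub("\\.csv$", "", path), "_outcomes.csv")
  }
  utils::write.csv(.order_intervals(x$intervals), path, row.names = FALSE)
  oc <- x$outcomes[order(x$outcomes$session_id, x$outcomes$participant_id), ,
    drop = FALSE
  ]
  utils::write.csv(oc, outcomes_path, row.names = FALSE)
  invisible(c(path, outcomes_path))
}

#' Serialize a dataset to/from JSON
#'
#' Compact JSON form used for plain-text fixtures.
#'
#' @param x A [trust_dataset()].
#' @param path JSON file path.
#' @return `dataset_to_json()` returns `path` invisibly;
#'   `dataset_from_json()` returns a [trust_dataset()].
#' @export
dataset_to_json <- function(x, path) {
  validate_dataset(x)
  jsonlite::write_json(
    list(
      duration_s = x$duration_s,
      intervals = x$intervals,
      outcomes = x$outcomes
    ),
    path,
    auto_unbox = TRUE, digits = NA, na = "null"
  )
  invisible(path)
}

#' @rdname dataset_to_json
#' @export
dataset_from_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trust_dataset(obj$intervals, obj$outcomes, duration_s = obj$duration_s)
}
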