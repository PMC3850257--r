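#' The coded nonverbal-cue vocabulary
#'
#' The 22 coded nonverbal behaviors, grouped into six body-region categories.
#' Gestures within a category are mutually exclusive: a participant cannot,
#' for example, be coded as both "smiling" and "not smiling" at the same
#' instant, so intervals of cues sharing a category may touch but never
#' overlap.  Twenty-one behaviors were coded in the original study corpus;
#' "hand gesturing" was added for the redesigned study, so the naive
#' frequency/duration feature set (see [extract_naive_features()]) covers
#' only the original 21 (`phase2 = TRUE` rows).
#'
#' @return A data frame with columns `cue`, `category` (one of `"mouth"`,
#'   `"lean"`, `"gaze"`, `"arms"`, `"touch"`, `"head"`), and `phase2`
#'   (logical; part of the original 21-cue corpus).
#' @examples
#' head(cue_vocabulary())
#' table(cue_vocabulary()$category)
#' @export
cue_vocabulary <- function() {
  .cue_vocabulary
}

.cue_vocabulary <- data.frame(
  cue = c(
    "smiling", "laughing", "not smiling",
    "leaning forward", "leaning backward", "not leaning",
    "eye contact", "looking away",
    "arms crossed", "arms open", "arms in lap",
    "arms in conversational gesture", "arms on table", "hand gesturing",
    "hair touching", "face touching", "hand touching", "body touching",
    "no touching",
    "head shaking", "head nodding", "head still"
  ),
  category = c(
    "mouth", "mouth", "mouth",
    "lean", "lean", "lean",
    "gaze", "gaze",
    "arms", "arms", "arms", "arms", "arms", "arms",
    "touch", "touch", "touch", "touch", "touch",
    "head", "head", "head"
  ),
  phase2 = c(rep(TRUE, 13), FALSE, rep(TRUE, 8)),
  stringsAsFactors = FALSE
)

#' Trust-related cue sets and the eight-symbol alphabet
#'
#' Four cues signal lower trust (face touching, arms crossed, leaning
#' backward, hand touching) and four signal higher trust (leaning forward,
#' smiling, arms in lap, arms open).  Together they form the eight-symbol
#' alphabet over which cue sequences and hidden Markov models are defined.
#'
#' @return Character vectors of cue labels.
#' @examples
#' low_trust_cues()
#' trust_cue_alphabet()
#' @export
low_trust_cues <- function() {
  c("face touching", "arms crossed", "leaning backward", "hand touching")
}

#' @rdname low_trust_cues
#' @export
high_trust_cues <- function() {
  c("leaning forward", "smiling", "arms in lap", "arms open")
}

#' @rdname low_trust_cues
#' @export
trust_cue_alphabet <- function() {
  c(
    "smiling", "leaning forward", "leaning backward", "hand touching",
    "face touching", "arms open", "arms crossed", "arms in lap"
  )
}

#' Map trust cues to their +/- sign
#'
#' High-trust cues map to `"+"`, low-trust cues to `"-"`.
#'
#' @param cues Character vector of cue labels from [trust_cue_alphabet()].
#' @return Character vector of `"+"`/`"-"` signs.
#' @examples
#' cue_signs(c("smiling", "arms crossed"))
#' @export
cue_signs <- function(cues) {
  out <- character(length(cues))
  out[cues %in% high_trust_cues()] <- "+"
  out[cues %in% low_trust_cues()] <- "-"
  bad <- cues[out == ""]
  if (length(bad) > 0) {
    stop("not trust-related cues: ", paste(unique(bad), collapse = ", "))
  }
  out
}

# validate a vector of cue labels against the vocabulary, error naming offenders
.check_cues <- function(cues) {
  bad <- setdiff(unique(cues), .cue_vocabulary$cue)
  if (length(bad) > 0) {
    stop("unknown cue label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}
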