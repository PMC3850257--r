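Package: trustcues
Title: Predicting Interpersonal Trust from Nonverbal Cues in Dyadic
    Conversation
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Models the degree of trust a person has toward a novel
    partner from the timed nonverbal cues expressed during a short
    dyadic conversation, with trust operationalized as tokens given in
    the Give-Some economic game.  Provides interval-annotation data
    structures with category-exclusivity validation, domain-knowledge
    and sequence-template feature extraction, discrete hidden Markov
    models over the eight trust-related cues (Baum-Welch training,
    forward-algorithm scoring, simulation, class-conditional model
    selection), support-vector-machine prediction evaluated by nested
    leave-one-out cross-validation, non-learning baselines, paired
    Wilcoxon signed-rank comparisons with Bonferroni correction,
    feature-category ablation, and a seeded synthetic dyad generator so
    the full pipeline runs without access to the original study videos.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
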