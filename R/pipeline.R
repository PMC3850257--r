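#' Pipeline configuration
#'
#' One configuration object drives the whole pipeline: synthetic-data
#' generation, feature extraction, nested cross-validation of both SVM
#' arms with baselines, class-conditional HMM selection, and (optionally)
#' feature-category ablation.  A single global seed deterministically
#' derives independent per-stage seeds, so e.g. changing the HMM stage
#' seed leaves the generated data untouched.
#'
#' @param n_dyads Number of synthetic dyads.
#' @param seed Global seed; stage seeds are `seed`, `seed + 1`,
#'   `seed + 2`, `seed + 3` (generator, evaluation, HMM, ablation).
#' @param generator Extra arguments for [generator_config()] (besides
#'   `n_dyads` and `seed`).
#' @param svm An [svm_config()] hyper-parameter grid.
#' @param arms Which SVM arms to evaluate.
#' @param rank_k Features kept by variable ranking in the `svm-s` arm.
#' @param include_templates Include the template slots in the domain arm.
#' @param hmm List of [select_hmm_pair()] settings (`n_runs`,
#'   `state_range`, `max_iter`, `tol`); set to `NULL` to skip the HMM
#'   stage.
#' @param ablation Named list of exclusion-token vectors for
#'   [ablate_categories()], or `NULL` to skip.
#' @param alpha Family-wise significance level for model comparisons.
#' @return List of class `pipeline_config`.
#' @seealso [run_pipeline()], [read_pipeline_config()]
#' @export
pipeline_config <- function(n_dyads = 56, seed = 1, generator = list(),
                            svm = svm_config(), arms = c("svm-d", "svm-s"),
                            rank_k = 10, include_templates = TRUE,
                            hmm = list(
                              n_runs = 10, state_range = 2:5,
                              max_iter = 200, tol = 1e-4
                            ),
                            ablation = NULL, alpha = 0.05) {
  stopifnot(inherits(svm, "svm_config"))
  arms <- match.arg(arms, c("svm-d", "svm-s"), several.ok = TRUE)
  structure(
    list(
      n_dyads = as.integer(n_dyads), seed = as.integer(seed),
      generator = generator, svm = svm, arms = arms, rank_k = rank_k,
      include_templates = include_templates, hmm = hmm,
      ablation = ablation, alpha = alpha
    ),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' Recognized top-level keys mirror the [pipeline_config()] arguments;
#' `svm` may be a list with `cost` and `gamma` vectors.
#'
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- y[intersect(names(y), c(
    "n_dyads", "seed", "generator", "arms", "rank_k",
    "include_templates", "hmm", "ablation", "alpha"
  ))]
  if (!is.null(y$svm)) {
    args$svm <- svm_config(
      cost = as.numeric(y$svm$cost),
      gamma = as.numeric(y$svm$gamma)
    )
  }
  do.call(pipeline_config, args)
}

#' Run the full pipeline
#'
#' Generates a synthetic dataset, writes the annotation and feature
#' files, evaluates the requested SVM arms under nested leave-one-out
#' cross-validation against the a priori, random, and human baselines,
#' selects the class-conditional HMM pair and simulates signed sequences
#' from it, and optionally runs the feature-category ablation.  All
#' artifacts are written under `out_dir`; identical configurations
#' produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the dataset, cross-validation results,
#'   the comparison table, the HMM pair, and the ablation table.
#' @export
run_pipeline <- function(config, out_dir = "trustcues_out", verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[trustcues] ", ...)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
        call. = FALSE
      )
    })
  }

  say("generate: ", config$n_dyads, " dyads (seed ", config$seed, ")")
  dataset <- step("generate", {
    gen <- do.call(generator_config, c(
      list(n_dyads = config$n_dyads, seed = config$seed), config$generator
    ))
    generate_dataset(gen)
  })
  write_annotations(
    dataset,
    file.path(out_dir, "annotations.csv"),
    file.path(out_dir, "outcomes.csv")
  )

  say("features: domain + naive matrices")
  step("features", {
    utils::write.csv(
      feature_matrix(dataset, "domain", config$include_templates),
      file.path(out_dir, "features_domain.csv"),
      row.names = FALSE
    )
    utils::write.csv(
      feature_matrix(dataset, "naive"),
      file.path(out_dir, "features_naive.csv"),
      row.names = FALSE
    )
  })

  say("evaluate: nested LOOCV (", paste(config$arms, collapse = ", "), ")")
  results <- step("evaluate", {
    out <- list()
    for (arm in config$arms) {
      out[[arm]] <- nested_loocv(
        dataset,
        arm = arm, config = config$svm, rank_k = config$rank_k,
        include_templates = config$include_templates,
        seed = config$seed + 1
      )
    }
    out
  })
  y <- feature_matrix(dataset, "domain", FALSE)$tokens_given
  errors <- list()
  ref <- config$arms[1]
  for (arm in config$arms) errors[[arm]] <- results[[arm]]$folds$abs_error
  errors[["apriori"]] <- apriori_loocv_errors(y)
  errors[["random"]] <- random_expected_error(y)
  human <- human_baseline_errors(dataset)
  if (attr(human, "n_missing") == 0) errors[["human"]] <- as.numeric(human)
  comparison <- step("evaluate", {
    compare_models(errors, reference = ref, alpha = config$alpha)
  })
  report <- list(
    seed = config$seed,
    m = n_examples(dataset),
    comparison = as.data.frame(comparison),
    alpha_adj = attr(comparison, "alpha_adj"),
    hyper_parameters = lapply(results, function(r) {
      unique(r$folds[, c("cost", "gamma")])
    }),
    confusion = lapply(results, confusion_matrix)
  )

  hmm_pair <- NULL
  if (!is.null(config$hmm)) {
    say("hmm: class-conditional model selection")
    hmm_pair <- step("hmm", {
      do.call(select_hmm_pair, c(
        list(dataset = dataset, seed = config$seed + 2), config$hmm
      ))
    })
    write_hmm(hmm_pair$hmm_low, file.path(out_dir, "hmm_low.json"))
    write_hmm(hmm_pair$hmm_high, file.path(out_dir, "hmm_high.json"))
    sim <- simulate_and_sign(hmm_pair, length = 20, seed = config$seed + 2)
    report$hmm <- list(
      accuracy = hmm_pair$accuracy, hits = hmm_pair$hits,
      misses = hmm_pair$misses, majority_rate = hmm_pair$majority_rate,
      n_states = as.list(hmm_pair$n_states),
      simulated_signs = lapply(sim, function(s) paste(s$signs, collapse = " "))
    )
  }

  ablation <- NULL
  if (!is.null(config$ablation)) {
    say("ablate: ", length(config$ablation), " exclusion sets")
    ablation <- step("ablate", {
      ablate_categories(dataset, config$ablation,
        config = config$svm,
        seed = config$seed + 3
      )
    })
    report$ablation <- as.data.frame(ablation)
    utils::write.csv(as.data.frame(ablation),
      file.path(out_dir, "ablation.csv"),
      row.names = FALSE
    )
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null"
  )
  writeLines(
    utils::capture.output(print(comparison)),
    file.path(out_dir, "comparison.txt")
  )
  say("done: artifacts in ", normalizePath(out_dir))
  invisible(list(
    dataset = dataset, results = results, comparison = comparison,
    hmm_pair = hmm_pair, ablation = ablation, report = report
  ))
}
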