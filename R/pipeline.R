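#' Configure a full comparative-classification experiment
#'
#' Bundles everything [run_pipeline()] needs: the input table (a CSV/TSV
#' path or a [synthetic_config()]), the classifier protocols, and switches
#' for each analysis stage.
#'
#' @param input Path to a feature-table CSV/TSV, or a [synthetic_config()].
#' @param specs A [classifier_spec()] or list of them.
#' @param k Outer cross-validation folds (default 20).
#' @param seed Master seed for fold assignment and sampling.
#' @param ladder Run the confusion-averaging / UPGMA merge-ladder analysis.
#' @param consensus `NULL`, or `list(runs = , min_wrong = )` for the
#'   repeated-CV consensus-misclassification analysis.
#' @param thresholds `NULL`, or an ascending threshold grid for the
#'   reject-option curves.
#' @param subsample `NULL`, or `list(fractions = , repeats = )` for the
#'   stratified subsampling experiment.
#' @param tune Hyperparameter tuning mode passed to [cross_validate()]
#'   (default `"once"`).
#' @param global_scaling Normalize the whole table once instead of per fold.
#' @param output_dir Directory for result files (created if needed), or
#'   `NULL` to skip writing.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(input, specs, k = 20L, seed = 1L,
                              ladder = TRUE, consensus = NULL,
                              thresholds = seq(0, 0.95, by = 0.05),
                              subsample = NULL, tune = "once",
                              global_scaling = FALSE, output_dir = NULL) {
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  if (!length(specs)) stop_config("at least one classifier_spec is required")
  if (is.character(input) && !file.exists(input))
    stop_config("input path does not exist: ", input)
  if (!is.character(input) && !inherits(input, "synthetic_config"))
    stop_config("input must be a file path or a synthetic_config")
  structure(list(input = input, specs = specs, k = as.integer(k),
                 seed = as.integer(seed), ladder = isTRUE(ladder),
                 consensus = consensus, thresholds = thresholds,
                 subsample = subsample, tune = tune,
                 global_scaling = isTRUE(global_scaling),
                 output_dir = output_dir),
            class = "experiment_config")
}

config_manifest <- function(config) {
  input <- if (is.character(config$input)) {
    list(type = "file", path = config$input)
  } else {
    c(list(type = "synthetic"), unclass(config$input))
  }
  list(package = "phenoclass",
       version = as.character(utils::packageVersion("phenoclass")),
       r_version = paste(R.version$major, R.version$minor, sep = "."),
       input = input,
       specs = lapply(config$specs, unclass),
       k = config$k, seed = config$seed, ladder = config$ladder,
       consensus = config$consensus, thresholds = config$thresholds,
       subsample = config$subsample, tune = config$tune,
       global_scaling = config$global_scaling)
}

write_stage <- function(dir, name, obj) {
  if (is.null(dir)) return(invisible(NULL))
  path <- file.path(dir, name)
  if (grepl("\\.csv$", name)) {
    utils::write.csv(obj, path, row.names = FALSE)
  } else if (grepl("\\.json$", name)) {
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  } else {
    writeLines(obj, path)
  }
  invisible(path)
}

#' Run the full comparative-classification pipeline
#'
#' Executes, in order: table generation/loading, per-classifier stratified
#' k-fold cross-validation, averaged-confusion dissimilarity and UPGMA
#' merge-ladder evaluation, repeated-CV consensus misclassification with
#' pairwise overlap fractions, posterior reject-option threshold curves,
#' and the stratified subsampling experiment — each stage only if enabled
#' in the configuration.  All outputs (CSV/JSON/Newick plus a manifest
#' echoing the configuration and seeds) are written to
#' `config$output_dir`; given the same configuration the run is fully
#' reproducible.
#'
#' @param config An [experiment_config()].
#' @param quiet Suppress per-stage progress messages.
#' @return A results bundle (list) with elements `table`, `cv`, `ladder`,
#'   `consensus`, `threshold_curves`, `subsample`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  say <- function(...) if (!quiet) message("[phenoclass] ", ...)
  stage <- function(name, expr) {
    t0 <- proc.time()["elapsed"]
    out <- tryCatch(force(expr), error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
    say(name, " done in ", sprintf("%.1fs", proc.time()["elapsed"] - t0))
    out
  }
  dir <- config$output_dir
  if (!is.null(dir) && !dir.exists(dir))
    dir.create(dir, recursive = TRUE)
  bundle <- list(manifest = config_manifest(config))
  write_stage(dir, "manifest.json", bundle$manifest)

  bundle$table <- stage("input", {
    if (is.character(config$input)) read_feature_table(config$input)
    else generate_dataset(config$input)
  })
  if (!is.null(dir) && inherits(config$input, "synthetic_config"))
    write_feature_table(bundle$table, file.path(dir, "feature_table.csv"))

  methods <- vapply(config$specs, `[[`, character(1), "method")

  if (config$ladder) {
    lad <- stage("ladder", ladder_evaluation(
      bundle$table, config$specs, k = config$k, seed = config$seed,
      tune = config$tune, global_scaling = config$global_scaling))
    bundle$cv <- lad$cv_results
    bundle$ladder <- lad
    write_stage(dir, "ladder_accuracies.csv", lad$accuracies)
    write_stage(dir, "dissimilarity.csv",
                data.frame(phenotype = rownames(lad$dissimilarity),
                           lad$dissimilarity, check.names = FALSE))
    write_stage(dir, "merge_events.csv", lad$ladder$events)
    write_stage(dir, "level_maps.json", lad$ladder$level_maps)
    if (!is.null(dir))
      writeLines(ladder_newick(lad$ladder), file.path(dir, "dendrogram.nwk"))
  } else {
    bundle$cv <- stage("cross-validation", lapply(config$specs, function(sp)
      cross_validate(bundle$table, sp, k = config$k, seed = config$seed,
                     tune = config$tune,
                     global_scaling = config$global_scaling)))
  }
  acc <- data.frame(method = methods,
                    accuracy = vapply(bundle$cv, `[[`, numeric(1), "accuracy"))
  write_stage(dir, "cv_accuracies.csv", acc)
  ## wall times are informational only and deliberately kept out of the
  ## deterministic result files
  write_stage(dir, "timings.csv",
              data.frame(method = methods,
                         elapsed_s = vapply(bundle$cv, `[[`, numeric(1),
                                            "elapsed")))
  for (i in seq_along(bundle$cv))
    write_stage(dir, paste0("confusion_", methods[i], ".csv"),
                data.frame(true = rownames(bundle$cv[[i]]$confusion),
                           bundle$cv[[i]]$confusion, check.names = FALSE))

  if (!is.null(config$consensus)) {
    cons <- stage("consensus", lapply(config$specs, function(sp)
      consensus_misclassified(bundle$table, sp,
                              runs = config$consensus$runs,
                              k = config$k,
                              min_wrong = config$consensus$min_wrong,
                              base_seed = config$seed)))
    names(cons) <- methods
    bundle$consensus <- cons
    counts_df <- data.frame(cell_id = bundle$table$cell_ids)
    for (m in methods) counts_df[[m]] <- cons[[m]]$counts
    write_stage(dir, "consensus_counts.csv", counts_df)
    if (!is.null(dir))
      for (m in methods)
        writeLines(cons[[m]]$flagged,
                   file.path(dir, paste0("flagged_", m, ".txt")))
    ov <- expand.grid(reference = methods, other = methods,
                      stringsAsFactors = FALSE)
    ov$overlap <- mapply(function(a, b) {
      if (!length(cons[[a]]$flagged)) NA_real_
      else overlap_fraction(cons[[a]], cons[[b]])
    }, ov$reference, ov$other)
    bundle$overlaps <- ov
    write_stage(dir, "consensus_overlaps.csv", ov)
  }

  if (!is.null(config$thresholds)) {
    bundle$threshold_curves <- stage("threshold curves", {
      out <- list()
      for (i in seq_along(config$specs)) {
        res <- cross_validate(bundle$table, config$specs[[i]], k = config$k,
                              seed = config$seed, tune = config$tune,
                              global_scaling = config$global_scaling,
                              posterior = TRUE)
        out[[methods[i]]] <- suppressWarnings(
          threshold_curve(res$posterior, bundle$table$labels,
                          res$predicted, thresholds = config$thresholds))
      }
      out
    })
    for (m in names(bundle$threshold_curves))
      write_stage(dir, paste0("threshold_curve_", m, ".csv"),
                  as.data.frame(bundle$threshold_curves[[m]]))
  }

  if (!is.null(config$subsample)) {
    bundle$subsample <- stage("subsampling", subsample_experiment(
      bundle$table, config$specs,
      fractions = config$subsample$fractions,
      repeats = config$subsample$repeats,
      k = config$k, seed = config$seed, tune = config$tune))
    write_stage(dir, "subsample_runs.csv", bundle$subsample$runs)
    write_stage(dir, "subsample_summary.csv", bundle$subsample$summary)
  }
  say("pipeline complete")
  invisible(bundle)
}
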