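#' Stratified k-fold assignment
#'
#' Cells of each phenotype are shuffled with the given seed and dealt
#' round-robin (in a seeded random fold order per phenotype) so that, within
#' every phenotype, fold sizes differ by at most one.  With strong class
#' imbalance this keeps relative phenotype frequencies roughly constant
#' across folds.  Phenotypes with fewer cells than folds simply leave some
#' folds without that phenotype.
#'
#' @param labels Integer phenotype labels.
#' @param k Number of folds (`>= 2`).
#' @param seed Integer seed; the same seed reproduces the same assignment.
#' @return A list with `fold` (fold index per cell), `k` and `seed`.
#' @export
stratified_kfold <- function(labels, k, seed = 1L) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop_config("k must be an integer >= 2")
  n <- length(labels)
  fold <- integer(n)
  with_seed(seed, {
    for (cl in sort(unique(labels))) {
      idx <- which(labels == cl)
      idx <- idx[sample.int(length(idx))]
      slots <- rep(sample.int(k), length.out = length(idx))
      fold[idx] <- slots
    }
  })
  list(fold = fold, k = k, seed = as.integer(seed))
}

#' Confusion matrix of predictions
#'
#' @param labels True phenotype indices.
#' @param predicted Predicted phenotype indices.
#' @param phenotype_names Phenotype catalog fixing matrix order and size.
#' @return Integer `K x K` matrix, rows true, columns predicted.
#' @export
confusion_matrix <- function(labels, predicted, phenotype_names) {
  K <- length(phenotype_names)
  cm <- table(factor(labels, levels = seq_len(K)),
              factor(predicted, levels = seq_len(K)))
  cm <- matrix(as.integer(cm), nrow = K,
               dimnames = list(true = phenotype_names,
                               predicted = phenotype_names))
  cm
}

#' Accuracy from a confusion matrix
#' @param cm A confusion matrix (counts, rows true / columns predicted).
#' @return `trace(cm) / sum(cm)`.
#' @export
confusion_accuracy <- function(cm) sum(diag(cm)) / sum(cm)

#' Select SVM hyperparameters by stratified inner cross-validation
#'
#' Every grid point is scored by stratified `inner_k`-fold accuracy (with
#' fold-safe feature normalization) and the argmax is returned; ties are
#' broken by the smaller `C`, then the smaller `gamma`.
#'
#' @param ft A [feature_table()].
#' @param spec A [classifier_spec()] for one of the SVM methods.
#' @param inner_k Folds of the selection CV (defaults to `spec$inner_folds`).
#' @param seed Seed for the inner fold split.
#' @return `list(C = , gamma = )` (`gamma` is `NULL` for the linear SVM).
#' @export
grid_search_cv <- function(ft, spec, inner_k = NULL, seed = 1L) {
  if (!spec$method %in% c("svm_linear", "svm_rbf"))
    return(list(C = NULL, gamma = NULL))
  inner_k <- inner_k %||% spec$inner_folds
  if (spec$method == "svm_linear") {
    grid <- data.frame(C = sort(spec$C_grid))
  } else {
    grid <- expand.grid(gamma = sort(spec$gamma_grid), C = sort(spec$C_grid))
    grid <- grid[order(grid$C, grid$gamma), c("C", "gamma")]
  }
  if (nrow(grid) == 1L)
    return(list(C = grid$C[1], gamma = grid$gamma[1]))
  folds <- stratified_kfold(ft$labels, k = inner_k, seed = seed)
  correct <- numeric(nrow(grid))
  total <- 0L
  for (f in seq_len(inner_k)) {
    te <- folds$fold == f
    if (!any(te) || all(te)) next
    tr_tab <- subset_cells(ft, !te)
    norm <- normalize_features(tr_tab, warn_constant = FALSE)
    Xte <- apply_normalization(ft$values[te, , drop = FALSE], norm$params)
    yte <- ft$labels[te]
    total <- total + length(yte)
    for (g in seq_len(nrow(grid))) {
      model <- fit_classifier(norm$table, spec,
                              hyper = list(C = grid$C[g],
                                           gamma = grid$gamma[g]))
      correct[g] <- correct[g] + sum(predict(model, Xte) == yte)
    }
  }
  best <- which.max(correct)       # grid pre-sorted: first max = smallest C
  list(C = grid$C[best], gamma = grid$gamma[best])
}

#' Stratified k-fold cross-validation of a classifier
#'
#' For each outer fold the features are normalized on the training cells
#' only (unless `global_scaling`), SVM hyperparameters are selected by inner
#' grid search (per outer fold by default, once up front with
#' `tune = "once"`, or skipped with `tune = "none"`), the model is fitted
#' and the held-out fold predicted.  Predictions are pooled into a single
#' confusion matrix over all cells, so the accuracy is the number of
#' correctly classified cells divided by the total number of cells.
#'
#' @param ft A [feature_table()].
#' @param spec A [classifier_spec()].
#' @param k Number of outer folds (default 20).
#' @param seed Seed controlling fold assignment (and tuning splits).
#' @param tune `"per_fold"` (nested, default), `"once"`, or `"none"`.
#' @param hyper Hyperparameters used when `tune = "none"`.
#' @param global_scaling Normalize the whole table once instead of per
#'   training fold (replicates whole-data-set scaling at the cost of mild
#'   leakage).
#' @param posterior Also compute out-of-fold posterior probabilities
#'   (Platt-calibrated within each training fold where needed).
#' @param calibration_folds Internal folds of [platt_calibrate()].
#' @return A `cv_result`: `predicted`, `confusion`, `accuracy`, `hyper`
#'   (per-fold choices), optional `posterior`, `elapsed` seconds (logged
#'   only), plus the fold assignment.
#' @export
cross_validate <- function(ft, spec, k = 20L, seed = 1L,
                           tune = c("per_fold", "once", "none"),
                           hyper = NULL, global_scaling = FALSE,
                           posterior = FALSE, calibration_folds = 3L) {
  tune <- match.arg(tune)
  t0 <- proc.time()["elapsed"]
  n <- nrow(ft$values)
  K <- n_phenotypes(ft)
  folds <- stratified_kfold(ft$labels, k = k, seed = seed)
  needs_tuning <- spec$method %in% c("svm_linear", "svm_rbf")
  if (needs_tuning && tune == "once")
    hyper <- grid_search_cv(ft, spec, seed = seed)
  predicted <- integer(n)
  post <- if (posterior)
    matrix(NA_real_, nrow = n, ncol = K,
           dimnames = list(NULL, ft$phenotype_names)) else NULL
  hypers <- vector("list", k)
  work_tab <- ft
  glob_params <- NULL
  if (global_scaling) {
    normed <- normalize_features(ft, warn_constant = FALSE)
    work_tab <- normed$table
  }
  for (f in seq_len(k)) {
    te <- folds$fold == f
    if (!any(te)) next
    tr_tab <- subset_cells(work_tab, !te)
    if (global_scaling) {
      Xte <- work_tab$values[te, , drop = FALSE]
      fit_tab <- tr_tab
    } else {
      norm <- normalize_features(tr_tab, warn_constant = FALSE)
      fit_tab <- norm$table
      Xte <- apply_normalization(work_tab$values[te, , drop = FALSE],
                                 norm$params)
    }
    h <- hyper
    if (needs_tuning && tune == "per_fold")
      h <- grid_search_cv(fit_tab, spec, seed = derive_seed(seed, f))
    hypers[[f]] <- h
    model <- tryCatch(fit_classifier(fit_tab, spec, hyper = h),
                      error = function(e)
                        stop_data("fold ", f, ": ", conditionMessage(e)))
    predicted[te] <- predict(model, Xte)
    if (posterior) {
      if (!is.null(model$platt) || model$method == "lda_pinv") {
        post[te, ] <- predict_posterior(model, Xte)
      } else {
        cal <- platt_calibrate(model, fit_tab, cv = calibration_folds,
                               seed = derive_seed(seed, 1000L + f))
        post[te, ] <- predict_posterior(cal, Xte)
      }
    }
  }
  cm <- confusion_matrix(work_tab$labels, predicted, work_tab$phenotype_names)
  structure(list(predicted = predicted,
                 confusion = cm,
                 accuracy = confusion_accuracy(cm),
                 hyper = hypers,
                 posterior = post,
                 folds = folds,
                 method = spec$method,
                 elapsed = unname(proc.time()["elapsed"] - t0)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat("cv_result:", x$method, "- accuracy",
      sprintf("%.4f", x$accuracy), "over", sum(x$confusion), "cells\n")
  invisible(x)
}

## Deterministic seed derivation kept inside 32-bit integer range.
derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(i) * 104729) %% 2147483647)
}

#' Stratified subsampling learning-curve experiment
#'
#' For each fraction, `repeats` stratified subsamples are drawn (per
#' phenotype, `round(fraction * count)` cells, at least 1) and each is
#' scored by [cross_validate()]; the mean and sd of accuracy over repeats
#' summarize how performance depends on the number of labelled cells.
#'
#' @param ft A [feature_table()].
#' @param specs A [classifier_spec()] or list of them.
#' @param fractions Subsampling fractions in (0, 1], default
#'   `c(1/2, 1/4, 1/8, 1/16)`.
#' @param repeats Random subsamples per fraction (default 50).
#' @param k,seed,tune,... Passed to [cross_validate()].
#' @return A list with `runs` (one row per spec x fraction x repeat) and
#'   `summary` (mean and sd per spec x fraction).
#' @export
subsample_experiment <- function(ft, specs,
                                 fractions = c(1/2, 1/4, 1/8, 1/16),
                                 repeats = 50L, k = 20L, seed = 1L,
                                 tune = "once", ...) {
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  if (any(fractions <= 0 | fractions > 1))
    stop_config("fractions must lie in (0, 1]")
  K <- n_phenotypes(ft)
  counts <- tabulate(ft$labels, nbins = K)
  rows <- list()
  for (spec in specs) {
    for (fr in fractions) {
      target <- pmax(1L, as.integer(round(fr * counts)))
      reps <- if (fr == 1) 1L else as.integer(repeats)
      for (r in seq_len(reps)) {
        idx <- draw_stratified(ft$labels, target,
                               seed = derive_seed(seed, r * 131L + round(1e4 * fr)))
        res <- cross_validate(subset_cells(ft, idx), spec, k = k,
                              seed = derive_seed(seed, r), tune = tune, ...)
        rows[[length(rows) + 1L]] <-
          data.frame(method = spec$method, fraction = fr, rep = r,
                     n_cells = length(idx), accuracy = res$accuracy)
      }
    }
  }
  runs <- do.call(rbind, rows)
  summ <- stats::aggregate(accuracy ~ method + fraction, data = runs,
                           FUN = function(a) c(mean = mean(a), sd = stats::sd(a)))
  summ <- data.frame(method = summ$method, fraction = summ$fraction,
                     mean_accuracy = summ$accuracy[, "mean"],
                     sd_accuracy = summ$accuracy[, "sd"])
  list(runs = runs, summary = summ[order(summ$method, -summ$fraction), ])
}

## Seeded stratified sample: `target[k]` cells from each phenotype k.
draw_stratified <- function(labels, target, seed) {
  with_seed(seed, {
    idx <- integer(0)
    for (cl in seq_along(target)) {
      pool <- which(labels == cl)
      if (length(pool) < target[cl])
        stop_config("phenotype index ", cl, " has only ", length(pool),
                    " cells; cannot draw ", target[cl])
      idx <- c(idx, pool[sample.int(length(pool), target[cl])])
    }
    sort(idx)
  })
}
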