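#' Consensus misclassification over repeated cross-validation
#'
#' Runs `runs` independent k-fold cross-validations, differing only in the
#' fold assignment (run `r` uses seed `base_seed + r`), counts per cell how
#' often it was wrongly classified, and flags cells wrong in at least
#' `min_wrong` runs as consensus-misclassified.  SVM hyperparameters are by
#' default tuned once on the full table and reused across runs (set
#' `retune_per_run` to re-tune inside every run).
#'
#' @param ft A [feature_table()].
#' @param spec A [classifier_spec()].
#' @param runs Number of repeated cross-validations (default 100).
#' @param k Folds per run (default 20).
#' @param min_wrong Consensus cutoff: flag cells wrong in `>= min_wrong`
#'   runs (default 80).
#' @param base_seed Base seed; run `r` uses `base_seed + r`.
#' @param retune_per_run Re-run the hyperparameter grid search inside every
#'   run instead of once up front.
#' @return A `consensus_counts` object: `counts` (per-cell wrong counts),
#'   `flagged` (cell ids with `counts >= min_wrong`), `runs`, `min_wrong`,
#'   `method`, `cell_ids`.
#' @export
consensus_misclassified <- function(ft, spec, runs = 100L, k = 20L,
                                    min_wrong = 80L, base_seed = 1L,
                                    retune_per_run = FALSE) {
  runs <- as.integer(runs)
  if (is.na(runs) || runs < 1L) stop_config("runs must be >= 1")
  if (min_wrong < 1L || min_wrong > runs)
    stop_config("min_wrong must lie in 1..runs")
  hyper <- NULL
  tune_mode <- "none"
  if (spec$method %in% c("svm_linear", "svm_rbf")) {
    if (retune_per_run) {
      tune_mode <- "once"
    } else {
      hyper <- grid_search_cv(ft, spec, seed = base_seed)
    }
  }
  wrong <- integer(nrow(ft$values))
  for (r in seq_len(runs)) {
    res <- tryCatch(
      cross_validate(ft, spec, k = k, seed = as.integer(base_seed) + r,
                     tune = tune_mode, hyper = hyper),
      error = function(e) stop_data("run ", r, ": ", conditionMessage(e)))
    wrong <- wrong + (res$predicted != ft$labels)
  }
  structure(list(counts = wrong,
                 flagged = ft$cell_ids[wrong >= min_wrong],
                 runs = runs, min_wrong = as.integer(min_wrong),
                 method = spec$method, cell_ids = ft$cell_ids),
            class = "consensus_counts")
}

#' @export
print.consensus_counts <- function(x, ...) {
  cat("consensus_counts:", x$method, "-", length(x$flagged),
      "of", length(x$counts), "cells wrong in >=", x$min_wrong,
      "of", x$runs, "runs\n")
  invisible(x)
}

#' Overlap fraction between two flagged cell sets
#'
#' The fraction of the reference set `flagged_a` that is also flagged in
#' `flagged_b`: `|A intersect B| / |A|`.  Quantifies, e.g., how many cells
#' consensus-misclassified by one classifier are also consensus-misclassified
#' by another.
#'
#' @param flagged_a Reference flagged cell ids (non-empty), or a
#'   `consensus_counts` object.
#' @param flagged_b Comparison flagged cell ids or `consensus_counts`.
#' @return A fraction in \[0, 1\].
#' @export
overlap_fraction <- function(flagged_a, flagged_b) {
  if (inherits(flagged_a, "consensus_counts")) flagged_a <- flagged_a$flagged
  if (inherits(flagged_b, "consensus_counts")) flagged_b <- flagged_b$flagged
  if (!length(flagged_a))
    stop_data("reference flagged set is empty; overlap fraction undefined")
  length(intersect(flagged_a, flagged_b)) / length(unique(flagged_a))
}

#' Smallest posterior threshold excluding a phenotype
#'
#' With the reject option "keep a cell iff its maximum posterior is at least
#' t", a phenotype disappears once t exceeds the largest maximum posterior
#' among its cells.  The smallest such value over phenotypes is the natural
#' stopping point for reject-option curves: beyond it, accuracy gains could
#' come from dropping a phenotype wholesale.
#'
#' @param posteriors Posterior matrix (cells by phenotypes, rows sum to 1).
#' @param labels True phenotype indices.
#' @return A list: `threshold` (min over phenotypes of the max of its cells'
#'   max-posteriors) and `phenotype` (the arg-min phenotype's column name or
#'   index).
#' @export
phenotype_exclusion_threshold <- function(posteriors, labels) {
  maxp <- apply(posteriors, 1, max)
  phen <- sort(unique(labels))
  peak <- vapply(phen, function(cl) max(maxp[labels == cl]), numeric(1))
  i <- which.min(peak)
  nm <- colnames(posteriors)
  list(threshold = peak[i],
       phenotype = if (!is.null(nm)) nm[phen[i]] else phen[i])
}

#' Reject-option accuracy/coverage curve
#'
#' At each threshold `t`, cells whose maximum posterior is at least `t` are
#' included; the curve reports the fraction of cells included and the
#' accuracy on the included cells.  The curve is truncated at the
#' [phenotype_exclusion_threshold()] so that accuracy gains cannot be due to
#' a phenotype being dropped entirely; thresholds beyond it trigger a
#' truncation warning, not an error.
#'
#' @param posteriors Posterior matrix (cells by phenotypes, rows sum to 1
#'   within 1e-6).
#' @param labels True phenotype indices.
#' @param predictions Predicted phenotype indices (e.g. out-of-fold CV
#'   predictions).
#' @param thresholds Ascending thresholds in \[0, 1\] (default 0 to 0.95 by
#'   0.05).
#' @param truncate Truncate at the phenotype-exclusion threshold (default
#'   `TRUE`).
#' @return A `threshold_curve` data frame: `threshold`, `n_included`,
#'   `fraction_included`, `accuracy`, plus attributes `exclusion` (the
#'   exclusion threshold and phenotype) and `included_by_phenotype`.
#' @export
threshold_curve <- function(posteriors, labels, predictions,
                            thresholds = seq(0, 0.95, by = 0.05),
                            truncate = TRUE) {
  if (is.unsorted(thresholds))
    stop_config("thresholds must be sorted ascending")
  bad <- abs(rowSums(posteriors) - 1) > 1e-6
  if (any(bad))
    stop_data("posterior rows do not sum to 1 (first bad row: ",
              which(bad)[1], ")")
  maxp <- apply(posteriors, 1, max)
  excl <- phenotype_exclusion_threshold(posteriors, labels)
  use <- thresholds
  if (truncate && any(thresholds > excl$threshold)) {
    warning("curve truncated at phenotype-exclusion threshold ",
            sprintf("%.4f", excl$threshold), " (phenotype ",
            excl$phenotype, ")")
    use <- thresholds[thresholds <= excl$threshold]
  }
  K <- ncol(posteriors)
  rows <- lapply(use, function(t) {
    inc <- maxp >= t
    by_phen <- tabulate(labels[inc], nbins = K)
    data.frame(threshold = t, n_included = sum(inc),
               fraction_included = mean(inc),
               accuracy = if (any(inc))
                 mean(predictions[inc] == labels[inc]) else NA_real_,
               t(by_phen))
  })
  out <- do.call(rbind, rows)
  names(out)[-(1:4)] <- paste0("n_", colnames(posteriors) %||%
                                 paste0("P", seq_len(K)))
  attr(out, "exclusion") <- excl
  class(out) <- c("threshold_curve", class(out))
  out
}
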