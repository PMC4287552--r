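#' Describe a classification protocol
#'
#' A classifier specification bundles a method name with its tuning
#' parameters: the stump count for gentle boosting, and the hyperparameter
#' grids searched by 5-fold inner cross-validation for the SVMs.  Default
#' grids are `C` in `2^(-5..6)` for the linear SVM and `C` in `2^(-1..6)`,
#' `gamma` in `2^(-5..1)` for the RBF SVM.
#'
#' @param method One of `"gentle_boost"`, `"svm_linear"`, `"svm_rbf"`,
#'   `"lda_pinv"`.
#' @param n_stumps Number of boosting rounds (gentle boosting; default 50).
#' @param C_grid Positive cost values searched for the SVMs.
#' @param gamma_grid Positive kernel widths searched for the RBF SVM.
#' @param inner_folds Folds of the hyperparameter-selection CV (default 5).
#' @return An object of class `classifier_spec`.
#' @export
classifier_spec <- function(method = c("gentle_boost", "svm_linear",
                                       "svm_rbf", "lda_pinv"),
                            n_stumps = 50L,
                            C_grid = NULL, gamma_grid = NULL,
                            inner_folds = 5L) {
  method <- match.arg(method)
  if (method == "svm_linear" && is.null(C_grid)) C_grid <- 2^(-5:6)
  if (method == "svm_rbf") {
    if (is.null(C_grid)) C_grid <- 2^(-1:6)
    if (is.null(gamma_grid)) gamma_grid <- 2^(-5:1)
  }
  if (method %in% c("svm_linear", "svm_rbf")) {
    if (!length(C_grid) || any(C_grid <= 0))
      stop_config("C_grid must be non-empty and positive")
    if (method == "svm_rbf" && (!length(gamma_grid) || any(gamma_grid <= 0)))
      stop_config("gamma_grid must be non-empty and positive")
  }
  n_stumps <- as.integer(n_stumps)
  if (method == "gentle_boost" && (is.na(n_stumps) || n_stumps < 1L))
    stop_config("n_stumps must be >= 1")
  structure(list(method = method, n_stumps = n_stumps,
                 C_grid = C_grid, gamma_grid = gamma_grid,
                 inner_folds = as.integer(inner_folds)),
            class = "classifier_spec")
}

#' Fit a classifier described by a specification
#'
#' Dispatches to the method implementations.  For the SVMs, `hyper` supplies
#' the chosen hyperparameters (e.g. from [grid_search_cv()]); when absent,
#' the first grid point is used.
#'
#' @param ft A normalized [feature_table()].
#' @param spec A [classifier_spec()].
#' @param hyper Optional `list(C = , gamma = )`.
#' @return A fitted model (class `phenoclass_model`).
#' @export
fit_classifier <- function(ft, spec, hyper = NULL) {
  switch(spec$method,
    gentle_boost = fit_gentle_boost(ft, n_stumps = spec$n_stumps),
    lda_pinv     = fit_lda_pinv(ft),
    svm_linear   = fit_svm_linear(ft, C = hyper$C %||% spec$C_grid[1]),
    svm_rbf      = fit_svm_rbf(ft, C = hyper$C %||% spec$C_grid[1],
                               gamma = hyper$gamma %||% spec$gamma_grid[1]))
}

#' Fit a one-vs-all gentle boosting classifier
#'
#' For each phenotype a binary (+1 vs -1) gentle-boost ensemble of
#' regression stumps is trained; prediction is the phenotype with the
#' largest additive score.  Each boosting round fits, by exhaustive search
#' over every feature and every midpoint threshold, the regression stump
#' `a * 1[x_j > theta] + b` minimizing the weighted squared error against
#' the class targets, then reweights cells by `exp(-y * f(x))`.
#'
#' @param ft A [feature_table()] with at least 2 phenotypes.
#' @param n_stumps Number of boosting rounds (default 50).
#' @return A fitted `gentle_boost_model`.
#' @export
fit_gentle_boost <- function(ft, n_stumps = 50L) {
  fit_gentle_boost_impl(ft, n_stumps)
}

#' Fit linear discriminant analysis with pseudo-inverse covariance
#'
#' Class means, empirical priors and the pooled within-class covariance are
#' estimated, and the covariance is inverted with the Moore-Penrose
#' pseudo-inverse so that rank-deficient feature matrices (exactly linearly
#' dependent columns) are handled without error.  On full-rank problems the
#' discriminant coincides with textbook LDA.
#'
#' @param ft A [feature_table()]; every phenotype needs at least 2 cells.
#' @return A fitted `lda_pinv_model`.
#' @export
fit_lda_pinv <- function(ft) fit_lda_pinv_impl(ft)

#' Fit a one-vs-all L2-regularized L2-loss linear SVM
#'
#' One squared-hinge linear classifier per phenotype, decoded by argmax of
#' the decision scores.
#'
#' @param ft A [feature_table()].
#' @param C Positive cost parameter.
#' @return A fitted `svm_linear_model`.
#' @export
fit_svm_linear <- function(ft, C = 1) fit_svm_linear_impl(ft, C)

#' Fit a one-vs-one RBF-kernel SVM
#'
#' Gaussian-kernel soft-margin SVM with one-against-one decomposition and
#' majority-vote decoding (libsvm back-end).
#'
#' @param ft A [feature_table()].
#' @param C Positive cost parameter.
#' @param gamma Positive kernel width (inverse squared length scale);
#'   defaults to `1 / n_features`.
#' @return A fitted `svm_rbf_model`.
#' @export
fit_svm_rbf <- function(ft, C = 1, gamma = NULL) fit_svm_rbf_impl(ft, C, gamma)

model_values <- function(newdata) {
  if (inherits(newdata, "feature_table")) newdata$values else as.matrix(newdata)
}

#' Decision scores of a fitted model
#'
#' One column per phenotype; prediction is the column-wise argmax.  For the
#' one-vs-one RBF SVM the returned scores are the per-phenotype vote counts.
#'
#' @param model A fitted `phenoclass_model`.
#' @param newdata A [feature_table()] or numeric matrix.
#' @return Numeric matrix, cells by phenotypes.
#' @export
decision_scores <- function(model, newdata) {
  X <- model_values(newdata)
  switch(model$method,
    gentle_boost = boost_scores(model, X),
    lda_pinv     = lda_scores(model, X),
    svm_linear   = svm_linear_scores(model, X),
    svm_rbf      = {
      pw <- svm_rbf_pairwise(model, X)
      K <- length(model$classes)
      V <- matrix(0, nrow = nrow(X), ncol = K,
                  dimnames = list(NULL, model$phenotype_names))
      for (p in seq_len(nrow(pw$pairs))) {
        i <- pw$pairs[p, 1]; j <- pw$pairs[p, 2]
        win <- pw$values[, p] > 0
        V[, i] <- V[, i] + win
        V[, j] <- V[, j] + !win
      }
      V
    })
}

#' Predict phenotype labels
#'
#' @param object A fitted `phenoclass_model`.
#' @param newdata A [feature_table()] or numeric matrix.
#' @param ... Unused.
#' @return Integer phenotype indices.
#' @export
predict.phenoclass_model <- function(object, newdata, ...) {
  if (object$method == "svm_rbf") {
    X <- model_values(newdata)
    K <- length(object$classes)
    pr <- predict(object$fit, X)
    return(as.integer(as.character(pr)))
  }
  S <- decision_scores(object, newdata)
  max.col(S, ties.method = "first")
}

#' Calibrate a model's posterior probabilities by Platt scaling
#'
#' Per-class (one-vs-all methods) or per-pair (one-vs-one RBF SVM) sigmoids
#' are fitted by regularized maximum likelihood on *cross-fitted* decision
#' scores: the training table is split into `cv` stratified folds, the model
#' is refitted with the same hyperparameters on each complement and scored
#' on the held-out fold, so the calibration data are out-of-sample.  This
#' guards against the optimistic calibration that resubstitution scores
#' would give.
#'
#' @param model A fitted `phenoclass_model`.
#' @param ft The training [feature_table()] the model was fitted on.
#' @param cv Number of internal calibration folds (default 3).
#' @param seed Seed for the internal fold split.
#' @return The model with a `platt` component; [predict_posterior()] then
#'   returns calibrated probabilities.
#' @export
platt_calibrate <- function(model, ft, cv = 3L, seed = 1L) {
  folds <- stratified_kfold(ft$labels, k = cv, seed = seed)
  K <- length(model$classes)
  n <- nrow(ft$values)
  if (model$method == "svm_rbf") {
    npair <- K * (K - 1) / 2
    oos <- matrix(NA_real_, nrow = n, ncol = npair)
    pair_idx <- NULL
    for (f in seq_len(cv)) {
      tr <- folds$fold != f; te <- !tr
      sub <- refit_model(model, subset_cells(ft, tr))
      pw <- svm_rbf_pairwise(sub, ft$values[te, , drop = FALSE])
      if (is.null(pair_idx)) pair_idx <- pw$pairs
      ## align columns by pair id in case libsvm orders them differently
      key <- paste(pw$pairs[, 1], pw$pairs[, 2])
      ref <- paste(pair_idx[, 1], pair_idx[, 2])
      oos[te, ] <- pw$values[, match(ref, key), drop = FALSE]
    }
    sigs <- vector("list", npair)
    for (p in seq_len(npair)) {
      i <- pair_idx[p, 1]; j <- pair_idx[p, 2]
      keep <- ft$labels %in% c(i, j) & !is.na(oos[, p])
      y <- ifelse(ft$labels[keep] == i, 1, -1)
      sigs[[p]] <- fit_platt_sigmoid(oos[keep, p], y)
    }
    model$platt <- list(type = "pairwise", pairs = pair_idx, sigmoids = sigs)
  } else {
    oos <- matrix(NA_real_, nrow = n, ncol = K)
    for (f in seq_len(cv)) {
      tr <- folds$fold != f; te <- !tr
      sub <- refit_model(model, subset_cells(ft, tr))
      oos[te, ] <- decision_scores(sub, ft$values[te, , drop = FALSE])
    }
    sigs <- vector("list", K)
    for (k in seq_len(K)) {
      y <- ifelse(ft$labels == k, 1, -1)
      sigs[[k]] <- fit_platt_sigmoid(oos[, k], y)
    }
    model$platt <- list(type = "per_class", sigmoids = sigs)
  }
  model
}

## Refit with the hyperparameters already chosen for `model`.
refit_model <- function(model, ft) {
  switch(model$method,
    gentle_boost = fit_gentle_boost(ft, n_stumps = model$n_stumps),
    lda_pinv     = fit_lda_pinv(ft),
    svm_linear   = fit_svm_linear(ft, C = model$C),
    svm_rbf      = fit_svm_rbf(ft, C = model$C, gamma = model$gamma))
}

#' Posterior phenotype probabilities
#'
#' For Platt-calibrated one-vs-all models, per-class sigmoid outputs are
#' normalized to sum to one; for the calibrated one-vs-one RBF SVM, pairwise
#' sigmoid probabilities are combined by pairwise coupling.  LDA needs no
#' calibration: its native Gaussian posteriors are returned.  Rows sum to 1
#' within 1e-9.
#'
#' @param model A fitted (and, for the SVMs and boosting, Platt-calibrated)
#'   `phenoclass_model`.
#' @param newdata A [feature_table()] or numeric matrix.
#' @return Numeric matrix of posteriors, cells by phenotypes.
#' @export
predict_posterior <- function(model, newdata) {
  X <- model_values(newdata)
  K <- length(model$classes)
  if (is.null(model$platt)) {
    if (model$method == "lda_pinv") {
      P <- lda_posterior(model, X)
      colnames(P) <- model$phenotype_names
      return(P)
    }
    stop_config("model has no Platt calibration; run platt_calibrate() first")
  }
  if (model$platt$type == "per_class") {
    S <- decision_scores(model, X)
    P <- matrix(0, nrow = nrow(X), ncol = K)
    for (k in seq_len(K))
      P[, k] <- platt_prob(model$platt$sigmoids[[k]], S[, k])
    z <- rowSums(P)
    zero <- z <= 0
    if (any(zero)) { P[zero, ] <- 1 / K; z[zero] <- 1 }
    P <- P / z
  } else {
    pw <- svm_rbf_pairwise(model, X)
    key <- paste(pw$pairs[, 1], pw$pairs[, 2])
    ref <- paste(model$platt$pairs[, 1], model$platt$pairs[, 2])
    vals <- pw$values[, match(ref, key), drop = FALSE]
    P <- matrix(0, nrow = nrow(X), ncol = K)
    for (r in seq_len(nrow(X))) {
      R <- matrix(0, K, K)
      for (p in seq_len(nrow(model$platt$pairs))) {
        i <- model$platt$pairs[p, 1]; j <- model$platt$pairs[p, 2]
        rij <- platt_prob(model$platt$sigmoids[[p]], vals[r, p])
        R[i, j] <- rij
        R[j, i] <- 1 - rij
      }
      P[r, ] <- couple_pairwise(R)
    }
  }
  colnames(P) <- model$phenotype_names
  P
}
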