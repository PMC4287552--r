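## Support vector machines.
##
## svm_linear: one-vs-all L2-regularized L2-loss (squared hinge) linear
## classification.  Each binary problem solves the smooth convex primal
##     min_w  0.5 ||w||^2 + C * sum_i max(0, 1 - y_i w'x~_i)^2
## with the bias absorbed by augmenting x with a constant 1 (the augmented
## coordinate is regularized, as in common linear-SVM practice).  The primal
## is differentiable, so a quasi-Newton solve with an analytic gradient is
## deterministic and exact enough for classification.
##
## svm_rbf: soft-margin Gaussian-kernel SVM with one-vs-one decomposition
## and majority-vote decoding (libsvm via e1071).

squared_hinge_objective <- function(w, Xa, y, C) {
  m <- 1 - y * drop(Xa %*% w)
  viol <- pmax(m, 0)
  0.5 * sum(w * w) + C * sum(viol^2)
}

squared_hinge_gradient <- function(w, Xa, y, C) {
  m <- 1 - y * drop(Xa %*% w)
  act <- m > 0
  g <- w
  if (any(act))
    g <- g - 2 * C * drop(crossprod(Xa[act, , drop = FALSE],
                                    y[act] * m[act]))
  g
}

fit_l2l2_binary <- function(Xa, y, C) {
  w0 <- numeric(ncol(Xa))
  opt <- stats::optim(w0, fn = squared_hinge_objective,
                      gr = squared_hinge_gradient,
                      Xa = Xa, y = y, C = C,
                      method = "L-BFGS-B",
                      control = list(maxit = 500, factr = 1e4))
  opt$par
}

fit_svm_linear_impl <- function(ft, C = 1) {
  if (!is.numeric(C) || length(C) != 1L || C <= 0)
    stop_config("C must be a positive scalar")
  K <- n_phenotypes(ft)
  if (K < 2L) stop_config("svm_linear needs at least 2 phenotypes")
  Xa <- cbind(ft$values, bias = 1)
  W <- matrix(0, nrow = ncol(Xa), ncol = K)
  for (k in seq_len(K)) {
    y <- ifelse(ft$labels == k, 1, -1)
    W[, k] <- fit_l2l2_binary(Xa, y, C)
  }
  structure(list(method = "svm_linear", classes = seq_len(K),
                 phenotype_names = ft$phenotype_names,
                 weights = W, C = C, platt = NULL),
            class = c("svm_linear_model", "phenoclass_model"))
}

svm_linear_scores <- function(model, X) {
  S <- cbind(X, bias = 1) %*% model$weights
  colnames(S) <- model$phenotype_names
  S
}

fit_svm_rbf_impl <- function(ft, C = 1, gamma = NULL) {
  if (!is.numeric(C) || length(C) != 1L || C <= 0)
    stop_config("C must be a positive scalar")
  if (is.null(gamma)) gamma <- 1 / ncol(ft$values)
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0)
    stop_config("gamma must be a positive scalar")
  K <- n_phenotypes(ft)
  if (K < 2L) stop_config("svm_rbf needs at least 2 phenotypes")
  fit <- e1071::svm(x = ft$values,
                    y = factor(ft$labels, levels = seq_len(K)),
                    kernel = "radial", cost = C, gamma = gamma,
                    scale = FALSE)
  structure(list(method = "svm_rbf", classes = seq_len(K),
                 phenotype_names = ft$phenotype_names,
                 fit = fit, C = C, gamma = gamma, platt = NULL),
            class = c("svm_rbf_model", "phenoclass_model"))
}

## Pairwise decision values oriented so that positive favours the first
## class of the libsvm "i/j" pair name.  Returns the n x K(K-1)/2 matrix
## plus the (i, j) index pairs.
svm_rbf_pairwise <- function(model, X) {
  pr <- predict(model$fit, X, decision.values = TRUE)
  dv <- attr(pr, "decision.values")
  nm <- strsplit(colnames(dv), "/", fixed = TRUE)
  pairs <- t(vapply(nm, function(p) as.integer(p), integer(2)))
  list(values = dv, pairs = pairs, predicted = as.integer(as.character(pr)))
}
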