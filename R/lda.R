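## Linear discriminant analysis with a Moore-Penrose pseudo-inverse pooled
## covariance.  The pseudo-inverse makes the discriminant well defined on
## rank-deficient feature matrices (derived features are exact linear
## combinations of others in some screening feature sets), where a standard
## inverse of the pooled covariance does not exist.

fit_lda_pinv_impl <- function(ft) {
  K <- n_phenotypes(ft)
  if (K < 2L) stop_config("LDA needs at least 2 phenotypes")
  counts <- tabulate(ft$labels, nbins = K)
  small <- which(counts < 2L)
  if (length(small))
    stop_data("phenotype(s) with fewer than 2 cells: ",
              paste(ft$phenotype_names[small], collapse = ", "))
  X <- ft$values
  n <- nrow(X); d <- ncol(X)
  means <- matrix(0, nrow = K, ncol = d)
  SSw <- matrix(0, nrow = d, ncol = d)
  for (k in seq_len(K)) {
    Xk <- X[ft$labels == k, , drop = FALSE]
    means[k, ] <- colMeans(Xk)
    Xc <- sweep(Xk, 2, means[k, ], "-")
    SSw <- SSw + crossprod(Xc)
  }
  sigma <- SSw / (n - K)
  sigma_pinv <- MASS::ginv(sigma)
  priors <- counts / n
  structure(list(method = "lda_pinv", classes = seq_len(K),
                 phenotype_names = ft$phenotype_names,
                 means = means, sigma_pinv = sigma_pinv, priors = priors,
                 platt = NULL),
            class = c("lda_pinv_model", "phenoclass_model"))
}

## Linear discriminant scores delta_k(x) = x' S+ mu_k - mu_k' S+ mu_k / 2
## + log pi_k, one column per phenotype.
lda_scores <- function(model, X) {
  M <- model$sigma_pinv %*% t(model$means)      # d x K
  S <- X %*% M
  const <- -0.5 * colSums(t(model$means) * M) + log(model$priors)
  S <- sweep(S, 2, const, "+")
  colnames(S) <- model$phenotype_names
  S
}

## Native Gaussian posteriors: softmax of the discriminant scores.
lda_posterior <- function(model, X) {
  S <- lda_scores(model, X)
  S <- S - apply(S, 1, max)
  P <- exp(S)
  P / rowSums(P)
}
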