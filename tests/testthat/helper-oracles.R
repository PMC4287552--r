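## Shared fixtures and independent oracles used across test files.
## Oracles are deliberately naive (direct loops / textbook formulas) and do
## not share code paths with the package implementation.

## A small well-separated table for smoke checks.
separable_table <- function(K = 3, n_per = 20, d = 4, sep = 8, seed = 11) {
  generate_dataset(synthetic_config(K, rep(n_per, K), d,
                                    class_separation = sep, seed = seed))
}

## Brute-force regression-stump oracle: for every feature and every midpoint
## between consecutive sorted unique values, fit the two-sided stump by
## weighted means and score the weighted squared error directly.
oracle_best_stump <- function(X, y, w) {
  best <- NULL
  for (j in seq_len(ncol(X))) {
    ux <- sort(unique(X[, j]))
    if (length(ux) < 2) next
    for (t in (ux[-1] + ux[-length(ux)]) / 2) {
      above <- X[, j] > t
      b <- sum(w[!above] * y[!above]) / sum(w[!above])
      ab <- sum(w[above] * y[above]) / sum(w[above])
      pred <- ifelse(above, ab, b)
      err <- sum(w * (y - pred)^2)
      if (is.null(best) || err < best$err - 1e-12)
        best <- list(err = err, feature = j, threshold = t,
                     a = ab - b, b = b)
    }
  }
  best
}

## Textbook full-rank LDA scores with an ordinary matrix inverse.
oracle_lda_scores <- function(X_train, labels, X_test) {
  K <- max(labels); d <- ncol(X_train); n <- nrow(X_train)
  mus <- t(sapply(seq_len(K), function(k)
    colMeans(X_train[labels == k, , drop = FALSE])))
  SSw <- matrix(0, d, d)
  for (k in seq_len(K)) {
    Xc <- sweep(X_train[labels == k, , drop = FALSE], 2, mus[k, ], "-")
    SSw <- SSw + t(Xc) %*% Xc
  }
  Sigma_inv <- solve(SSw / (n - K))
  priors <- tabulate(labels, K) / n
  S <- matrix(0, nrow(X_test), K)
  for (k in seq_len(K))
    S[, k] <- X_test %*% Sigma_inv %*% mus[k, ] -
      0.5 * drop(mus[k, ] %*% Sigma_inv %*% mus[k, ]) + log(priors[k])
  S
}

## Random symmetric zero-diagonal dissimilarity for clustering oracles.
random_dissimilarity <- function(K, seed) {
  set.seed(seed)
  M <- matrix(runif(K * K, 0.05, 1), K, K)
  D <- (M + t(M)) / 2
  diag(D) <- 0
  dimnames(D) <- list(paste0("P", 1:K), paste0("P", 1:K))
  D
}

## Cluster partition at each agglomeration level from an hclust-style
## merge matrix, as canonical label vectors (for order-free comparison).
partition_at_levels <- function(merge, K) {
  members <- lapply(seq_len(K), identity)
  parts <- list()
  for (s in seq_len(nrow(merge))) {
    get <- function(e) if (e < 0) list(-e) else members[[K + e]]
    members[[K + s]] <- c(unlist(get(merge[s, 1])), unlist(get(merge[s, 2])))
    lab <- integer(K)
    alive <- setdiff(seq_len(K + s), unlist(lapply(seq_len(s), function(r)
      c(if (merge[r,1] < 0) -merge[r,1] else K + merge[r,1],
        if (merge[r,2] < 0) -merge[r,2] else K + merge[r,2]))))
    ci <- 0
    for (cl in alive) {
      ci <- ci + 1
      mem <- if (cl <= K) cl else members[[cl]]
      lab[unlist(mem)] <- ci
    }
    ## canonicalize: renumber by first appearance
    lab <- match(lab, unique(lab))
    parts[[s]] <- lab
  }
  parts
}
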