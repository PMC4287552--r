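## Gentle boosting with regression stumps, one-vs-all multiclass.
##
## Each binary problem (phenotype k vs rest, targets y in {-1,+1}) is boosted
## for n_stumps rounds: starting from F = 0 and uniform cell weights, every
## round fits the regression stump f(x) = a * 1[x_j > theta] + b minimizing
## the weighted squared error sum_i w_i (y_i - f(x_i))^2 over all features j
## and all midpoint thresholds theta, adds it to F, and reweights
## w_i <- w_i * exp(-y_i f(x_i)) (renormalized).  Prediction is
## argmax_k F_k(x).

## Best stump for one feature: returns c(err, theta, a, b) or NULL if the
## feature is constant.  Thresholds are midpoints between consecutive sorted
## unique values.  For the two-sided stump, the optimal fit at a split is the
## weighted mean of y on each side; with y in {-1,+1} the weighted SSE is
## W - S_lo^2/W_lo - S_hi^2/W_hi (S = sum w*y, W = sum w per side).
best_stump_feature <- function(x, y, w) {
  o <- order(x)
  xs <- x[o]; ys <- y[o]; ws <- w[o]
  n <- length(xs)
  ## candidate split after position i requires xs[i] < xs[i+1]
  ok <- which(xs[-n] < xs[-1])
  if (!length(ok)) return(NULL)
  cw <- cumsum(ws); cwy <- cumsum(ws * ys)
  W <- cw[n]; S <- cwy[n]
  Wlo <- cw[ok]; Slo <- cwy[ok]
  Whi <- W - Wlo; Shi <- S - Slo
  err <- W - Slo^2 / Wlo - Shi^2 / Whi
  best <- which.min(err)                      # lowest threshold on ties
  i <- ok[best]
  theta <- (xs[i] + xs[i + 1]) / 2
  b <- Slo[best] / Wlo[best]                  # mean below
  a <- Shi[best] / Whi[best] - b              # jump so that above = a + b
  c(err[best], theta, a, b)
}

## Exhaustive search over all features; ties broken by lower feature index
## (features scanned in order; strict improvement required to switch).
best_stump <- function(X, y, w) {
  best <- NULL
  for (j in seq_len(ncol(X))) {
    cand <- best_stump_feature(X[, j], y, w)
    if (is.null(cand)) next
    if (is.null(best) || cand[1] < best$err - 1e-12)
      best <- list(err = cand[1], feature = j, threshold = cand[2],
                   a = cand[3], b = cand[4])
  }
  best
}

stump_predict <- function(stump, X) {
  stump$a * (X[, stump$feature] > stump$threshold) + stump$b
}

fit_gentle_boost_binary <- function(X, y, n_stumps) {
  n <- nrow(X)
  w <- rep(1 / n, n)
  Fx <- numeric(n)
  stumps <- vector("list", n_stumps)
  exp_loss <- numeric(n_stumps)
  for (r in seq_len(n_stumps)) {
    st <- best_stump(X, y, w)
    if (is.null(st)) { stumps <- stumps[seq_len(r - 1L)]
                       exp_loss <- exp_loss[seq_len(r - 1L)]; break }
    f <- stump_predict(st, X)
    Fx <- Fx + f
    w <- w * exp(-y * f)
    w <- w / sum(w)
    stumps[[r]] <- st[c("feature", "threshold", "a", "b")]
    exp_loss[r] <- mean(exp(-y * Fx))
  }
  list(stumps = stumps, exp_loss = exp_loss)
}

fit_gentle_boost_impl <- function(ft, n_stumps = 50L) {
  n_stumps <- as.integer(n_stumps)
  if (is.na(n_stumps) || n_stumps < 1L)
    stop_config("n_stumps must be an integer >= 1")
  K <- n_phenotypes(ft)
  if (K < 2L) stop_config("gentle boosting needs at least 2 phenotypes")
  X <- ft$values
  ensembles <- vector("list", K)
  for (k in seq_len(K)) {
    y <- ifelse(ft$labels == k, 1, -1)
    ensembles[[k]] <- fit_gentle_boost_binary(X, y, n_stumps)
  }
  structure(list(method = "gentle_boost", n_stumps = n_stumps,
                 classes = seq_len(K), phenotype_names = ft$phenotype_names,
                 ensembles = ensembles, platt = NULL),
            class = c("gentle_boost_model", "phenoclass_model"))
}

boost_scores <- function(model, X) {
  K <- length(model$ensembles)
  S <- matrix(0, nrow = nrow(X), ncol = K)
  for (k in seq_len(K)) {
    for (st in model$ensembles[[k]]$stumps)
      S[, k] <- S[, k] + stump_predict(st, X)
  }
  colnames(S) <- model$phenotype_names
  S
}
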