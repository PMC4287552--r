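## Platt sigmoid calibration: p(y = +1 | s) = 1 / (1 + exp(A*s + B)),
## fitted by regularized maximum likelihood on decision scores with Platt's
## smoothed targets t+ = (N+ + 1)/(N+ + 2), t- = 1/(N- + 2).

#' Fit a Platt sigmoid to decision scores
#'
#' @param scores Numeric decision scores (larger favours the positive class).
#' @param y Labels in `{-1, +1}` (or logical, `TRUE` = positive).
#' @return A list with sigmoid coefficients `A` and `B` such that
#'   `p = 1 / (1 + exp(A * s + B))`.
#' @export
fit_platt_sigmoid <- function(scores, y) {
  if (is.logical(y)) y <- ifelse(y, 1, -1)
  npos <- sum(y > 0); nneg <- sum(y < 0)
  if (npos == 0L || nneg == 0L)
    stop_data("calibration data must contain both signs")
  t <- ifelse(y > 0, (npos + 1) / (npos + 2), 1 / (nneg + 2))
  log1pexp <- function(f) pmax(f, 0) + log1p(exp(-abs(f)))
  obj <- function(par) {
    f <- par[1] * scores + par[2]
    sum(log1pexp(f) - (1 - t) * f)
  }
  grad <- function(par) {
    f <- par[1] * scores + par[2]
    p <- 1 / (1 + exp(f))
    r <- t - p
    c(sum(r * scores), sum(r))
  }
  init <- c(0, log((nneg + 1) / (npos + 1)))
  opt <- stats::optim(init, fn = obj, gr = grad, method = "BFGS",
                      control = list(maxit = 200, reltol = 1e-12))
  list(A = opt$par[1], B = opt$par[2])
}

platt_prob <- function(sig, scores) 1 / (1 + exp(sig$A * scores + sig$B))

## Pairwise-coupling of one-vs-one class probabilities (Wu & Lin style
## second formulation): minimize sum_{i<j} (r_ji p_i - r_ij p_j)^2 subject
## to sum(p) = 1, solved as an equality-constrained quadratic program; tiny
## negative components are clipped and the vector renormalized.
couple_pairwise <- function(R) {
  K <- nrow(R)
  Q <- matrix(0, K, K)
  for (i in seq_len(K)) {
    for (j in seq_len(K)) {
      if (i == j) next
      Q[i, i] <- Q[i, i] + R[j, i]^2
      Q[i, j] <- Q[i, j] - R[i, j] * R[j, i]
    }
  }
  A <- rbind(cbind(Q, 1), c(rep(1, K), 0))
  b <- c(rep(0, K), 1)
  p <- tryCatch(solve(A, b)[seq_len(K)],
                error = function(e) rep(1 / K, K))
  p <- pmax(p, 0)
  s <- sum(p)
  if (s <= 0) rep(1 / K, K) else p / s
}
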