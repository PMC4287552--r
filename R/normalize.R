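#' Normalize features to \[0, 1\]
#'
#' Each feature column is z-scored (mean 0, sd 1; constant columns map to 0
#' with a warning) and then min-max rescaled to \[0, 1\].  The per-column
#' parameters are returned so that held-out cells can be transformed with
#' statistics learned on the training fold only, via
#' [apply_normalization()].
#'
#' @param ft A [feature_table()] with at least one row.
#' @param warn_constant Warn when a constant column is encountered.
#' @return A list with elements `table` (the normalized `feature_table`) and
#'   `params` (column means, sds, and post-z-score min/max).
#' @export
normalize_features <- function(ft, warn_constant = TRUE) {
  X <- ft$values
  if (nrow(X) < 1L) stop_data("feature table has no rows")
  mu <- colMeans(X)
  sdev <- apply(X, 2, stats::sd)
  const <- !is.finite(sdev) | sdev == 0
  if (any(const) && warn_constant)
    warning("constant feature column(s) mapped to 0: ",
            paste(colnames(X)[const], collapse = ", "))
  sdev[const] <- 1
  Z <- sweep(sweep(X, 2, mu, "-"), 2, sdev, "/")
  zmin <- apply(Z, 2, min)
  zmax <- apply(Z, 2, max)
  rng <- zmax - zmin
  degenerate <- rng == 0
  rng[degenerate] <- 1
  S <- sweep(sweep(Z, 2, zmin, "-"), 2, rng, "/")
  S[, degenerate] <- 0
  params <- list(mean = mu, sd = sdev, zmin = zmin, range = rng,
                 degenerate = degenerate)
  out <- ft
  out$values <- S
  list(table = out, params = params)
}

#' Apply stored normalization parameters to new cells
#'
#' Transforms a held-out feature table (or bare matrix) with the z-score and
#' min-max parameters learned by [normalize_features()] on a training fold.
#' Held-out values can fall outside \[0, 1\]; they are not clipped.
#'
#' @param ft A [feature_table()] or numeric matrix with the same columns the
#'   parameters were fitted on.
#' @param params The `params` element returned by [normalize_features()].
#' @return Object of the same type as `ft`, transformed.
#' @export
apply_normalization <- function(ft, params) {
  X <- if (inherits(ft, "feature_table")) ft$values else as.matrix(ft)
  if (ncol(X) != length(params$mean))
    stop_data("column count does not match normalization parameters")
  Z <- sweep(sweep(X, 2, params$mean, "-"), 2, params$sd, "/")
  S <- sweep(sweep(Z, 2, params$zmin, "-"), 2, params$range, "/")
  S[, params$degenerate] <- 0
  if (inherits(ft, "feature_table")) { ft$values <- S; ft } else S
}
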