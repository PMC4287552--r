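#' Configuration for the synthetic cell-feature generator
#'
#' Describes a Gaussian-mixture feature table with controlled class
#' imbalance, pairwise phenotype confusability and (optionally) exactly
#' linearly dependent feature columns, mimicking the structural properties
#' of expert-labelled screening data sets: strongly imbalanced phenotype
#' counts, features rescalable to \[0,1\], and rank-deficient feature
#' matrices arising from derived features.
#'
#' Class means are placed as follows.  Phenotypes are grouped by the
#' `confusable_pairs` graph; each group's representative (its smallest
#' phenotype index) sits on its own scaled coordinate vertex, so that
#' representatives of different groups are `class_separation` apart (in
#' within-class sd units).  Every other member of a group is displaced from
#' the representative by `(1 - overlap) * class_separation` along a
#' coordinate direction of its own, which makes the planted pair structure
#' the unique closest-pair structure whenever overlaps exceed zero.
#' Within-class covariance is spherical with unit variance, so separation
#' and overlap are single interpretable knobs.
#'
#' @param n_phenotypes Integer `K >= 2`.
#' @param class_counts Integer vector of length `K`, all `>= 2`; the exact
#'   per-phenotype cell counts of the generated table.
#' @param n_features Integer `d >= 2`: number of base (independent) feature
#'   columns.  Must be at least the number of independent mean directions
#'   required (one per phenotype group plus one per displaced member).
#' @param class_separation Nonnegative scalar distance between
#'   non-confusable class means, in within-class sd units.
#' @param confusable_pairs List of `list(pair = c(i, j), overlap = w)` with
#'   distinct valid phenotype indices and overlap strength `w` in \[0,1\];
#'   `w = 1` means identical means.
#' @param n_dependent_features Integer `>= 0`: extra columns appended as
#'   exact linear combinations of the base columns, with coefficients drawn
#'   uniform(-1, 1) from the seeded stream.
#' @param phenotype_names Optional phenotype names (default `"P1".."PK"`).
#' @param seed Integer seed; identical configurations generate bit-identical
#'   tables.
#'
#' @return An object of class `synthetic_config`.
#' @seealso [generate_dataset()], [planted_merge_order()]
#' @export
synthetic_config <- function(n_phenotypes, class_counts, n_features,
                             class_separation = 4,
                             confusable_pairs = list(),
                             n_dependent_features = 0L,
                             phenotype_names = NULL,
                             seed = 1L) {
  K <- as.integer(n_phenotypes)
  if (is.na(K) || K < 2L) stop_config("n_phenotypes must be an integer >= 2")
  class_counts <- as.integer(class_counts)
  if (length(class_counts) != K)
    stop_config("class_counts must have length n_phenotypes = ", K)
  if (any(is.na(class_counts)) || any(class_counts < 2L))
    stop_config("class_counts must all be >= 2")
  d <- as.integer(n_features)
  if (is.na(d) || d < 2L) stop_config("n_features must be an integer >= 2")
  if (!is.numeric(class_separation) || class_separation < 0)
    stop_config("class_separation must be a nonnegative scalar")
  if (length(confusable_pairs)) {
    for (cp in confusable_pairs) {
      if (is.null(cp$pair) || length(cp$pair) != 2L)
        stop_config("confusable_pairs entries need a length-2 'pair'")
      p <- as.integer(cp$pair)
      if (anyNA(p) || any(p < 1L) || any(p > K) || p[1] == p[2])
        stop_config("confusable pair (", paste(cp$pair, collapse = ","),
                    ") must reference distinct phenotype indices in 1..", K)
      w <- cp$overlap
      if (is.null(w) || !is.numeric(w) || w < 0 || w > 1)
        stop_config("overlap strength must lie in [0,1] for pair (",
                    paste(p, collapse = ","), ")")
    }
  }
  ndep <- as.integer(n_dependent_features)
  if (is.na(ndep) || ndep < 0L)
    stop_config("n_dependent_features must be an integer >= 0")
  if (is.null(phenotype_names)) phenotype_names <- paste0("P", seq_len(K))
  cfg <- structure(list(n_phenotypes = K, class_counts = class_counts,
                        n_features = d,
                        class_separation = as.numeric(class_separation),
                        confusable_pairs = confusable_pairs,
                        n_dependent_features = ndep,
                        phenotype_names = as.character(phenotype_names),
                        seed = as.integer(seed)),
                   class = "synthetic_config")
  ## fail early if the mean-placement scheme cannot fit in d dimensions
  mp <- mean_plan(cfg)
  if (d < mp$n_directions)
    stop_config("n_features = ", d, " is smaller than the ", mp$n_directions,
                " independent directions required by n_phenotypes and ",
                "confusable_pairs")
  cfg
}

## Group phenotypes by the confusable-pair graph and assign, per phenotype,
## the coordinate direction and displacement that define its mean.
mean_plan <- function(cfg) {
  K <- cfg$n_phenotypes
  rep_of <- seq_len(K)                     # union-find over pairs
  find <- function(i) { i <- as.integer(i)
                        while (rep_of[i] != i) i <- rep_of[i]; i }
  for (cp in cfg$confusable_pairs) {
    a <- find(min(cp$pair)); b <- find(max(cp$pair))
    if (a != b) rep_of[max(a, b)] <- min(a, b)
  }
  group <- vapply(seq_len(K), find, integer(1))
  reps <- sort(unique(group))
  ## directions: one per group vertex, then one per displaced member
  dir_of <- integer(K); disp <- numeric(K); base_of <- integer(K)
  next_dir <- 0L
  for (g in reps) { next_dir <- next_dir + 1L; dir_of[g] <- next_dir }
  displaced <- setdiff(seq_len(K), reps)
  for (m in displaced) { next_dir <- next_dir + 1L; dir_of[m] <- next_dir }
  ## displacement magnitude: member m paired (directly or transitively) with
  ## its group representative; use the overlap of the pair that links m.
  overlap_of <- rep(NA_real_, K)
  for (cp in cfg$confusable_pairs) {
    p <- as.integer(cp$pair)
    m <- max(p)
    if (is.na(overlap_of[m]) || cp$overlap > overlap_of[m])
      overlap_of[m] <- cp$overlap
  }
  for (m in displaced) {
    w <- overlap_of[m]
    if (is.na(w)) w <- 0           # chained member without a direct pair
    disp[m] <- (1 - w) * cfg$class_separation
    base_of[m] <- group[m]
  }
  list(group = group, reps = reps, dir_of = dir_of, disp = disp,
       base_of = base_of, displaced = displaced,
       n_directions = next_dir)
}

#' Generate a synthetic feature table
#'
#' Draws `sum(class_counts)` cells from the Gaussian mixture described by a
#' [synthetic_config()]: each phenotype is a spherical unit-variance
#' Gaussian around its planted mean, and `n_dependent_features` extra
#' columns are exact linear combinations of the base columns.  One RNG
#' stream seeded by `config$seed` is consumed in a fixed order (cells
#' class-by-class, then dependent-column coefficients), so identical
#' configurations give bit-identical tables.
#'
#' @param config A [synthetic_config()].
#' @return A [feature_table()] with `sum(class_counts)` rows and
#'   `n_features + n_dependent_features` columns.
#' @export
generate_dataset <- function(config) {
  if (!inherits(config, "synthetic_config"))
    stop_config("config must be a synthetic_config")
  K <- config$n_phenotypes; d <- config$n_features
  mp <- mean_plan(config)
  ## representatives at (separation / sqrt(2)) * e_g: pairwise distance
  ## between group vertices is exactly class_separation
  a <- config$class_separation / sqrt(2)
  means <- matrix(0, nrow = K, ncol = d)
  for (g in mp$reps) means[g, mp$dir_of[g]] <- a
  for (m in mp$displaced) {
    means[m, ] <- means[mp$base_of[m], ]
    means[m, mp$dir_of[m]] <- means[m, mp$dir_of[m]] + mp$disp[m]
  }
  with_seed(config$seed, {
    n <- sum(config$class_counts)
    X <- matrix(NA_real_, nrow = n, ncol = d)
    labels <- integer(n)
    at <- 0L
    for (k in seq_len(K)) {
      nk <- config$class_counts[k]
      rows <- at + seq_len(nk)
      X[rows, ] <- matrix(rnorm(nk * d), nrow = nk, ncol = d) +
        matrix(means[k, ], nrow = nk, ncol = d, byrow = TRUE)
      labels[rows] <- k
      at <- at + nk
    }
    if (config$n_dependent_features > 0L) {
      coefs <- matrix(runif(d * config$n_dependent_features, -1, 1),
                      nrow = d)
      dep <- X %*% coefs
      colnames(dep) <- paste0("dep", seq_len(config$n_dependent_features))
      X <- cbind(X, dep)
    }
    colnames(X)[seq_len(d)] <- paste0("f", seq_len(d))
    feature_table(X, labels, phenotype_names = config$phenotype_names)
  })
}

#' Planted merge order of a synthetic configuration
#'
#' The merge order an ideal confusion-driven clustering should recover:
#' confusable pairs sorted by descending overlap strength, ties broken by
#' the smaller first phenotype index (then the smaller second index).
#'
#' @param config A [synthetic_config()] with non-empty `confusable_pairs`.
#' @return A list of length-2 integer vectors (each sorted ascending).
#' @export
planted_merge_order <- function(config) {
  if (!length(config$confusable_pairs))
    stop_config("confusable_pairs is empty; no planted merge order exists")
  pairs <- lapply(config$confusable_pairs,
                  function(cp) sort(as.integer(cp$pair)))
  w <- vapply(config$confusable_pairs, function(cp) as.numeric(cp$overlap),
              numeric(1))
  i1 <- vapply(pairs, `[`, integer(1), 1L)
  i2 <- vapply(pairs, `[`, integer(1), 2L)
  pairs[order(-w, i1, i2)]
}
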