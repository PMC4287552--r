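#' Build a phenotype dissimilarity matrix from confusion matrices
#'
#' The confusion matrices (one per classifier, same phenotype set and
#' orientation) are element-wise averaged; upper and lower triangles of the
#' average are added to give a symmetric matrix of total confusions; each
#' row is divided by its row sum; and the result is subtracted from one to
#' give a dissimilarity.  Because row-normalizing a symmetric matrix breaks
#' symmetry whenever row sums differ, the final matrix is re-symmetrized by
#' averaging with its transpose, the minimal correction that satisfies the
#' clustering input contract.
#'
#' @param confusions A confusion matrix or list of them (counts, rows true /
#'   columns predicted, identical dimnames).
#' @param exclude_diagonal Drop correct classifications from the row sums
#'   before normalizing (default keeps them, so frequently-correct
#'   phenotypes look less confusable overall).
#' @return A symmetric, zero-diagonal dissimilarity matrix with phenotype
#'   dimnames.
#' @export
build_dissimilarity <- function(confusions, exclude_diagonal = FALSE) {
  if (is.matrix(confusions)) confusions <- list(confusions)
  if (!length(confusions)) stop_config("no confusion matrices supplied")
  dims <- vapply(confusions, nrow, integer(1))
  if (length(unique(dims)) != 1L || any(dims != ncol(confusions[[1]])))
    stop_config("confusion matrices must share a square phenotype set")
  A <- Reduce(`+`, lapply(confusions, function(m) m / length(confusions)))
  K <- nrow(A)
  S <- A + t(A)
  diag(S) <- diag(A)
  rs <- rowSums(S)
  if (exclude_diagonal) rs <- rs - diag(S)
  if (any(rs == 0)) {
    nm <- rownames(A) %||% as.character(seq_len(K))
    stop_data("phenotype(s) with zero confusion row sum: ",
              paste(nm[rs == 0], collapse = ", "))
  }
  N <- S / rs
  D <- 1 - N
  diag(D) <- 0
  D <- (D + t(D)) / 2
  dimnames(D) <- list(rownames(A), rownames(A))   # drop true/predicted roles
  D
}

validate_dissimilarity <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D))
    stop_config("dissimilarity must be a square matrix")
  if (nrow(D) < 2L) stop_config("need at least 2 phenotypes to cluster")
  if (any(!is.finite(D))) stop_data("dissimilarity has non-finite entries")
  if (max(abs(D - t(D))) > 1e-12) stop_data("dissimilarity is not symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop_data("dissimilarity diagonal not zero")
  invisible(D)
}

#' UPGMA merge ladder of a phenotype dissimilarity
#'
#' Standard unweighted pair-group agglomeration: starting from singleton
#' clusters, the closest pair (ties broken by the lexicographically smallest
#' cluster-id pair) is merged at its distance, and distances to the merged
#' cluster are the unweighted arithmetic means over all member pairs.  The
#' full ladder of `K - 1` merge events is returned together with, for every
#' level `m` in `K..2`, the map from original phenotype index to the level's
#' cluster labels (merged clusters are named by hyphen-joining their member
#' names).
#'
#' @param D A symmetric zero-diagonal dissimilarity matrix, e.g. from
#'   [build_dissimilarity()].
#' @return A `merge_ladder`: `events` data frame (`step`, `cluster_a`,
#'   `cluster_b`, `height`, `new_id`), `level_maps` (named by level), the
#'   phenotype names, and an `hclust`-compatible representation.
#' @export
upgma <- function(D) {
  validate_dissimilarity(D)
  K <- nrow(D)
  phen <- rownames(D) %||% paste0("P", seq_len(K))
  d <- D
  active <- seq_len(K)             # current cluster ids (1..K originals)
  size <- rep(1L, K)
  members <- as.list(seq_len(K))   # original phenotype indices per cluster
  id_of <- seq_len(K)              # column position -> cluster id
  events <- data.frame(step = integer(0), cluster_a = integer(0),
                       cluster_b = integer(0), height = numeric(0),
                       new_id = integer(0))
  hc_merge <- matrix(0L, nrow = K - 1L, ncol = 2)
  hc_height <- numeric(K - 1L)
  hc_row_of <- integer(2L * K)     # cluster id -> hclust row (0 = singleton)
  level_maps <- list()
  snapshot <- function(mem, level) {
    ord <- order(vapply(mem, min, integer(1)))
    map <- integer(K); nms <- character(length(mem))
    for (ci in seq_along(ord)) {
      m <- mem[[ord[ci]]]
      map[m] <- ci
      nms[ci] <- paste(phen[sort(m)], collapse = "-")
    }
    list(map = map, names = nms)
  }
  level_maps[[as.character(K)]] <- snapshot(members, K)
  next_id <- K
  for (step in seq_len(K - 1L)) {
    ## closest active pair; ties -> lexicographically smallest id pair
    nA <- length(id_of)
    best <- NULL
    for (i in seq_len(nA - 1L)) {
      for (j in (i + 1L):nA) {
        a <- min(id_of[i], id_of[j]); b <- max(id_of[i], id_of[j])
        dij <- d[i, j]
        if (is.null(best) || dij < best$d - 1e-15 ||
            (abs(dij - best$d) <= 1e-15 &&
             (a < best$a || (a == best$a && b < best$b)))) {
          best <- list(i = i, j = j, d = dij, a = a, b = b)
        }
      }
    }
    i <- min(best$i, best$j); j <- max(best$i, best$j)
    next_id <- next_id + 1L
    events <- rbind(events,
                    data.frame(step = step, cluster_a = best$a,
                               cluster_b = best$b, height = best$d,
                               new_id = next_id))
    enc <- function(id) if (hc_row_of[id] > 0L) hc_row_of[id] else -id
    hc_merge[step, ] <- sort(c(enc(best$a), enc(best$b)))
    hc_height[step] <- best$d
    hc_row_of[next_id] <- step
    ## unweighted average-linkage update
    ni <- size[i]; nj <- size[j]
    newrow <- (ni * d[i, ] + nj * d[j, ]) / (ni + nj)
    d[i, ] <- newrow; d[, i] <- newrow; d[i, i] <- 0
    members[[i]] <- c(members[[i]], members[[j]])
    size[i] <- ni + nj
    id_of[i] <- next_id
    d <- d[-j, -j, drop = FALSE]
    members <- members[-j]; size <- size[-j]; id_of <- id_of[-j]
    if (K - step >= 2L)
      level_maps[[as.character(K - step)]] <- snapshot(members, K - step)
  }
  leaf_order <- function(row) {
    unlist(lapply(hc_merge[row, ], function(e)
      if (e < 0L) -e else leaf_order(e)))
  }
  hc <- structure(list(merge = hc_merge, height = hc_height,
                       order = leaf_order(K - 1L), labels = phen,
                       method = "average", call = match.call()),
                  class = "hclust")
  structure(list(events = events, level_maps = level_maps,
                 phenotype_names = phen, hclust = hc),
            class = "merge_ladder")
}

#' @export
print.merge_ladder <- function(x, ...) {
  K <- length(x$phenotype_names)
  cat("merge_ladder:", K, "phenotypes,", nrow(x$events), "merge events\n")
  for (s in seq_len(nrow(x$events))) {
    lm <- x$level_maps[[as.character(K - s + 1L)]]
    cat(sprintf("  step %d: height %.4f -> %d clusters\n",
                s, x$events$height[s], K - s))
  }
  invisible(x)
}

#' Relabel a feature table at a ladder level
#'
#' @param ft The original [feature_table()].
#' @param ladder A [upgma()] merge ladder built on `ft`'s phenotypes.
#' @param level Number of clusters `m` in `2..K`.
#' @return A `feature_table` whose labels and phenotype names are the
#'   level-`m` merged clusters.
#' @export
relabel_at_level <- function(ft, ladder, level) {
  lm <- ladder$level_maps[[as.character(level)]]
  if (is.null(lm)) stop_config("no level ", level, " in ladder")
  relabel_cells(ft, lm$map, lm$names)
}

#' First merges of a ladder as phenotype-index pairs
#'
#' Returns the first `n` merge events as sorted pairs of *original*
#' phenotype indices; events merging already-merged clusters report the
#' pair of smallest member indices.  Useful for comparing against a planted
#' merge order.
#'
#' @param ladder A [upgma()] ladder.
#' @param n Number of leading events (default all).
#' @return List of length-2 integer vectors.
#' @export
ladder_first_merges <- function(ladder, n = nrow(ladder$events)) {
  K <- length(ladder$phenotype_names)
  members <- as.list(seq_len(K))
  names(members) <- as.character(seq_len(K))
  out <- vector("list", n)
  for (s in seq_len(n)) {
    ev <- ladder$events[s, ]
    ma <- members[[as.character(ev$cluster_a)]]
    mb <- members[[as.character(ev$cluster_b)]]
    out[[s]] <- sort(c(min(ma), min(mb)))
    members[[as.character(ev$new_id)]] <- c(ma, mb)
  }
  out
}

#' Export a merge ladder as a Newick tree
#'
#' The dendrogram is converted to a phylogenetic tree with ultrametric
#' branch lengths derived from the merge heights.
#'
#' @param ladder A [upgma()] ladder.
#' @return A Newick string (also suitable for [ape::write.tree()]).
#' @export
ladder_newick <- function(ladder) {
  ape::write.tree(ape::as.phylo(ladder$hclust))
}

#' Evaluate classifiers along the merge ladder
#'
#' Runs level-`K` cross-validation for every specification, averages the
#' confusion matrices of the designated classifier set into a dissimilarity
#' ([build_dissimilarity()]), clusters it once with [upgma()], and then
#' walks the ladder from `K - 1` clusters down to 2, relabeling cells at
#' each level and re-running cross-validation for every specification.  The
#' merging is identical for all classifiers.
#'
#' @param ft A [feature_table()].
#' @param specs A [classifier_spec()] or list of them.
#' @param k,seed Cross-validation folds and seed (same fold seed per level).
#' @param confusion_specs Indices into `specs` whose confusions build the
#'   dissimilarity (default: all).
#' @param exclude_diagonal Passed to [build_dissimilarity()].
#' @param ... Passed to [cross_validate()] (e.g. `tune`).
#' @return A list: `accuracies` (data frame `method`, `level`, `accuracy`),
#'   `ladder`, `dissimilarity`, and the level-`K` `cv_results`.
#' @export
ladder_evaluation <- function(ft, specs, k = 20L, seed = 1L,
                              confusion_specs = NULL,
                              exclude_diagonal = FALSE, ...) {
  if (inherits(specs, "classifier_spec")) specs <- list(specs)
  K <- n_phenotypes(ft)
  if (K < 2L) stop_config("need at least 2 phenotypes")
  top <- lapply(specs, function(sp)
    cross_validate(ft, sp, k = k, seed = seed, ...))
  confusion_specs <- confusion_specs %||% seq_along(specs)
  D <- build_dissimilarity(lapply(top[confusion_specs], `[[`, "confusion"),
                           exclude_diagonal = exclude_diagonal)
  ladder <- upgma(D)
  rows <- list()
  for (s in seq_along(specs))
    rows[[length(rows) + 1L]] <-
      data.frame(method = specs[[s]]$method, level = K,
                 accuracy = top[[s]]$accuracy)
  for (m in seq(K - 1L, 2L)) {
    ft_m <- relabel_at_level(ft, ladder, m)
    for (s in seq_along(specs)) {
      res <- tryCatch(cross_validate(ft_m, specs[[s]], k = k, seed = seed, ...),
                      error = function(e)
                        stop_data("level ", m, ": ", conditionMessage(e)))
      rows[[length(rows) + 1L]] <-
        data.frame(method = specs[[s]]$method, level = m,
                   accuracy = res$accuracy)
    }
  }
  list(accuracies = do.call(rbind, rows), ladder = ladder,
       dissimilarity = D, cv_results = top)
}
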