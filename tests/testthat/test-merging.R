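test_that("dissimilarity construction follows the stated arithmetic", {
  A <- matrix(c(8, 4, 2, 6), 2, 2)   # rows true: [[8,2],[4,6]]
  dimnames(A) <- list(c("a", "b"), c("a", "b"))
  D <- build_dissimilarity(A)
  ## S off-diag = 6 both ways, rows (14, 12); D12 = 1 - mean(6/14, 6/12)
  expect_equal(D["a", "b"], 1 - (6 / 14 + 6 / 12) / 2)
  expect_equal(D["a", "b"], 0.5357142857, tolerance = 1e-9)
  expect_equal(diag(D), c(a = 0, b = 0))
  expect_equal(D, t(D))
})

test_that("error-free confusion gives maximal dissimilarity", {
  A <- diag(c(10, 20, 30))
  dimnames(A) <- list(paste0("P", 1:3), paste0("P", 1:3))
  D <- build_dissimilarity(A)
  off <- D[upper.tri(D)]
  expect_true(all(off == 1))
})

test_that("averaging duplicate confusions is idempotent and rows can't be empty", {
  A <- matrix(c(8, 4, 2, 6), 2, 2)
  expect_equal(build_dissimilarity(list(A, A)), build_dissimilarity(A))
  bad <- matrix(c(5, 0, 0, 0), 2, 2,
                dimnames = list(c("ok", "gone"), c("ok", "gone")))
  expect_error(build_dissimilarity(bad), "gone")
})

test_that("UPGMA reproduces the hand-worked three-leaf ladder", {
  D <- matrix(c(0, .2, .6, .2, 0, .8, .6, .8, 0), 3, 3,
              dimnames = list(paste0("P", 1:3), paste0("P", 1:3)))
  lad <- upgma(D)
  expect_equal(nrow(lad$events), 2)
  expect_equal(lad$events$cluster_a[1], 1)
  expect_equal(lad$events$cluster_b[1], 2)
  expect_equal(lad$events$height, c(0.2, 0.7))
  ## two-leaf case: single merge at the only distance
  D2 <- matrix(c(0, .3, .3, 0), 2, 2,
               dimnames = list(c("x", "y"), c("x", "y")))
  expect_equal(upgma(D2)$events$height, 0.3)
})

test_that("the ladder matches hclust average linkage on random matrices", {
  for (seed in 1:30) {
    K <- sample(3:8, 1)
    D <- random_dissimilarity(K, seed = 1000 + seed)
    lad <- upgma(D)
    hc <- hclust(as.dist(D), method = "average")
    expect_equal(lad$events$height, hc$height, tolerance = 1e-12)
    expect_equal(partition_at_levels(lad$hclust$merge, K),
                 partition_at_levels(hc$merge, K))
  }
})

test_that("merge heights are non-decreasing and level maps compose", {
  D <- random_dissimilarity(7, seed = 99)
  lad <- upgma(D)
  expect_equal(nrow(lad$events), 6)
  expect_true(all(diff(lad$events$height) >= -1e-12))
  K <- 7
  for (m in K:3) {
    hi <- lad$level_maps[[as.character(m)]]$map
    lo <- lad$level_maps[[as.character(m - 1)]]$map
    ## lo must be a coarsening of hi: each hi-cluster maps into one lo-cluster
    expect_true(all(tapply(lo, hi, function(v) length(unique(v))) == 1))
    expect_equal(sort(unique(hi)), seq_len(m))     # surjective
  }
  ## exactly one pair of hi-clusters fuses between adjacent levels
  hi <- lad$level_maps[["7"]]$map; lo <- lad$level_maps[["6"]]$map
  fused <- unique(tapply(hi, lo, function(v) length(unique(v))))
  expect_equal(sort(unique(as.integer(tapply(hi, lo, function(v)
    length(unique(v)))))), c(1L, 2L))
})

test_that("ladder evaluation walks K..2 and merging helps accuracy", {
  cfg <- synthetic_config(4, rep(45, 4), 8, class_separation = 5,
                          confusable_pairs = list(list(pair = c(1, 2),
                                                       overlap = .95)),
                          seed = 55)
  ft <- generate_dataset(cfg)
  lad <- ladder_evaluation(ft, classifier_spec("lda_pinv"), k = 10, seed = 6)
  acc <- lad$accuracies
  expect_equal(nrow(acc), 3)           # levels 4, 3, 2 -> K-1 evaluations
  expect_equal(acc$level, c(4, 3, 2))
  ## the first merge recovers the planted overlapping pair
  expect_equal(ladder_first_merges(lad$ladder, 1)[[1]], c(1L, 2L))
  ## merging the most-confused pair cannot hurt much; typically it helps
  expect_gte(acc$accuracy[acc$level == 3],
             acc$accuracy[acc$level == 4])
  ## merged phenotype names are hyphen-joined member names
  expect_true("P1-P2" %in% lad$ladder$level_maps[["3"]]$names)
})

test_that("newick export is a valid ultrametric tree", {
  D <- random_dissimilarity(5, seed = 123)
  lad <- upgma(D)
  nwk <- ladder_newick(lad)
  tree <- ape::read.tree(text = nwk)
  expect_equal(sort(tree$tip.label), paste0("P", 1:5))
  depths <- ape::node.depth.edgelength(tree)
  tipd <- depths[seq_len(5)]
  expect_lt(diff(range(tipd)), 1e-8)
})
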