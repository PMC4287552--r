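test_that("stratified folds split 34 cells over 20 folds as 14x2 + 6x1", {
  labels <- rep(1L, 34)
  folds <- stratified_kfold(labels, k = 20, seed = 1)
  sizes <- tabulate(folds$fold, 20)
  expect_equal(sort(sizes), c(rep(1, 6), rep(2, 14)))
})

test_that("folds partition the cells with the per-phenotype +/-1 bound", {
  set.seed(10)
  for (seed in 1:5) {
    labels <- sample(rep(1:4, times = c(34, 563, 59, 107)))
    k <- sample(c(5, 10, 20), 1)
    folds <- stratified_kfold(labels, k, seed = seed)
    expect_equal(length(folds$fold), length(labels))
    expect_true(all(folds$fold %in% 1:k))
    for (cl in 1:4) {
      sizes <- tabulate(folds$fold[labels == cl], k)
      expect_lte(diff(range(sizes)), 1)
    }
  }
  ## singletons land in exactly one fold; determinism
  f1 <- stratified_kfold(c(1L, 2L, 2L, 2L), 3, seed = 7)
  expect_equal(sum(f1$fold[1] == f1$fold[1]), 1)
  expect_identical(f1, stratified_kfold(c(1L, 2L, 2L, 2L), 3, seed = 7))
  expect_error(stratified_kfold(1:5, k = 1), "k")
})

test_that("default SVM grids have the documented cardinalities", {
  rbf <- classifier_spec("svm_rbf")
  expect_equal(length(rbf$C_grid), 8)
  expect_equal(length(rbf$gamma_grid), 7)
  expect_equal(length(rbf$C_grid) * length(rbf$gamma_grid), 56)
  lin <- classifier_spec("svm_linear")
  expect_equal(length(lin$C_grid), 12)
})

test_that("grid search returns single points untouched and breaks ties low", {
  ft <- separable_table(K = 2, n_per = 20, d = 3, sep = 6, seed = 3)
  one <- grid_search_cv(ft, classifier_spec("svm_linear", C_grid = 4),
                        seed = 1)
  expect_equal(one$C, 4)
  ## separable data: every C wins every fold, so the tie-break gives min C
  h <- grid_search_cv(ft, classifier_spec("svm_linear", C_grid = c(8, 1, 2)),
                      seed = 1)
  expect_equal(h$C, 1)
})

test_that("accuracy is trace over total of the pooled confusion", {
  cm <- matrix(c(9, 2, 1, 8), 2)
  expect_equal(confusion_accuracy(cm), 17 / 20)
  ft <- separable_table(K = 3, n_per = 25, d = 4, sep = 8, seed = 41)
  res <- cross_validate(ft, classifier_spec("lda_pinv"), k = 5, seed = 2)
  expect_equal(res$accuracy, 1)
  expect_true(all(res$confusion[upper.tri(res$confusion)] == 0))
  expect_true(all(res$confusion[lower.tri(res$confusion)] == 0))
  expect_equal(sum(res$confusion), 75)
  expect_equal(res$accuracy,
               sum(diag(res$confusion)) / sum(res$confusion))
})

test_that("cross-validation is reproducible given the same seed", {
  ft <- generate_dataset(synthetic_config(
    3, c(30, 40, 35), 5, class_separation = 2, seed = 15))
  a <- cross_validate(ft, classifier_spec("gentle_boost", n_stumps = 5),
                      k = 5, seed = 9)
  b <- cross_validate(ft, classifier_spec("gentle_boost", n_stumps = 5),
                      k = 5, seed = 9)
  expect_identical(a$predicted, b$predicted)
  expect_identical(a$confusion, b$confusion)
})

test_that("permuted labels score near the majority-class frequency", {
  ft <- generate_dataset(synthetic_config(
    3, c(60, 30, 30), 5, class_separation = 5, seed = 25))
  set.seed(77)
  ft$labels <- sample(ft$labels)
  res <- cross_validate(ft, classifier_spec("lda_pinv"), k = 10, seed = 1)
  p_max <- 60 / 120
  sd3 <- 3 * sqrt(p_max * (1 - p_max) / 120)
  expect_lt(res$accuracy, p_max + sd3)
})

test_that("subsampling uses round-with-minimum-one per-phenotype counts", {
  ft <- generate_dataset(synthetic_config(
    2, c(34, 563), 4, class_separation = 6, seed = 33))
  out <- subsample_experiment(ft, classifier_spec("lda_pinv"),
                              fractions = 1/2, repeats = 2, k = 5, seed = 1)
  expect_true(all(out$runs$n_cells == 17 + 282))
  ## fraction 1 is a single repeat identical to plain cross-validation
  full <- subsample_experiment(ft, classifier_spec("lda_pinv"),
                               fractions = 1, repeats = 5, k = 5, seed = 4)
  expect_equal(nrow(full$runs), 1)
  plain <- cross_validate(ft, classifier_spec("lda_pinv"), k = 5,
                          seed = phenoclass:::derive_seed(4, 1))
  expect_equal(full$runs$accuracy, plain$accuracy)
  expect_error(subsample_experiment(ft, classifier_spec("lda_pinv"),
                                    fractions = 0), "fractions")
})
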