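test_that("generated tables honour class counts, imbalance and determinism", {
  counts <- ht29_phenotype_counts()$cells
  cfg <- synthetic_config(14, counts, 16, class_separation = 3, seed = 5)
  ft <- generate_dataset(cfg)
  expect_equal(nrow(ft$values), 2526)
  expect_equal(tabulate(ft$labels, 14), counts)

  ## same config (incl. seed) => bit-identical serialized table
  ft2 <- generate_dataset(cfg)
  expect_identical(serialize(ft, NULL), serialize(ft2, NULL))

  ## different seed => different values
  cfg2 <- synthetic_config(14, counts, 16, class_separation = 3, seed = 6)
  expect_false(identical(generate_dataset(cfg2)$values, ft$values))
})

test_that("dependent columns are exact linear combinations (rank check)", {
  cfg <- synthetic_config(3, c(20, 20, 20), 10, class_separation = 4,
                          n_dependent_features = 3, seed = 2)
  ft <- generate_dataset(cfg)
  expect_equal(ncol(ft$values), 13)
  expect_equal(qr(ft$values)$rank, 10)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(synthetic_config(1, c(10), 5), "n_phenotypes")
  expect_error(synthetic_config(2, c(10, 1), 5), "class_counts")
  expect_error(synthetic_config(2, c(10, 10), 1), "n_features")
  expect_error(synthetic_config(2, c(10, 10), 5, class_separation = -1),
               "class_separation")
  expect_error(synthetic_config(3, c(10, 10, 10), 5,
                                confusable_pairs = list(list(pair = c(1, 1),
                                                             overlap = .5))),
               "distinct")
  expect_error(synthetic_config(3, c(10, 10, 10), 5,
                                confusable_pairs = list(list(pair = c(1, 4),
                                                             overlap = .5))),
               "distinct|1..3")
  ## too few feature dimensions for the required mean directions
  expect_error(synthetic_config(5, rep(10, 5), 2), "n_features")
})

test_that("planted merge order sorts by strength with index tie-breaks", {
  base <- function(pairs) synthetic_config(6, rep(10, 6), 10,
                                           confusable_pairs = pairs)
  cfg <- base(list(list(pair = c(3, 4), overlap = .4),
                   list(pair = c(1, 2), overlap = .9)))
  expect_equal(planted_merge_order(cfg), list(c(1L, 2L), c(3L, 4L)))

  cfg <- base(list(list(pair = c(1, 3), overlap = .5),
                   list(pair = c(1, 2), overlap = .5)))
  expect_equal(planted_merge_order(cfg), list(c(1L, 2L), c(1L, 3L)))

  cfg <- base(list(list(pair = c(5, 2), overlap = .1)))
  expect_equal(planted_merge_order(cfg), list(c(2L, 5L)))

  expect_error(planted_merge_order(synthetic_config(3, rep(10, 3), 5)),
               "confusable_pairs")
})

test_that("fully overlapping identical classes classify at chance", {
  cfg <- synthetic_config(2, c(60, 60), 4, class_separation = 0,
                          confusable_pairs = list(list(pair = c(1, 2),
                                                       overlap = 1)),
                          seed = 9)
  ft <- generate_dataset(cfg)
  res <- cross_validate(ft, classifier_spec("lda_pinv"), k = 10, seed = 3)
  ## chance is 0.5; 3 binomial sd over 120 cells is ~0.137
  expect_lt(abs(res$accuracy - 0.5), 3 * sqrt(0.25 / 120))
})

test_that("well-separated classes are almost perfectly classifiable", {
  cfg <- synthetic_config(3, rep(50, 3), 6, class_separation = 6, seed = 4)
  ft <- generate_dataset(cfg)
  res <- cross_validate(ft, classifier_spec("svm_linear", C_grid = 1),
                        k = 20, seed = 1, tune = "once")
  expect_gte(res$accuracy, 0.99)
})

test_that("a fully confusable planted pair dominates the confusion matrix", {
  cfg <- synthetic_config(4, rep(100, 4), 8, class_separation = 6,
                          confusable_pairs = list(list(pair = c(2, 3),
                                                       overlap = 1)),
                          seed = 21)
  ft <- generate_dataset(cfg)
  res <- cross_validate(ft, classifier_spec("lda_pinv"), k = 10, seed = 2)
  cm <- res$confusion
  off <- cm; diag(off) <- 0
  planted <- off[2, 3] + off[3, 2]
  others <- off; others[2, 3] <- 0; others[3, 2] <- 0
  expect_gt(off[2, 3], max(others))
  expect_gt(off[3, 2], max(others))
  expect_gt(planted, 0)
})
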