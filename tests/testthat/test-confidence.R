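test_that("overlap fraction follows its set definition", {
  expect_equal(overlap_fraction(c("1", "2", "3", "4"),
                                c("1", "2", "3", "5", "6")), 0.75)
  expect_equal(overlap_fraction(c("a", "b"), c("a", "b", "c")), 1)
  expect_equal(overlap_fraction(c("a", "b"), c("x")), 0)
  expect_equal(overlap_fraction(c("a"), c("a")), 1)
  expect_error(overlap_fraction(character(0), c("a")), "empty")
})

test_that("consensus counts respect bounds and degenerate settings", {
  ft <- generate_dataset(synthetic_config(
    3, c(30, 30, 30), 5, class_separation = 2,
    confusable_pairs = list(list(pair = c(1, 2), overlap = .8)), seed = 61))
  cons <- consensus_misclassified(ft, classifier_spec("lda_pinv"),
                                  runs = 6, k = 5, min_wrong = 5,
                                  base_seed = 3)
  expect_true(all(cons$counts >= 0 & cons$counts <= 6))
  expect_true(all(cons$flagged %in% ft$cell_ids[cons$counts >= 5]))
  ## runs = 1, min_wrong = 1: flagged set is that run's misclassified cells
  one <- consensus_misclassified(ft, classifier_spec("lda_pinv"),
                                 runs = 1, k = 5, min_wrong = 1,
                                 base_seed = 3)
  res <- cross_validate(ft, classifier_spec("lda_pinv"), k = 5, seed = 4)
  expect_setequal(one$flagged, ft$cell_ids[res$predicted != ft$labels])
  ## perfectly separable data flags nothing
  sep <- separable_table(K = 3, n_per = 20, sep = 9, seed = 71)
  none <- consensus_misclassified(sep, classifier_spec("lda_pinv"),
                                  runs = 3, k = 5, min_wrong = 2,
                                  base_seed = 1)
  expect_length(none$flagged, 0)
  expect_error(consensus_misclassified(ft, classifier_spec("lda_pinv"),
                                       runs = 5, min_wrong = 6), "min_wrong")
})

test_that("consensus counts are exchangeable in run order", {
  ft <- generate_dataset(synthetic_config(
    2, c(40, 40), 4, class_separation = 1.5, seed = 83))
  spec <- classifier_spec("lda_pinv")
  a <- consensus_misclassified(ft, spec, runs = 4, k = 5, min_wrong = 3,
                               base_seed = 10)
  ## same seeds, accumulated in a different order
  wrong <- integer(nrow(ft$values))
  for (r in c(3, 1, 4, 2)) {
    res <- cross_validate(ft, spec, k = 5, seed = 10L + r, tune = "none")
    wrong <- wrong + (res$predicted != ft$labels)
  }
  expect_equal(a$counts, wrong)
})

test_that("the exclusion threshold matches its definition and a grid scan", {
  P <- rbind(c(.3, .7, 0), c(.25, .35, .4),     # phenotype peaks: .7/.4 ...
             c(.6, .2, .2), c(.5, .3, .2),
             c(.1, .1, .8))
  labels <- c(1L, 1L, 2L, 2L, 3L)
  got <- phenotype_exclusion_threshold(P, labels)
  expect_equal(got$threshold, 0.6)               # phenotype 2 peaks at 0.6
  expect_equal(got$phenotype, 2L)
  ## grid-scan oracle at 1e-3 on random posteriors
  set.seed(5)
  for (i in 1:10) {
    n <- 40; K <- 4
    raw <- matrix(rexp(n * K), n, K)
    Pr <- raw / rowSums(raw)
    lab <- sample.int(K, n, replace = TRUE)
    while (length(unique(lab)) < K) lab <- sample.int(K, n, replace = TRUE)
    t_star <- phenotype_exclusion_threshold(Pr, lab)$threshold
    grid <- seq(0, 1, by = 1e-3)
    maxp <- apply(Pr, 1, max)
    excluded <- vapply(grid, function(t)
      any(tapply(maxp >= t, lab, sum) == 0), logical(1))
    scan <- grid[which(excluded)[1]]
    expect_lt(abs(scan - t_star), 1e-3 + 1e-9)
    ## at t = t_star (inclusive rule) every phenotype still has a cell
    expect_true(all(tapply(maxp >= t_star, lab, sum) > 0))
  }
})

test_that("threshold curves are identity at zero and monotone in coverage", {
  ft <- generate_dataset(synthetic_config(
    3, c(40, 40, 40), 6, class_separation = 2.5,
    confusable_pairs = list(list(pair = c(2, 3), overlap = .6)), seed = 91))
  res <- cross_validate(ft, classifier_spec("svm_linear", C_grid = 1),
                        k = 5, seed = 2, tune = "none",
                        hyper = list(C = 1), posterior = TRUE)
  curve <- suppressWarnings(
    threshold_curve(res$posterior, ft$labels, res$predicted))
  expect_equal(curve$fraction_included[1], 1)
  expect_equal(curve$accuracy[1], res$accuracy)
  expect_true(all(diff(curve$fraction_included) <= 0))
  expect_true(all(curve$threshold <= attr(curve, "exclusion")$threshold))
  ## thresholds past the exclusion point warn rather than error
  expect_warning(threshold_curve(res$posterior, ft$labels, res$predicted,
                                 thresholds = c(0, 0.999)), "truncated")
  expect_error(threshold_curve(res$posterior, ft$labels, res$predicted,
                               thresholds = c(.5, .1)), "ascending")
})
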