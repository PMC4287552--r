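#' Published phenotype count tables
#'
#' Per-phenotype cell counts of the two expert-labelled reference data sets
#' this package's synthetic generator emulates: the HT29 colon-cancer set
#' (14 phenotypes, 615 features per cell, image set BBBC018v1) and the HeLa
#' set distributed with EBImage (10 phenotypes, 51 features per cell).  The
#' tables are bundled as plain CSV under `extdata`; they are the canonical
#' class-imbalance profiles for [synthetic_config()] and the inputs to the
#' retained-cell arithmetic in [ht29_cell_arithmetic()].
#'
#' @return A data frame with columns `phenotype`, `abbreviation`, `cells`.
#' @export
ht29_phenotype_counts <- function() {
  utils::read.csv(system.file("extdata", "ht29_phenotype_counts.csv",
                              package = "phenoclass"),
                  stringsAsFactors = FALSE)
}

#' @rdname ht29_phenotype_counts
#' @export
hela_phenotype_counts <- function() {
  utils::read.csv(system.file("extdata", "hela_phenotype_counts.csv",
                              package = "phenoclass"),
                  stringsAsFactors = FALSE)
}

#' Retained-cell arithmetic of the HT29 training set
#'
#' The HT29 expert labels contained 55 cells carrying two phenotype labels
#' at once; these ambiguously classified cells were removed before
#' analysis.  This helper recomputes the bookkeeping from the bundled
#' phenotype table: the retained total (sum of the per-phenotype counts),
#' and the positive-example total before removal (retained + ambiguous).
#'
#' @param ambiguous Number of doubly-labelled cells removed (55 in the
#'   reference labelling).
#' @return A list: `retained` (sum over phenotypes), `ambiguous`, and
#'   `positives` (= retained + ambiguous).
#' @export
ht29_cell_arithmetic <- function(ambiguous = 55L) {
  retained <- sum(ht29_phenotype_counts()$cells)
  list(retained = retained, ambiguous = as.integer(ambiguous),
       positives = retained + as.integer(ambiguous))
}
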