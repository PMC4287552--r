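#' Construct a cell feature table
#'
#' A feature table holds one row per segmented cell, numeric image-derived
#' features in columns, and an expert phenotype label per cell.  It is the
#' common currency of all classification, merging and confidence analyses in
#' this package.
#'
#' @param values Numeric matrix, cells in rows and features in columns.
#' @param labels Integer vector of phenotype indices in `1..K`, or a factor /
#'   character vector of phenotype names (converted using order of first
#'   appearance, which keeps confusion-matrix orientation stable across runs).
#' @param phenotype_names Character vector of length `K`.  Defaults to the
#'   label levels, or `"P1".."PK"` for integer labels.
#' @param cell_ids Character vector of unique cell identifiers.  Defaults to
#'   `"cell_00001"` style ids.
#'
#' @return An object of class `feature_table`: a list with elements `values`,
#'   `labels` (integer), `phenotype_names`, `cell_ids`.
#' @export
feature_table <- function(values, labels, phenotype_names = NULL,
                          cell_ids = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.character(labels) || is.factor(labels)) {
    lev <- unique(as.character(labels))
    idx <- match(as.character(labels), lev)
    if (is.null(phenotype_names)) phenotype_names <- lev
    labels <- idx
  }
  labels <- as.integer(labels)
  K <- max(labels)
  if (is.null(phenotype_names)) phenotype_names <- paste0("P", seq_len(K))
  if (is.null(cell_ids))
    cell_ids <- sprintf("cell_%05d", seq_len(nrow(values)))
  if (is.null(colnames(values)))
    colnames(values) <- paste0("f", seq_len(ncol(values)))
  ft <- structure(list(values = values, labels = labels,
                       phenotype_names = as.character(phenotype_names),
                       cell_ids = as.character(cell_ids)),
                  class = "feature_table")
  validate_feature_table(ft)
  ft
}

validate_feature_table <- function(ft) {
  if (nrow(ft$values) != length(ft$labels))
    stop_data("number of rows (", nrow(ft$values),
              ") does not match number of labels (", length(ft$labels), ")")
  if (anyNA(ft$values) || any(!is.finite(ft$values))) {
    bad <- which(apply(ft$values, 2, function(x) anyNA(x) || any(!is.finite(x))))
    stop_data("non-finite or missing feature values in column(s): ",
              paste(colnames(ft$values)[bad], collapse = ", "))
  }
  K <- length(ft$phenotype_names)
  if (any(ft$labels < 1L) || any(ft$labels > K))
    stop_data("labels must lie in 1..", K)
  present <- tabulate(ft$labels, nbins = K)
  if (any(present == 0L))
    stop_data("phenotype(s) with no cells: ",
              paste(ft$phenotype_names[present == 0L], collapse = ", "))
  invisible(ft)
}

#' @export
print.feature_table <- function(x, ...) {
  cat("feature_table:", nrow(x$values), "cells,", ncol(x$values),
      "features,", length(x$phenotype_names), "phenotypes\n")
  tab <- table(factor(x$phenotype_names[x$labels], levels = x$phenotype_names))
  print(tab)
  invisible(x)
}

#' Number of phenotypes in a feature table
#' @param ft A [feature_table()].
#' @return Integer count of phenotype classes.
#' @export
n_phenotypes <- function(ft) length(ft$phenotype_names)

#' Subset a feature table by row
#' @param ft A [feature_table()].
#' @param i Integer or logical row index.
#' @return A `feature_table` with the selected cells.  The phenotype catalog
#'   is retained even if a phenotype loses all its cells.
#' @export
subset_cells <- function(ft, i) {
  structure(list(values = ft$values[i, , drop = FALSE],
                 labels = ft$labels[i],
                 phenotype_names = ft$phenotype_names,
                 cell_ids = ft$cell_ids[i]),
            class = "feature_table")
}

## Relabel cells through a phenotype-index map (old index -> new index).
relabel_cells <- function(ft, map, new_names) {
  structure(list(values = ft$values,
                 labels = as.integer(map[ft$labels]),
                 phenotype_names = new_names,
                 cell_ids = ft$cell_ids),
            class = "feature_table")
}

#' Write a feature table to CSV
#'
#' Layout: columns `cell_id`, `label` (phenotype name strings), then one
#' column per feature.  The companion reader is [read_feature_table()].
#'
#' @param ft A [feature_table()].
#' @param path Output file path; `.tsv` extension switches to tab delimiter.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  df <- data.frame(cell_id = ft$cell_ids,
                   label = ft$phenotype_names[ft$labels],
                   ft$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a feature table from CSV/TSV
#'
#' Expects columns `cell_id`, `label`, and at least one numeric feature
#' column.  The delimiter is sniffed from the file extension (`.tsv` means
#' tab, anything else comma).  Label strings are mapped to phenotype indices
#' by order of first appearance.
#'
#' @param path Input file path.
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) stop_data("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop_data("empty feature table: ", path)
  need <- c("cell_id", "label")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop_data("missing required column(s): ", paste(miss, collapse = ", "))
  feat <- df[, setdiff(names(df), need), drop = FALSE]
  if (ncol(feat) == 0L) stop_data("no feature columns found in ", path)
  for (j in seq_along(feat)) {
    v <- feat[[j]]
    if (!is.numeric(v)) {
      vn <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v))
      if (length(bad))
        stop_data("non-numeric feature value in column '", names(feat)[j],
                  "', data row ", bad[1])
      v <- vn
    }
    if (anyNA(v))
      stop_data("missing feature value in column '", names(feat)[j],
                "', data row ", which(is.na(v))[1])
    feat[[j]] <- v
  }
  feature_table(as.matrix(feat), labels = df$label, cell_ids = df$cell_id)
}
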