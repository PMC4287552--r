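#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif optim predict sd var cov aggregate
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

## Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
## caller's .Random.seed afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  force(expr)
}

stop_config <- function(...) {
  stop(structure(class = c("phenoclass_config_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("phenoclass_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
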