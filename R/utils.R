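#' @importFrom stats rnorm runif rpois rnbinom quantile median sd kmeans
#'   pnorm pchisq dist ecdf setNames
#' @importFrom utils read.csv write.csv head tail
NULL

# Run `expr` under a fixed RNG state, restoring the caller's state afterwards.
# All stochastic stages funnel their `seed` argument through here so that a
# single integer reproduces a run bit-identically.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Structured one-line stage log
#'
#' Emits a single `message()` of the form `[histomorph] stage: key=value ...`.
#' Used by every pipeline stage to report counts (tiles processed, nuclei
#' found, genes retained).
#'
#' @param stage character scalar naming the pipeline stage.
#' @param ... named scalar values to report.
#' @return invisibly, the formatted line.
#' @export
stageLog <- function(stage, ...) {
  kv <- list(...)
  txt <- if (length(kv))
    paste(names(kv), vapply(kv, function(x) paste(format(x), collapse = ","),
                            character(1)), sep = "=", collapse = " ")
  else ""
  line <- sprintf("[histomorph] %s: %s", stage, txt)
  message(line)
  invisible(line)
}

# Population standard deviation (divide by n); the normalization target used
# by the deep-clustering z-score.
popSd <- function(x) sqrt(mean((x - mean(x))^2))

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
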