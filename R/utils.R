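#' @importFrom methods new validObject is slot setClass setGeneric setMethod
#'   setValidity show slotNames
#' @importFrom stats rnorm runif rpois sd var coef lm residuals predict
#'   setNames
#' @importFrom utils read.delim read.csv write.csv head
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so package functions never clobber it.
withSeed <- function(seed, expr) {
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

# Deterministic fold assignment: seeded shuffle then round-robin.
assignFolds <- function(n, folds, seed) {
  stopifnot(folds >= 2)
  if (folds > n) stop("'folds' (", folds, ") exceeds the number of rows (", n, ")")
  perm <- withSeed(seed, sample.int(n))
  fold <- integer(n)
  fold[perm] <- rep_len(seq_len(folds), n)
  fold
}

# Numbers written so they survive a text round trip exactly.
formatNum <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

stopIfNotScalarFinite <- function(x, what) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop("'", what, "' must be a single finite number")
  invisible(x)
}
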