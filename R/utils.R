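#' @useDynLib bsaqtl, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm rpois rbinom rnbinom rmultinom var pnorm qnorm sd
#'   t.test median setNames complete.cases
#' @importFrom utils read.delim write.table head tail as.roman
NULL

# Run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL draws from the ambient stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive k reproducible child seeds (< 2^31) from one parent seed.
derive_seeds <- function(seed, k) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, k))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bsa <- function(...) stop(..., call. = FALSE)

assert_scalar_num <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper)
    stop_bsa(sprintf("'%s' must be a finite number in [%s, %s]", name, lower, upper))
  invisible(x)
}
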