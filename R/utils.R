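#' Run code under a temporary RNG seed
#'
#' Sets the R random seed, evaluates `expr`, and restores the previous RNG
#' state so callers never perturb the session stream. All stochastic
#' operations in the package funnel through this helper, which is what makes
#' sampling, weight initialization, training and the synthetic generator
#' reproducible from a single integer.
#'
#' @param seed integer seed, or `NULL` to evaluate without touching the RNG.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a child seed from a root seed and a stream label, staying inside
# 32-bit integer range.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(as.character(stream)) * seq_along(utf8ToInt(as.character(stream))))
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587L) + 1L
}

#' Round half away from zero
#'
#' Fixed-point rounding where .5 always rounds up in magnitude (the convention
#' used when reporting percentage metrics to two decimals), unlike base
#' [round()] which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Numerically stable softmax
#'
#' @param x numeric vector or matrix of logits; for a matrix the softmax is
#'   taken over rows (dimension 1), i.e. each column is a distribution.
#' @return same shape, non-negative, columns (or the vector) summing to 1.
#' @export
softmax <- function(x) {
  if (is.matrix(x)) {
    m <- apply(x, 2, max)
    e <- exp(sweep(x, 2, m))
    sweep(e, 2, colSums(e), "/")
  } else {
    e <- exp(x - max(x))
    e / sum(e)
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

log_msg <- function(fmt, ..., file = NULL) {
  line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...))
  message(line)
  if (!is.null(file)) cat(line, "\n", file = file, append = TRUE)
  invisible(line)
}
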