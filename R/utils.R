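#' @useDynLib eegfusion, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif var fft sd setNames
#' @importFrom utils write.csv head
NULL

# Run `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards. All stochastic entry points funnel through this
# so a seed argument never clobbers user RNG state.
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
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a child seed from a parent seed and a stream label, staying within
# 32-bit integer range. Deterministic, order-free (no RNG consumed).
derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "/")
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483587
  as.integer(h + 1L)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar_num <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_invalid("`%s` must be a finite numeric scalar", name)
  if (positive && x <= 0) stop_invalid("`%s` must be positive", name)
  invisible(x)
}
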