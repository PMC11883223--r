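#' Round half away from zero
#'
#' Display rounding used in registry-style summary tables: 0.5 always rounds
#' up (so 22.5 -> 23), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
#' @examples
#' round_half_up(c(12.45, 22.34, 42.49))
round_half_up <- function(x, digits = 0) {
  s <- 10^digits
  floor(x * s + 0.5) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed derivation; keeps results below .Machine$integer.max
derive_seed <- function(seed, offset) {
  as.integer((abs(as.numeric(seed)) + 97 * (as.numeric(offset) + 1)) %% 2147483629)
}

clamp_prob <- function(p, eps = 1e-12) pmin(pmax(p, eps), 1 - eps)

# first column index holding TRUE per row; NA_integer_ when the row has none
row_first_true <- function(m) {
  out <- rep(NA_integer_, nrow(m))
  w <- which(m, arr.ind = TRUE)
  if (nrow(w)) {
    w <- w[order(w[, 1L], w[, 2L]), , drop = FALSE]
    keep <- !duplicated(w[, 1L])
    out[w[keep, 1L]] <- w[keep, 2L]
  }
  out
}

is_flag <- function(x) is.logical(x) && length(x) == 1L && !is.na(x)

# row-wise cumulative product that keeps matrix shape for 1-row/1-col input
cumprod_rows <- function(m) {
  out <- matrix(apply(m, 1L, cumprod), nrow = ncol(m), ncol = nrow(m))
  t(out)
}
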