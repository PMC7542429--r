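#' @keywords internal
#' @useDynLib boldpatch, .registration = TRUE
#' @importFrom Rcpp sourceCpp
"_PACKAGE"

#' Derive a reproducible child seed from a master seed
#'
#' Combines a master seed with any number of non-negative integer indices
#' (subject index, frame index, restart index, ...) through a
#' Lehmer-style modular recurrence, so that cohorts and per-frame searches
#' are extensible without reshuffling earlier draws. The result is always
#' a valid, positive, 32-bit R seed.
#'
#' @param master integer master seed.
#' @param ... further non-negative integer indices, combined in order.
#' @return a single integer in `[1, 2147483562]`.
#' @export
derive_seed <- function(master, ...) {
  idx <- c(...)
  s <- as.numeric(master) %% 2147483563
  for (x in c(idx, 0)) {
    # 69069 * 2147483562 < 2^53, so the double arithmetic is exact
    s <- (s * 69069 + as.numeric(x) + 1) %% 2147483563
  }
  as.integer(s + 1)
}

# internal argument checks -----------------------------------------------

stop_arg <- function(...) stop(..., call. = FALSE)

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_arg(name, " must be a single finite number")
  if (x < lower || x > upper)
    stop_arg(name, " must be in [", lower, ", ", upper, "], got ", x)
  invisible(x)
}

check_count <- function(x, name, lower = 0L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x != round(x))
    stop_arg(name, " must be a single integer")
  if (x < lower) stop_arg(name, " must be >= ", lower, ", got ", x)
  as.integer(x)
}

# clip correlations away from +/-1 before the Fisher transform
clip_cor <- function(r, eps = 1e-7) {
  pmin(pmax(r, -1 + eps), 1 - eps)
}

# row-wise Pearson correlation between two matrices of equal shape;
# zero-variance rows are returned as NA (callers decide the flagging rule)
rowwise_cor <- function(a, b) {
  a <- a - rowMeans(a)
  b <- b - rowMeans(b)
  num <- rowSums(a * b)
  den <- sqrt(rowSums(a * a) * rowSums(b * b))
  out <- rep(NA_real_, nrow(a))
  ok <- den > 0
  out[ok] <- num[ok] / den[ok]
  out
}

# percentile bootstrap CI of a mean, seeded
bootstrap_ci_mean <- function(x, n_boot = 2000L, level = 0.95, seed = 1L) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(c(lower = NA_real_, upper = NA_real_))
  set.seed(seed)
  idx <- matrix(sample.int(length(x), length(x) * n_boot, replace = TRUE),
                nrow = n_boot)
  means <- rowMeans(matrix(x[idx], nrow = n_boot))
  alpha <- (1 - level) / 2
  qs <- stats::quantile(means, c(alpha, 1 - alpha), names = FALSE)
  c(lower = qs[1], upper = qs[2])
}
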