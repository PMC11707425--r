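# Internal helpers shared across modules.

#' @noRd
idicss_log <- function(..., level = "INFO") {
  opt <- getOption("idicss.verbose", FALSE)
  if (isTRUE(opt)) message(sprintf("[idicss %s] %s", level, paste0(...)))
  invisible(NULL)
}

# Row-wise z-score of a matrix; rows with zero variance become all-zero
# rather than NaN so downstream linear algebra stays total.
#' @noRd
row_zscore <- function(m) {
  mu <- rowMeans(m)
  s <- apply(m, 1, sd)
  z <- sweep(sweep(m, 1, mu, "-"), 1, ifelse(s > 0, s, 1), "/")
  z[s == 0, ] <- 0
  z
}

#' @noRd
col_skewness <- function(m) {
  n <- nrow(m)
  mu <- colMeans(m)
  d <- sweep(m, 2, mu, "-")
  m2 <- colMeans(d^2)
  m3 <- colMeans(d^3)
  ifelse(m2 > 0, m3 / m2^1.5, 0)
}

# Derive a stream of child seeds from one seed, kept below .Machine$integer.max.
#' @noRd
derive_seeds <- function(seed, n) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, n))
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_matrix_named <- function(m, what = "matrix") {
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m)))
    stopf("%s must be a matrix with row and column names", what)
  invisible(m)
}
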