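#' Column-wise z-scoring
#'
#' Standardizes every column of a matrix to mean 0 and standard deviation 1.
#' The default uses the population (1/k) standard deviation so that the
#' cross-product of a standardized column with itself equals the number of
#' rows; the sample (1/(k-1)) convention is available and changes regression
#' coefficients only by the constant factor sqrt(k/(k-1)).
#'
#' @param x numeric matrix (or vector, treated as one column).
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return matrix of the same shape with standardized columns.
#' @export
zscore_columns <- function(x, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("zscore_columns: input must be numeric")
  k <- nrow(x)
  if (k < 2L) stop("zscore_columns: need at least 2 rows")
  mu <- colMeans(x)
  xc <- sweep(x, 2L, mu, "-")
  ss <- colSums(xc^2)
  denom <- if (sd_type == "population") k else k - 1L
  s <- sqrt(ss / denom)
  bad <- which(s == 0 | !is.finite(s))
  if (length(bad) > 0L) {
    nm <- colnames(x)[bad]
    if (is.null(nm)) nm <- as.character(bad)
    stop("zscore_columns: constant column(s): ", paste(nm, collapse = ", "))
  }
  sweep(xc, 2L, s, "/")
}

#' @keywords internal
zscore_vector <- function(y, sd_type = "population") {
  drop(zscore_columns(matrix(y, ncol = 1L), sd_type = sd_type))
}

# Derive a child seed from a root seed; keeps results within 32-bit
# integer range so set.seed() accepts them.
#' @keywords internal
derive_seed <- function(seed, stream) {
  (as.integer(seed) + 104729L * as.integer(stream)) %% 2147483629L
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stop(name, " must be a single integer >= ", min)
  invisible(as.integer(x))
}
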