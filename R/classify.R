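#' Train a linear discriminant on log-likelihood-ratio features
#'
#' Fisher's linear discriminant with equal class covariances and (by
#' default) equal priors: the weight vector solves `S_w w = mu_M - mu_N`
#' where `S_w` is the pooled within-class covariance, inverted through the
#' singular value decomposition with singular values below
#' `rank_threshold` times the largest treated as zero. The positive class
#' is `musician`.
#'
#' @param features participants x regions matrix of log-likelihood-ratio
#'   features.
#' @param labels character vector, `"musician"` / `"nonmusician"`.
#' @param rank_threshold relative singular-value cutoff for the SVD-based
#'   inversion (default 1e-4).
#' @param priors length-2 vector of class priors (musician, nonmusician);
#'   equal by default for a balanced cohort. Unequal priors shift the bias
#'   by `log(p_M / p_N)` expressed on the normalized-distance scale.
#' @return a `discriminant_model` with weight vector `w`, bias `b` and the
#'   training metadata. Decision values are reported as signed Euclidean
#'   distance to the hyperplane, `d(x) = (w . x + b) / ||w||`.
#' @export
train_lda <- function(features, labels, rank_threshold = 1e-4,
                      priors = c(0.5, 0.5)) {
  features <- as.matrix(features)
  if (!all(is.finite(features))) stop("train_lda: non-finite features")
  if (nrow(features) != length(labels))
    stop("train_lda: feature rows and labels differ in length")
  is_m <- labels == "musician"
  if (!any(is_m) || all(is_m))
    stop("train_lda: both classes must be present")
  Xm <- features[is_m, , drop = FALSE]
  Xn <- features[!is_m, , drop = FALSE]
  mu_m <- colMeans(Xm); mu_n <- colMeans(Xn)
  n <- nrow(features)
  Cm <- sweep(Xm, 2L, mu_m, "-")
  Cn <- sweep(Xn, 2L, mu_n, "-")
  Sw <- (crossprod(Cm) + crossprod(Cn)) / n
  if (sum(Sw^2) == 0)
    stop("train_lda: degenerate input (zero within-class scatter; ",
         "all features identical within classes)")
  sv <- svd(Sw)
  keep <- sv$d > rank_threshold * sv$d[1L]
  Sw_inv <- sv$v[, keep, drop = FALSE] %*%
    (t(sv$u[, keep, drop = FALSE]) / sv$d[keep])
  w <- drop(Sw_inv %*% (mu_m - mu_n))
  if (sqrt(sum(w^2)) == 0)
    stop("train_lda: degenerate input (identical class means)")
  b <- -sum(w * (mu_m + mu_n)) / 2
  if (any(priors <= 0)) stop("train_lda: priors must be positive")
  b <- b + log(priors[1L] / priors[2L]) * sqrt(sum(w^2))
  structure(list(w = w, b = b, rank_threshold = rank_threshold,
                 priors = priors, rank = sum(keep),
                 feature_names = colnames(features)),
            class = "discriminant_model")
}

#' Signed distance to the discriminant hyperplane
#'
#' `d(x) = (w . x + b) / ||w||`: positive on the musician side, negative
#' on the nonmusician side, zero on the hyperplane. `normalized = FALSE`
#' returns the raw decision value `w . x + b`.
#'
#' @param model a `discriminant_model`.
#' @param x feature vector, or matrix with one sample per row.
#' @param normalized divide by `||w||` (default TRUE).
#' @return scalar or per-row vector of signed distances.
#' @export
decision_distance <- function(model, x, normalized = TRUE) {
  stopifnot(inherits(model, "discriminant_model"))
  if (is.matrix(x)) {
    if (ncol(x) != length(model$w))
      stop("decision_distance: expected ", length(model$w),
           " features, got ", ncol(x))
    d <- drop(x %*% model$w) + model$b
  } else {
    if (length(x) != length(model$w))
      stop("decision_distance: expected ", length(model$w),
           " features, got ", length(x))
    d <- sum(x * model$w) + model$b
  }
  if (normalized) d / sqrt(sum(model$w^2)) else d
}

#' Predict class labels
#'
#' `musician` iff the signed distance is > 0; a sample exactly on the
#' hyperplane is assigned to the positive (musician) class by convention.
#'
#' @inheritParams decision_distance
#' @return character vector of labels.
#' @export
predict_class <- function(model, x) {
  d <- decision_distance(model, x)
  ifelse(d >= 0, "musician", "nonmusician")
}

#' @export
predict.discriminant_model <- function(object, newdata, ...) {
  predict_class(object, newdata)
}

#' Musician-class probability
#'
#' Sigmoid of the signed Euclidean distance to the hyperplane,
#' `P = 1 / (1 + exp(-d))`.
#'
#' @inheritParams decision_distance
#' @param normalized use the Euclidean distance (default); `FALSE` uses the
#'   raw decision value instead.
#' @return probabilities in (0, 1).
#' @export
class_probability <- function(model, x, normalized = TRUE) {
  d <- decision_distance(model, x, normalized = normalized)
  1 / (1 + exp(-d))
}

#' Serialize a discriminant model to JSON
#'
#' @param model a `discriminant_model`.
#' @param path optional file to write to.
#' @return JSON string (invisibly when writing to a file).
#' @export
write_discriminant <- function(model, path = NULL) {
  js <- jsonlite::toJSON(unclass(model), digits = NA, auto_unbox = TRUE,
                         null = "null")
  if (!is.null(path)) {
    writeLines(js, path)
    invisible(js)
  } else js
}
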