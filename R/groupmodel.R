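#' Fit a diagonal-Gaussian group model for one region
#'
#' Models a group's encoded region series as a multivariate normal with
#' independent time points: at each scan t the group mean `mu_t` and
#' variance `sigma2_t` are estimated across the member participants'
#' predicted series. The covariance is restricted to its diagonal — with
#' tens of participants and hundreds of scans a full covariance would have
#' far more parameters than data. Variances are floored at `var_floor` to
#' keep the log-likelihood finite in degenerate cases; the floor should
#' never engage on realistic data and the number of floored time points is
#' recorded.
#'
#' @param members matrix of encoded series, one row per group member
#'   (>= 2 rows), or a list of equal-length vectors.
#' @param group group label stored with the model.
#' @param var_type `"population"` (1/n, default) or `"sample"` (1/(n-1))
#'   variance estimator.
#' @param var_floor minimum admissible variance (default 1e-8, negligible
#'   on z-scored data).
#' @return a `gaussian_group_model` list: `group`, `mu`, `sigma2`, `k`,
#'   `n_members`, `n_floored`, `var_type`, `var_floor`.
#' @export
fit_group_model <- function(members, group = "M",
                            var_type = c("population", "sample"),
                            var_floor = 1e-8) {
  var_type <- match.arg(var_type)
  if (is.list(members)) members <- do.call(rbind, members)
  members <- as.matrix(members)
  n <- nrow(members)
  if (n < 2L)
    stop("fit_group_model: need >= 2 members (variance undefined)")
  mu <- colMeans(members)
  dev2 <- colSums(sweep(members, 2L, mu, "-")^2)
  sigma2 <- dev2 / if (var_type == "population") n else n - 1L
  n_floored <- sum(sigma2 < var_floor)
  if (n_floored > 0L)
    sigma2 <- pmax(sigma2, var_floor)
  structure(list(group = group, mu = mu, sigma2 = sigma2,
                 k = length(mu), n_members = n, n_floored = n_floored,
                 var_type = var_type, var_floor = var_floor),
            class = "gaussian_group_model")
}

#' Log-likelihood of an encoded series under a group model
#'
#' The diagonal-covariance multivariate normal log-density
#' `-1/2 * sum_t [ln sigma2_t + (y_t - mu_t)^2 / sigma2_t + ln 2*pi]`.
#'
#' @param model a `gaussian_group_model`.
#' @param yhat encoded series (length `model$k`), or a matrix with one
#'   series per row.
#' @return scalar log-likelihood, or a vector with one value per row.
#' @export
log_likelihood <- function(model, yhat) {
  stopifnot(inherits(model, "gaussian_group_model"))
  if (any(model$sigma2 <= 0))
    stop("log_likelihood: non-positive variance in model")
  if (is.matrix(yhat)) {
    if (ncol(yhat) != model$k)
      stop("log_likelihood: series length ", ncol(yhat),
           " does not match model k = ", model$k)
    dev2 <- sweep(yhat, 2L, model$mu, "-")^2
    quad <- dev2 %*% (1 / model$sigma2)
    drop(-0.5 * (sum(log(model$sigma2)) + quad + model$k * log(2 * pi)))
  } else {
    if (length(yhat) != model$k)
      stop("log_likelihood: series length ", length(yhat),
           " does not match model k = ", model$k)
    -0.5 * sum(log(model$sigma2) + (yhat - model$mu)^2 / model$sigma2 +
                 log(2 * pi))
  }
}

#' Log-likelihood ratio between two group models
#'
#' `Lambda = ln L^M - ln L^N`: positive when the series fits the first
#' (musician) model better than the second.
#'
#' @param model_m,model_n `gaussian_group_model`s sharing the same `k`.
#' @param yhat encoded series or matrix of series (rows).
#' @return scalar or per-row vector of log-likelihood ratios.
#' @export
llr <- function(model_m, model_n, yhat) {
  if (model_m$k != model_n$k)
    stop("llr: models have different lengths (", model_m$k, " vs ",
         model_n$k, ")")
  log_likelihood(model_m, yhat) - log_likelihood(model_n, yhat)
}

#' Rank regions by correct-group fit
#'
#' Scores each region by the summed log-likelihood of the training
#' participants' encoded series under their own group's model, and returns
#' regions sorted by descending score. Regions whose group models describe
#' their members tightly and consistently score high; ties break by
#' ascending region index so the ranking is deterministic.
#'
#' @param models_m,models_n lists of `gaussian_group_model`, one per
#'   region, fitted on the training participants of each group.
#' @param encoded list of `encoded_participant` for the training set (the
#'   same participants the models were fitted on).
#' @return integer vector of region indices, best first, with the scores
#'   as the `scores` attribute (in ranked order).
#' @export
rank_regions <- function(models_m, models_n, encoded) {
  if (length(encoded) == 0L) stop("rank_regions: empty training set")
  nr <- length(models_m)
  if (length(models_n) != nr)
    stop("rank_regions: region count mismatch between groups")
  groups <- vapply(encoded, function(e) e$group, character(1L))
  scores <- vapply(seq_len(nr), function(r) {
    sum(vapply(seq_along(encoded), function(i) {
      model <- if (groups[i] == "musician") models_m[[r]] else models_n[[r]]
      log_likelihood(model, encoded[[i]]$yhat[r, ])
    }, numeric(1L)))
  }, numeric(1L))
  ord <- order(-scores, seq_len(nr))
  structure(ord, scores = scores[ord])
}
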