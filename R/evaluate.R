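#' Train a complete decoder on a set of encoded participants
#'
#' Fits both groups' diagonal-Gaussian region models on the supplied
#' (training) participants only, ranks regions by summed correct-group
#' log-likelihood, and trains the linear discriminant on the
#' log-likelihood-ratio features of the top-ranked regions. Held-out
#' participants must simply not be passed in: group models and the
#' discriminant see nothing but `encoded`.
#'
#' @param encoded list of `encoded_participant` (the training set; both
#'   groups present, >= 2 members each).
#' @param n_top_regions number of top-ranked regions to keep; ignored when
#'   `regions` is given.
#' @param regions optional fixed set of region indices or names; disables
#'   ranking-based selection (used e.g. for hemisphere comparisons).
#' @param var_type,var_floor passed to [fit_group_model()].
#' @param rank_threshold passed to [train_lda()].
#' @return a `decoder_model`: per-region group models for both groups, the
#'   ranked region order and scores, the `selected` region indices, and the
#'   trained `discriminant_model`.
#' @export
train_decoder <- function(encoded, n_top_regions = 9L, regions = NULL,
                          var_type = "population", var_floor = 1e-8,
                          rank_threshold = 1e-4) {
  if (length(encoded) < 4L)
    stop("train_decoder: need at least 2 participants per group")
  groups <- vapply(encoded, function(e) e$group, character(1L))
  is_m <- groups == "musician"
  if (sum(is_m) < 2L || sum(!is_m) < 2L)
    stop("train_decoder: need >= 2 training participants in each group")
  nr <- nrow(encoded[[1L]]$yhat)
  k <- ncol(encoded[[1L]]$yhat)
  region_names <- rownames(encoded[[1L]]$yhat) %||% paste0("R", seq_len(nr))

  # participants x k stack per region
  big <- vapply(encoded, function(e) e$yhat, matrix(0, nr, k))

  models_m <- vector("list", nr)
  models_n <- vector("list", nr)
  lambda_train <- matrix(0, length(encoded), nr,
                         dimnames = list(NULL, region_names))
  scores <- numeric(nr)
  for (r in seq_len(nr)) {
    Yr <- t(big[r, , ])                      # participants x k
    models_m[[r]] <- fit_group_model(Yr[is_m, , drop = FALSE], "M",
                                     var_type = var_type,
                                     var_floor = var_floor)
    models_n[[r]] <- fit_group_model(Yr[!is_m, , drop = FALSE], "N",
                                     var_type = var_type,
                                     var_floor = var_floor)
    ll_m <- log_likelihood(models_m[[r]], Yr)
    ll_n <- log_likelihood(models_n[[r]], Yr)
    scores[r] <- sum(ll_m[is_m]) + sum(ll_n[!is_m])
    lambda_train[, r] <- ll_m - ll_n
  }
  ranking <- order(-scores, seq_len(nr))

  if (is.null(regions)) {
    assert_count(n_top_regions, "n_top_regions")
    if (n_top_regions > nr)
      stop("train_decoder: n_top_regions (", n_top_regions,
           ") exceeds number of regions (", nr, ")")
    selected <- ranking[seq_len(n_top_regions)]
  } else {
    if (is.character(regions)) {
      miss <- setdiff(regions, region_names)
      if (length(miss) > 0L)
        stop("train_decoder: unknown region(s): ",
             paste(miss, collapse = ", "), "; valid names are: ",
             paste(region_names, collapse = ", "))
      selected <- match(regions, region_names)
    } else {
      if (any(regions < 1L | regions > nr))
        stop("train_decoder: region indices out of range 1..", nr)
      selected <- as.integer(regions)
    }
  }

  lda <- train_lda(lambda_train[, selected, drop = FALSE], groups,
                   rank_threshold = rank_threshold)
  structure(list(models_m = models_m, models_n = models_n,
                 ranking = ranking, scores = scores, selected = selected,
                 region_names = region_names, lda = lda,
                 var_type = var_type, var_floor = var_floor,
                 rank_threshold = rank_threshold, k = k),
            class = "decoder_model")
}

#' Apply a trained decoder to new participants
#'
#' Computes each participant's per-region log-likelihood ratio against the
#' decoder's (training-only) group models and classifies from the selected
#' regions' features.
#'
#' @param decoder a `decoder_model` from [train_decoder()].
#' @param encoded list of `encoded_participant` to classify.
#' @return list with `label`, `probability`, `distance` (per participant)
#'   and `llr` (participants x all-regions matrix).
#' @export
predict_decoder <- function(decoder, encoded) {
  nr <- length(decoder$models_m)
  n <- length(encoded)
  k <- ncol(encoded[[1L]]$yhat)
  big <- vapply(encoded, function(e) e$yhat, matrix(0, nr, k))
  lambda <- matrix(0, n, nr, dimnames = list(NULL, decoder$region_names))
  for (r in seq_len(nr)) {
    Yr <- matrix(big[r, , ], ncol = k, byrow = TRUE)
    lambda[, r] <- llr(decoder$models_m[[r]], decoder$models_n[[r]], Yr)
  }
  feats <- lambda[, decoder$selected, drop = FALSE]
  d <- decision_distance(decoder$lda, feats)
  list(label = ifelse(d >= 0, "musician", "nonmusician"),
       probability = 1 / (1 + exp(-d)),
       distance = d, llr = lambda)
}

#' Repeated stratified held-out-pair cross-validation
#'
#' The full decoding experiment. Each run draws a random bijective pairing
#' of musicians with nonmusicians; each of the `n_per_group` folds holds
#' out one pair, trains the complete decoder (group models, region
#' ranking, discriminant) on the remaining participants only, and
#' classifies the held-out pair. Per-run accuracy, sensitivity,
#' specificity and AUC are aggregated across runs.
#'
#' @param cohort a cohort (balanced; see [make_cohort()] / [read_cohort()]).
#' @param X design matrix (default: the cohort's own feature matrix).
#' @param n_top_regions regions kept by ranking selection.
#' @param n_runs number of cross-validation repetitions (default 10).
#' @param seed root seed; per-run seeds are derived from it and recorded.
#' @param regions optional fixed region set (disables ranking), passed to
#'   [train_decoder()].
#' @param var_type,var_floor,rank_threshold model options, see
#'   [train_decoder()].
#' @param encoded optional precomputed [encode_cohort()] output for this
#'   cohort and `X` (saves re-encoding in sweeps).
#' @return a `cv_result`: per-run held-out predictions, probabilities,
#'   all-region log-likelihood ratios and selected-region lists; per-run
#'   and mean metrics; labels, ids, familiarity and seeds.
#' @export
run_cv <- function(cohort, X = NULL, n_top_regions = 9L, n_runs = 10L,
                   seed = 1L, regions = NULL, var_type = "population",
                   var_floor = 1e-8, rank_threshold = 1e-4,
                   encoded = NULL) {
  if (is.null(X)) X <- attr(cohort, "feature_matrix")
  if (is.null(X)) stop("run_cv: no design matrix supplied")
  labels <- cohort_labels(cohort)
  idx_m <- which(labels == "musician")
  idx_n <- which(labels == "nonmusician")
  if (length(idx_m) != length(idx_n) || length(idx_m) == 0L)
    stop("run_cv: cohort must be balanced with both groups present")
  n_fold <- length(idx_m)
  n <- length(cohort)
  nr <- nrow(cohort[[1L]]$bold)
  if (is.null(regions)) {
    assert_count(n_top_regions, "n_top_regions")
    if (n_top_regions > nr)
      stop("run_cv: n_top_regions out of range 1..", nr)
  }

  if (is.null(encoded)) encoded <- encode_cohort(X, cohort)
  ids <- cohort_ids(cohort)
  fam <- vapply(cohort, function(p) p$familiarity %||% NA_real_, numeric(1L))

  runs <- vector("list", n_runs)
  metric_rows <- vector("list", n_runs)
  for (run in seq_len(n_runs)) {
    run_seed <- derive_seed(seed, run)
    set.seed(run_seed)
    ord_m <- sample(idx_m)
    ord_n <- sample(idx_n)
    pred <- character(n)
    prob <- numeric(n)
    dist <- numeric(n)
    lambda_all <- matrix(NA_real_, n, nr)
    fold_regions <- vector("list", n_fold)
    for (f in seq_len(n_fold)) {
      held <- c(ord_m[f], ord_n[f])
      train <- setdiff(seq_len(n), held)
      dec <- train_decoder(encoded[train], n_top_regions = n_top_regions,
                           regions = regions, var_type = var_type,
                           var_floor = var_floor,
                           rank_threshold = rank_threshold)
      out <- predict_decoder(dec, encoded[held])
      pred[held] <- out$label
      prob[held] <- out$probability
      dist[held] <- out$distance
      lambda_all[held, ] <- out$llr
      fold_regions[[f]] <- dec$selected
    }
    colnames(lambda_all) <- dec$region_names
    mets <- metrics(pred, prob, labels)
    runs[[run]] <- list(seed = run_seed, pred = pred, prob = prob,
                        distance = dist, llr = lambda_all,
                        fold_regions = fold_regions,
                        pairing = cbind(musician = ord_m,
                                        nonmusician = ord_n))
    metric_rows[[run]] <- data.frame(run = run, accuracy = mets$accuracy,
                                     sensitivity = mets$sensitivity,
                                     specificity = mets$specificity,
                                     auc = mets$auc)
  }
  per_run <- do.call(rbind, metric_rows)
  structure(list(runs = runs, per_run = per_run,
                 mean_metrics = colMeans(per_run[, -1L]),
                 labels = labels, ids = ids, familiarity = fam,
                 n_runs = n_runs, n_folds = n_fold,
                 n_top_regions = if (is.null(regions)) n_top_regions
                                 else length(runs[[1L]]$fold_regions[[1L]]),
                 fixed_regions = regions, seed = seed,
                 region_names = colnames(runs[[1L]]$llr)),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  m <- x$mean_metrics
  cat(sprintf("Cross-validated decoding: %d runs x %d folds (%d fold models)\n",
              x$n_runs, x$n_folds, x$n_runs * x$n_folds))
  cat(sprintf("  mean accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  AUC %.4f\n",
              100 * m[["accuracy"]], 100 * m[["sensitivity"]],
              100 * m[["specificity"]], m[["auc"]]))
  invisible(x)
}

#' Classification performance metrics
#'
#' Accuracy, sensitivity (musician recall), specificity (nonmusician
#' recall) and the area under the ROC curve. The AUC is computed by the
#' rank statistic over the class probabilities (equivalent to the
#' normalized Mann-Whitney U; ties contribute 1/2).
#'
#' @param predictions character vector of predicted labels.
#' @param probabilities musician-class probabilities.
#' @param labels true labels; both classes must be present.
#' @return list with `accuracy`, `sensitivity`, `specificity`, `auc`.
#' @export
metrics <- function(predictions, probabilities, labels) {
  if (length(labels) == 0L) stop("metrics: empty input")
  pos <- labels == "musician"
  if (!any(pos) || all(pos))
    stop("metrics: both classes must be present (AUC undefined otherwise)")
  acc <- mean(predictions == labels)
  sens <- mean(predictions[pos] == "musician")
  spec <- mean(predictions[!pos] == "nonmusician")
  r <- rank(probabilities)
  n_p <- sum(pos); n_n <- sum(!pos)
  auc <- (sum(r[pos]) - n_p * (n_p + 1) / 2) / (n_p * n_n)
  list(accuracy = acc, sensitivity = sens, specificity = spec, auc = auc)
}

#' Binomial significance of cross-validated accuracies
#'
#' Compares each run's accuracy against the chance distribution
#' Binomial(n, 1/2): the per-run p-value is the exact upper-tail
#' probability `P(X >= round(accuracy * n))`, and the reported value is
#' the median across runs.
#'
#' @param per_run_accuracies accuracies in \[0, 1\], one per run.
#' @param n number of classified participants per run.
#' @return list with `median_p` and the per-run `p_values`.
#' @export
binomial_significance <- function(per_run_accuracies, n) {
  if (n <= 0) stop("binomial_significance: n must be positive")
  if (any(per_run_accuracies < 0 | per_run_accuracies > 1))
    stop("binomial_significance: accuracies must lie in [0, 1]")
  kk <- round(per_run_accuracies * n)
  p <- stats::pbinom(kk - 1, n, 0.5, lower.tail = FALSE)
  list(median_p = stats::median(p), p_values = p)
}

#' Region selection frequency across folds
#'
#' How consistently each region was picked by the ranking selection over
#' all runs and folds: counts normalized by the total number of fold
#' models, sorted descending. Frequencies sum to the number of regions
#' selected per fold.
#'
#' @param cv a `cv_result`.
#' @return named numeric vector of selection frequencies.
#' @export
region_consistency <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  sel <- unlist(lapply(cv$runs, function(r) r$fold_regions))
  total <- cv$n_runs * cv$n_folds
  counts <- tabulate(sel, nbins = length(cv$region_names))
  freq <- counts / total
  names(freq) <- cv$region_names
  sort(freq, decreasing = TRUE)
}

#' Group comparison of cross-validated log-likelihood ratios
#'
#' For each region and each run, the held-out log-likelihood ratios
#' (computed under the cross-validation procedure, i.e. the classifier's
#' own input features) are compared between musicians and nonmusicians
#' with a one-tailed two-sample Student's t-test (musicians expected
#' higher). Each run's t is mapped to a Z-value through its one-tailed
#' p-quantile; Z-values are averaged across runs and the reported p comes
#' from the average Z.
#'
#' @param cv a `cv_result`.
#' @param df degrees of freedom for the t reference distribution. The
#'   default `n - 1` (35 for 18 + 18) follows the reported analysis; the
#'   conventional pooled two-sample value would be `n - 2`.
#' @param method `"z_mapping"` (default: t -> one-tailed p -> Z) or
#'   `"direct_t"` (average the t statistics themselves).
#' @return data.frame with `region`, `z`, `p`, sorted by the region order
#'   of the cohort.
#' @export
llr_group_test <- function(cv, df = NULL,
                           method = c("z_mapping", "direct_t")) {
  stopifnot(inherits(cv, "cv_result"))
  method <- match.arg(method)
  pos <- cv$labels == "musician"
  n1 <- sum(pos); n2 <- sum(!pos)
  if (n1 < 2L || n2 < 2L) stop("llr_group_test: missing group")
  if (is.null(df)) df <- n1 + n2 - 1L
  nr <- length(cv$region_names)
  zmat <- vapply(cv$runs, function(run) {
    x <- run$llr[pos, , drop = FALSE]
    y <- run$llr[!pos, , drop = FALSE]
    mx <- colMeans(x); my <- colMeans(y)
    vx <- apply(x, 2L, stats::var); vy <- apply(y, 2L, stats::var)
    sp2 <- ((n1 - 1) * vx + (n2 - 1) * vy) / (n1 + n2 - 2)
    tt <- (mx - my) / sqrt(sp2 * (1 / n1 + 1 / n2))
    if (method == "z_mapping") {
      p1 <- stats::pt(tt, df = df, lower.tail = FALSE)
      stats::qnorm(p1, lower.tail = FALSE)
    } else tt
  }, numeric(nr))
  zbar <- rowMeans(zmat)
  data.frame(region = cv$region_names, z = zbar,
             p = stats::pnorm(zbar, lower.tail = FALSE),
             row.names = NULL)
}

#' Partial correlation of decoder probabilities with class, controlling
#' familiarity
#'
#' Per run, the musician-class probabilities are partially correlated with
#' the true class indicator while removing the linear effect of each
#' participant's mean stimulus familiarity (residual-on-residual
#' correlation); the mean across runs is reported. A substantial partial
#' correlation shows the decoder is not merely reading out familiarity.
#'
#' @param cv a `cv_result` from a cohort carrying familiarity ratings.
#' @return list with `mean_r` and per-run `r_values`.
#' @export
familiarity_partial_correlation <- function(cv) {
  stopifnot(inherits(cv, "cv_result"))
  fam <- cv$familiarity
  if (anyNA(fam))
    stop("familiarity_partial_correlation: missing familiarity ratings")
  y <- as.numeric(cv$labels == "musician")
  plain <- stats::var(fam) == 0
  if (plain)
    warning("familiarity_partial_correlation: zero-variance familiarity; ",
            "reporting plain correlation")
  r <- vapply(cv$runs, function(run) {
    if (plain) return(stats::cor(run$prob, y))
    rx <- stats::residuals(stats::lm(run$prob ~ fam))
    ry <- stats::residuals(stats::lm(y ~ fam))
    stats::cor(rx, ry)
  }, numeric(1L))
  list(mean_r = mean(r), r_values = r)
}

#' Group tests on encoding coefficients
#'
#' For every region/feature cell of a coefficient table: a two-sample
#' pooled-variance t-test (musicians minus nonmusicians, two-sided p) for
#' the group difference, and one-sample t-tests against zero within each
#' group.
#'
#' @param betas long-format table from [beta_table()] (columns `group`,
#'   `region`, `feature`, `beta`).
#' @return data.frame with one row per region/feature: `t`, `p` for the
#'   group contrast and `t_mus`, `p_mus`, `t_nonmus`, `p_nonmus` for the
#'   one-sample tests.
#' @export
beta_group_tests <- function(betas) {
  need <- c("group", "region", "feature", "beta")
  if (!all(need %in% names(betas)))
    stop("beta_group_tests: table must have columns ",
         paste(need, collapse = ", "))
  cells <- unique(betas[, c("region", "feature")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- betas[betas$region == cells$region[i] &
                   betas$feature == cells$feature[i], ]
    bm <- sub$beta[sub$group == "musician"]
    bn <- sub$beta[sub$group == "nonmusician"]
    if (length(bm) < 2L || length(bn) < 2L)
      stop("beta_group_tests: need >= 2 participants per group")
    tw <- stats::t.test(bm, bn, var.equal = TRUE)
    om <- stats::t.test(bm, mu = 0)
    on <- stats::t.test(bn, mu = 0)
    data.frame(region = cells$region[i], feature = cells$feature[i],
               t = unname(tw$statistic), p = tw$p.value,
               t_mus = unname(om$statistic), p_mus = om$p.value,
               t_nonmus = unname(on$statistic), p_nonmus = on$p.value)
  })
  do.call(rbind, rows)
}

#' Accuracy as a function of the number of selected regions
#'
#' Runs the full cross-validation at each region count and reports the
#' mean accuracy with 68% and 95% confidence bands for the mean, computed
#' from the across-run dispersion.
#'
#' @param cohort,X,n_runs,seed,var_type,var_floor,rank_threshold as in
#'   [run_cv()].
#' @param region_counts integer vector of region counts to evaluate.
#' @return data.frame with `n_regions`, `mean_accuracy`, `lo68`, `hi68`,
#'   `lo95`, `hi95`, and the full `cv_result`s as the `cv` attribute.
#' @export
sweep_regions <- function(cohort, X = NULL, region_counts, n_runs = 10L,
                          seed = 1L, var_type = "population",
                          var_floor = 1e-8, rank_threshold = 1e-4) {
  if (is.null(X)) X <- attr(cohort, "feature_matrix")
  nr <- nrow(cohort[[1L]]$bold)
  if (any(region_counts < 1L | region_counts > nr))
    stop("sweep_regions: region counts must lie in 1..", nr)
  encoded <- encode_cohort(X, cohort)
  cvs <- lapply(region_counts, function(ct)
    run_cv(cohort, X, n_top_regions = ct, n_runs = n_runs, seed = seed,
           var_type = var_type, var_floor = var_floor,
           rank_threshold = rank_threshold, encoded = encoded))
  rows <- lapply(seq_along(region_counts), function(i) {
    acc <- cvs[[i]]$per_run$accuracy
    se <- stats::sd(acc) / sqrt(length(acc))
    data.frame(n_regions = region_counts[i], mean_accuracy = mean(acc),
               lo68 = mean(acc) - se, hi68 = mean(acc) + se,
               lo95 = mean(acc) - stats::qnorm(0.975) * se,
               hi95 = mean(acc) + stats::qnorm(0.975) * se)
  })
  out <- do.call(rbind, rows)
  attr(out, "cv") <- cvs
  out
}

#' Compare decoding accuracy across fixed region sets
#'
#' Re-runs the cross-validation with the decoder restricted to each named
#' region set (no ranking selection inside a set), e.g. the left-hemisphere,
#' right-hemisphere and bilateral versions of a region, and reports the
#' mean accuracy per set.
#'
#' @param cohort,X,n_runs,seed as in [run_cv()].
#' @param region_sets named list of region index or name vectors.
#' @param ... further options passed to [run_cv()].
#' @return data.frame with `set`, `mean_accuracy`, `median_binomial_p`;
#'   full `cv_result`s in the `cv` attribute.
#' @export
lateralization_compare <- function(cohort, X = NULL, region_sets,
                                   n_runs = 10L, seed = 1L, ...) {
  if (is.null(names(region_sets)) || any(names(region_sets) == ""))
    stop("lateralization_compare: region_sets must be a named list")
  cvs <- lapply(region_sets, function(rs)
    run_cv(cohort, X, regions = rs, n_runs = n_runs, seed = seed, ...))
  n <- length(cohort_labels(cohort))
  rows <- lapply(names(region_sets), function(nm) {
    acc <- cvs[[nm]]$per_run$accuracy
    data.frame(set = nm, mean_accuracy = mean(acc),
               median_binomial_p = binomial_significance(acc, n)$median_p)
  })
  out <- do.call(rbind, rows)
  attr(out, "cv") <- cvs
  out
}
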