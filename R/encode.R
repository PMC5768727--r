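#' Fit a linear encoding model for one region
#'
#' Least-squares regression of a (z-scored) region BOLD series on the
#' standardized stimulus features, `y ~ X beta` with no intercept: both
#' sides are centered by construction, so the intercept is identically 0.
#' The solution uses a QR decomposition; if `X` is rank deficient the
#' minimum-norm solution is returned via the SVD pseudoinverse with a
#' warning.
#'
#' @param X `k x m` standardized design matrix.
#' @param y length-`k` region series (already z-scored).
#' @return an `encoded_region` list: `betas` (m-vector of standardized
#'   coefficients), `yhat` (the predicted series `X %*% betas`), and
#'   `r_squared = 1 - ||y - yhat||^2 / ||y||^2`.
#' @export
fit_encoding <- function(X, y) {
  X <- as.matrix(X)
  if (length(y) != nrow(X))
    stop("fit_encoding: length of y (", length(y),
         ") does not match nrow(X) (", nrow(X), ")")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    warning("fit_encoding: rank-deficient design (rank ", qrX$rank,
            " < ", ncol(X), "); returning minimum-norm solution")
    sv <- svd(X)
    keep <- sv$d > sv$d[1L] * 1e-10
    beta <- sv$v[, keep, drop = FALSE] %*%
      ((t(sv$u[, keep, drop = FALSE]) %*% y) / sv$d[keep])
    beta <- drop(beta)
  } else {
    beta <- drop(qr.coef(qrX, y))
  }
  yhat <- drop(X %*% beta)
  ss_tot <- sum(y^2)
  r2 <- if (ss_tot > 0) 1 - sum((y - yhat)^2) / ss_tot else 0
  structure(list(betas = beta, yhat = yhat,
                 r_squared = min(max(r2, 0), 1)),
            class = "encoded_region")
}

#' Encode every region of one participant
#'
#' Applies [fit_encoding()] independently to each region's BOLD series
#' after z-scoring it. Returns compact matrices rather than one object per
#' region, since downstream stages consume whole-cohort stacks.
#'
#' @param X `k x m` standardized design matrix.
#' @param participant a participant record with a `bold` region x time
#'   matrix (as produced by [make_cohort()] or [read_cohort()]).
#' @param sd_type z-score convention for the region series.
#' @return an `encoded_participant` list: `betas` (regions x features),
#'   `yhat` (regions x time), `r_squared` (per-region vector).
#' @export
encode_participant <- function(X, participant, sd_type = "population") {
  bold <- participant$bold
  if (is.null(bold)) stop("encode_participant: participant has no bold matrix")
  if (ncol(bold) != nrow(X))
    stop("encode_participant: bold has ", ncol(bold),
         " time points but X has ", nrow(X))
  nr <- nrow(bold)
  region_names <- rownames(bold) %||% paste0("R", seq_len(nr))
  # z-score each region series, then solve all regions in one QR pass
  Yz <- t(zscore_columns(t(bold), sd_type = sd_type))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    res <- lapply(seq_len(nr), function(r) fit_encoding(X, Yz[r, ]))
    betas <- t(vapply(res, function(e) e$betas, numeric(ncol(X))))
    yhat <- t(vapply(res, function(e) e$yhat, numeric(nrow(X))))
    r2 <- vapply(res, function(e) e$r_squared, numeric(1L))
  } else {
    betas <- t(qr.coef(qrX, t(Yz)))
    yhat <- betas %*% t(X)
    resid2 <- rowSums((Yz - yhat)^2)
    tot2 <- rowSums(Yz^2)
    r2 <- ifelse(tot2 > 0, 1 - resid2 / tot2, 0)
    r2 <- pmin(pmax(r2, 0), 1)
  }
  dimnames(betas) <- list(region_names, colnames(X))
  rownames(yhat) <- region_names
  names(r2) <- region_names
  structure(list(id = participant$id, group = participant$group,
                 betas = betas, yhat = yhat, r_squared = r2),
            class = "encoded_participant")
}

#' Encode every participant of a cohort
#'
#' @param X design matrix.
#' @param cohort a cohort (list of participant records).
#' @inheritParams encode_participant
#' @return list of `encoded_participant`, same order as the cohort.
#' @export
encode_cohort <- function(X, cohort, sd_type = "population") {
  lapply(cohort, function(p) encode_participant(X, p, sd_type = sd_type))
}

#' Long-format table of encoding coefficients
#'
#' Flattens a cohort's encoded coefficients into a participant x region x
#' feature long table for group-level statistics and export.
#'
#' @param encoded list of `encoded_participant`.
#' @return data.frame with columns `id`, `group`, `region`, `feature`,
#'   `beta`.
#' @export
beta_table <- function(encoded) {
  do.call(rbind, lapply(encoded, function(e) {
    b <- e$betas
    data.frame(id = e$id, group = e$group,
               region = rep(rownames(b), times = ncol(b)),
               feature = rep(colnames(b), each = nrow(b)),
               beta = as.vector(b), stringsAsFactors = FALSE)
  }))
}
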