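#' Hemodynamic response function specification
#'
#' Parameters of the canonical double-gamma hemodynamic response function
#' (HRF): a positive gamma lobe peaking at `peak_delay` seconds followed by
#' a negative undershoot lobe peaking at `undershoot_delay` seconds.
#'
#' @param peak_delay time-to-peak of the positive lobe, seconds (default 5).
#' @param undershoot_delay time-to-peak of the undershoot, seconds
#'   (default 15).
#' @param sampling_rate kernel sampling rate in Hz.
#' @param duration kernel support in seconds; must be long enough that the
#'   tail is negligible (< 1e-4 of the peak).
#' @param undershoot_ratio amplitude of the undershoot lobe relative to the
#'   positive lobe before peak normalization (default 1/6, the conventional
#'   canonical value).
#' @return an object of class `hrf_spec`.
#' @export
hrf_spec <- function(peak_delay = 5, undershoot_delay = 15,
                     sampling_rate = 0.5, duration = 40,
                     undershoot_ratio = 1 / 6) {
  if (peak_delay <= 0 || undershoot_delay <= 0)
    stop("hrf_spec: delays must be positive")
  if (peak_delay >= undershoot_delay)
    stop("hrf_spec: peak_delay must be smaller than undershoot_delay")
  if (sampling_rate <= 0 || duration <= 0)
    stop("hrf_spec: sampling_rate and duration must be positive")
  structure(list(peak_delay = peak_delay,
                 undershoot_delay = undershoot_delay,
                 sampling_rate = sampling_rate, duration = duration,
                 undershoot_ratio = undershoot_ratio),
            class = "hrf_spec")
}

#' Double-gamma hemodynamic response kernel
#'
#' Difference of two gamma densities with unit scale, shapes chosen so the
#' modes land exactly at `peak_delay` and `undershoot_delay` (a gamma density
#' with shape a and scale 1 has its mode at a - 1). The undershoot is scaled
#' by `undershoot_ratio` and the kernel is normalized to peak value 1. The
#' kernel starts at t = 0 where it is exactly 0.
#'
#' @param spec an [hrf_spec()].
#' @return numeric vector sampled at `sampling_rate`, with attribute
#'   `times` (seconds).
#' @export
double_gamma_hrf <- function(spec = hrf_spec()) {
  stopifnot(inherits(spec, "hrf_spec"))
  t <- seq(0, spec$duration, by = 1 / spec$sampling_rate)
  shape1 <- spec$peak_delay + 1
  shape2 <- spec$undershoot_delay + 1
  h <- stats::dgamma(t, shape = shape1, scale = 1) -
    spec$undershoot_ratio * stats::dgamma(t, shape = shape2, scale = 1)
  h <- h / max(h)
  if (abs(h[length(h)]) > 1e-4)
    warning("double_gamma_hrf: kernel tail exceeds 1e-4 of peak; ",
            "increase duration")
  attr(h, "times") <- t
  h
}

#' Causal convolution with a hemodynamic kernel
#'
#' Full linear convolution of a feature series with a kernel, truncated to
#' the input length, so the output at time t depends only on present and
#' past inputs.
#'
#' @param series numeric vector.
#' @param kernel numeric vector (e.g. from [double_gamma_hrf()]).
#' @return numeric vector of `length(series)`.
#' @export
convolve_feature <- function(series, kernel) {
  n <- length(series); nk <- length(kernel)
  if (n < 1L || nk < 1L) stop("convolve_feature: empty input")
  full <- stats::convolve(series, rev(kernel), type = "open")
  full[seq_len(n)]
}

#' Spline detrending
#'
#' Removes slow drifts by fitting a natural cubic spline through block means
#' computed in contiguous windows of `knot_spacing_s` seconds and
#' subtracting the fit. Components slower than the knot spacing are
#' suppressed; faster components pass through largely unchanged.
#'
#' @param series numeric vector.
#' @param knot_spacing_s knot spacing in seconds (default 60).
#' @param sampling_rate series sampling rate in Hz.
#' @return detrended series of the same length.
#' @export
detrend_spline <- function(series, knot_spacing_s = 60, sampling_rate = 0.5) {
  n <- length(series)
  if (knot_spacing_s <= 0 || sampling_rate <= 0)
    stop("detrend_spline: knot spacing and sampling rate must be positive")
  block <- max(2L, round(knot_spacing_s * sampling_rate))
  if (n < 2L * block)
    stop("detrend_spline: series must span at least 2 knots ",
         "(need >= ", 2L * block, " samples, got ", n, ")")
  nb <- floor(n / block)
  idx <- rep(seq_len(nb), each = block, length.out = nb * block)
  centers <- tapply(seq_len(nb * block), idx, mean)
  means <- tapply(series[seq_len(nb * block)], idx, mean)
  fit <- stats::splinefun(centers, means, method = "natural")
  series - fit(seq_len(n))
}

#' Gaussian temporal smoothing
#'
#' Filters a series with a normalized Gaussian kernel whose full width at
#' half maximum is `fwhm_s` seconds; edges are handled by reflection so a
#' constant series passes through unchanged.
#'
#' @param series numeric vector.
#' @param fwhm_s kernel FWHM in seconds (the common neuroimaging reading of
#'   a smoothing "width"; pass `fwhm_s = sd * 2*sqrt(2*log(2))` to specify
#'   the sd instead).
#' @param sampling_rate series sampling rate in Hz.
#' @return smoothed series of the same length.
#' @export
temporal_smooth <- function(series, fwhm_s = 4, sampling_rate = 0.5) {
  if (fwhm_s <= 0) stop("temporal_smooth: fwhm must be positive")
  n <- length(series)
  if (n < 1L) stop("temporal_smooth: empty series")
  sd_samples <- fwhm_s * sampling_rate / (2 * sqrt(2 * log(2)))
  half <- max(1L, ceiling(4 * sd_samples))
  w <- stats::dnorm(seq(-half, half), sd = sd_samples)
  w <- w / sum(w)
  # reflective padding
  pad_l <- series[pmin(n, pmax(1L, (half + 1L):2L))]
  pad_r <- series[pmin(n, pmax(1L, (n - 1L):(n - half)))]
  ext <- c(pad_l, series, pad_r)
  out <- stats::filter(ext, w, sides = 2L)
  as.numeric(out[(half + 1L):(half + n)])
}

#' Downsample by block averaging
#'
#' Reduces a series from `in_rate` to `out_rate` Hz by averaging contiguous
#' windows of `in_rate / out_rate` samples. When the rates are not
#' commensurate, the series is first linearly interpolated onto a
#' commensurate grid (the smallest integer multiple of `out_rate` at or
#' above `in_rate`), then block-averaged.
#'
#' @param series numeric vector at `in_rate` Hz.
#' @param in_rate input sampling rate, Hz.
#' @param out_rate output sampling rate, Hz; `in_rate >= out_rate > 0`.
#' @return series at `out_rate` Hz.
#' @export
resample_to_scans <- function(series, in_rate, out_rate) {
  if (out_rate <= 0 || in_rate < out_rate)
    stop("resample_to_scans: need in_rate >= out_rate > 0")
  ratio <- in_rate / out_rate
  if (abs(ratio - round(ratio)) > 1e-9) {
    ratio <- ceiling(ratio)
    new_rate <- ratio * out_rate
    t_in <- (seq_along(series) - 1L) / in_rate
    n_new <- floor(t_in[length(t_in)] * new_rate) + 1L
    t_new <- (seq_len(n_new) - 1L) / new_rate
    series <- stats::approx(t_in, series, xout = t_new, rule = 2L)$y
  } else {
    ratio <- round(ratio)
  }
  n_out <- floor(length(series) / ratio)
  if (n_out < 1L) stop("resample_to_scans: series too short")
  colMeans(matrix(series[seq_len(n_out * ratio)], nrow = ratio))
}

#' Varimax-rotated principal components
#'
#' Principal component analysis followed by orthogonal varimax rotation of
#' the retained loadings, the standard route for reducing a bank of
#' correlated acoustic descriptors to a few interpretable components.
#'
#' @param x numeric matrix, rows = observations (more rows than columns).
#' @param n_components number of components to retain (<= `ncol(x)` and
#'   <= the achieved rank of the centered data).
#' @return list with `loadings` (variables x components, rotated),
#'   `scores` (observations x components), `rotation` (the orthonormal
#'   varimax rotation matrix) and `var_explained`.
#' @export
varimax_components <- function(x, n_components) {
  x <- as.matrix(x)
  if (nrow(x) <= ncol(x))
    stop("varimax_components: need more rows than columns")
  assert_count(n_components, "n_components")
  if (n_components > ncol(x))
    stop("varimax_components: n_components exceeds number of variables")
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  rank <- sum(pc$sdev > pc$sdev[1L] * 1e-10)
  if (n_components > rank)
    stop("varimax_components: input rank is ", rank,
         ", below the requested ", n_components, " components")
  L <- pc$rotation[, seq_len(n_components), drop = FALSE] %*%
    diag(pc$sdev[seq_len(n_components)], n_components)
  if (n_components > 1L) {
    vm <- stats::varimax(L, normalize = FALSE)
    R <- vm$rotmat
    L_rot <- L %*% R
  } else {
    R <- matrix(1, 1L, 1L)
    L_rot <- L
  }
  scores <- pc$x[, seq_len(n_components), drop = FALSE] %*%
    diag(1 / pc$sdev[seq_len(n_components)], n_components) %*% R
  list(loadings = L_rot, scores = scores, rotation = R,
       var_explained = sum(pc$sdev[seq_len(n_components)]^2) /
         sum(pc$sdev^2))
}

#' Prepare a stimulus feature matrix for encoding
#'
#' The full feature processing chain: convolve each column with the
#' double-gamma HRF, spline-detrend, temporally smooth, downsample to the
#' scan rate, and z-score. Deterministic; re-running yields identical
#' output.
#'
#' @param features numeric matrix at `feature_rate` Hz, one column per
#'   feature.
#' @param feature_rate input sampling rate, Hz.
#' @param scan_rate output (scan) rate, Hz (default 0.5, i.e. TR = 2 s).
#' @param hrf an [hrf_spec()]; its `sampling_rate` is overridden with
#'   `feature_rate`.
#' @param knot_spacing_s spline detrend knot spacing, seconds.
#' @param fwhm_s temporal smoothing FWHM, seconds.
#' @param sd_type z-score convention, see [zscore_columns()].
#' @return scan-rate design matrix with standardized columns.
#' @export
prepare_features <- function(features, feature_rate, scan_rate = 0.5,
                             hrf = hrf_spec(), knot_spacing_s = 60,
                             fwhm_s = 4, sd_type = "population") {
  features <- as.matrix(features)
  hrf$sampling_rate <- feature_rate
  kernel <- double_gamma_hrf(hrf)
  out <- apply(features, 2L, function(col) {
    col <- convolve_feature(col, kernel)
    col <- detrend_spline(col, knot_spacing_s, feature_rate)
    col <- temporal_smooth(col, fwhm_s, feature_rate)
    resample_to_scans(col, feature_rate, scan_rate)
  })
  zscore_columns(out, sd_type = sd_type)
}
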