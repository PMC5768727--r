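#' Specification of a synthetic cohort
#'
#' Describes a two-group cohort (musicians vs nonmusicians) with the
#' statistical structure the decoder assumes: every region's BOLD series is
#' a noisy linear readout of the stimulus features, participants within a
#' group share a region-level mean coefficient vector, and a planted subset
#' of regions carries a group difference in those coefficients.
#'
#' The defaults mirror the study design this package targets: 18
#' participants per group, 116 anatomical regions, 720 scans (three ~8-min
#' stimuli at a 2-s repetition time, concatenated) and 6 stimulus features.
#' `effect_size` is the total separation between the group mean coefficient
#' vectors in a discriminative region (split as +/- `effect_size`/2 on one
#' randomly chosen feature coordinate per region), `beta_sd` the
#' between-participant coefficient dispersion within a group, and `noise_sd`
#' the residual BOLD noise scale. With z-scored features and unit-scale
#' coefficients, `noise_sd = 12` puts encoding-model prediction correlations
#' in the 0.1-0.3 range typical of region-averaged naturalistic fMRI.
#'
#' @param n_per_group participants per class.
#' @param n_regions number of parcellated regions.
#' @param n_discriminative number of regions whose group mean coefficients
#'   differ; must be positive whenever `effect_size > 0`.
#' @param n_timepoints scans per participant (k).
#' @param n_features stimulus features (m).
#' @param effect_size group separation delta (dimensionless, on the
#'   coefficient scale).
#' @param beta_sd within-group between-participant coefficient sd (tau).
#' @param disc_beta_sd within-group coefficient sd in the discriminative
#'   regions (default `beta_sd / 2`). Regions shaped by training are
#'   modelled as both separated between groups and more consistent within
#'   them; this within-group tightness is what the decoder's
#'   correct-group-fit region ranking keys on.
#' @param noise_sd residual noise sd (sigma) on the BOLD scale.
#' @param beta_base_sd sd of the region-level base coefficient vectors
#'   shared by both groups.
#' @param familiarity_means length-2 vector of group mean familiarity
#'   ratings (musician, nonmusician) on the 1-5 scale.
#' @param familiarity_sd familiarity rating sd (ratings are clipped to
#'   \[1, 5\]).
#' @param seed root seed; all randomness flows from it through
#'   per-participant substreams.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 18L, n_regions = 116L,
                        n_discriminative = 9L, n_timepoints = 720L,
                        n_features = 6L, effect_size = 0.5, beta_sd = 0.5,
                        disc_beta_sd = beta_sd / 2,
                        noise_sd = 12, beta_base_sd = 1,
                        familiarity_means = c(2.96, 2.07),
                        familiarity_sd = 1.1, seed = 1L) {
  assert_count(n_per_group, "n_per_group")
  assert_count(n_regions, "n_regions")
  assert_count(n_discriminative, "n_discriminative", min = 0L)
  assert_count(n_timepoints, "n_timepoints")
  assert_count(n_features, "n_features")
  if (n_discriminative > n_regions)
    stop("n_discriminative cannot exceed n_regions")
  if (effect_size < 0 || beta_sd < 0 || noise_sd < 0 || disc_beta_sd < 0)
    stop("effect_size, beta_sd, disc_beta_sd and noise_sd must be >= 0")
  if (effect_size > 0 && n_discriminative == 0L)
    stop("effect_size > 0 requires n_discriminative >= 1")
  structure(list(
    n_per_group = as.integer(n_per_group),
    n_regions = as.integer(n_regions),
    n_discriminative = as.integer(n_discriminative),
    n_timepoints = as.integer(n_timepoints),
    n_features = as.integer(n_features),
    effect_size = effect_size, beta_sd = beta_sd,
    disc_beta_sd = disc_beta_sd, noise_sd = noise_sd,
    beta_base_sd = beta_base_sd,
    familiarity_means = familiarity_means, familiarity_sd = familiarity_sd,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Generate a smooth, standardized stimulus feature matrix
#'
#' Draws white Gaussian noise per feature, smooths it with a Gaussian kernel
#' of the given sd (in samples) to induce the slow temporal autocorrelation
#' of real stimulus features, and z-scores each column. `smoothness = 0`
#' skips the smoothing and yields (approximately) white columns.
#'
#' @param k number of time points (rows); must exceed `m`.
#' @param m number of features (columns).
#' @param smoothness Gaussian kernel sd in samples (>= 0).
#' @param seed integer seed.
#' @param sd_type z-score convention, see [zscore_columns()].
#' @return k x m matrix, columns named `F1..Fm`, each with mean 0 and sd 1.
#' @export
make_feature_series <- function(k, m, smoothness = 4, seed = 1L,
                                sd_type = "population") {
  assert_count(k, "k")
  assert_count(m, "m")
  if (k <= m) stop("make_feature_series: need k > m")
  if (smoothness < 0) stop("make_feature_series: smoothness must be >= 0")
  set.seed(derive_seed(seed, 0L))
  X <- matrix(stats::rnorm(k * m), nrow = k, ncol = m)
  if (smoothness > 0) {
    fwhm_samples <- smoothness * 2 * sqrt(2 * log(2))
    X <- apply(X, 2L, temporal_smooth, fwhm_s = fwhm_samples,
               sampling_rate = 1)
  }
  X <- zscore_columns(X, sd_type = sd_type)
  colnames(X) <- paste0("F", seq_len(m))
  X
}

#' Simulate a cohort of participants
#'
#' For each region a base coefficient vector is drawn once and shared by
#' both groups; in the first `n_discriminative` regions the groups receive
#' +/- `effect_size`/2 offsets on one randomly chosen feature coordinate, so
#' `effect_size` is the total group separation. Each participant's regional
#' coefficients are drawn around their group mean with sd `beta_sd`
#' (`disc_beta_sd` in the discriminative regions, which are modelled as
#' more consistent within a group), and the BOLD series is the linear
#' readout `X %*% beta` plus i.i.d. Gaussian noise with sd `noise_sd`. Familiarity ratings are drawn per group and clipped
#' to the 1-5 rating scale.
#'
#' Randomness is organized in substreams keyed on the root seed: region-level
#' structure uses one stream, each participant another, so enlarging the
#' cohort does not perturb existing records.
#'
#' @param spec a [cohort_spec()].
#' @param X a `k x m` feature matrix matching `spec`; default generates one
#'   from the spec's seed.
#' @return an object of class `cohort`: a list of participant records
#'   (fields `id`, `group`, `familiarity`, `bold` region x time matrix),
#'   with attributes `spec`, `discriminative_regions`, `region_names`.
#' @export
make_cohort <- function(spec, X = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(X))
    X <- make_feature_series(spec$n_timepoints, spec$n_features,
                             seed = derive_seed(spec$seed, 999L))
  if (nrow(X) != spec$n_timepoints || ncol(X) != spec$n_features)
    stop("make_cohort: X dimensions do not match the cohort spec")

  nr <- spec$n_regions; m <- spec$n_features; k <- spec$n_timepoints
  disc <- seq_len(spec$n_discriminative)

  # region-level structure: one substream. Base vectors have random
  # direction but a common norm so every region is equally coupled to the
  # stimulus; region ranking then reflects the planted group structure
  # rather than arbitrary signal-to-noise differences between regions.
  set.seed(derive_seed(spec$seed, 1L))
  beta_base <- matrix(stats::rnorm(nr * m), nrow = nr, ncol = m)
  beta_base <- beta_base / sqrt(rowSums(beta_base^2)) *
    (spec$beta_base_sd * sqrt(m))
  disc_coord <- sample.int(m, spec$n_discriminative, replace = TRUE)

  beta_group <- list(musician = beta_base, nonmusician = beta_base)
  if (spec$n_discriminative > 0L && spec$effect_size > 0) {
    # zero the base component on the discriminative coordinate (and
    # restore the common norm) before applying the +/- delta/2 offsets:
    # the groups then differ purely in direction, with identical overall
    # stimulus coupling, so delta is a clean separation parameter
    idx <- cbind(disc, disc_coord)
    beta_base[idx] <- 0
    beta_base[disc, ] <- beta_base[disc, , drop = FALSE] /
      sqrt(rowSums(beta_base[disc, , drop = FALSE]^2)) *
      (spec$beta_base_sd * sqrt(m))
    beta_group <- list(musician = beta_base, nonmusician = beta_base)
    beta_group$musician[idx] <- beta_group$musician[idx] + spec$effect_size / 2
    beta_group$nonmusician[idx] <- beta_group$nonmusician[idx] - spec$effect_size / 2
  }

  groups <- rep(c("musician", "nonmusician"), each = spec$n_per_group)
  records <- vector("list", length(groups))
  tau <- rep(spec$beta_sd, nr)
  tau[disc] <- spec$disc_beta_sd
  for (p in seq_along(groups)) {
    set.seed(derive_seed(spec$seed, 100L + p))
    g <- groups[p]
    beta_p <- beta_group[[g]] +
      matrix(stats::rnorm(nr * m), nrow = nr, ncol = m) * tau
    bold <- beta_p %*% t(X) +
      matrix(stats::rnorm(nr * k, sd = spec$noise_sd), nrow = nr, ncol = k)
    fam_mean <- spec$familiarity_means[if (g == "musician") 1L else 2L]
    fam <- stats::rnorm(1L, fam_mean, spec$familiarity_sd)
    fam <- min(max(fam, 1), 5)
    rownames(bold) <- paste0("R", seq_len(nr))
    records[[p]] <- list(
      id = sprintf("%s%02d", if (g == "musician") "M" else "N",
                   ((p - 1L) %% spec$n_per_group) + 1L),
      group = g, familiarity = fam, bold = bold
    )
  }
  structure(records,
            class = "cohort",
            spec = spec,
            feature_matrix = X,
            discriminative_regions = as.integer(disc),
            region_names = paste0("R", seq_len(nr)))
}

#' @export
print.cohort <- function(x, ...) {
  spec <- attr(x, "spec")
  cat(sprintf("Synthetic cohort: %d participants (%d per group), %d regions, k = %d\n",
              length(x), spec$n_per_group, spec$n_regions, spec$n_timepoints))
  cat(sprintf("  effect size %.3g in %d planted region(s); beta sd %.3g; noise sd %.3g\n",
              spec$effect_size, spec$n_discriminative, spec$beta_sd,
              spec$noise_sd))
  invisible(x)
}

#' @keywords internal
cohort_labels <- function(cohort) {
  vapply(cohort, function(p) p$group, character(1L))
}

#' @keywords internal
cohort_ids <- function(cohort) {
  vapply(cohort, function(p) p$id, character(1L))
}
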