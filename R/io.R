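# Delimited-matrix cohort layout: one metadata manifest (TSV: id, group,
# familiarity, path) plus one region x time matrix file per participant,
# regions as rows with their names in the first column, time indices in
# the header. Synthetic and real cohorts share this layout.

#' @keywords internal
provenance_header <- function(seed = NULL, config = NULL) {
  ver <- tryCatch(as.character(utils::packageVersion("musdecode")),
                  error = function(e) "dev")
  h <- sprintf("# musdecode %s", ver)
  if (!is.null(seed)) h <- c(h, sprintf("# seed: %s", seed))
  if (!is.null(config))
    h <- c(h, sprintf("# config: %s", config_hash(config)))
  h
}

# small polynomial rolling hash of a deparsed object, for provenance headers
#' @keywords internal
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ";"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Write a region-by-time matrix
#'
#' TSV with a provenance header, region names in the first column and one
#' column per time point; values at full double precision so write/read
#' round-trips are lossless.
#'
#' @param mat numeric matrix (regions x time), rownames = region names.
#' @param path output file.
#' @param seed,config optional provenance fields.
#' @export
write_region_matrix <- function(mat, path, seed = NULL, config = NULL) {
  rn <- rownames(mat) %||% paste0("R", seq_len(nrow(mat)))
  header <- paste(c("region", paste0("t", seq_len(ncol(mat)))),
                  collapse = "\t")
  body <- vapply(seq_len(nrow(mat)), function(i)
    paste(c(rn[i], sprintf("%.17g", mat[i, ])), collapse = "\t"),
    character(1L))
  writeLines(c(provenance_header(seed, config), header, body), path)
  invisible(path)
}

#' Read a region-by-time matrix
#'
#' Reads the TSV layout of [write_region_matrix()]; also accepts CSV
#' (delimiter auto-detected from the header line) and matrices written
#' time-as-rows (auto-transposed when the first column matches known time
#' labels rather than region names).
#'
#' @param path input file.
#' @return numeric matrix with region rownames.
#' @export
read_region_matrix <- function(path) {
  if (!file.exists(path))
    stop("read_region_matrix: no such file: ", path)
  first <- readLines(path, n = 50L)
  first <- first[!startsWith(first, "#")][1L]
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  rn <- df[[1L]]
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  rownames(mat) <- rn
  if (all(grepl("^t[0-9]+$", rn)))      # written time-as-rows: transpose
    mat <- t(mat)
  colnames(mat) <- NULL
  mat
}

#' Write a cohort to disk
#'
#' Writes the manifest (`manifest.tsv`), one region x time matrix per
#' participant, and the design matrix (`features.tsv`) if the cohort
#' carries one.
#'
#' @param cohort a cohort object.
#' @param dir output directory (created if needed).
#' @return the manifest path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- attr(cohort, "spec")
  seed <- if (!is.null(spec)) spec$seed else NULL
  paths <- character(length(cohort))
  for (i in seq_along(cohort)) {
    p <- cohort[[i]]
    paths[i] <- paste0(p$id, ".tsv")
    write_region_matrix(p$bold, file.path(dir, paths[i]), seed = seed,
                        config = spec)
  }
  man <- data.frame(id = cohort_ids(cohort), group = cohort_labels(cohort),
                    familiarity = vapply(cohort, function(p)
                      p$familiarity %||% NA_real_, numeric(1L)),
                    path = paths, stringsAsFactors = FALSE)
  man_path <- file.path(dir, "manifest.tsv")
  lines <- c(provenance_header(seed, spec),
             paste(names(man), collapse = "\t"),
             vapply(seq_len(nrow(man)), function(i)
               paste(c(man$id[i], man$group[i],
                       sprintf("%.17g", man$familiarity[i]), man$path[i]),
                     collapse = "\t"), character(1L)))
  writeLines(lines, man_path)
  X <- attr(cohort, "feature_matrix")
  if (!is.null(X))
    write_region_matrix(t(X), file.path(dir, "features.tsv"), seed = seed,
                        config = spec)
  invisible(man_path)
}

#' Read a cohort from disk
#'
#' Reads a manifest and the participant matrices it references, validating
#' unique ids, known group labels, class balance and dimensional
#' consistency across participants.
#'
#' @param manifest_path path to a `manifest.tsv` written by
#'   [write_cohort()] (or hand-built in the same layout).
#' @param require_balance error if the two groups differ in size
#'   (default TRUE, since the decoder's cross-validation needs balance).
#' @return a cohort object; if a `features.tsv` sits next to the manifest
#'   it is attached as the `feature_matrix` attribute.
#' @export
read_cohort <- function(manifest_path, require_balance = TRUE) {
  if (!file.exists(manifest_path))
    stop("read_cohort: no such manifest: ", manifest_path)
  man <- utils::read.table(manifest_path, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  need <- c("id", "group", "path")
  if (!all(need %in% names(man)))
    stop("read_cohort: manifest must have columns ",
         paste(need, collapse = ", "))
  if (anyDuplicated(man$id))
    stop("read_cohort: duplicate participant ids: ",
         paste(unique(man$id[duplicated(man$id)]), collapse = ", "))
  bad <- !man$group %in% c("musician", "nonmusician")
  if (any(bad))
    stop("read_cohort: unknown group label(s): ",
         paste(unique(man$group[bad]), collapse = ", "))
  dir <- dirname(manifest_path)
  records <- vector("list", nrow(man))
  dims <- matrix(0L, nrow(man), 2L)
  for (i in seq_len(nrow(man))) {
    fp <- file.path(dir, man$path[i])
    if (!file.exists(fp))
      stop("read_cohort: matrix file missing for participant ",
           man$id[i], ": ", fp)
    bold <- read_region_matrix(fp)
    dims[i, ] <- dim(bold)
    records[[i]] <- list(id = man$id[i], group = man$group[i],
                         familiarity = if ("familiarity" %in% names(man))
                           man$familiarity[i] else NA_real_,
                         bold = bold)
  }
  if (nrow(man) > 1L && (length(unique(dims[, 1L])) > 1L ||
                         length(unique(dims[, 2L])) > 1L)) {
    ref <- dims[1L, ]
    off <- which(dims[, 1L] != ref[1L] | dims[, 2L] != ref[2L])
    stop("read_cohort: inconsistent matrix dimensions for participant(s): ",
         paste(man$id[off], collapse = ", "))
  }
  n_m <- sum(man$group == "musician")
  if (require_balance && n_m != nrow(man) - n_m)
    stop("read_cohort: unbalanced cohort (", n_m, " musicians vs ",
         nrow(man) - n_m, " nonmusicians)")
  out <- structure(records, class = "cohort",
                   region_names = rownames(records[[1L]]$bold))
  feat_path <- file.path(dir, "features.tsv")
  if (file.exists(feat_path))
    attr(out, "feature_matrix") <- t(read_region_matrix(feat_path))
  out
}

#' Average voxel time series within labelled regions
#'
#' Reduces a 4-D volume time series to a region x time matrix by the
#' unweighted mean over each region's voxels at every time point.
#'
#' @param volume 4-D numeric array (x, y, z, time).
#' @param label_volume 3-D integer array of region labels, spatially
#'   aligned with `volume`; 0 (or NA) marks background.
#' @param region_ids integer labels to extract (default: all positive
#'   labels present, sorted).
#' @param region_names optional names for the rows (default `"R<label>"`).
#' @return region x time matrix; regions with no voxels are returned as
#'   all-NA rows with a warning.
#' @export
parcellate <- function(volume, label_volume, region_ids = NULL,
                       region_names = NULL) {
  dv <- dim(volume); dl <- dim(label_volume)
  if (length(dv) != 4L || length(dl) != 3L || !all(dv[1:3] == dl))
    stop("parcellate: volume must be 4-D and spatially aligned with the ",
         "3-D label volume")
  lab <- as.integer(label_volume)
  lab[is.na(lab)] <- 0L
  if (is.null(region_ids))
    region_ids <- sort(unique(lab[lab > 0L]))
  nt <- dv[4L]
  vmat <- matrix(volume, ncol = nt)      # voxels x time
  out <- matrix(NA_real_, length(region_ids), nt)
  empty <- character(0L)
  for (i in seq_along(region_ids)) {
    vox <- which(lab == region_ids[i])
    if (length(vox) == 0L) {
      empty <- c(empty, as.character(region_ids[i]))
      next
    }
    out[i, ] <- colMeans(vmat[vox, , drop = FALSE])
  }
  if (length(empty) > 0L)
    warning("parcellate: empty region(s), emitted as NA: ",
            paste(empty, collapse = ", "))
  rownames(out) <- region_names %||% paste0("R", region_ids)
  out
}

#' Serialize group models for one region pair
#'
#' Writes both groups' mean and variance vectors with a JSON header
#' recording the group labels, series length, variance floor and
#' estimator convention.
#'
#' @param model_m,model_n `gaussian_group_model`s.
#' @param path output file.
#' @export
write_group_models <- function(model_m, model_n, path) {
  hdr <- jsonlite::toJSON(list(groups = c(model_m$group, model_n$group),
                               k = model_m$k,
                               var_floor = model_m$var_floor,
                               var_type = model_m$var_type),
                          auto_unbox = TRUE)
  lines <- c(paste0("# ", hdr),
             paste(c("mu_M", sprintf("%.17g", model_m$mu)), collapse = "\t"),
             paste(c("sigma2_M", sprintf("%.17g", model_m$sigma2)),
                   collapse = "\t"),
             paste(c("mu_N", sprintf("%.17g", model_n$mu)), collapse = "\t"),
             paste(c("sigma2_N", sprintf("%.17g", model_n$sigma2)),
                   collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}
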