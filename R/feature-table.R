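#' Construct a feature table
#'
#' An aligned LC-MS feature table: per-feature attributes (m/z, retention
#' time, upstream isotope annotation), a non-negative integrated-area
#' matrix (features x samples), sample metadata, and a provenance log of
#' the filters applied. Peak picking, alignment and isotope detection are
#' upstream of this container; the isotope flag is an input column.
#'
#' @param features Tibble/data.frame with columns `feature_id` (unique),
#'   `mz` (> 0), `rt_min` (>= 0), `isotope_flag` (logical).
#' @param areas Numeric matrix, rows = features (named by `feature_id`),
#'   columns = samples (named by `sample_id`), all values >= 0.
#' @param samples Tibble/data.frame with columns `sample_id` (unique),
#'   `strain`, `host` (`highbush`/`wild`), `medium` (`ML`/`PDB`),
#'   `matrix` (`filtrate`/`mycelium`).
#' @param log Character vector of provenance lines.
#' @return An object of class `feature_table`.
#' @export
feature_table <- function(features, areas, samples, log = character(0)) {
  features <- tibble::as_tibble(features)
  samples <- tibble::as_tibble(samples)
  need_f <- c("feature_id", "mz", "rt_min", "isotope_flag")
  need_s <- c("sample_id", "strain", "host", "medium", "matrix")
  miss_f <- setdiff(need_f, names(features))
  miss_s <- setdiff(need_s, names(samples))
  if (length(miss_f)) stop("features table missing column(s): ",
                           paste(miss_f, collapse = ", "), call. = FALSE)
  if (length(miss_s)) stop("sample metadata missing column(s): ",
                           paste(miss_s, collapse = ", "), call. = FALSE)
  if (anyDuplicated(features$feature_id)) {
    stop("duplicate feature_id values", call. = FALSE)
  }
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id values", call. = FALSE)
  }
  check_levels <- function(x, field, levels) {
    bad <- setdiff(unique(x), levels)
    if (length(bad)) stop("unknown level(s) in ", field, ": ",
                          paste(sQuote(bad), collapse = ", "), call. = FALSE)
  }
  check_levels(samples$host, "host", c("highbush", "wild"))
  check_levels(samples$medium, "medium", c("ML", "PDB"))
  check_levels(samples$matrix, "matrix", c("filtrate", "mycelium"))
  areas <- as.matrix(areas)
  if (!setequal(rownames(areas), features$feature_id) ||
      !setequal(colnames(areas), samples$sample_id)) {
    stop("area matrix dimnames must match feature_id and sample_id",
         call. = FALSE)
  }
  areas <- areas[features$feature_id, samples$sample_id, drop = FALSE]
  if (any(is.na(areas)) || any(areas < 0)) {
    stop("areas must be non-negative and complete", call. = FALSE)
  }
  stopifnot(all(features$mz > 0), all(features$rt_min >= 0),
            is.logical(features$isotope_flag))
  structure(list(features = features, areas = areas, samples = samples,
                 log = log),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table> ", nrow(x$features), " features x ",
      nrow(x$samples), " samples\n", sep = "")
  if (length(x$log)) cat(paste0("  - ", x$log, collapse = "\n"), "\n")
  invisible(x)
}

#' Read a feature table and sample metadata from CSV
#'
#' Strict schema: the features CSV has columns `feature_id`, `mz`,
#' `rt_min`, `isotope_flag` and then exactly one area column per
#' `sample_id` in the metadata CSV; the metadata CSV has `sample_id`,
#' `strain`, `host`, `medium`, `matrix`. Header rows required; UTF-8.
#'
#' @param features_csv,metadata_csv File paths.
#' @return A `feature_table`.
#' @export
read_feature_table <- function(features_csv, metadata_csv) {
  feats <- utils::read.csv(features_csv, stringsAsFactors = FALSE,
                           check.names = FALSE, encoding = "UTF-8")
  meta <- utils::read.csv(metadata_csv, stringsAsFactors = FALSE,
                          check.names = FALSE, encoding = "UTF-8")
  need_f <- c("feature_id", "mz", "rt_min", "isotope_flag")
  miss <- setdiff(need_f, names(feats))
  if (length(miss)) stop("features CSV missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  area_cols <- setdiff(names(feats), need_f)
  miss_a <- setdiff(meta$sample_id, area_cols)
  if (length(miss_a)) stop("features CSV missing area column(s) for sample(s): ",
                           paste(miss_a, collapse = ", "), call. = FALSE)
  if (is.character(feats$isotope_flag)) {
    feats$isotope_flag <- feats$isotope_flag %in% c("TRUE", "true", "1")
  }
  feats$isotope_flag <- as.logical(feats$isotope_flag)
  areas <- as.matrix(feats[, meta$sample_id, drop = FALSE])
  rownames(areas) <- feats$feature_id
  ft <- feature_table(feats[, need_f], areas, meta)
  ft$log <- sprintf("read %d features x %d samples from %s",
                    nrow(ft$features), nrow(ft$samples),
                    basename(features_csv))
  ft
}

#' Write a feature table to CSV
#'
#' Inverse of [read_feature_table()]: writes `<stem>_features.csv` and
#' `<stem>_metadata.csv`.
#'
#' @param t A `feature_table`.
#' @param stem Output path stem.
#' @return The two paths, invisibly.
#' @export
write_feature_table <- function(t, stem) {
  fpath <- paste0(stem, "_features.csv")
  mpath <- paste0(stem, "_metadata.csv")
  out <- cbind(t$features, as.data.frame(t$areas, check.names = FALSE))
  utils::write.csv(out, fpath, row.names = FALSE)
  utils::write.csv(t$samples, mpath, row.names = FALSE)
  invisible(c(features = fpath, metadata = mpath))
}

#' Apply the feature-list filters
#'
#' Produces the final metabolite feature list: (1) features flagged as
#' isotopic ions are removed; (2) a feature is removed when its maximum
#' integrated area across retained samples is strictly below `area_min`
#' (the unit of the feature list is the feature, so the threshold applies
#' to the per-feature maximum, not per cell); (3) for a mycelium-matrix
#' table (all samples `matrix == "mycelium"`), features eluting after
#' `mycelium_rt_max` minutes are removed. Mixed-matrix tables should be
#' split with [split_by_matrix()] first; the retention-time rule is scoped
#' to the mycelium metabolome only. Idempotent; never alters retained
#' values.
#'
#' @param t A `feature_table`.
#' @param area_min Minimum per-feature maximum area (> 0); default 10000.
#' @param mycelium_rt_max Retention-time ceiling in minutes for mycelium
#'   tables (> 0); default 25.
#' @return The filtered `feature_table` with provenance appended.
#' @export
filter_features <- function(t, area_min = 10000, mycelium_rt_max = 25) {
  stopifnot(inherits(t, "feature_table"), area_min > 0, mycelium_rt_max > 0)
  keep <- !t$features$isotope_flag
  max_area <- apply(t$areas, 1L, max)
  keep <- keep & max_area >= area_min
  all_mycelium <- nrow(t$samples) > 0 && all(t$samples$matrix == "mycelium")
  if (all_mycelium) keep <- keep & t$features$rt_min <= mycelium_rt_max
  out <- t
  out$features <- t$features[keep, , drop = FALSE]
  out$areas <- t$areas[keep, , drop = FALSE]
  out$log <- c(t$log, sprintf(
    "filter: isotopes removed, max area >= %g%s; %d -> %d features",
    area_min,
    if (all_mycelium) sprintf(", rt <= %g min (mycelium)", mycelium_rt_max)
    else "",
    nrow(t$features), sum(keep)))
  out
}

#' Split a feature table by extract matrix
#'
#' @param t A `feature_table`.
#' @return A named list of `feature_table`s, one per matrix level present.
#' @export
split_by_matrix <- function(t) {
  lapply(stats::setNames(nm = unique(t$samples$matrix)), function(m) {
    subset_samples(t, t$samples$matrix == m)
  })
}

#' Subset the samples of a feature table
#'
#' @param t A `feature_table`.
#' @param which Logical or integer index into the sample rows.
#' @return A `feature_table` with the selected samples.
#' @export
subset_samples <- function(t, which) {
  out <- t
  out$samples <- t$samples[which, , drop = FALSE]
  out$areas <- t$areas[, t$samples$sample_id[which], drop = FALSE]
  out$log <- c(t$log, sprintf("subset to %d samples", nrow(out$samples)))
  out
}

#' Pareto scaling
#'
#' Mean-centers each feature column, then divides by the square root of its
#' standard deviation (n-1 denominator) — the compromise between unit
#' variance and no scaling conventional for LC-MS areas. A scaled
#' non-constant column has mean 0 and variance equal to the pre-scaling
#' standard deviation. Zero-variance columns are centered only and flagged
#' in the `"constant"` attribute. Not idempotent: apply once, which the
#' provenance log of the pipeline enforces.
#'
#' @param X Numeric matrix, samples x features (>= 2 samples).
#' @return The scaled matrix with attributes `center`, `scale` (sqrt of
#'   sd, 1 for constant columns) and `constant` (logical per column).
#' @export
pareto_scale <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("pareto scaling needs at least 2 samples",
                         call. = FALSE)
  ctr <- colMeans(X)
  sds <- apply(X, 2L, stats::sd)
  constant <- sds == 0
  scl <- ifelse(constant, 1, sqrt(sds))
  out <- sweep(sweep(X, 2L, ctr, "-"), 2L, scl, "/")
  attr(out, "center") <- ctr
  attr(out, "scale") <- scl
  attr(out, "constant") <- constant
  out
}
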