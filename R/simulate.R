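#' Study design for the synthetic feature-table generator
#'
#' Encodes the structure of the endophyte culturing study the pipeline was
#' built around: 15 strains (4 from highbush, 11 from wild blueberry) each
#' grown on two media (ML, PDB) and extracted from two matrices (filtrate,
#' mycelium), yielding 60 samples; 3856 aligned LC-MS features. Per
#' contrast (medium; host within ML; host within PDB) a disjoint set of
#' marker features is planted with a log-scale abundance shift.
#'
#' Defaults not dictated by the study design are conventional for LC-MS
#' metabolomics: log-normal integrated areas (between-feature baseline
#' log-mean 10.5, log-sd 1.2; within-feature biological/technical log-sd
#' 0.4, i.e. ~40% CV), 5% isotope-flagged features, markers shifted by
#' `effect_size` within-feature standard deviations on the log scale and
#' planted among the abundant features (above the `marker_min_quantile`
#' baseline quantile), as condition-discriminant secondary metabolites
#' present as major peaks.
#'
#' @param n_highbush,n_wild Strains per host group.
#' @param n_features Number of aligned features.
#' @param n_markers Planted markers per contrast.
#' @param effect_size Log-scale marker shift, in units of `log_sd_within`.
#' @param marker_min_quantile Markers are drawn from features whose
#'   baseline abundance lies above this quantile (default 0.9):
#'   condition-discriminant secondary metabolites present as major
#'   chromatographic peaks (isolable at mg quantities), not trace
#'   features.
#' @param log_mean,log_sd_between Baseline abundance distribution across
#'   features (log scale).
#' @param log_sd_within Within-feature log-sd across samples.
#' @param isotope_fraction Fraction of features flagged as isotopic ions.
#' @param mz_range,rt_range Acquisition m/z range and gradient length.
#' @param seed Mandatory integer seed.
#' @return A list of class `study_design`.
#' @export
study_design <- function(n_highbush = 4, n_wild = 11, n_features = 3856,
                         n_markers = 30, effect_size = 3,
                         marker_min_quantile = 0.9,
                         log_mean = 10.5, log_sd_between = 1.2,
                         log_sd_within = 0.4, isotope_fraction = 0.05,
                         mz_range = c(150, 1100), rt_range = c(0, 31),
                         seed) {
  stopifnot(effect_size >= 0, n_features >= 1, !missing(seed))
  structure(as.list(environment()), class = "study_design")
}

#' Simulate a feature table with planted group markers
#'
#' Draws a full study feature table from a [study_design()]: every
#' strain x medium x matrix combination is one sample; integrated areas are
#' log-normal per feature; for each of the three contrasts (`medium`:
#' ML vs PDB; `host_ML`: highbush vs wild within ML; `host_PDB`: within
#' PDB) a disjoint marker set is multiplied by
#' `exp(direction * effect_size * log_sd_within)` in the first-named group
#' (direction drawn ±1 per marker). Feature m/z is uniform over the
#' acquisition range and retention time uniform over the gradient;
#' `isotope_fraction` of features carry the isotope flag. Fully
#' reproducible from the design seed.
#'
#' @param design A `study_design`.
#' @return A list: `table` (a [feature_table()]) and `truth` (tibble of
#'   planted markers: `contrast`, `feature_id`, `direction`).
#' @export
simulate_study <- function(design) {
  d <- design
  if (3L * d$n_markers > d$n_features) {
    stop("marker count exceeds feature count", call. = FALSE)
  }
  strains <- c(sprintf("HB-%02d", seq_len(d$n_highbush)),
               sprintf("WL-%02d", seq_len(d$n_wild)))
  hosts <- rep(c("highbush", "wild"), c(d$n_highbush, d$n_wild))
  grid <- expand.grid(matrix = c("filtrate", "mycelium"),
                      medium = c("ML", "PDB"),
                      strain = strains, stringsAsFactors = FALSE)
  grid$host <- hosts[match(grid$strain, strains)]
  samples <- tibble::tibble(
    sample_id = sprintf("%s_%s_%s", grid$strain, grid$medium,
                        substr(grid$matrix, 1, 3)),
    strain = grid$strain, host = grid$host, medium = grid$medium,
    matrix = grid$matrix)

  with_seed(d$seed, {
    fid <- sprintf("F%04d", seq_len(d$n_features))
    features <- tibble::tibble(
      feature_id = fid,
      mz = stats::runif(d$n_features, d$mz_range[1], d$mz_range[2]),
      rt_min = stats::runif(d$n_features, d$rt_range[1], d$rt_range[2]),
      isotope_flag = stats::runif(d$n_features) < d$isotope_fraction)
    base_log <- stats::rnorm(d$n_features, d$log_mean, d$log_sd_between)
    n_samp <- nrow(samples)
    log_area <- matrix(stats::rnorm(d$n_features * n_samp,
                                    mean = rep(base_log, n_samp),
                                    sd = d$log_sd_within),
                       nrow = d$n_features, ncol = n_samp,
                       dimnames = list(fid, samples$sample_id))

    abundant <- fid[base_log >= stats::quantile(base_log,
                                                 d$marker_min_quantile)]
    if (length(abundant) < 3L * d$n_markers) abundant <- fid
    marker_ids <- matrix(sample(abundant, 3L * d$n_markers), ncol = 3L)
    contrasts <- list(
      medium = list(markers = marker_ids[, 1L],
                    in_group = samples$medium == "ML"),
      host_ML = list(markers = marker_ids[, 2L],
                     in_group = samples$host == "highbush" &
                       samples$medium == "ML"),
      host_PDB = list(markers = marker_ids[, 3L],
                      in_group = samples$host == "highbush" &
                        samples$medium == "PDB"))
    truth_rows <- list()
    for (cn in names(contrasts)) {
      ct <- contrasts[[cn]]
      dir <- sample(c(-1, 1), d$n_markers, replace = TRUE)
      shift <- dir * d$effect_size * d$log_sd_within
      rows <- match(ct$markers, fid)
      log_area[rows, ct$in_group] <- log_area[rows, ct$in_group] + shift
      truth_rows[[cn]] <- tibble::tibble(contrast = cn,
                                         feature_id = ct$markers,
                                         direction = dir)
    }
    truth <- do.call(rbind, truth_rows)
    areas <- exp(log_area)
    list(table = feature_table(features, areas, samples,
                               log = sprintf("simulated study (seed %d)",
                                             d$seed)),
         truth = truth)
  })
}

#' Simulate an MS/MS spectrum of a cyclic peptide
#'
#' Takes the deduplicated theoretical cyclospectrum, jitters each mass with
#' Gaussian noise, drops a random fraction of peaks, and adds uniform
#' contaminant peaks between the smallest residue ion and the precursor.
#' With zero noise, dropout and contaminants the result is exactly the
#' deduplicated cyclospectrum.
#'
#' @param p A `cyclic_peptide`.
#' @param mz_noise_sd Gaussian m/z jitter (Da).
#' @param dropout Fraction of theoretical peaks dropped (0 <= dropout < 1).
#' @param n_contaminants Number of uniform contaminant peaks.
#' @param seed Integer seed.
#' @return An `msms_spectrum` with precursor `precursor_mz(p)`.
#' @export
simulate_msms <- function(p, mz_noise_sd = 0, dropout = 0,
                          n_contaminants = 0, seed = 1) {
  stopifnot(dropout >= 0, dropout < 1, mz_noise_sd >= 0, n_contaminants >= 0)
  theo <- cyclospectrum(p, dedup = TRUE)
  prec <- precursor_mz(p)
  with_seed(seed, {
    keep <- stats::runif(length(theo)) >= dropout
    mz <- theo[keep] + stats::rnorm(sum(keep), 0, mz_noise_sd)
    if (n_contaminants > 0) {
      mz <- c(mz, stats::runif(n_contaminants, min(theo) * 0.5, prec))
    }
    msms_spectrum(prec, mz)
  })
}
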