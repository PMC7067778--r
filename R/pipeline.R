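#' Run the discovery workflow on a feature table
#'
#' Orchestrates the statistics half of the metabolomic-guided discovery
#' pipeline for one two-group contrast: subset the samples, apply the
#' feature filters, pareto-scale, fit OPLS-DA, compute the cross-validated
#' Q2 and verdict, rank features by VIP, compute S-plot coordinates, run
#' the include/exclude-top-VIP subset validation, and dereplicate the
#' prioritized features against the bundled compound library.
#'
#' @param t A [feature_table()].
#' @param contrast Name of the metadata column defining the two groups
#'   (`"medium"`, `"host"`, ...).
#' @param sample_filter Optional logical vector over samples selecting the
#'   subset to model (e.g. one matrix, one medium).
#' @param area_min,mycelium_rt_max Passed to [filter_features()].
#' @param n_orth,folds,seed,top_n Modeling parameters; `top_n` also drives
#'   [validate_subset()].
#' @param vip_min VIP threshold marking significant drivers (default 0.7).
#' @param tol_ppm,tol_rt Dereplication windows.
#' @param out_dir Optional directory: when given, the filtered table,
#'   ledger, VIP ranking, S-plot coordinates and dereplication hits are
#'   written as CSV.
#' @return A list: `table` (filtered), `model`, `q2`, `verdict`,
#'   `vip` (with `mz`, `rt_min` and `significant` columns), `s_plot`,
#'   `validation` (ledger + useful-subset flag), `derep_hits`.
#' @export
run_discovery <- function(t, contrast, sample_filter = NULL,
                          area_min = 10000, mycelium_rt_max = 25,
                          n_orth = 1, folds = 7, seed = 1, top_n = 30,
                          vip_min = 0.7, tol_ppm = 5, tol_rt = 0.5,
                          out_dir = NULL) {
  stopifnot(inherits(t, "feature_table"),
            contrast %in% c("medium", "host", "matrix", "strain"))
  if (!is.null(sample_filter)) t <- subset_samples(t, sample_filter)
  groups <- t$samples[[contrast]]
  if (length(unique(groups)) != 2L) {
    stop("contrast ", sQuote(contrast), " does not define two groups on ",
         "the selected samples", call. = FALSE)
  }
  t <- filter_features(t, area_min = area_min,
                       mycelium_rt_max = mycelium_rt_max)
  X <- pareto_scale(base::t(t$areas))
  model <- fit_oplsda(X, groups, n_orth = n_orth)
  q2 <- cross_validate_q2(X, groups, n_orth = n_orth, folds = folds,
                          seed = seed)
  vip <- vip_scores(model, feature_id = t$features$feature_id,
                    mz = t$features$mz)
  vip$mz <- t$features$mz[match(vip$feature_id, t$features$feature_id)]
  vip$rt_min <- t$features$rt_min[match(vip$feature_id,
                                        t$features$feature_id)]
  vip$significant <- vip$vip > vip_min
  splot <- s_plot(model, X, feature_id = t$features$feature_id)
  validation <- validate_subset(X, groups, ranking = vip, top_n = top_n,
                                n_orth = n_orth, folds = folds, seed = seed,
                                conditions = contrast)
  top <- vip[seq_len(min(top_n, nrow(vip))), ]
  hits <- do.call(rbind, lapply(seq_len(nrow(top)), function(i) {
    h <- dereplicate(top$mz[i], top$rt_min[i], tol_ppm = tol_ppm,
                     tol_rt = tol_rt)
    if (nrow(h) == 0L) return(NULL)
    h$feature_id <- top$feature_id[i]
    h
  }))
  if (is.null(hits)) hits <- tibble::tibble()
  out <- list(table = t, model = model, q2 = q2,
              verdict = classify_model(q2), vip = vip, s_plot = splot,
              validation = validation, derep_hits = hits)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(out$validation$ledger,
                     file.path(out_dir, "validation_ledger.csv"),
                     row.names = FALSE)
    utils::write.csv(vip, file.path(out_dir, "vip_ranking.csv"),
                     row.names = FALSE)
    utils::write.csv(splot, file.path(out_dir, "s_plot.csv"),
                     row.names = FALSE)
    if (nrow(hits)) utils::write.csv(hits,
                                     file.path(out_dir, "derep_hits.csv"),
                                     row.names = FALSE)
    write_feature_table(t, file.path(out_dir, "filtered"))
  }
  out
}
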