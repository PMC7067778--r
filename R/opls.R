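#' Fit a two-class OPLS-DA model
#'
#' Orthogonal projections to latent structures discriminant analysis for a
#' binary outcome, fitted by the NIPALS-style O-PLS decomposition: a single
#' predictive component (sufficient for one response column) after
#' iterative removal of `n_orth` Y-orthogonal components. The class vector
#' is coded -1/+1 and mean-centered; X columns are mean-centered internally
#' (centering an already centered matrix is a no-op), so the caller
#' normally passes a [pareto_scale()]d matrix.
#'
#' Per orthogonal round: with the predictive weight `w` (X'y normalized),
#' scores `t = Xw`, loadings `p = X't/t't`, the orthogonal weight is the
#' part of `p` orthogonal to `w`, normalized; its scores/loadings are
#' deflated from X. The final predictive component is extracted from the
#' deflated matrix. The fit is deterministic.
#'
#' @param X Numeric matrix, samples x features.
#' @param y Two-level factor/character/numeric class labels, length
#'   `nrow(X)`.
#' @param n_orth Number of orthogonal components (0 <= n_orth <= n-3).
#' @return An object of class `opls_model`: predictive weights `w` (unit
#'   norm), scores `t`, loadings `p`, regression scalar `c`; orthogonal
#'   `w_orth`, `t_orth`, `p_orth` (columns per component); `r2x`, `r2y`;
#'   centers and label coding needed for prediction.
#' @examples
#' set.seed(1)
#' X <- matrix(rnorm(20 * 10), 20)
#' X[, 1] <- X[, 1] + rep(c(2, -2), each = 10)
#' m <- fit_oplsda(X, rep(c("a", "b"), each = 10), n_orth = 1)
#' m$r2y
#' @export
fit_oplsda <- function(X, y, n_orth = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 4L) stop("OPLS-DA needs at least 4 samples", call. = FALSE)
  lev <- sort(unique(as.character(y)))
  if (length(lev) != 2L) stop("y must have exactly two classes", call. = FALSE)
  if (n_orth < 0 || n_orth >= n - 2L) {
    stop("n_orth must satisfy 0 <= n_orth < n - 2", call. = FALSE)
  }
  yv <- ifelse(as.character(y) == lev[2L], 1, -1)
  y_center <- mean(yv)
  yc <- yv - y_center
  x_center <- colMeans(X)
  Xc <- sweep(X, 2L, x_center, "-")
  ss_x_total <- sum(Xc^2)

  w_orth <- t_orth <- p_orth <- NULL
  Xd <- Xc
  for (a in seq_len(n_orth)) {
    w <- crossprod(Xd, yc)[, 1L]
    w <- w / sqrt(sum(w^2))
    tt <- Xd %*% w
    p <- crossprod(Xd, tt)[, 1L] / sum(tt^2)
    wo <- p - sum(w * p) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) break  # no orthogonal variation left
    wo <- wo / nwo
    to <- Xd %*% wo
    po <- crossprod(Xd, to)[, 1L] / sum(to^2)
    Xd <- Xd - to %*% t(po)
    w_orth <- cbind(w_orth, wo)
    t_orth <- cbind(t_orth, to)
    p_orth <- cbind(p_orth, po)
  }
  w <- crossprod(Xd, yc)[, 1L]
  w <- w / sqrt(sum(w^2))
  tt <- (Xd %*% w)[, 1L]
  p <- crossprod(Xd, tt)[, 1L] / sum(tt^2)
  cc <- sum(yc * tt) / sum(tt^2)
  y_hat <- tt * cc
  r2y <- 1 - sum((yc - y_hat)^2) / sum(yc^2)
  ss_model <- sum((tt %*% t(p))^2) +
    (if (is.null(t_orth)) 0 else
      sum(vapply(seq_len(ncol(t_orth)), function(a) {
        sum((t_orth[, a] %*% t(p_orth[, a]))^2)
      }, numeric(1))))
  r2x <- ss_model / ss_x_total
  structure(list(w = w, scores = tt, p = p, c = cc,
                 w_orth = w_orth, t_orth = t_orth, p_orth = p_orth,
                 n_orth = if (is.null(w_orth)) 0L else ncol(w_orth),
                 r2x = r2x, r2y = r2y,
                 x_center = x_center, y_center = y_center, levels = lev,
                 n = n, p_features = ncol(X)),
            class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat("<opls_model> 1 predictive + ", x$n_orth, " orthogonal component(s); ",
      x$n, " samples x ", x$p_features, " features\n",
      "  R2X(cum) = ", round(x$r2x, 3), "  R2Y = ", round(x$r2y, 3), "\n",
      sep = "")
  invisible(x)
}

#' Predict continuous class scores for new samples
#'
#' Applies the training centering, deflates the orthogonal components,
#' and projects on the predictive weight. Values near -1/+1 correspond to
#' the two (sorted) class levels.
#'
#' @param object An `opls_model`.
#' @param newdata Numeric matrix, samples x features.
#' @param ... Unused.
#' @return Numeric vector of predicted (centered-scale) responses plus the
#'   training response center.
#' @export
predict.opls_model <- function(object, newdata, ...) {
  Xn <- sweep(as.matrix(newdata), 2L, object$x_center, "-")
  if (object$n_orth > 0L) {
    for (a in seq_len(object$n_orth)) {
      to <- Xn %*% object$w_orth[, a]
      Xn <- Xn - to %*% t(object$p_orth[, a])
    }
  }
  drop(Xn %*% object$w) * object$c + object$y_center
}

#' Cross-validated predictive ability Q2
#'
#' Q2 = 1 - PRESS/SS, with PRESS accumulated over class-stratified
#' held-out folds (the fold count conventional in SIMCA is 7) and SS the
#' total sum of squares of the centered -1/+1 response. Fold assignment is
#' a seeded permutation within each class, so identical inputs and seed
#' give identical folds. Each training split is re-fitted (including
#' centering) before predicting its held-out samples.
#'
#' @param X Samples x features matrix (scaled as for [fit_oplsda()]).
#' @param y Two-level class labels.
#' @param n_orth Orthogonal components per fold model.
#' @param folds Number of folds (>= 2, <= n); reduced to the minority class
#'   size when a class is smaller than `folds`, so every fold retains both
#'   classes.
#' @param seed Integer seed for the fold assignment.
#' @return Q2 (<= 1; can be negative for models worse than the mean).
#' @export
cross_validate_q2 <- function(X, y, n_orth = 1, folds = 7, seed = 1) {
  X <- as.matrix(X)
  n <- nrow(X)
  y <- as.character(y)
  lev <- sort(unique(y))
  if (length(lev) != 2L) stop("y must have exactly two classes", call. = FALSE)
  if (folds < 2L || folds > n) stop("folds must be in [2, n]", call. = FALSE)
  class_sizes <- table(y)
  folds <- min(folds, min(class_sizes))
  if (folds < 2L) {
    stop("cannot stratify: minority class has fewer than 2 samples",
         call. = FALSE)
  }
  fold_id <- integer(n)
  with_seed(seed, {
    for (lv in lev) {
      idx <- sample(which(y == lv))
      fold_id[idx] <- rep_len(seq_len(folds), length(idx))
    }
  })
  yv <- ifelse(y == lev[2L], 1, -1)
  press <- 0
  for (k in seq_len(folds)) {
    test <- fold_id == k
    m <- fit_oplsda(X[!test, , drop = FALSE], y[!test], n_orth = n_orth)
    pred <- predict(m, X[test, , drop = FALSE])
    press <- press + sum((yv[test] - pred)^2)
  }
  1 - press / sum((yv - mean(yv))^2)
}

# evaluate `code` (in the caller's frame) under a temporary RNG seed,
# restoring the caller-visible RNG state afterwards
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Variable importance in projection
#'
#' VIP over the predictive component(s): with one predictive component,
#' `VIP_j = sqrt(p) * |w_j| / ||w||`, so the squared scores average to 1
#' (`sum(VIP^2) = p`). Orthogonal components are Y-uncorrelated by
#' construction and do not contribute. Ranks break ties by feature m/z
#' ascending, then feature id.
#'
#' @param m An `opls_model`.
#' @param feature_id Optional feature identifiers (default column index).
#' @param mz Optional feature m/z values used for tie-breaking.
#' @return A tibble `feature_id`, `vip`, `rank` sorted by rank.
#' @export
vip_scores <- function(m, feature_id = NULL, mz = NULL) {
  p <- m$p_features
  vip <- sqrt(p) * abs(m$w) / sqrt(sum(m$w^2))
  if (is.null(feature_id)) feature_id <- as.character(seq_len(p))
  if (is.null(mz)) mz <- rep(NA_real_, p)
  ord <- order(-vip, mz, feature_id)
  out <- tibble::tibble(feature_id = feature_id[ord], vip = vip[ord],
                        rank = seq_len(p))
  out
}

#' S-plot coordinates
#'
#' For each feature: `p1 = cov(t, x_j)` and `pcorr1 = cor(t, x_j)` against
#' the predictive scores. Zero-variance features have undefined
#' correlation, reported as 0 with `constant = TRUE`. Output sorted by
#' `p1`.
#'
#' @param m An `opls_model`.
#' @param X The matrix the model was fitted on.
#' @param feature_id Optional feature identifiers.
#' @return A tibble `feature_id`, `p1`, `pcorr1`, `constant`.
#' @export
s_plot <- function(m, X, feature_id = NULL) {
  X <- as.matrix(X)
  if (is.null(feature_id)) feature_id <- as.character(seq_len(ncol(X)))
  tt <- m$scores
  p1 <- drop(stats::cov(tt, X))
  sds <- apply(X, 2L, stats::sd)
  constant <- sds == 0
  pcorr1 <- rep(0, ncol(X))
  pcorr1[!constant] <- drop(stats::cor(tt, X[, !constant, drop = FALSE]))
  out <- tibble::tibble(feature_id = feature_id, p1 = p1, pcorr1 = pcorr1,
                        constant = constant)
  out[order(out$p1), ]
}

#' Model verdict from Q2
#'
#' Boundaries are strict: Q2 <= 0.4 is `invalid`, 0.4 < Q2 <= 0.7 is
#' `valid` (a statistically robust model), Q2 > 0.7 is
#' `highly significant`.
#'
#' @param q2 Numeric vector of Q2 values.
#' @return Character vector of verdicts.
#' @examples
#' classify_model(c(0.615, 0.778, 0.40))
#' @export
classify_model <- function(q2) {
  ifelse(q2 > 0.7, "highly significant",
         ifelse(q2 > 0.4, "valid", "invalid"))
}

#' Parallel include/exclude-top-VIP subset validation
#'
#' Fits three models — all features, only the `top_n` top-VIP features,
#' and all features except those — with cross-validated Q2 and verdicts,
#' mirroring the ledger layout of OPLS-DA validation tables. The selected
#' features form a useful subset when the include-only model is at least
#' valid while the exclude model is invalid.
#'
#' @param X Samples x features matrix (scaled).
#' @param y Two-level class labels.
#' @param ranking A [vip_scores()] tibble for the full model fitted on
#'   `X`/`y` (computed internally when `NULL`).
#' @param top_n Number of top-VIP features (1 <= top_n < ncol(X)).
#' @param n_orth,folds,seed Passed to the fits and [cross_validate_q2()].
#' @param conditions Text describing the contrast, echoed in the ledger.
#' @return A list with `ledger` (tibble: `model`, `n_features`, `r2x`,
#'   `r2y`, `q2`, `conditions`, `verdict`) and `useful_subset` (logical).
#' @export
validate_subset <- function(X, y, ranking = NULL, top_n = 30, n_orth = 1,
                            folds = 7, seed = 1, conditions = "") {
  X <- as.matrix(X)
  p <- ncol(X)
  if (top_n < 1 || top_n >= p) {
    stop("top_n must satisfy 1 <= top_n < ncol(X)", call. = FALSE)
  }
  full <- fit_oplsda(X, y, n_orth = n_orth)
  if (is.null(ranking)) ranking <- vip_scores(full)
  if (is.null(colnames(X))) colnames(X) <- as.character(seq_len(p))
  top <- ranking$feature_id[seq_len(top_n)]
  sel <- colnames(X) %in% top
  row_for <- function(label, Xs, cond) {
    m <- fit_oplsda(Xs, y, n_orth = n_orth)
    q2 <- cross_validate_q2(Xs, y, n_orth = n_orth, folds = folds,
                            seed = seed)
    tibble::tibble(model = label, n_features = ncol(Xs), r2x = m$r2x,
                   r2y = m$r2y, q2 = q2, conditions = cond,
                   verdict = classify_model(q2))
  }
  ledger <- rbind(
    row_for("full", X, conditions),
    row_for("include_top_vip", X[, sel, drop = FALSE],
            paste(conditions, sprintf("(including top %d VIP)", top_n))),
    row_for("exclude_top_vip", X[, !sel, drop = FALSE],
            paste(conditions, sprintf("(excluding top %d VIP)", top_n)))
  )
  useful <- ledger$verdict[2L] != "invalid" && ledger$verdict[3L] == "invalid"
  list(ledger = ledger, useful_subset = useful)
}

#' Null distribution of Q2 under label permutation
#'
#' Recomputes the cross-validated Q2 after randomly permuting the class
#' labels `n_perm` times (seeded); an observed Q2 above the upper tail of
#' this null is evidence the class structure is real rather than over-fit.
#'
#' @param X Samples x features matrix (scaled).
#' @param y Two-level class labels.
#' @param n_perm Number of permutations (>= 10).
#' @param n_orth,folds,seed As in [cross_validate_q2()].
#' @return A list: `q2_null` (vector), `median`, `q95`.
#' @export
permutation_q2 <- function(X, y, n_perm = 20, n_orth = 1, folds = 7,
                           seed = 1) {
  stopifnot(n_perm >= 10)
  perms <- with_seed(seed, {
    lapply(seq_len(n_perm), function(i) sample(length(y)))
  })
  q2s <- vapply(seq_len(n_perm), function(i) {
    cross_validate_q2(X, y[perms[[i]]], n_orth = n_orth, folds = folds,
                      seed = seed + i)
  }, numeric(1))
  list(q2_null = q2s, median = stats::median(q2s),
       q95 = unname(stats::quantile(q2s, 0.95)))
}
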