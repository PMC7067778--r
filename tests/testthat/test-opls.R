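test_that("fit recovers a single separating feature and validates inputs", {
  sim <- sim_gauss(n = 30, p = 100, n_inf = 0, seed = 7)
  X <- sim$X
  X[, 17] <- X[, 17] + ifelse(sim$y == "a", 2, -2)
  m <- fit_oplsda(X, sim$y, n_orth = 0)
  expect_gte(m$r2y, 0.8)
  expect_identical(which.max(abs(m$w)), 17L)
  expect_equal(sum(m$w^2), 1, tolerance = 1e-12)
  expect_error(fit_oplsda(X, rep("a", 30)), "two classes")
  expect_error(fit_oplsda(X, sim$y, n_orth = -1), "n_orth")
  expect_error(fit_oplsda(X, sim$y, n_orth = 29), "n_orth")
  expect_error(fit_oplsda(X[1:3, ], sim$y[1:3]), "4 samples")
})

test_that("orthogonal scores are uncorrelated with predictive scores and
           duplication leaves the fit unchanged", {
  sim <- sim_gauss(n = 20, p = 60, n_inf = 10, effect = 2, seed = 3)
  m <- fit_oplsda(sim$X, sim$y, n_orth = 2)
  for (a in seq_len(m$n_orth)) {
    expect_lt(abs(cor(m$scores, m$t_orth[, a])), 1e-8)
    expect_equal(sum(m$w_orth[, a]^2), 1, tolerance = 1e-12)
  }
  m2 <- fit_oplsda(rbind(sim$X, sim$X), c(sim$y, sim$y), n_orth = 2)
  expect_equal(m2$w, m$w, tolerance = 1e-10)
  expect_true(m$r2y >= 0 && m$r2y <= 1)
})

test_that("with no orthogonal component the predictive direction matches
           reference PLS1", {
  set.seed(42)
  for (i in 1:3) {
    X <- matrix(rnorm(30 * 50), 30)
    y <- rep(c("a", "b"), 15)
    m <- fit_oplsda(X, y, n_orth = 0)
    ref <- mixOmics::pls(X, ifelse(y == "b", 1, -1), ncomp = 1,
                         mode = "regression", scale = FALSE)
    wref <- ref$loadings$X[, 1]
    cosine <- abs(sum(m$w * wref) / sqrt(sum(m$w^2) * sum(wref^2)))
    expect_gt(cosine, 0.9999)
  }
})

test_that("Q2 separates structure from noise and is seed-deterministic", {
  q2_structured <- q2_noise <- q2_perm <- numeric(25)
  for (i in 1:25) {
    sim <- sim_gauss(n = 30, p = 200, n_inf = 30, effect = 3, seed = 100 + i)
    q2_structured[i] <- cross_validate_q2(sim$X, sim$y, n_orth = 1,
                                          folds = 7, seed = i)
    noise <- sim_gauss(n = 30, p = 200, n_inf = 0, seed = 200 + i)
    q2_noise[i] <- cross_validate_q2(noise$X, noise$y, n_orth = 1,
                                     folds = 7, seed = i)
    yperm <- with_seed(300 + i, sample(sim$y))
    q2_perm[i] <- cross_validate_q2(sim$X, yperm, n_orth = 1, folds = 7,
                                    seed = i)
  }
  expect_gt(median(q2_structured), 0.7)
  expect_lt(median(q2_noise), 0.4)
  expect_lt(median(q2_perm), 0.4)
  expect_true(all(q2_structured <= 1))
  # training R2Y stays high on pure noise even though Q2 collapses
  noise <- sim_gauss(n = 30, p = 200, n_inf = 0, seed = 1)
  expect_gt(fit_oplsda(noise$X, noise$y, n_orth = 1)$r2y, 0.9)
  # determinism
  sim <- sim_gauss(seed = 5)
  expect_identical(cross_validate_q2(sim$X, sim$y, folds = 7, seed = 11),
                   cross_validate_q2(sim$X, sim$y, folds = 7, seed = 11))
})

test_that("VIP scores are normalized, rank planted features first and
           break ties by m/z", {
  sim <- sim_gauss(n = 30, p = 100, n_inf = 0, seed = 7)
  X <- sim$X
  X[, 17] <- X[, 17] + ifelse(sim$y == "a", 2, -2)
  m <- fit_oplsda(X, sim$y, n_orth = 1)
  v <- vip_scores(m)
  expect_equal(sum(v$vip^2), 100, tolerance = 1e-6)
  expect_identical(v$feature_id[1], "17")
  expect_gt(v$vip[1], 0.7)
  # identical columns share VIP 1 by symmetry + normalization
  Xeq <- matrix(rep(rnorm(20), 8), nrow = 20)
  meq <- fit_oplsda(Xeq, rep(c("a", "b"), 10), n_orth = 0)
  expect_equal(vip_scores(meq)$vip, rep(1, 8), tolerance = 1e-9)
  # m/z tie-break on equal VIPs
  veq <- vip_scores(meq, feature_id = paste0("F", 1:8), mz = 8:1)
  expect_identical(veq$feature_id, paste0("F", 8:1))
})

test_that("S-plot pulls informative features to the extremes", {
  extreme_hits <- 0L
  noise_pcorr <- numeric(20)
  for (i in 1:20) {
    sim <- sim_gauss(n = 30, p = 50, n_inf = 1, effect = 3, seed = 400 + i)
    m <- fit_oplsda(sim$X, sim$y, n_orth = 0)
    sp <- s_plot(m, sim$X)
    if (sp$feature_id[which.max(abs(sp$pcorr1))] == "1") {
      extreme_hits <- extreme_hits + 1L
    }
    noise_pcorr[i] <- abs(sp$pcorr1[sp$feature_id == "30"])
  }
  expect_gte(extreme_hits, 18L)
  expect_gt(mean(noise_pcorr < 0.5), 0.9)
  expect_true(all(abs(s_plot(m, sim$X)$pcorr1) <= 1))
  # zero-variance feature flagged with pcorr 0
  Xc <- cbind(sim$X, 5)
  mc <- fit_oplsda(Xc, sim$y, n_orth = 0)
  spc <- s_plot(mc, Xc, feature_id = c(as.character(1:50), "const"))
  expect_true(spc$constant[spc$feature_id == "const"])
  expect_identical(spc$pcorr1[spc$feature_id == "const"], 0)
})

test_that("verdict thresholds are strict at 0.4 and 0.7", {
  expect_identical(classify_model(c(0.615, 0.778, 0.40, 0.70, -0.2)),
                   c("valid", "highly significant", "invalid", "valid",
                     "invalid"))
})

test_that("subset validation flags planted markers as a useful subset", {
  sim <- sim_gauss(n = 30, p = 200, n_inf = 30, effect = 3, seed = 9)
  val <- validate_subset(sim$X, sim$y, top_n = 30, folds = 7, seed = 9,
                         conditions = "synthetic two-group")
  expect_identical(val$ledger$model,
                   c("full", "include_top_vip", "exclude_top_vip"))
  expect_identical(val$ledger$n_features, c(200L, 30L, 170L))
  expect_gt(val$ledger$q2[2], 0.7)
  expect_lt(val$ledger$q2[3], 0.4)
  expect_true(val$useful_subset)
  # pure noise: no useful subset
  noise <- sim_gauss(n = 30, p = 100, n_inf = 0, seed = 10)
  valn <- validate_subset(noise$X, noise$y, top_n = 20, folds = 7, seed = 10)
  expect_false(valn$useful_subset)
  expect_error(validate_subset(sim$X, sim$y, top_n = 200), "top_n")
  # determinism: identical inputs and seed give identical ledgers
  val2 <- validate_subset(sim$X, sim$y, top_n = 30, folds = 7, seed = 9,
                          conditions = "synthetic two-group")
  expect_identical(val$ledger, val2$ledger)
})

test_that("permutation null lies below the observed Q2 for structured data", {
  sim <- sim_gauss(n = 30, p = 200, n_inf = 30, effect = 3, seed = 12)
  obs <- cross_validate_q2(sim$X, sim$y, folds = 7, seed = 12)
  null <- permutation_q2(sim$X, sim$y, n_perm = 20, folds = 7, seed = 12)
  expect_gt(obs, null$q95)
  expect_lt(null$median, 0.4)
  expect_length(null$q2_null, 20L)
})
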