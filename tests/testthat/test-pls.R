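test_that("one latent direction is recovered exactly", {
  withr::with_seed(1, {
    t_true <- rnorm(20)
    load <- rnorm(10)
    X <- outer(t_true, load) + 5
    y <- 2 * t_true + 3
  })
  fit <- fit_pls1(X, y, 1)
  expect_lt(sqrt(mean((predict(fit, X) - y)^2)), 1e-10)

  # the first weight vector is the normalized centered cross-covariance
  prob <- random_problem(seed = 2)
  f1 <- fit_pls1(prob$X, prob$y, 1)
  w_ref <- drop(crossprod(sweep(prob$X, 2, colMeans(prob$X)),
                          prob$y - mean(prob$y)))
  w_ref <- w_ref / sqrt(sum(w_ref^2))
  expect_equal(drop(f1$W), w_ref)
})

test_that("NIPALS matches the independent Krylov-subspace oracle", {
  for (seed in 1:3) {
    prob <- random_problem(seed = seed)
    for (a in 1:5) {
      fit <- fit_pls1(prob$X, prob$y, a)
      oracle <- krylov_pls1(prob$X, prob$y, a)
      expect_equal(predict(fit, prob$X_new),
                   krylov_predict(oracle, prob$X_new), tolerance = 1e-8)
    }
  }
})

test_that("scores are orthogonal and both prediction forms agree", {
  prob <- random_problem(seed = 4)
  fit <- fit_pls1(prob$X, prob$y, 5)
  G <- crossprod(fit$T)
  offdiag <- G - diag(diag(G))
  expect_lt(max(abs(offdiag)) / min(diag(G)), 1e-8)
  # score-recursion predictions (y_mean + sum_a q_a t_a) equal b-vector form
  via_scores <- fit$y_mean + drop(fit$T %*% fit$q)
  expect_equal(predict(fit, prob$X), via_scores, tolerance = 1e-10)
})

test_that("fit rejects degenerate inputs", {
  prob <- random_problem()
  expect_error(fit_pls1(prob$X, rep(1, 20), 2), "zero variance",
               class = "plasmapls_error")
  expect_error(fit_pls1(prob$X, prob$y, 25), class = "plasmapls_error")
  expect_error(fit_pls1(prob$X[1, , drop = FALSE], prob$y[1], 1),
               class = "plasmapls_error")
})

test_that("LOO RMSECV matches brute-force folds and ignores row order", {
  # n = 3 toy, hand-deleted folds at 1 LV
  withr::with_seed(5, {
    X3 <- matrix(rnorm(12), 3, 4)
    y3 <- c(1, 2, 4)
  })
  cv <- loo_rmsecv(X3, y3, max_lv = 1)
  expect_equal(cv$curve$rmsecv, brute_loo_rmsecv_1lv(X3, y3))

  # noiseless single-direction data: curve at 1 LV is ~ 0
  withr::with_seed(6, {
    t_true <- rnorm(15)
    X1 <- outer(t_true, rnorm(8))
    y1 <- t_true
  })
  expect_lt(loo_rmsecv(X1, y1, 1)$curve$rmsecv[1], 1e-10)

  # permutation invariance
  prob <- random_problem(seed = 7)
  perm <- sample(nrow(prob$X))
  expect_equal(loo_rmsecv(prob$X, prob$y, 4)$curve,
               loo_rmsecv(prob$X[perm, ], prob$y[perm], 4)$curve)
})

test_that("the 5%-improvement rule picks LVs greedily", {
  expect_equal(select_lv(c(5.0, 4.0, 3.9)), 2)
  expect_equal(select_lv(rep(2, 6)), 1)
  # 9.5 = 0.95*10 accepted; 9.02 < 0.95*9.5 accepted; 8.6 > 0.95*9.02 rejected
  expect_equal(select_lv(c(10, 9.5, 9.02, 8.6)), 3)
  expect_equal(select_lv(c(10, 9.51, 9)), 1)   # first failure stops the search
  expect_error(select_lv(numeric(0)), class = "plasmapls_error")
})

test_that("evaluation metrics follow the model evaluation standard", {
  cfg <- clean_config()
  sets <- simulate_dataset(cfg)
  rep_ <- evaluate_pls(preprocess_spectra(sets$calibration),
                       preprocess_spectra(sets$prediction))
  g <- glance(rep_)
  expect_equal(g$re_cv_pct, 100 * g$rmsecv / mean(sets$calibration$pmi_h))
  expect_equal(g$re_pred_pct, 100 * g$rmsep / mean(sets$prediction$pmi_h))
  expect_equal(g$ratio, g$rmsep / g$rmsecv)
  expect_equal(g$robust, g$ratio < 1.2)
  expect_true(g$r2_cv >= 0 && g$r2_cv <= 1)
  # RE% convention reproduces the reference arithmetic: RMSE 5.31 h over a
  # prediction set averaging 24 h is 22.12%
  expect_equal(round(100 * 5.31 / mean(rep(seq(3, 45, 6), each = 3)), 2), 22.12)
})

test_that("VIP satisfies its normalization identity and formula collapse", {
  # single informative variable: VIP_j = sqrt(p), others 0
  withr::with_seed(8, y <- rnorm(20))
  X <- cbind(matrix(0, 20, 4), y, matrix(0, 20, 3))
  X <- X + 1  # keep other columns constant, centered away
  fit <- fit_pls1(X, y, 1)
  v <- vip(fit)
  expect_equal(v$vip[5], sqrt(8))
  expect_equal(v$vip[-5], rep(0, 7))

  # normalization: mean squared VIP is 1 for any fitted model
  for (seed in 1:5) {
    prob <- random_problem(n = 15, p = 8, seed = seed)
    f <- fit_pls1(prob$X, prob$y, 3)
    expect_equal(mean(vip(f)$vip^2), 1, tolerance = 1e-10)
  }
})

test_that("VIP concentrates in the informative amide region on synthetic data", {
  cfg <- synth_config(seed = 5)
  sets <- simulate_dataset(cfg)
  pc <- preprocess_spectra(sets$calibration)
  cv <- loo_rmsecv(pc, max_lv = 10)
  fit <- fit_pls1(pc, n_lv = select_lv(cv))
  v <- vip(fit)
  hot <- v$variable[v$vip > 1]
  expect_gt(length(hot), 0)
  expect_gt(mean(hot <= 1705 & hot >= 1373), 0.6)
})

test_that("prediction error tracks the noise floor on synthetic mixtures", {
  noisy <- evaluate_pls(
    preprocess_spectra(simulate_dataset(clean_config(noise_sd = 1e-5))$calibration),
    preprocess_spectra(simulate_dataset(clean_config(noise_sd = 1e-5))$prediction))
  quieter <- evaluate_pls(
    preprocess_spectra(simulate_dataset(clean_config(noise_sd = 1e-6))$calibration),
    preprocess_spectra(simulate_dataset(clean_config(noise_sd = 1e-6))$prediction))
  # decreasing noise cannot worsen recovery much: allow small CV jitter
  expect_lt(quieter$rmsep, noisy$rmsep * 1.25)
})
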