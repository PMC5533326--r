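#' Per-sample leverage from PLS scores
#'
#' `h_i = 1/n + t_i^T (T^T T)^{-1} t_i` on the calibration scores, including
#' the centering term, so `sum(h) = A + 1` and `1/n <= h_i <= 1`.
#'
#' @param model a fitted `pls1` model.
#' @return numeric vector of leverages.
#' @export
pls_leverage <- function(model) {
  stopifnot(inherits(model, "pls1"))
  Tm <- model$T
  G <- crossprod(Tm)
  if (rcond(G) < 1e-12) {
    abort_plasmapls("degenerate scores: T'T is singular", "outlier_degenerate")
  }
  1 / model$n + rowSums((Tm %*% solve(G)) * Tm)
}

#' Per-sample Q-residuals (squared X-reconstruction error)
#'
#' `Q_i = ||x_i - xhat_i||^2` where `xhat` is the A-LV reconstruction
#' `T P^T` of the centered spectrum. Q is zero exactly when a sample lies in
#' the model plane, and the centered squared norm decomposes as
#' explained + Q per sample.
#'
#' @param x calibration matrix or spectra table (the data the model was fit
#'   on, or new data on the same axis).
#' @param model a fitted `pls1` model.
#' @return numeric vector of Q-residuals.
#' @export
q_residuals <- function(x, model) {
  stopifnot(inherits(model, "pls1"))
  X <- if (is.data.frame(x)) spectra_matrix(as_spectra(x, quiet = TRUE)) else as.matrix(x)
  Xc <- sweep(X, 2, model$x_mean)
  R <- model$W %*% solve(crossprod(model$P, model$W))
  Tn <- Xc %*% R
  E <- Xc - tcrossprod(Tn, model$P)
  rowSums(E^2)
}

#' Studentized y-residuals
#'
#' `r_i = e_i / (s * sqrt(1 - h_i))` with `e_i = y_i - yhat_i` and
#' `s = sqrt(sum(e^2) / (n - A - 1))`. Residuals with `h_i >= 1` cannot be
#' studentized and are returned as `NA` with a warning. The statistic is
#' invariant to adding a constant to both `y` and `yhat`.
#'
#' @param y actual response.
#' @param y_hat predicted response (typically cross-validated).
#' @param h per-sample leverages.
#' @param n_lv LV count A used for the degrees of freedom.
#' @return numeric vector of studentized residuals.
#' @export
studentized_y_residuals <- function(y, y_hat, h, n_lv) {
  e <- y - y_hat
  s <- sqrt(sum(e^2) / (length(y) - n_lv - 1))
  bad <- h >= 1
  if (any(bad)) {
    rlang::warn(sprintf("%d sample(s) with leverage >= 1 not studentized", sum(bad)))
  }
  r <- e / (s * sqrt(pmax(1 - h, 0)))
  r[bad] <- NA_real_
  r
}

#' Screen calibration samples for outliers
#'
#' Computes the three pre-modeling diagnostics (leverage, Q-residual,
#' Studentized y-residual of the LOO predictions) at the LV count chosen on
#' the full calibration set, then flags samples by a two-of-three vote:
#' `h > 3 (A + 1) / n`, `|r| > 3`, `Q >` its empirical 95th percentile.
#' Flagged samples are removed and reported; the caller refits afterwards.
#'
#' @param data labeled calibration spectra table.
#' @param policy `"default"` (two-of-three vote), `"strict"` (any single
#'   criterion) or `"off"`.
#' @param max_lv,improvement LV selection settings (see [evaluate_pls()]).
#' @param max_removal_fraction abort when the policy would remove more than
#'   this fraction of samples (guard against misconfiguration).
#' @return a list: `retained` (spectra table), `report` (per-sample tibble
#'   with diagnostics, per-criterion flags and the combined flag),
#'   `thresholds`, `n_lv`.
#' @export
flag_outliers <- function(data, policy = c("default", "strict", "off"),
                          max_lv = 15, improvement = 0.05,
                          max_removal_fraction = 0.2) {
  policy <- match.arg(policy)
  ds <- as_spectra(data, quiet = TRUE)
  d <- resolve_xy(ds, NULL)
  n <- nrow(d$X)
  max_lv <- max(1, min(max_lv, floor(n / 3), n - 2, ncol(d$X)))
  cv <- loo_rmsecv(d$X, d$y, max_lv)
  n_lv <- select_lv(cv, improvement)
  model <- fit_pls1(d$X, d$y, n_lv)
  h <- pls_leverage(model)
  q <- q_residuals(d$X, model)
  r <- studentized_y_residuals(d$y, cv$predictions[, n_lv], h, n_lv)
  thr <- list(leverage = 3 * (n_lv + 1) / n, student = 3,
              q = as.numeric(stats::quantile(q, 0.95)))
  flag_h <- h > thr$leverage
  flag_r <- !is.na(r) & abs(r) > thr$student
  flag_q <- q > thr$q
  votes <- flag_h + flag_r + flag_q
  outlier <- switch(policy,
                    default = votes >= 2,
                    strict = votes >= 1,
                    off = rep(FALSE, n))
  if (mean(outlier) > max_removal_fraction) {
    abort_plasmapls(
      sprintf("outlier policy '%s' would remove %d of %d samples (> %.0f%%); check configuration",
              policy, sum(outlier), n, 100 * max_removal_fraction),
      "outlier_excessive_removal")
  }
  report <- tibble::tibble(
    sample_id = ds$sample_id, pmi_h = ds$pmi_h,
    leverage = h, q_residual = q, student_residual = r,
    flag_leverage = flag_h, flag_student = flag_r, flag_q = flag_q,
    votes = as.integer(votes), outlier = outlier)
  list(retained = ds[!outlier, ], report = report, thresholds = thr, n_lv = n_lv)
}
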