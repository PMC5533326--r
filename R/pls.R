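#' Fit a PLS1 regression model (NIPALS)
#'
#' Univariate-response partial least squares. `X` and `y` are mean-centered
#' (no variance scaling: derivative spectra share a common scale). For each
#' latent variable (LV) the NIPALS recursion is
#' \deqn{w \propto X^T y,\quad t = X w,\quad p = X^T t / t^T t,\quad
#'       q = y^T t / t^T t,}
#' after which `X` (and `y`) are deflated by the extracted component. The
#' regression vector `b = W (P^T W)^{-1} q` reproduces the score-recursion
#' predictions, and scores of different LVs are mutually orthogonal.
#'
#' @param x predictor matrix (samples x variables) or a spectra table whose
#'   `pmi_h` column supplies the response.
#' @param y numeric response; ignored when `x` is a spectra table.
#' @param n_lv number of latent variables, `<= min(n - 1, p)`.
#' @return a `pls1` object with weights `W`, X-loadings `P`, response
#'   loadings `q`, scores `T`, per-LV-count coefficient matrix `B` (column `a`
#'   holds the regression vector of the `a`-LV model), centering offsets, and
#'   per-LV explained X-variance (%).
#' @export
fit_pls1 <- function(x, y = NULL, n_lv) {
  d <- resolve_xy(x, y)
  fit <- pls1_engine(d$X, d$y, n_lv)
  fit$axis <- d$axis
  class(fit) <- "pls1"
  fit
}

resolve_xy <- function(x, y) {
  if (is.data.frame(x)) {
    ds <- as_spectra(x, quiet = TRUE)
    if (anyNA(ds$pmi_h)) {
      abort_plasmapls("spectra table has missing pmi_h labels", "pls_invalid")
    }
    list(X = spectra_matrix(ds), y = ds$pmi_h, axis = wavenumbers(ds))
  } else {
    list(X = as.matrix(x), y = as.numeric(y), axis = NULL)
  }
}

pls1_engine <- function(X, y, n_lv) {
  n <- nrow(X); p <- ncol(X)
  if (n < 2) abort_plasmapls("need at least 2 samples", "pls_invalid")
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    abort_plasmapls("X and y must be finite", "pls_invalid")
  }
  if (length(y) != n) abort_plasmapls("length(y) != nrow(X)", "pls_invalid")
  if (n_lv > min(n - 1, p)) {
    abort_plasmapls(sprintf("n_lv = %d exceeds min(n - 1, p) = %d",
                            n_lv, min(n - 1, p)), "pls_invalid")
  }
  if (stats::sd(y) == 0) abort_plasmapls("response has zero variance", "pls_invalid")
  x_mean <- colMeans(X); y_mean <- mean(y)
  Xc <- sweep(X, 2, x_mean); yc <- y - y_mean
  ss_x <- sum(Xc^2)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv); Tm <- matrix(0, n, n_lv)
  q <- numeric(n_lv); expl <- numeric(n_lv)
  for (a in seq_len(n_lv)) {
    w <- drop(crossprod(Xc, yc))
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps * 100) {
      abort_plasmapls(
        sprintf("X-y covariance vanished at LV %d; reduce n_lv", a),
        "pls_degenerate")
    }
    w <- w / nw
    t_ <- drop(Xc %*% w)
    tt <- sum(t_^2)
    if (tt < .Machine$double.eps * 100) {
      abort_plasmapls(sprintf("degenerate score at LV %d", a), "pls_degenerate")
    }
    pl <- drop(crossprod(Xc, t_)) / tt
    qa <- sum(yc * t_) / tt
    Xc <- Xc - tcrossprod(t_, pl)
    yc <- yc - qa * t_
    W[, a] <- w; P[, a] <- pl; Tm[, a] <- t_; q[a] <- qa
    expl[a] <- 100 * tt * sum(pl^2) / ss_x
  }
  R <- W %*% solve(crossprod(P, W))
  B <- matrix(vapply(seq_len(n_lv),
                     function(k) drop(R[, 1:k, drop = FALSE] %*% q[1:k]),
                     numeric(p)),
              nrow = p)
  list(n_lv = n_lv, W = W, P = P, q = q, T = Tm,
       b = B[, n_lv], B = B, x_mean = x_mean, y_mean = y_mean,
       explained_x_variance = expl, n = n, p = p, y = y)
}

#' Predict from a PLS1 model
#'
#' @param object a `pls1` fit.
#' @param newdata matrix or spectra table on the training axis.
#' @param n_lv number of LVs to use (default: all fitted).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.pls1 <- function(object, newdata, n_lv = object$n_lv, ...) {
  X <- if (is.data.frame(newdata)) {
    spectra_matrix(as_spectra(newdata, quiet = TRUE))
  } else {
    as.matrix(newdata)
  }
  if (ncol(X) != object$p) {
    abort_plasmapls(sprintf("newdata has %d variables, model expects %d",
                            ncol(X), object$p), "pls_invalid")
  }
  stopifnot(n_lv >= 1, n_lv <= object$n_lv)
  drop(sweep(X, 2, object$x_mean) %*% object$B[, n_lv]) + object$y_mean
}

#' @export
print.pls1 <- function(x, ...) {
  cat(sprintf("PLS1 model: %d LVs, %d samples x %d variables\n",
              x$n_lv, x$n, x$p))
  cat(sprintf("cumulative explained X-variance: %.3f%%\n",
              sum(x$explained_x_variance)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PLS1 fit: one row per variable
#'
#' @param x a `pls1` fit.
#' @param ... unused.
#' @return tibble with `variable` (wavenumber when known, index otherwise),
#'   regression coefficient and VIP score.
#' @export
tidy.pls1 <- function(x, ...) {
  tibble::tibble(
    variable = x$axis %||% seq_len(x$p),
    coefficient = x$b,
    vip = vip(x)$vip)
}

#' @rdname tidy.pls1
#' @export
glance.pls1 <- function(x, ...) {
  tibble::tibble(n = x$n, p = x$p, n_lv = x$n_lv,
                 explained_x_variance = sum(x$explained_x_variance))
}

#' Leave-one-out cross-validated RMSE per LV count
#'
#' Each sample is held out in turn and the model refit on the remainder; the
#' curve entry for `a` LVs is `sqrt(mean((y_i - yhat_{-i,a})^2))`. The curve
#' is invariant to sample order.
#'
#' @param x predictor matrix or labeled spectra table.
#' @param y response (ignored for spectra tables).
#' @param max_lv largest LV count to evaluate.
#' @return a `loo_cv` object: `$curve` tibble (`n_lv`, `rmsecv`),
#'   `$predictions` (n x max_lv matrix of held-out predictions), `$y`.
#' @export
loo_rmsecv <- function(x, y = NULL, max_lv) {
  d <- resolve_xy(x, y)
  X <- d$X; y <- d$y
  n <- nrow(X)
  if (n < 3) abort_plasmapls("LOO needs at least 3 samples", "pls_invalid")
  max_lv <- min(max_lv, n - 2, ncol(X))
  pred <- matrix(NA_real_, n, max_lv)
  for (i in seq_len(n)) {
    fit <- pls1_engine(X[-i, , drop = FALSE], y[-i], max_lv)
    pred[i, ] <- drop((X[i, ] - fit$x_mean) %*% fit$B) + fit$y_mean
  }
  structure(
    list(curve = tibble::tibble(n_lv = seq_len(max_lv),
                                rmsecv = sqrt(colMeans((pred - y)^2))),
         predictions = pred, y = y),
    class = "loo_cv")
}

#' Choose the LV count by the 5%-improvement rule
#'
#' Greedy from one LV: LV `a + 1` is accepted only if it improves RMSECV by
#' at least the `improvement` fraction, i.e.
#' `curve[a + 1] <= (1 - improvement) * curve[a]`; the first failure stops the
#' search (ties count as failures). Returns the last accepted count.
#'
#' @param curve RMSECV values (numeric vector, the `$curve` tibble, or a
#'   `loo_cv` object).
#' @param improvement required fractional improvement (default 0.05).
#' @return selected LV count.
#' @export
select_lv <- function(curve, improvement = 0.05) {
  if (inherits(curve, "loo_cv")) curve <- curve$curve
  if (is.data.frame(curve)) curve <- curve$rmsecv
  if (length(curve) == 0) abort_plasmapls("empty RMSECV curve", "pls_invalid")
  a <- 1
  while (a < length(curve) && curve[a + 1] <= (1 - improvement) * curve[a]) {
    a <- a + 1
  }
  a
}

#' Variable importance in projection (VIP) scores
#'
#' \deqn{VIP_j = \sqrt{p \sum_a SSY_a (w_{ja}/\|w_a\|)^2 / \sum_a SSY_a}}
#' with `SSY_a = q_a^2 t_a^T t_a` the response variance captured by LV `a`.
#' Scores are non-negative and satisfy `sum(VIP^2) = p`; variables above 1.0
#' are conventionally called important contributors.
#'
#' @param model a `pls1` fit.
#' @param threshold importance cutoff stored on the result (default 1.0).
#' @return a `vip_scores` tibble: `variable`, `vip`, `important`.
#' @export
vip <- function(model, threshold = 1) {
  stopifnot(inherits(model, "pls1"))
  ssy <- model$q^2 * colSums(model$T^2)
  wn2 <- sweep(model$W^2, 2, colSums(model$W^2), `/`)
  v <- sqrt(model$p * drop(wn2 %*% ssy) / sum(ssy))
  out <- tibble::tibble(variable = model$axis %||% seq_len(model$p),
                        vip = v, important = v > threshold)
  attr(out, "threshold") <- threshold
  class(out) <- c("vip_scores", class(out))
  out
}

#' Calibrate, cross-validate and evaluate a PLS model
#'
#' The full model-evaluation standard: leave-one-out RMSECV per LV count, LV
#' selection by the 5%-improvement rule, refit at the chosen count, and
#' held-out prediction. Reported metrics: RMSECV and RMSEP (hours), relative
#' errors `RE% = 100 * RMSE / mean(actual y of the evaluated set)`, squared
#' Pearson correlations between actual and predicted values, cumulative
#' explained X-variance, and the robustness ratio RMSEP/RMSECV (a model below
#' 1.2 is conventionally called robust).
#'
#' @param calibration labeled spectra table (or matrix with `y_cal`).
#' @param prediction labeled spectra table (or matrix with `y_pred`).
#' @param y_cal,y_pred responses when matrices are supplied.
#' @param max_lv LV search ceiling (default 15, additionally capped at n/3
#'   to bound the LOO cost).
#' @param improvement LV-rule fraction (default 0.05).
#' @param method label stored in the report (e.g. "PLS", "GA-PLS").
#' @return a `cv_report` object; see [glance.cv_report()] for the one-row
#'   summary shape.
#' @export
evaluate_pls <- function(calibration, prediction, y_cal = NULL, y_pred = NULL,
                         max_lv = 15, improvement = 0.05, method = "PLS") {
  dc <- resolve_xy(calibration, y_cal)
  dp <- resolve_xy(prediction, y_pred)
  if (anyNA(dp$y)) abort_plasmapls("prediction set must be labeled", "pls_invalid")
  n <- nrow(dc$X)
  max_lv <- max(1, min(max_lv, floor(n / 3), n - 2, ncol(dc$X)))
  cv <- loo_rmsecv(dc$X, dc$y, max_lv)
  n_lv <- select_lv(cv, improvement)
  model <- fit_pls1(dc$X, dc$y, n_lv)
  model$axis <- dc$axis
  y_cv <- cv$predictions[, n_lv]
  y_hat <- predict(model, dp$X)
  rmsecv <- sqrt(mean((y_cv - dc$y)^2))
  rmsep <- sqrt(mean((y_hat - dp$y)^2))
  out <- list(
    method = method,
    variable_number = ncol(dc$X),
    n_lv = n_lv,
    r2_cv = r2_pearson(dc$y, y_cv),
    rmsecv = rmsecv,
    re_cv_pct = 100 * rmsecv / mean(dc$y),
    explained_variance = sum(model$explained_x_variance),
    r2_pred = r2_pearson(dp$y, y_hat),
    rmsep = rmsep,
    re_pred_pct = 100 * rmsep / mean(dp$y),
    ratio = rmsep / rmsecv,
    robust = rmsep / rmsecv < 1.2,
    r2_cv_sse = 1 - sum((dc$y - y_cv)^2) / sum((dc$y - mean(dc$y))^2),
    r2_pred_sse = 1 - sum((dp$y - y_hat)^2) / sum((dp$y - mean(dp$y))^2),
    curve = cv$curve,
    cv_predictions = tibble::tibble(actual = dc$y, predicted = y_cv),
    test_predictions = tibble::tibble(actual = dp$y, predicted = y_hat),
    model = model)
  class(out) <- "cv_report"
  out
}

r2_pearson <- function(actual, predicted) {
  if (stats::sd(predicted) == 0) {
    abort_plasmapls("predictions are constant; R^2 undefined", "pls_degenerate")
  }
  stats::cor(actual, predicted)^2
}

#' One-row summary of a PLS evaluation report
#'
#' The columns mirror the conventional calibration-table layout: method,
#' variable number, LVs, cross-validated R^2 / RMSECV (RE%) / explained
#' variance, prediction R^2 / RMSEP (RE%), and the RMSEP/RMSECV ratio.
#'
#' @param x a `cv_report`.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.cv_report <- function(x, ...) {
  tibble::tibble(
    method = x$method, variable_number = x$variable_number, n_lv = x$n_lv,
    r2_cv = x$r2_cv, rmsecv = x$rmsecv, re_cv_pct = x$re_cv_pct,
    explained_variance = x$explained_variance,
    r2_pred = x$r2_pred, rmsep = x$rmsep, re_pred_pct = x$re_pred_pct,
    ratio = x$ratio, robust = x$robust)
}

#' @rdname glance.cv_report
#' @export
tidy.cv_report <- function(x, ...) x$curve

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("%s model: %d variables, %d LVs\n",
              x$method, x$variable_number, x$n_lv))
  cat(sprintf("  RMSECV %.3f h (RE %.2f%%), R2_cv %.3f, explained X %.3f%%\n",
              x$rmsecv, x$re_cv_pct, x$r2_cv, x$explained_variance))
  cat(sprintf("  RMSEP  %.3f h (RE %.2f%%), R2_pred %.3f, RMSEP/RMSECV %.2f%s\n",
              x$rmsep, x$re_pred_pct, x$r2_pred, x$ratio,
              if (x$robust) " (robust)" else ""))
  invisible(x)
}
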