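#' Standard normal variate (SNV) correction
#'
#' Row-wise centering and scaling: `(x - mean(x)) / sd(x)` per spectrum, with
#' the sample standard deviation (denominator `n - 1`). SNV removes
#' multiplicative scatter and additive offsets; every output row has mean 0
#' and sd 1, i.e. lies on the sphere of radius `sqrt(p - 1)`.
#'
#' @param x a numeric matrix (spectra in rows) or a spectra table.
#' @return an object of the same kind as `x`.
#' @export
snv <- function(x) {
  if (is.data.frame(x)) {
    ds <- as_spectra(x, quiet = TRUE)
    m <- snv(spectra_matrix(ds))
    out <- rebuild_spectra(ds, m, wavenumbers(ds))
    return(add_step(out, attr(x, "preprocessing"), "snv"))
  }
  mu <- rowMeans(x)
  sdev <- apply(x, 1, stats::sd)
  if (any(sdev == 0)) {
    bad <- rownames(x)[sdev == 0][1] %||% as.character(which(sdev == 0)[1])
    abort_plasmapls(
      sprintf("constant spectrum (zero variance), sample '%s'", bad),
      "preprocess_constant_row")
  }
  (x - mu) / sdev
}

#' Savitzky-Golay derivative filter coefficients
#'
#' Least-squares local-polynomial convolution weights. The 7-point,
#' polynomial-order-2, second-derivative kernel equals
#' `(5, 0, -3, -4, -3, 0, 5) / 42`. Coefficients are in index units: no
#' normalisation by the axis spacing is applied (harmless downstream, since
#' PLS is scale-equivariant per column set).
#'
#' @param window odd window length in points.
#' @param polyorder local polynomial order, `>= deriv`.
#' @param deriv derivative order.
#' @return numeric vector of `window` convolution weights.
#' @export
savgol_coefficients <- function(window = 7, polyorder = 2, deriv = 2) {
  if (window %% 2 != 1 || window < polyorder + 1) {
    abort_plasmapls("window must be odd and >= polyorder + 1", "preprocess_invalid")
  }
  if (deriv > polyorder) {
    abort_plasmapls("deriv must be <= polyorder", "preprocess_invalid")
  }
  h <- (window - 1) / 2
  A <- outer(seq(-h, h), 0:polyorder, `^`)
  C <- solve(crossprod(A), t(A))
  C[deriv + 1, ] * factorial(deriv)
}

#' Savitzky-Golay second derivative of spectra
#'
#' Applies the local-polynomial second-derivative filter along the wavenumber
#' axis. `edge_policy = "shrink"` (default) drops `(window - 1) / 2` points
#' per side; `"reflect"` pads each row by reflection and keeps the full axis.
#' The filter is exact for quadratic rows and annihilates affine rows.
#'
#' @param x a numeric matrix (spectra in rows) or a spectra table.
#' @param window odd filter length in points (default 7).
#' @param polyorder local polynomial order (default 2; the second-derivative
#'   kernel at window 7 is identical for orders 2 and 3).
#' @param edge_policy `"shrink"` or `"reflect"`.
#' @return filtered object of the same kind as `x`.
#' @export
savgol_deriv2 <- function(x, window = 7, polyorder = 2,
                          edge_policy = c("shrink", "reflect")) {
  edge_policy <- match.arg(edge_policy)
  if (is.data.frame(x)) {
    ds <- as_spectra(x, quiet = TRUE)
    m <- savgol_deriv2(spectra_matrix(ds), window, polyorder, edge_policy)
    axis <- wavenumbers(ds)
    h <- (window - 1) / 2
    if (edge_policy == "shrink") axis <- axis[(h + 1):(length(axis) - h)]
    out <- rebuild_spectra(ds, m, axis)
    return(add_step(out, attr(x, "preprocessing"),
                    sprintf("savgol_deriv2(window=%d,polyorder=%d,%s)",
                            window, polyorder, edge_policy)))
  }
  p <- ncol(x)
  if (p < window) {
    abort_plasmapls(sprintf("need >= %d points, got %d", window, p),
                    "preprocess_invalid")
  }
  k <- savgol_coefficients(window, polyorder, 2)
  h <- (window - 1) / 2
  xe <- if (edge_policy == "reflect") {
    cbind(x[, (h + 1):2, drop = FALSE], x, x[, (p - 1):(p - h), drop = FALSE])
  } else {
    x
  }
  pe <- ncol(xe)
  out <- matrix(0, nrow(x), pe - window + 1)
  for (j in seq_len(window)) {
    out <- out + k[j] * xe[, j:(pe - window + j), drop = FALSE]
  }
  rownames(out) <- rownames(x)
  out
}

#' Preprocess spectra: SNV then Savitzky-Golay second derivative
#'
#' The fixed pipeline order is SNV first, then the derivative. A provenance
#' record of the applied steps is attached as the `"preprocessing"` attribute
#' and grows on repeated application (the pipeline is deliberately not
#' idempotent).
#'
#' @param data a spectra table.
#' @param snv apply SNV (default `TRUE`).
#' @param sg apply the second-derivative filter (default `TRUE`).
#' @param sg_window,sg_polyorder,edge_policy filter settings, see
#'   [savgol_deriv2()].
#' @return a preprocessed spectra table.
#' @export
preprocess_spectra <- function(data, snv = TRUE, sg = TRUE, sg_window = 7,
                               sg_polyorder = 2,
                               edge_policy = c("shrink", "reflect")) {
  edge_policy <- match.arg(edge_policy)
  out <- as_spectra(data, quiet = TRUE)
  attr(out, "preprocessing") <- attr(data, "preprocessing")
  if (snv) out <- plasmapls::snv(out)
  if (sg) out <- savgol_deriv2(out, sg_window, sg_polyorder, edge_policy)
  out
}

rebuild_spectra <- function(ds, m, axis) {
  new_spectra(m, axis, sample_id = ds$sample_id, pmi_h = ds$pmi_h,
              parent_id = ds[["parent_id"]])
}

add_step <- function(out, prev, step) {
  attr(out, "preprocessing") <- c(prev, step)
  out
}

#' Preprocessing provenance of a spectra table
#' @param data a spectra table.
#' @return character vector of applied steps (possibly empty).
#' @export
preprocessing_steps <- function(data) {
  attr(data, "preprocessing") %||% character(0)
}
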