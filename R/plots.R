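#' Plot spectra
#'
#' Overlaid spectra with the conventional reversed (descending) wavenumber
#' axis, colored by PMI when labels are present.
#'
#' @param data a spectra table.
#' @param n_max plot at most this many spectra (default 30).
#' @return a ggplot object.
#' @export
plot_spectra <- function(data, n_max = 30) {
  ds <- as_spectra(data, quiet = TRUE)
  if (nrow(ds) > n_max) ds <- ds[seq_len(n_max), ]
  long <- tidyr::pivot_longer(ds, cols = -dplyr::any_of(.meta_cols),
                              names_to = "wavenumber", values_to = "absorbance")
  long$wavenumber <- as.numeric(long$wavenumber)
  ggplot2::ggplot(long, ggplot2::aes(.data$wavenumber, .data$absorbance,
                                     group = .data$sample_id,
                                     color = .data$pmi_h)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "wavenumber (cm⁻¹)", y = "absorbance",
                  color = "PMI (h)") +
    ggplot2::theme_minimal()
}

#' Plot an RMSECV curve
#' @param report a `cv_report` or `loo_cv` object.
#' @return a ggplot object.
#' @export
plot_cv_curve <- function(report) {
  curve <- if (inherits(report, "cv_report")) report$curve else report$curve
  ggplot2::ggplot(curve, ggplot2::aes(.data$n_lv, .data$rmsecv)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "latent variables", y = "RMSECV (h)") +
    ggplot2::theme_minimal()
}

#' Plot VIP scores along the wavenumber axis
#' @param scores a [vip()] result.
#' @return a ggplot object.
#' @export
plot_vip <- function(scores) {
  thr <- attr(scores, "threshold") %||% 1
  ggplot2::ggplot(scores, ggplot2::aes(.data$variable, .data$vip)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = thr, linetype = "dashed", color = "orange") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "wavenumber (cm⁻¹)", y = "VIP score") +
    ggplot2::theme_minimal()
}

#' Plot GA selection frequencies per bin
#' @param selection a `ga_selection`.
#' @return a ggplot object.
#' @export
plot_ga_frequency <- function(selection) {
  d <- selection$frequency
  x_is_wn <- !all(is.na(d$wavenumber))
  aes_x <- if (x_is_wn) "wavenumber" else "bin"
  p <- ggplot2::ggplot(d, ggplot2::aes(.data[[aes_x]], .data$frequency,
                                       fill = .data$retained)) +
    ggplot2::geom_col(width = if (x_is_wn) NULL else 0.9) +
    ggplot2::geom_hline(yintercept = selection$threshold * selection$n_runs,
                        linetype = "dashed") +
    ggplot2::labs(y = sprintf("selection frequency (of %d runs)", selection$n_runs),
                  x = if (x_is_wn) "wavenumber (cm⁻¹)" else "bin") +
    ggplot2::theme_minimal()
  if (x_is_wn) p <- p + ggplot2::scale_x_reverse()
  p
}

#' Plot predicted versus actual PMI
#' @param report a `cv_report`.
#' @return a ggplot object.
#' @export
plot_predictions <- function(report) {
  d <- dplyr::bind_rows(
    calibration = report$cv_predictions,
    prediction = report$test_predictions, .id = "set")
  ggplot2::ggplot(d, ggplot2::aes(.data$actual, .data$predicted,
                                  color = .data$set)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, color = "darkgreen") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "actual PMI (h)", y = "predicted PMI (h)") +
    ggplot2::theme_minimal()
}

#' Plot similarity group means with SD bars
#' @param profile a [similarity_profile()] result (one or several masks).
#' @return a ggplot object.
#' @export
plot_similarity <- function(profile) {
  d <- profile_group_stats(profile)
  ggplot2::ggplot(d, ggplot2::aes(.data$pmi_h, .data$mean_cos2)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_cos2 - .data$sd_cos2,
                                        ymax = .data$mean_cos2 + .data$sd_cos2),
                           width = 1) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~mask, scales = "free_y") +
    ggplot2::labs(x = "PMI (h)", y = "Cos² similarity") +
    ggplot2::theme_minimal()
}
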