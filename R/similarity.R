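#' Cosine-squared spectral similarity
#'
#' `Cos2(x, y) = (sum x_i y_i)^2 / (sum x_i^2 * sum y_i^2)`: the squared
#' cosine of the angle between two spectra treated as vectors. Bounded in
#' `[0, 1]` (0 = orthogonal, 1 = identical direction), symmetric, and
#' invariant to rescaling either argument by any nonzero factor.
#'
#' @param x,y numeric vectors of equal length, neither all-zero.
#' @return similarity in `[0, 1]`.
#' @export
cos_squared <- function(x, y) {
  if (length(x) != length(y)) {
    abort_plasmapls("vectors must have equal length", "similarity_invalid")
  }
  sx <- sum(x^2); sy <- sum(y^2)
  if (sx == 0 || sy == 0) {
    abort_plasmapls("cosine similarity undefined for a zero vector",
                    "similarity_invalid")
  }
  sum(x * y)^2 / (sx * sy)
}

#' Per-sample similarity to a reference spectrum
#'
#' Computes Cos2 between every (preprocessed) spectrum and a reference
#' spectrum — conventionally the mean preprocessed 0-h formed-element
#' spectrum — restricted to a wavenumber mask (e.g. full spectrum,
#' GA-selected, or GA-excluded regions).
#'
#' @param data a spectra table (preprocessed spectra recommended).
#' @param reference numeric vector on the same axis as `data`, or a
#'   single-row spectra table.
#' @param mask optional wavenumber values to keep (default: full axis).
#' @param mask_label label stored in the output (default derived).
#' @return a `similarity_profile` tibble: `sample_id`, `pmi_h`, `mask`,
#'   `cos2`.
#' @export
similarity_profile <- function(data, reference, mask = NULL,
                               mask_label = NULL) {
  ds <- as_spectra(data, quiet = TRUE)
  axis <- wavenumbers(ds)
  if (is.data.frame(reference)) {
    ref_ds <- as_spectra(reference, quiet = TRUE)
    if (nrow(ref_ds) != 1) {
      abort_plasmapls("reference table must have exactly one row", "similarity_invalid")
    }
    if (!isTRUE(all.equal(wavenumbers(ref_ds), axis))) {
      abort_plasmapls("reference axis does not match data axis", "similarity_invalid")
    }
    reference <- drop(spectra_matrix(ref_ds))
  }
  if (length(reference) != length(axis)) {
    abort_plasmapls(
      sprintf("reference has %d points, data axis has %d",
              length(reference), length(axis)),
      "similarity_invalid")
  }
  if (is.null(mask)) {
    keep <- seq_along(axis)
    mask_label <- mask_label %||% "full"
  } else {
    keep <- which(axis %in% mask)
    if (length(keep) == 0) {
      abort_plasmapls("mask shares no wavenumbers with the data axis",
                      "similarity_invalid")
    }
    mask_label <- mask_label %||% "masked"
  }
  X <- spectra_matrix(ds)[, keep, drop = FALSE]
  r <- reference[keep]
  out <- tibble::tibble(
    sample_id = ds$sample_id,
    pmi_h = ds$pmi_h,
    mask = mask_label,
    cos2 = unname(apply(X, 1, cos_squared, y = r)))
  class(out) <- c("similarity_profile", class(out))
  out
}

#' Group means and SDs of a similarity profile
#' @param profile a [similarity_profile()] result.
#' @return tibble with one row per (mask, pmi_h) group.
#' @export
profile_group_stats <- function(profile) {
  dplyr::summarise(dplyr::group_by(profile, .data$mask, .data$pmi_h),
                   mean_cos2 = mean(.data$cos2),
                   sd_cos2 = stats::sd(.data$cos2),
                   n = dplyr::n(), .groups = "drop")
}

# classical one-way decomposition used by both the ANOVA and Levene's test;
# direct computation keeps the 2000-rep null calibration fast
anova_decompose <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2) abort_plasmapls("need at least 2 groups", "anova_invalid")
  if (any(tabulate(groups) < 2)) {
    abort_plasmapls("every group needs n >= 2", "anova_invalid")
  }
  gm <- tapply(values, groups, mean)
  gn <- tabulate(groups)
  ss_between <- sum(gn * (gm - mean(values))^2)
  ss_within <- sum((values - gm[as.integer(groups)])^2)
  df1 <- k - 1
  df2 <- n - k
  if (ss_within <= 0) {
    abort_plasmapls(
      "zero within-group variance: the F statistic is undefined",
      "anova_degenerate")
  }
  f <- (ss_between / df1) / (ss_within / df2)
  list(f = f, p = stats::pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, ss_between = ss_between, ss_within = ss_within)
}

#' One-way analysis of variance
#'
#' Classical between/within decomposition, `F = MS_between / MS_within`.
#' Also runs Levene's variance-homogeneity test (center = mean), whose
#' p-value drives the post hoc method choice in [posthoc_pairwise()].
#'
#' @param data data frame with the response and grouping columns.
#' @param value,group column names (tidy-eval) of response and groups.
#' @return an `anova_result` list: `f`, `p`, `df1`, `df2`, `levene_p`, and
#'   the groups for downstream post hoc testing.
#' @export
one_way_anova <- function(data, value, group) {
  values <- dplyr::pull(data, {{ value }})
  groups <- factor(dplyr::pull(data, {{ group }}))
  dec <- anova_decompose(values, groups)
  gm <- tapply(values, groups, mean)
  lev <- try(anova_decompose(abs(values - gm[as.integer(groups)]), groups),
             silent = TRUE)
  levene_p <- if (inherits(lev, "try-error")) NA_real_ else lev$p
  structure(list(f = dec$f, p = dec$p, df1 = dec$df1, df2 = dec$df2,
                 levene_p = levene_p, values = values, groups = groups),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g (Levene p = %.3g)\n",
              x$df1, x$df2, x$f, x$p, x$levene_p))
  invisible(x)
}

#' @export
glance.anova_result <- function(x, ...) {
  tibble::tibble(f = x$f, p = x$p, df1 = x$df1, df2 = x$df2,
                 levene_p = x$levene_p)
}

#' Pairwise post hoc comparisons after one-way ANOVA
#'
#' Uses Fisher's least significant difference (pooled-variance pairwise t
#' tests, no correction) when Levene's test does not reject variance
#' homogeneity at `alpha`, and Tamhane's T2 (Welch t statistics with Sidak
#' correction) otherwise.
#'
#' @param anova an [one_way_anova()] result.
#' @param alpha homogeneity decision level (default 0.05).
#' @return tibble of pairs with the statistic, p-value, and method used.
#' @export
posthoc_pairwise <- function(anova, alpha = 0.05) {
  stopifnot(inherits(anova, "anova_result"))
  values <- anova$values
  groups <- anova$groups
  use_lsd <- !is.na(anova$levene_p) && anova$levene_p >= alpha
  pairs <- utils::combn(levels(groups), 2)
  m <- ncol(pairs)
  s2_pool <- NA_real_
  if (use_lsd) {
    gm <- tapply(values, groups, mean)
    ss_within <- sum((values - gm[as.integer(groups)])^2)
    s2_pool <- ss_within / anova$df2
  }
  res <- purrr::map_dfr(seq_len(m), function(i) {
    g1 <- pairs[1, i]; g2 <- pairs[2, i]
    x1 <- values[groups == g1]; x2 <- values[groups == g2]
    if (use_lsd) {
      se <- sqrt(s2_pool * (1 / length(x1) + 1 / length(x2)))
      tstat <- (mean(x1) - mean(x2)) / se
      p <- 2 * stats::pt(abs(tstat), anova$df2, lower.tail = FALSE)
    } else {
      tt <- stats::t.test(x1, x2)   # Welch
      tstat <- unname(tt$statistic)
      p <- min(1, 1 - (1 - tt$p.value)^m)  # Sidak family correction
    }
    tibble::tibble(group1 = g1, group2 = g2, statistic = tstat, p = p)
  })
  res$method <- if (use_lsd) "LSD" else "Tamhane-T2"
  res
}

#' A414 trend analysis
#'
#' Summarises the UV-Vis Soret-band absorbance per PMI group, tests for a
#' group effect with one-way ANOVA, and compares every group to the 0-h
#' baseline post hoc, flagging significant differences at `alpha` (the
#' star annotations of the conventional bar plot).
#'
#' @param data table with columns `pmi_h` and `a414` (see [simulate_a414()]).
#' @param alpha significance level for the star flags (default 0.05).
#' @return an `a414_trend` list: `$groups` tibble (mean, sd, n,
#'   `different_from_0h`), `$anova`, `$posthoc` (vs 0 h only).
#' @export
a414_trend <- function(data, alpha = 0.05) {
  stopifnot(all(c("pmi_h", "a414") %in% names(data)))
  if (!any(data$pmi_h == 0)) {
    abort_plasmapls("a414 trend needs a 0-h baseline group", "anova_invalid")
  }
  an <- one_way_anova(data, a414, pmi_h)
  ph <- posthoc_pairwise(an, alpha)
  vs0 <- ph[ph$group1 == "0" | ph$group2 == "0", ]
  vs0$pmi_h <- as.numeric(ifelse(vs0$group1 == "0", vs0$group2, vs0$group1))
  groups <- dplyr::summarise(
    dplyr::group_by(data, .data$pmi_h),
    mean_a414 = mean(.data$a414), sd_a414 = stats::sd(.data$a414),
    n = dplyr::n(), .groups = "drop")
  groups <- dplyr::left_join(
    groups,
    tibble::tibble(pmi_h = vs0$pmi_h, different_from_0h = vs0$p < alpha),
    by = "pmi_h")
  groups$different_from_0h[groups$pmi_h == 0] <- FALSE
  structure(list(groups = groups, anova = an, posthoc = vs0),
            class = "a414_trend")
}

#' @export
print.a414_trend <- function(x, ...) {
  print(x$anova)
  print(x$groups)
  invisible(x)
}
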