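#' Spectra tables
#'
#' A spectra table is a wide tibble with one row per spectrum: a `sample_id`
#' column (unique strings), a `pmi_h` column (postmortem interval in hours,
#' `NA` for unlabeled prediction input), an optional `parent_id` column mapping
#' replicate spectra to their parent sample, and one numeric-named column per
#' wavenumber (cm^-1). The canonical axis orientation is descending wavenumber,
#' the FTIR plotting convention; [as_spectra()] reverses an ascending axis and
#' says so.
#'
#' @name spectra_tbl
NULL

.meta_cols <- c("sample_id", "pmi_h", "parent_id")

#' Construct a spectra table from components
#'
#' @param x numeric matrix, samples in rows, wavenumbers in columns.
#' @param axis numeric wavenumber axis (cm^-1), one value per column of `x`.
#' @param sample_id character vector of unique sample identifiers.
#' @param pmi_h numeric PMI labels in hours (`NA` allowed), recycled if length 1.
#' @param parent_id optional character vector mapping each row to a parent
#'   sample (for replicate spectra).
#' @return a `spectra_tbl` tibble.
#' @export
new_spectra <- function(x, axis, sample_id, pmi_h = NA_real_, parent_id = NULL) {
  x <- as.matrix(x)
  if (length(axis) != ncol(x)) {
    abort_plasmapls("`axis` length must equal ncol(x)", "spectra_invalid")
  }
  tbl <- tibble::tibble(
    sample_id = as.character(sample_id),
    pmi_h = rep_len(as.numeric(pmi_h), nrow(x))
  )
  if (!is.null(parent_id)) tbl$parent_id <- as.character(parent_id)
  xs <- tibble::as_tibble(x, .name_repair = "minimal")
  names(xs) <- format_axis(axis)
  as_spectra(dplyr::bind_cols(tbl, xs))
}

# full-precision, round-trippable axis labels
format_axis <- function(axis) sprintf("%.17g", as.numeric(axis))

#' Validate and canonicalize a spectra table
#'
#' Checks the container invariants (unique sample ids, strictly monotone
#' numeric axis, finite non-negative labels where present) and reverses an
#' ascending axis to the canonical descending orientation.
#'
#' @param data a data frame in the wide spectra layout.
#' @param quiet suppress the message emitted when an ascending axis is reversed.
#' @return a validated `spectra_tbl` tibble.
#' @export
as_spectra <- function(data, quiet = FALSE) {
  data <- tibble::as_tibble(data)
  if (!all(c("sample_id", "pmi_h") %in% names(data))) {
    abort_plasmapls("spectra table needs `sample_id` and `pmi_h` columns",
                    "spectra_invalid")
  }
  wn_cols <- setdiff(names(data), .meta_cols)
  axis <- suppressWarnings(as.numeric(wn_cols))
  if (length(wn_cols) == 0) {
    abort_plasmapls("spectra table has no wavenumber columns", "spectra_invalid")
  }
  if (anyNA(axis)) {
    bad <- wn_cols[is.na(axis)][1]
    abort_plasmapls(
      sprintf("non-numeric wavenumber column header: '%s'", bad),
      "spectra_parse")
  }
  if (anyDuplicated(data$sample_id)) {
    dup <- data$sample_id[duplicated(data$sample_id)][1]
    abort_plasmapls(sprintf("duplicate sample_id: '%s'", dup), "spectra_invalid")
  }
  d <- diff(axis)
  if (any(d == 0) || (any(d > 0) && any(d < 0))) {
    abort_plasmapls("wavenumber axis must be strictly monotone", "spectra_invalid")
  }
  if (length(d) && all(d > 0)) {
    # ascending input: permute to the canonical descending orientation
    ord <- rev(seq_along(wn_cols))
    meta <- intersect(.meta_cols, names(data))
    data <- data[, c(meta, wn_cols[ord])]
    if (!quiet) rlang::inform("ascending wavenumber axis reversed to descending")
  }
  y <- data$pmi_h
  if (any(!is.na(y) & (!is.finite(y) | y < 0))) {
    abort_plasmapls("pmi_h labels must be finite and >= 0", "spectra_invalid")
  }
  class(data) <- c("spectra_tbl", class(data)[class(data) != "spectra_tbl"])
  data
}

#' Extract the absorbance matrix of a spectra table
#' @param data a spectra table.
#' @return numeric matrix, `sample_id` as rownames, axis labels as colnames.
#' @export
spectra_matrix <- function(data) {
  wn <- setdiff(names(data), .meta_cols)
  m <- as.matrix(data[, wn])
  storage.mode(m) <- "double"
  rownames(m) <- data$sample_id
  m
}

#' Extract the wavenumber axis of a spectra table
#' @param data a spectra table.
#' @return numeric vector of wavenumbers (cm^-1).
#' @export
wavenumbers <- function(data) {
  as.numeric(setdiff(names(data), .meta_cols))
}

#' Read a spectra table from CSV
#'
#' Canonical dialect: UTF-8, comma separated, `.` decimal, header
#' `sample_id,pmi_h[,parent_id],<wavenumber>...`. Ascending axes are reversed
#' to descending (with a message). Ragged rows, duplicate sample ids and
#' non-numeric wavenumber headers are rejected.
#'
#' @param path file path.
#' @return a `spectra_tbl` tibble.
#' @export
read_spectra <- function(path) {
  if (!file.exists(path)) {
    abort_plasmapls(sprintf("no such file: %s", path), "spectra_io")
  }
  # base strtod parser: exact double round trips (vroom's fast parser is
  # off by an ulp on some values); fill = FALSE rejects ragged rows
  data <- tryCatch(
    utils::read.csv(path, check.names = FALSE, fill = FALSE,
                    colClasses = c(sample_id = "character")),
    error = function(e) {
      abort_plasmapls(sprintf("malformed CSV (%s): %s",
                              conditionMessage(e), path),
                      "spectra_parse")
    })
  data$pmi_h <- as.numeric(data$pmi_h)
  as_spectra(tibble::as_tibble(data))
}

#' Write a spectra table to CSV
#'
#' Values are serialised with 17 significant digits so that a
#' write/read round trip reproduces the doubles bit-exactly.
#'
#' @param data a spectra table.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(data, path) {
  data <- as_spectra(data, quiet = TRUE)
  out <- data
  for (nm in setdiff(names(out), c("sample_id", "parent_id"))) {
    v <- out[[nm]]
    out[[nm]] <- ifelse(is.na(v), "", sprintf("%.17g", v))
  }
  class(out) <- setdiff(class(out), "spectra_tbl")
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' Keep a wavenumber region
#'
#' Retains columns with `low <= wavenumber <= high` (closed interval), order
#' preserved. The bio-fingerprint window used throughout is 1800-900 cm^-1.
#'
#' @param data a spectra table.
#' @param high,low region bounds in cm^-1, `high > low`.
#' @return a spectra table restricted to the region.
#' @export
slice_region <- function(data, high = 1800, low = 900) {
  stopifnot(high > low)
  data <- as_spectra(data, quiet = TRUE)
  axis <- wavenumbers(data)
  keep <- axis >= low & axis <= high
  if (!any(keep)) {
    abort_plasmapls(
      sprintf("no wavenumbers in [%g, %g]; axis spans [%g, %g]",
              low, high, min(axis), max(axis)),
      "spectra_empty_slice")
  }
  meta <- intersect(.meta_cols, names(data))
  wn_cols <- setdiff(names(data), .meta_cols)
  as_spectra(data[, c(meta, wn_cols[keep])], quiet = TRUE)
}

#' Average replicate spectra
#'
#' Collapses replicate rows to one row per parent sample (arithmetic mean of
#' the replicate spectra), mirroring the nonuplicate averaging applied to the
#' real measurements. Labels are inherited and must agree across the
#' replicates of a parent.
#'
#' @param data a spectra table with a complete `parent_id` column.
#' @return a spectra table with one row per parent, `sample_id = parent_id`.
#' @export
average_replicates <- function(data) {
  data <- as_spectra(data, quiet = TRUE)
  if (is.null(data[["parent_id"]]) || anyNA(data[["parent_id"]])) {
    abort_plasmapls("`parent_id` must be present for every row", "spectra_invalid")
  }
  y_check <- dplyr::summarise(
    dplyr::group_by(data, .data$parent_id),
    n_y = dplyr::n_distinct(.data$pmi_h), .groups = "drop")
  if (any(y_check$n_y > 1)) {
    bad <- y_check$parent_id[y_check$n_y > 1][1]
    abort_plasmapls(
      sprintf("replicates of parent '%s' carry conflicting pmi_h labels", bad),
      "spectra_invalid")
  }
  parents <- unique(data$parent_id)
  X <- spectra_matrix(data)
  grp <- factor(data$parent_id, levels = parents)
  Xm <- rowsum(X, grp) / as.vector(table(grp))
  y <- data$pmi_h[!duplicated(data$parent_id)]
  new_spectra(Xm, wavenumbers(data), sample_id = parents, pmi_h = y)
}

#' @export
print.spectra_tbl <- function(x, ...) {
  axis <- wavenumbers(x)
  cat(sprintf("# spectra table: %d spectra x %d wavenumbers (%.6g..%.6g cm-1)\n",
              nrow(x), length(axis), axis[1], axis[length(axis)]))
  NextMethod()
}
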