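## ROI time-series container: a T x N numeric matrix (rows = time points,
## columns = regions) plus the repetition time.

#' Construct an ROI time-series object
#'
#' @param values numeric T x N matrix, one column per ROI, one row per time
#'   point (BOLD signal, arbitrary units).
#' @param tr_s repetition time in seconds (default 2).
#' @param roi_labels character vector of N unique region names; defaults to
#'   existing column names.
#' @return An object of class `roi_timeseries`.
#' @export
roi_timeseries <- function(values, tr_s = 2, roi_labels = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(roi_labels)) roi_labels <- sprintf("ROI%03d", seq_len(ncol(values)))
  if (nrow(values) < 2L || ncol(values) < 2L) {
    pn_stop("an ROI time series needs at least 2 time points and 2 regions",
            "presbynet_shape_error")
  }
  if (!all(is.finite(values))) {
    pn_stop("ROI time series contains non-finite values",
            "presbynet_value_error")
  }
  if (length(roi_labels) != ncol(values) || anyDuplicated(roi_labels)) {
    pn_stop("roi_labels must be unique and match the number of columns",
            "presbynet_shape_error")
  }
  if (!is.numeric(tr_s) || length(tr_s) != 1L || tr_s <= 0) {
    pn_stop("tr_s must be a single positive number", "presbynet_config_error")
  }
  colnames(values) <- roi_labels
  structure(list(values = values, tr_s = tr_s), class = "roi_timeseries")
}

#' @export
print.roi_timeseries <- function(x, ...) {
  cat(sprintf("<roi_timeseries> %d time points x %d ROIs, TR = %g s\n",
              nrow(x$values), ncol(x$values), x$tr_s))
  invisible(x)
}

#' @export
dim.roi_timeseries <- function(x) dim(x$values)

#' @noRd
ts_labels <- function(ts) colnames(ts$values)
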