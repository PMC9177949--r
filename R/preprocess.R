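## Signal-level preprocessing chain: discard initial volumes -> screen head
## motion -> regress nuisance signals -> linear detrend + bandpass filter.
## Operates on ROI-level series; image-space steps (slice timing, realignment,
## normalization) are upstream of this package's inputs.

#' Discard initial volumes
#'
#' Drops the first `n_discard` rows of a series (scanner equilibration /
#' subject adaptation period). The default acquisition of 230 volumes minus
#' the conventional 10 leaves 220 retained time points.
#'
#' @param ts an [roi_timeseries()].
#' @param n_discard number of initial rows to drop (default 10).
#' @return The shortened [roi_timeseries()].
#' @export
discard_initial_volumes <- function(ts, n_discard = 10L) {
  stopifnot(inherits(ts, "roi_timeseries"))
  if (!is_count(n_discard)) {
    pn_stop("n_discard must be a non-negative integer", "presbynet_config_error")
  }
  if (n_discard >= nrow(ts$values)) {
    pn_stop(sprintf("cannot discard %d volumes from a %d-volume series",
                    n_discard, nrow(ts$values)),
            "presbynet_input_too_short_error")
  }
  if (n_discard == 0L) return(ts)
  roi_timeseries(ts$values[-seq_len(n_discard), , drop = FALSE],
                 tr_s = ts$tr_s, roi_labels = ts_labels(ts))
}

#' Screen a head-motion trace against exclusion limits
#'
#' A subject is excluded when any translation exceeds `trans_limit_mm`
#' millimetres or any rotation exceeds `rot_limit_deg` degrees in absolute
#' value, using strict inequality (a value exactly at the limit is retained).
#'
#' @param trace T x 6 motion table: 3 translation columns (mm) then 3
#'   rotation columns (degrees), e.g. from [generate_motion_trace()].
#' @param trans_limit_mm,rot_limit_deg exclusion limits (defaults 2.0 / 2.0).
#' @return A list of class `motion_screen`: `include` (logical), and when
#'   excluded, `offending_column`, `offending_time`, `offending_value`.
#' @export
screen_head_motion <- function(trace, trans_limit_mm = 2.0,
                               rot_limit_deg = 2.0) {
  trace <- as.matrix(trace)
  if (nrow(trace) < 1L || ncol(trace) != 6L) {
    pn_stop("motion trace must be a non-empty T x 6 table",
            "presbynet_shape_error")
  }
  if (!all(is.finite(trace))) {
    pn_stop("motion trace contains non-finite values", "presbynet_value_error")
  }
  limits <- rep(c(trans_limit_mm, rot_limit_deg), each = 3L)
  over <- sweep(abs(trace), 2, limits, ">")
  res <- list(include = !any(over),
              trans_limit_mm = trans_limit_mm, rot_limit_deg = rot_limit_deg)
  if (!res$include) {
    hit <- which(over, arr.ind = TRUE)
    # report the single worst violation relative to its limit
    ratio <- abs(trace[hit]) / limits[hit[, 2]]
    worst <- hit[which.max(ratio), ]
    cn <- colnames(trace) %||% sprintf("col%d", seq_len(6))
    res$offending_column <- cn[worst[2]]
    res$offending_time <- unname(worst[1])
    res$offending_value <- unname(trace[worst[1], worst[2]])
  }
  structure(res, class = "motion_screen")
}

#' @export
print.motion_screen <- function(x, ...) {
  if (x$include) {
    cat("<motion_screen> include (all motion within limits)\n")
  } else {
    cat(sprintf("<motion_screen> EXCLUDE: %s = %.3f at time %d exceeds limit\n",
                x$offending_column, x$offending_value, x$offending_time))
  }
  invisible(x)
}

#' Regress nuisance signals out of every ROI column
#'
#' Replaces each ROI column by its least-squares residual against an
#' intercept plus all confound columns (head-motion parameters, global mean,
#' white-matter and CSF signals, as supplied). Residuals are orthogonal to
#' every confound column.
#'
#' @param ts an [roi_timeseries()].
#' @param nuisance T x K numeric table of confound columns.
#' @return The residual [roi_timeseries()].
#' @export
regress_nuisance <- function(ts, nuisance) {
  stopifnot(inherits(ts, "roi_timeseries"))
  nuisance <- as.matrix(nuisance)
  if (nrow(nuisance) != nrow(ts$values)) {
    pn_stop("nuisance table row count must match the time series",
            "presbynet_shape_error")
  }
  if (ncol(nuisance) < 1L) {
    pn_stop("need at least one confound column", "presbynet_shape_error")
  }
  if (!all(is.finite(nuisance))) {
    pn_stop("nuisance table contains non-finite values", "presbynet_value_error")
  }
  if (all(abs(nuisance) < .Machine$double.eps)) {
    pn_stop("nuisance table is all zeros", "presbynet_collinearity_error")
  }
  X <- cbind(intercept = 1, nuisance)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dep <- setdiff(seq_len(ncol(X)), qr_x$pivot[seq_len(qr_x$rank)])
    cn <- colnames(X) %||% sprintf("col%d", seq_len(ncol(X)))
    pn_stop(sprintf("confound columns are collinear (dependent: %s)",
                    paste(cn[dep], collapse = ", ")),
            "presbynet_collinearity_error")
  }
  resid <- qr.resid(qr_x, ts$values)
  roi_timeseries(resid, tr_s = ts$tr_s, roi_labels = ts_labels(ts))
}

#' Global-mean confound from the ROI columns themselves
#'
#' Row mean over all ROI columns, a signal-level surrogate for the
#' whole-brain mean used in nuisance regression.
#'
#' @param ts an [roi_timeseries()].
#' @return Numeric vector of length T.
#' @export
global_mean_signal <- function(ts) {
  stopifnot(inherits(ts, "roi_timeseries"))
  rowMeans(ts$values)
}

#' Linear detrend followed by temporal bandpass filtering
#'
#' Each column is first detrended by ordinary least squares on an intercept
#' plus linear term, then filtered in the frequency domain with an ideal
#' passband `[low_hz, high_hz]` whose edges are cosine-tapered over
#' `taper_hz` to avoid a hard brick wall. Filtering a ramp would ring, so the
#' trend is removed before the filter is applied. Output length equals input
#' length.
#'
#' @param ts an [roi_timeseries()].
#' @param low_hz,high_hz passband edges in Hz (defaults 0.01 and 0.08,
#'   the conventional resting-state band).
#' @param taper_hz cosine taper half-width in Hz (default 0.002).
#' @return The filtered [roi_timeseries()].
#' @export
bandpass_detrend <- function(ts, low_hz = 0.01, high_hz = 0.08,
                             taper_hz = 0.002) {
  stopifnot(inherits(ts, "roi_timeseries"))
  nyquist <- 1 / (2 * ts$tr_s)
  if (!(low_hz > 0 && low_hz < high_hz && high_hz < nyquist)) {
    pn_stop(sprintf(
      "need 0 < low_hz < high_hz < Nyquist (%.4g Hz at TR %.3g s)",
      nyquist, ts$tr_s), "presbynet_config_error")
  }
  x <- ts$values
  t_len <- nrow(x)
  # detrend: residual of each column on intercept + time index
  time_idx <- seq_len(t_len)
  qr_t <- qr(cbind(1, time_idx))
  x <- qr.resid(qr_t, x)
  # frequency response on FFT bins (two-sided, symmetric)
  freqs <- c(0, seq_len(t_len - 1)) / (t_len * ts$tr_s)
  freqs <- pmin(freqs, 1 / ts$tr_s - freqs)  # fold to [0, Nyquist]
  resp <- cosine_band_response(freqs, low_hz, high_hz, taper_hz)
  filt <- apply(x, 2, function(col) Re(fft(fft(col) * resp, inverse = TRUE)) / t_len)
  roi_timeseries(matrix(filt, nrow = t_len), tr_s = ts$tr_s,
                 roi_labels = ts_labels(ts))
}

# Cosine-tapered ideal band response: 1 inside [low, high], 0 outside
# [low - taper, high + taper], raised-cosine ramps in between.
#' @noRd
cosine_band_response <- function(f, low, high, taper) {
  resp <- numeric(length(f))
  inside <- f >= low & f <= high
  resp[inside] <- 1
  lo_ramp <- f >= low - taper & f < low
  resp[lo_ramp] <- 0.5 * (1 + cos(pi * (low - f[lo_ramp]) / taper))
  hi_ramp <- f > high & f <= high + taper
  resp[hi_ramp] <- 0.5 * (1 + cos(pi * (f[hi_ramp] - high) / taper))
  resp
}

#' Run the full signal-level preprocessing chain on one subject
#'
#' Fixed order: discard initial volumes, screen head motion (on the rows
#' retained after the discard), regress nuisance signals, then detrend and
#' bandpass filter. The default nuisance set is the six motion parameters
#' plus the global mean over ROI columns; additional confound columns
#' (e.g. white-matter or CSF signals) can be appended via `extra_confounds`.
#'
#' @param ts an [roi_timeseries()] of acquired volumes.
#' @param motion T x 6 motion trace aligned to the acquired volumes.
#' @param n_discard initial volumes to drop (default 10).
#' @param trans_limit_mm,rot_limit_deg motion exclusion limits.
#' @param low_hz,high_hz bandpass edges in Hz.
#' @param extra_confounds optional numeric matrix (rows = acquired volumes).
#' @param include_global_mean include the ROI-mean confound? (default TRUE)
#' @return A list of class `preprocessed_subject`: `included` (logical),
#'   `screen` (the [screen_head_motion()] report), and when included, `ts`
#'   (the preprocessed [roi_timeseries()]).
#' @export
preprocess_timeseries <- function(ts, motion = NULL, n_discard = 10L,
                                  trans_limit_mm = 2.0, rot_limit_deg = 2.0,
                                  low_hz = 0.01, high_hz = 0.08,
                                  extra_confounds = NULL,
                                  include_global_mean = TRUE) {
  stopifnot(inherits(ts, "roi_timeseries"))
  keep <- seq_len(nrow(ts$values)) > n_discard
  ts2 <- discard_initial_volumes(ts, n_discard)
  screen <- NULL
  if (!is.null(motion)) {
    motion <- as.matrix(motion)
    if (nrow(motion) == length(keep)) {
      motion <- motion[keep, , drop = FALSE]
    } else if (nrow(motion) != nrow(ts2$values)) {
      pn_stop("motion trace length matches neither acquired nor retained volumes",
              "presbynet_shape_error")
    }
    screen <- screen_head_motion(motion, trans_limit_mm, rot_limit_deg)
    if (!screen$include) {
      return(structure(list(included = FALSE, screen = screen, ts = NULL),
                       class = "preprocessed_subject"))
    }
  }
  confounds <- NULL
  if (!is.null(motion)) confounds <- cbind(confounds, motion)
  if (include_global_mean) {
    confounds <- cbind(confounds, global_mean = global_mean_signal(ts2))
  }
  if (!is.null(extra_confounds)) {
    extra_confounds <- as.matrix(extra_confounds)
    if (nrow(extra_confounds) == length(keep)) {
      extra_confounds <- extra_confounds[keep, , drop = FALSE]
    }
    confounds <- cbind(confounds, extra_confounds)
  }
  if (!is.null(confounds)) ts2 <- regress_nuisance(ts2, confounds)
  ts2 <- bandpass_detrend(ts2, low_hz = low_hz, high_hz = high_hz)
  structure(list(included = TRUE, screen = screen, ts = ts2),
            class = "preprocessed_subject")
}
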