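#' Remove initial volumes from a time series
#'
#' Drops the first `k` volumes (scanner signal-stabilization period) and
#' records the count in the series metadata.
#'
#' @param ts A [parcel_ts()].
#' @param k Number of initial volumes to remove; must be smaller than the
#'   number of volumes.
#' @return The shortened `parcel_ts` with `n_dropped` incremented by `k`.
#' @export
drop_initial_volumes <- function(ts, k) {
  k <- as.integer(k)
  if (k < 0L) stop("k must be non-negative")
  if (k >= nrow(ts)) {
    stop("cannot drop ", k, " volumes from a series of length ", nrow(ts))
  }
  if (k == 0L) return(ts)
  rewrap_ts(ts, as_ts_matrix(ts)[-seq_len(k), , drop = FALSE],
            n_dropped = (attr(ts, "n_dropped") %||% 0L) + k)
}

#' Subject-level head-motion exclusion rule
#'
#' A subject is excluded when head motion exceeded 3 mm in displacement or
#' 3 degrees in rotation, or when the mean framewise displacement exceeded
#' 0.2 mm (all strict inequalities).
#'
#' @param max_translation_mm Maximum absolute translation (mm).
#' @param max_rotation_deg Maximum absolute rotation (degrees).
#' @param mean_fd_mm Mean framewise displacement (mm).
#' @return `TRUE` if the subject should be excluded.
#' @export
#' @examples
#' motion_exclude(2, 2, 0.19)  # keep
#' motion_exclude(3.1, 0, 0.05)  # exclude
motion_exclude <- function(max_translation_mm, max_rotation_deg, mean_fd_mm) {
  vals <- c(max_translation_mm, max_rotation_deg, mean_fd_mm)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("motion summaries must be finite and non-negative")
  }
  max_translation_mm > 3 || max_rotation_deg > 3 || mean_fd_mm > 0.2
}

#' Summarize motion parameters for the exclusion rule
#'
#' @param motion6 Time-by-6 matrix: three translations (mm) then three
#'   rotations (radians).
#' @param fd Per-volume framewise displacement series (mm).
#' @return List with `max_translation_mm`, `max_rotation_deg`, `mean_fd_mm`.
#' @export
motion_summary <- function(motion6, fd) {
  motion6 <- as.matrix(motion6)
  list(max_translation_mm = max(abs(motion6[, 1:3])),
       max_rotation_deg = max(abs(motion6[, 4:6])) * 180 / pi,
       mean_fd_mm = mean(fd))
}

#' Remove linear trends from each region's time course
#'
#' Subtracts the least-squares line (intercept + slope * t) from every
#' column, leaving zero-mean detrended residuals.
#'
#' @param ts A [parcel_ts()] with at least 3 volumes.
#' @return Detrended `parcel_ts`.
#' @export
detrend_linear <- function(ts) {
  m <- as_ts_matrix(ts)
  if (nrow(m) < 3L) stop("need at least 3 time points to detrend")
  t_idx <- seq_len(nrow(m))
  X <- cbind(1, t_idx)
  beta <- solve(crossprod(X), crossprod(X, m))
  rewrap_ts(ts, m - X %*% beta)
}

#' Temporal band-pass filter
#'
#' Zero-phase band-pass filtering of every region's time course, by default
#' a 4th-order Butterworth filter applied forward and backward
#' (`signal::filtfilt`). An ideal frequency-domain filter (hard FFT mask
#' over the passband) is available as a cross-check.
#'
#' @param ts A [parcel_ts()] carrying its repetition time.
#' @param low_hz,high_hz Passband edges in Hz (defaults 0.01 and 0.08, the
#'   conventional resting-state band). `high_hz` must be below the Nyquist
#'   frequency `1 / (2 * TR)`.
#' @param method `"butterworth"` (default) or `"fft"`.
#' @param order Butterworth order (default 4).
#' @return Filtered `parcel_ts`.
#' @export
bandpass <- function(ts, low_hz = 0.01, high_hz = 0.08,
                     method = c("butterworth", "fft"), order = 4L) {
  method <- match.arg(method)
  tr_s <- tr(ts)
  nyquist <- 1 / (2 * tr_s)
  if (low_hz <= 0 || high_hz <= low_hz) {
    stop("need 0 < low_hz < high_hz")
  }
  if (high_hz >= nyquist) {
    stop(sprintf("high_hz = %.3g Hz is not below Nyquist = %.3g Hz", high_hz,
                 nyquist))
  }
  m <- as_ts_matrix(ts)
  if (method == "butterworth") {
    filt <- signal::butter(order, c(low_hz, high_hz) / nyquist, type = "pass")
    out <- apply(m, 2L, function(col) signal::filtfilt(filt, col))
  } else {
    n <- nrow(m)
    freqs <- (seq_len(n) - 1L) / (n * tr_s)
    freqs <- pmin(freqs, 1 / tr_s - freqs)  # two-sided frequency axis
    keep <- freqs >= low_hz & freqs <= high_hz
    out <- apply(m, 2L, function(col) {
      Re(fft(fft(col) * keep, inverse = TRUE)) / n
    })
  }
  rewrap_ts(ts, out)
}

#' Regress nuisance signals out of a time series
#'
#' Ordinary-least-squares regression of each region's time course on the
#' nuisance design (plus an intercept); returns the residuals, which are
#' orthogonal to every regressor. Linearly dependent regressor columns are
#' dropped with a warning.
#'
#' @param ts A [parcel_ts()].
#' @param regressors Time-by-q numeric matrix of nuisance signals (e.g. the
#'   Friston-24 motion expansion plus white-matter and CSF columns).
#' @return Residual `parcel_ts`.
#' @export
regress_nuisance <- function(ts, regressors) {
  m <- as_ts_matrix(ts)
  regressors <- as.matrix(regressors)
  if (nrow(regressors) != nrow(m)) {
    stop("regressors have ", nrow(regressors), " rows but the series has ",
         nrow(m))
  }
  X <- cbind(intercept = 1, regressors)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    keep <- qr_x$pivot[seq_len(qr_x$rank)]
    warning("dropping ", ncol(X) - qr_x$rank,
            " linearly dependent nuisance column(s)")
    X <- X[, sort(keep), drop = FALSE]
    qr_x <- qr(X)
  }
  rewrap_ts(ts, m - X %*% qr.coef(qr_x, m))
}

#' Run the temporal preprocessing pipeline on one subject
#'
#' Applies, in the fixed default order: initial-volume dropping, linear
#' detrending, band-pass filtering, and nuisance regression. The order is
#' part of the output's metadata; any other order is rejected unless
#' `allow_reorder = TRUE`.
#'
#' @param ts A [parcel_ts()].
#' @param nuisance Optional nuisance regressor matrix.
#' @param drop_k Initial volumes to drop (default 0; rows are removed from
#'   `nuisance` as well).
#' @param low_hz,high_hz Band-pass edges; set `band = FALSE` to skip
#'   filtering.
#' @param band Apply the band-pass step? Default `TRUE`.
#' @param steps Processing order; must equal the default unless
#'   `allow_reorder`.
#' @param allow_reorder Permit a non-standard step order.
#' @return Preprocessed `parcel_ts` with a `preprocessing` attribute
#'   recording the steps applied.
#' @export
preprocess_ts <- function(ts, nuisance = NULL, drop_k = 0L,
                          low_hz = 0.01, high_hz = 0.08, band = TRUE,
                          steps = c("drop", "detrend", "bandpass", "regress"),
                          allow_reorder = FALSE) {
  default_steps <- c("drop", "detrend", "bandpass", "regress")
  if (!identical(steps, default_steps) && !allow_reorder) {
    stop("non-default preprocessing order; set allow_reorder = TRUE to override")
  }
  applied <- character(0)
  for (step in steps) {
    if (step == "drop") {
      if (drop_k > 0L) {
        ts <- drop_initial_volumes(ts, drop_k)
        if (!is.null(nuisance)) {
          nuisance <- nuisance[-seq_len(drop_k), , drop = FALSE]
        }
      }
    } else if (step == "detrend") {
      ts <- detrend_linear(ts)
    } else if (step == "bandpass") {
      if (band) ts <- bandpass(ts, low_hz, high_hz)
    } else if (step == "regress") {
      if (!is.null(nuisance)) ts <- regress_nuisance(ts, nuisance)
    } else {
      stop("unknown preprocessing step: ", step)
    }
    applied <- c(applied, step)
  }
  attr(ts, "preprocessing") <- applied
  ts
}
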