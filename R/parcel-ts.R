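#' Parcel time-series container
#'
#' A numeric time-by-region matrix with repetition-time metadata. This is
#' the unit the temporal preprocessing pipeline transforms: rows are fMRI
#' volumes, columns are regions (cortical parcels or thalamic voxels).
#'
#' @param values Numeric matrix, time in rows, regions in columns. No
#'   missing values are allowed.
#' @param tr_seconds Repetition time in seconds (positive).
#' @param region_names Optional character vector of region names; defaults
#'   to the column names of `values`.
#' @param n_dropped Number of initial volumes already removed upstream.
#' @return An object of class `parcel_ts`: the matrix with `tr_seconds` and
#'   `n_dropped` attributes.
#' @export
#' @examples
#' ts <- parcel_ts(matrix(rnorm(40), 10, 4), tr_seconds = 2)
#' tr(ts)
parcel_ts <- function(values, tr_seconds = 2, region_names = colnames(values),
                      n_dropped = 0L) {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("time series must be numeric")
  if (anyNA(values)) stop("time series contains missing values")
  if (nrow(values) < 2L) stop("need at least 2 time points")
  if (!is.numeric(tr_seconds) || length(tr_seconds) != 1L || tr_seconds <= 0) {
    stop("tr_seconds must be a positive scalar")
  }
  if (!is.null(region_names)) {
    if (length(region_names) != ncol(values)) {
      stop("region_names length (", length(region_names),
           ") does not match region count (", ncol(values), ")")
    }
    colnames(values) <- region_names
  }
  structure(values,
            tr_seconds = as.numeric(tr_seconds),
            n_dropped = as.integer(n_dropped),
            class = c("parcel_ts", "matrix", "array"))
}

#' @rdname parcel_ts
#' @param x A `parcel_ts` object.
#' @export
tr <- function(x) {
  attr(x, "tr_seconds") %||% stop("object carries no repetition time")
}

#' @export
print.parcel_ts <- function(x, ...) {
  cat(sprintf("parcel time series: %d volumes x %d regions (TR %.3g s, %d dropped)\n",
              nrow(x), ncol(x), attr(x, "tr_seconds"),
              attr(x, "n_dropped") %||% 0L))
  invisible(x)
}

# Rebuild a parcel_ts with new values, keeping metadata.
rewrap_ts <- function(template, values, n_dropped = NULL) {
  parcel_ts(values,
            tr_seconds = attr(template, "tr_seconds") %||% 2,
            region_names = colnames(template),
            n_dropped = n_dropped %||% (attr(template, "n_dropped") %||% 0L))
}

as_ts_matrix <- function(x) {
  m <- unclass(x)
  attr(m, "tr_seconds") <- NULL
  attr(m, "n_dropped") <- NULL
  m
}
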