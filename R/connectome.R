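#' Pearson functional connectivity matrix
#'
#' Correlates all region pairs of a time series, producing a symmetric
#' correlation matrix with a unit diagonal — the substrate of all graph
#' analyses in the package.
#'
#' @param ts A [parcel_ts()] (or time-by-region matrix) with at least 3
#'   volumes and no zero-variance region.
#' @param partition Optional node-to-module assignment stored on the
#'   result.
#' @return Object of class `conn_matrix`: the N-by-N correlation matrix
#'   with an optional `partition` attribute.
#' @export
#' @examples
#' ts <- parcel_ts(matrix(rnorm(300), 50, 6))
#' fc <- pearson_fc(ts)
#' range(fc)
pearson_fc <- function(ts, partition = NULL) {
  m <- if (inherits(ts, "parcel_ts")) as_ts_matrix(ts) else as.matrix(ts)
  if (nrow(m) < 3L) stop("need at least 3 time points")
  sds <- apply(m, 2L, sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[sds == 0] %||% which(sds == 0)
    stop("zero-variance region(s): ", paste(head(bad, 5L), collapse = ", "))
  }
  r <- cor(m)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  conn_matrix(r, partition)
}

#' @rdname pearson_fc
#' @param values Symmetric correlation matrix.
#' @export
conn_matrix <- function(values, partition = NULL) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) stop("correlation matrix must be square")
  if (max(abs(values - t(values))) > 1e-10) {
    stop("correlation matrix is not symmetric")
  }
  if (any(values < -1 - 1e-8 | values > 1 + 1e-8)) {
    stop("correlation entries outside [-1, 1]")
  }
  if (!is.null(partition)) {
    attr(values, "partition") <- as_partition(partition, nrow(values))
  }
  class(values) <- c("conn_matrix", "matrix", "array")
  values
}

#' Fisher z transform and its inverse
#'
#' `fisher_z` is `atanh(r)`; `inverse_fisher_z` is `tanh(z)`. Correlations
#' at or beyond +/-1 are clipped to +/-(1 - 1e-7) with a warning, so
#' averaging pipelines never produce infinities.
#'
#' @param r Correlation value(s).
#' @param z Fisher-z value(s).
#' @return Transformed numeric vector.
#' @export
#' @examples
#' inverse_fisher_z(mean(fisher_z(c(0.3, 0.7))))
fisher_z <- function(r) {
  out_of_range <- abs(r) >= 1
  if (any(out_of_range, na.rm = TRUE)) {
    warning(sum(out_of_range, na.rm = TRUE),
            " correlation(s) at or beyond +/-1 clipped before atanh")
    r[which(out_of_range)] <- sign(r[which(out_of_range)]) * (1 - 1e-7)
  }
  atanh(r)
}

#' @rdname fisher_z
#' @export
inverse_fisher_z <- function(z) {
  tanh(z)
}

# Rank the upper-triangle entries of a correlation block: strongest first,
# exact ties broken by ascending (row, column) index pair.
rank_upper_entries <- function(values) {
  n <- nrow(values)
  ut <- which(upper.tri(values), arr.ind = TRUE)
  ord_pairs <- order(ut[, 1L], ut[, 2L])  # row-major (i, j) order
  ut <- ut[ord_pairs, , drop = FALSE]
  v <- values[ut]
  list(pairs = ut, values = v, order = order(-v, seq_along(v)))
}

#' Proportional sparsity thresholding
#'
#' Keeps the strongest `K = round(sparsity * N(N-1)/2)` positive
#' correlations as binary undirected edges (rounding halves away from zero;
#' ties broken by ascending node-index pair). Negative correlations are
#' never admitted: when fewer than K positive entries exist, all positive
#' entries are kept and the achieved sparsity is recorded.
#'
#' @param conn A [conn_matrix()].
#' @param sparsity Fraction of possible edges to retain, in `(0, 1]`.
#' @return Object of class `binary_graph`: list with the 0/1 `adjacency`
#'   matrix (zero diagonal), requested `sparsity`, `achieved_sparsity`,
#'   `n_edges`, and the node `partition` if the matrix carried one.
#' @export
proportional_threshold <- function(conn, sparsity) {
  if (!is.numeric(sparsity) || length(sparsity) != 1L ||
      sparsity <= 0 || sparsity > 1) {
    stop("sparsity must be a single value in (0, 1]")
  }
  n <- nrow(conn)
  ranked <- rank_upper_entries(unclass(conn))
  n_pairs <- length(ranked$values)
  k_target <- round_half_up(sparsity * n_pairs)
  top <- ranked$order[seq_len(min(k_target, n_pairs))]
  top <- top[ranked$values[top] > 0]
  adj <- matrix(0L, n, n, dimnames = dimnames(conn))
  if (length(top) > 0L) {
    sel <- ranked$pairs[top, , drop = FALSE]
    adj[sel] <- 1L
    adj[sel[, c(2L, 1L), drop = FALSE]] <- 1L
  }
  structure(list(adjacency = adj,
                 sparsity = sparsity,
                 achieved_sparsity = length(top) / n_pairs,
                 n_edges = length(top),
                 partition = attr(conn, "partition")),
            class = "binary_graph")
}

#' @export
print.binary_graph <- function(x, ...) {
  cat(sprintf("binary graph: %d nodes, %d edges (sparsity %.3g, achieved %.3g)\n",
              nrow(x$adjacency), x$n_edges, x$sparsity, x$achieved_sparsity))
  invisible(x)
}

#' Threshold a connectivity matrix across a sparsity sweep
#'
#' @param conn A [conn_matrix()].
#' @param levels Strictly increasing sparsity levels in `(0, 1]`; default
#'   0.1 to 1.0 in steps of 0.1.
#' @return List of [proportional_threshold()] graphs, one per level. Edge
#'   sets are nested: each graph contains every sparser graph's edges.
#' @export
threshold_sweep <- function(conn, levels = sparsity_levels()) {
  if (any(diff(levels) <= 0)) stop("levels must be strictly increasing")
  if (any(levels <= 0 | levels > 1)) stop("levels must lie in (0, 1]")
  lapply(levels, function(s) proportional_threshold(conn, s))
}

#' @rdname threshold_sweep
#' @export
sparsity_levels <- function() {
  seq(0.1, 1, by = 0.1)
}

#' Area under a metric-versus-sparsity curve
#'
#' Trapezoidal integral of a graph metric over the sparsity axis — the
#' threshold-free summary reported for every topological property.
#'
#' @param values Metric values, one per level.
#' @param levels Sparsity levels (at least two).
#' @return The trapezoid integral (scalar).
#' @export
#' @examples
#' auc(rep(2, 10), sparsity_levels())  # 0.9 * 2
auc <- function(values, levels = sparsity_levels()) {
  if (length(values) != length(levels)) {
    stop("values (", length(values), ") and levels (", length(levels),
         ") differ in length")
  }
  if (length(levels) < 2L) stop("need at least 2 levels")
  sum(diff(levels) * (head(values, -1L) + tail(values, -1L)) / 2)
}

#' @rdname auc
#' @export
metric_curve <- function(values, levels = sparsity_levels()) {
  structure(list(levels = levels, values = unname(values),
                 auc = auc(values, levels)),
            class = "metric_curve")
}

#' @export
print.metric_curve <- function(x, ...) {
  cat(sprintf("metric curve over %d sparsity levels, AUC = %.4g\n",
              length(x$levels), x$auc))
  invisible(x)
}
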