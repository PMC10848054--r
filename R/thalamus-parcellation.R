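#' Binarize a probabilistic atlas volume
#'
#' A voxel is in-mask iff its probability strictly exceeds the threshold
#' (default 10%, the conventional cutoff for probabilistic thalamus
#' atlases). Boundary voxels at exactly the threshold are excluded.
#'
#' @param prob 3-D array of probabilities in `[0, 1]`.
#' @param threshold Probability cutoff, default 0.10.
#' @return Logical array of the same dimensions.
#' @export
mask_from_probability <- function(prob, threshold = 0.10) {
  if (any(prob < 0 | prob > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]")
  }
  prob > threshold
}

#' Seed-to-voxel functional connectivity map
#'
#' Correlates each of the seven network seed signals (mean time course over
#' the network's cortical parcels) with every in-mask thalamic voxel.
#'
#' @param cortical_ts Preprocessed cortical [parcel_ts()].
#' @param partition Parcel-to-network assignment.
#' @param thalamic_ts Time-by-voxel matrix of in-mask voxel time courses
#'   (same time axis as `cortical_ts`).
#' @param voxel_coords Optional V-by-3 integer matrix of voxel indices,
#'   carried through to the label map.
#' @return Object of class `seed_fc_map`: `values` (7-by-V correlation
#'   matrix, rows in `networks7()` order), `voxel_coords`, `network_order`.
#' @export
seed_fc_map <- function(cortical_ts, partition, thalamic_ts,
                        voxel_coords = NULL) {
  p <- as_partition(partition, ncol(cortical_ts))
  cort <- if (inherits(cortical_ts, "parcel_ts")) as_ts_matrix(cortical_ts) else as.matrix(cortical_ts)
  thal <- if (inherits(thalamic_ts, "parcel_ts")) as_ts_matrix(thalamic_ts) else as.matrix(thalamic_ts)
  if (nrow(cort) != nrow(thal)) {
    stop("cortical and thalamic series differ in time length")
  }
  if (ncol(thal) == 0L) stop("no in-mask voxels")
  nets <- networks7()
  seeds <- vapply(nets, function(m) {
    idx <- which(p == m)
    if (length(idx) == 0L) stop("network ", m, " has no parcels")
    rowMeans(cort[, idx, drop = FALSE])
  }, numeric(nrow(cort)))
  values <- t(cor(thal, seeds))  # 7 x V
  rownames(values) <- nets
  structure(list(values = values,
                 voxel_coords = voxel_coords,
                 network_order = nets),
            class = "seed_fc_map")
}

#' Average seed-to-voxel maps across subjects
#'
#' Cell-wise Fisher-z transform, arithmetic mean, inverse transform — the
#' variance-stabilized group average used before winner-take-all labelling.
#'
#' @param maps List of [seed_fc_map()] objects over identical voxel sets.
#' @return A `seed_fc_map` of the group-average correlations.
#' @export
group_average_fc <- function(maps) {
  if (length(maps) == 0L) stop("no maps to average")
  dims <- vapply(maps, function(m) dim(m$values), integer(2L))
  if (any(dims[1L, ] != dims[1L, 1L]) || any(dims[2L, ] != dims[2L, 1L])) {
    stop("seed FC maps cover different voxel sets")
  }
  z <- Reduce(`+`, lapply(maps, function(m) fisher_z(m$values))) / length(maps)
  out <- maps[[1L]]
  out$values <- inverse_fisher_z(z)
  out
}

#' Winner-take-all thalamic parcellation
#'
#' Labels each thalamic voxel with the network whose seed shows the
#' strongest functional connectivity to it. Exact ties go to the first
#' network in the fixed order (with a warning); voxels whose winning
#' correlation is not positive are labelled by the argmax anyway but
#' flagged.
#'
#' @param map A [seed_fc_map()] (typically the [group_average_fc()] map).
#' @return Object of class `thalamic_label_map`: `labels` (factor, one per
#'   voxel), `winning_fc`, `voxel_counts` (per network), `nonpositive`
#'   (logical flags), `voxel_coords`.
#' @export
winner_take_all <- function(map) {
  v <- map$values
  if (is.null(dim(v)) || ncol(v) == 0L) stop("empty seed FC map")
  win <- max.col(t(v), ties.method = "first")
  maxima <- v[cbind(win, seq_len(ncol(v)))]
  n_tied <- sum(colSums(v == rep(maxima, each = nrow(v))) > 1L)
  if (n_tied > 0L) {
    warning(n_tied, " voxel(s) had tied winning connectivity; ",
            "first network in fixed order wins")
  }
  labels <- factor(map$network_order[win], levels = map$network_order)
  structure(list(labels = labels,
                 winning_fc = maxima,
                 voxel_counts = table(labels),
                 nonpositive = maxima <= 0,
                 voxel_coords = map$voxel_coords),
            class = "thalamic_label_map")
}

#' @export
print.thalamic_label_map <- function(x, ...) {
  cat("winner-take-all thalamic parcellation:\n")
  print(x$voxel_counts)
  if (any(x$nonpositive)) {
    cat(sum(x$nonpositive), "voxel(s) flagged with non-positive winning FC\n")
  }
  invisible(x)
}

#' Render a label map into a volume array
#'
#' @param label_map A [winner_take_all()] result carrying voxel
#'   coordinates.
#' @param dims Dimensions of the target volume.
#' @return Integer 3-D array with codes 1-7 (`networks7()` order), 0
#'   elsewhere.
#' @export
label_volume <- function(label_map, dims) {
  if (is.null(label_map$voxel_coords)) {
    stop("label map carries no voxel coordinates")
  }
  vol <- array(0L, dim = dims)
  vol[label_map$voxel_coords] <- as.integer(label_map$labels)
  vol
}

#' Mean time series of each thalamic subdivision
#'
#' Averages the (preprocessed) voxel time courses within each
#' winner-take-all label, producing the seven thalamic node signals used in
#' the thalamocortical network. Labels with no voxels yield an NA column
#' flagged in the `missing` attribute.
#'
#' @param thalamic_ts Time-by-voxel matrix.
#' @param label_map A [winner_take_all()] result (or a factor of labels).
#' @return Time-by-7 matrix with columns `tha_VIS` ... `tha_DMN` and a
#'   `missing` attribute naming empty subdivisions.
#' @export
subdivision_timeseries <- function(thalamic_ts, label_map) {
  labels <- if (inherits(label_map, "thalamic_label_map")) label_map$labels else
    factor(as.character(label_map), levels = networks7())
  thal <- if (inherits(thalamic_ts, "parcel_ts")) as_ts_matrix(thalamic_ts) else as.matrix(thalamic_ts)
  if (ncol(thal) != length(labels)) {
    stop("label count (", length(labels), ") does not match voxel count (",
         ncol(thal), ")")
  }
  nets <- networks7()
  out <- matrix(NA_real_, nrow(thal), 7L,
                dimnames = list(NULL, paste0("tha_", nets)))
  missing <- character(0)
  for (n in seq_along(nets)) {
    idx <- which(labels == nets[n])
    if (length(idx) == 0L) {
      missing <- c(missing, nets[n])
    } else {
      out[, n] <- rowMeans(thal[, idx, drop = FALSE])
    }
  }
  attr(out, "missing") <- missing
  out
}
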