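#' Build the thalamocortical correlation matrix
#'
#' Pearson correlation over the concatenation of the cortical parcels and
#' the seven thalamic subdivision signals (appended after the cortex in
#' fixed network order), giving the 207-node matrix for the default
#' 200-parcel cortex. Each thalamic node inherits the module label of its
#' network. Missing (empty) subdivisions are dropped with a record.
#'
#' @param cortical_ts Preprocessed cortical [parcel_ts()].
#' @param subdivision_ts Time-by-7 matrix from [subdivision_timeseries()].
#' @param partition Cortical parcel-to-network assignment.
#' @return A [conn_matrix()] with attributes `n_cortical` and
#'   `dropped_subdivisions`.
#' @export
build_thalamocortical <- function(cortical_ts, subdivision_ts, partition) {
  p <- as_partition(partition, ncol(cortical_ts))
  cort <- if (inherits(cortical_ts, "parcel_ts")) as_ts_matrix(cortical_ts) else as.matrix(cortical_ts)
  sub <- as.matrix(subdivision_ts)
  if (nrow(cort) != nrow(sub)) stop("time axes differ")
  nets <- networks7()
  if (is.null(colnames(sub))) colnames(sub) <- paste0("tha_", nets)
  present <- !vapply(seq_len(ncol(sub)), function(j) anyNA(sub[, j]), logical(1L))
  dropped <- nets[!present]
  sub <- sub[, present, drop = FALSE]

  combined <- cbind(cort, sub)
  full_part <- c(as.character(p), nets[present])
  r <- cor(combined)
  r <- (r + t(r)) / 2
  diag(r) <- 1
  out <- conn_matrix(r, full_part)
  attr(out, "n_cortical") <- ncol(cort)
  attr(out, "dropped_subdivisions") <- dropped
  out
}

# Threshold a rectangular (bipartite) correlation block: keep the K
# strongest positive entries, ties broken by ascending (row, column).
threshold_bipartite <- function(block, sparsity) {
  n_entries <- length(block)
  k_target <- round_half_up(sparsity * n_entries)
  idx <- which(!is.na(block), arr.ind = TRUE)
  ord_pairs <- order(idx[, 1L], idx[, 2L])
  idx <- idx[ord_pairs, , drop = FALSE]
  v <- block[idx]
  keep <- order(-v, seq_along(v))[seq_len(min(k_target, n_entries))]
  keep <- keep[v[keep] > 0]
  out <- matrix(0L, nrow(block), ncol(block))
  if (length(keep) > 0L) out[idx[keep, , drop = FALSE]] <- 1L
  out
}

#' Two-step thresholding of a thalamocortical matrix
#'
#' Thresholding the full 207-node matrix at a single proportional cutoff
#' would sacrifice thalamocortical edges, which are systematically weaker
#' than cortico-cortical ones. Instead, the proportional threshold is
#' applied independently to the cortical-cortical block, the
#' thalamo-thalamic block, and the thalamo-cortical bipartite block (same
#' sparsity each), and the three binary blocks are reassembled into one
#' symmetric adjacency matrix.
#'
#' @param tc A [build_thalamocortical()] matrix.
#' @param sparsity Sparsity level in `(0, 1]`.
#' @param single_step If `TRUE`, threshold the whole matrix in one pass
#'   instead (for comparison only).
#' @return A `binary_graph` over all nodes, with per-block edge counts in
#'   `block_edges`.
#' @export
two_step_threshold <- function(tc, sparsity, single_step = FALSE) {
  if (single_step) {
    return(proportional_threshold(tc, sparsity))
  }
  n_cort <- attr(tc, "n_cortical") %||% stop("matrix lacks n_cortical attribute")
  n <- nrow(tc)
  ci <- seq_len(n_cort)
  ti <- (n_cort + 1L):n
  g_cc <- proportional_threshold(conn_matrix(unclass(tc)[ci, ci]), sparsity)
  g_tt <- proportional_threshold(conn_matrix(unclass(tc)[ti, ti, drop = FALSE]),
                                 sparsity)
  b_tc <- threshold_bipartite(unclass(tc)[ti, ci, drop = FALSE], sparsity)

  adj <- matrix(0L, n, n, dimnames = dimnames(tc))
  adj[ci, ci] <- g_cc$adjacency
  adj[ti, ti] <- g_tt$adjacency
  adj[ti, ci] <- b_tc
  adj[ci, ti] <- t(b_tc)
  n_edges <- sum(adj) / 2
  structure(list(adjacency = adj,
                 sparsity = sparsity,
                 achieved_sparsity = n_edges / (n * (n - 1) / 2),
                 n_edges = n_edges,
                 block_edges = c(cortical = g_cc$n_edges,
                                 thalamic = g_tt$n_edges,
                                 bipartite = sum(b_tc)),
                 partition = attr(tc, "partition")),
            class = "binary_graph")
}

#' Participation coefficient
#'
#' `PC_i = 1 - sum_m (k_im / k_i)^2`, where `k_im` counts node i's edges
#' into module m. 0 means all edges stay within one module; values near
#' `1 - 1/7` indicate a connector hub spreading evenly over the seven
#' networks. Disconnected nodes are assigned PC = 0.
#'
#' @param g A binary graph.
#' @param partition Node-to-module labels; defaults to the graph's own.
#' @param nodes Node indices (or names) to evaluate; default all.
#' @return Named numeric vector of PC values in `[0, 1)`.
#' @export
participation_coefficient <- function(g, partition = NULL, nodes = NULL) {
  p <- graph_partition(g, partition)
  A <- g$adjacency
  M <- vapply(levels(p), function(m) as.numeric(p == m), numeric(length(p)))
  kim <- A %*% M
  k <- rowSums(A)
  pc <- 1 - rowSums((kim / pmax(k, 1))^2)
  pc[k == 0] <- 0
  names(pc) <- rownames(A)
  if (!is.null(nodes)) pc <- pc[nodes]
  pc
}

#' Within-module degree z-score
#'
#' z-scores each node's within-module degree against all nodes of its own
#' module (population SD). A module whose nodes all share the same
#' within-degree yields z = 0; singleton modules are an error.
#'
#' @inheritParams participation_coefficient
#' @return Named numeric vector of WMD values.
#' @export
within_module_degree_z <- function(g, partition = NULL, nodes = NULL) {
  p <- graph_partition(g, partition)
  A <- g$adjacency
  z <- numeric(length(p))
  for (m in levels(p)) {
    idx <- which(p == m)
    if (length(idx) == 0L) next
    if (length(idx) == 1L) {
      stop("module ", m, " is a singleton; WMD undefined")
    }
    kappa <- rowSums(A[idx, idx, drop = FALSE])
    mu <- mean(kappa)
    sd_pop <- sqrt(mean((kappa - mu)^2))
    z[idx] <- if (sd_pop == 0) 0 else (kappa - mu) / sd_pop
  }
  names(z) <- rownames(A)
  if (!is.null(nodes)) z <- z[nodes]
  z
}

#' Thalamic hub metrics across the sparsity sweep
#'
#' Applies [two_step_threshold()] at each sparsity level and evaluates the
#' participation coefficient and within-module degree z-score of every
#' thalamic node, with trapezoidal AUC summaries.
#'
#' @param tc A [build_thalamocortical()] matrix.
#' @param levels Sparsity levels.
#' @param partition Node labels; defaults to the matrix's own.
#' @return Object of class `hub_metrics`: `pc` and `wmd` (node-by-level
#'   matrices), `pc_auc` and `wmd_auc` (named vectors), `levels`, `nodes`.
#' @export
hub_metrics <- function(tc, levels = sparsity_levels(), partition = NULL) {
  p <- as_partition(partition %||% attr(tc, "partition"), nrow(tc))
  n_cort <- attr(tc, "n_cortical") %||% stop("matrix lacks n_cortical attribute")
  thal_nodes <- (n_cort + 1L):nrow(tc)
  node_names <- rownames(tc)[thal_nodes] %||% paste0("tha_", as.character(p[thal_nodes]))

  pc <- wmd <- matrix(NA_real_, length(thal_nodes), length(levels),
                      dimnames = list(node_names, NULL))
  for (li in seq_along(levels)) {
    g <- two_step_threshold(tc, levels[li])
    pc[, li] <- participation_coefficient(g, p)[thal_nodes]
    wmd[, li] <- within_module_degree_z(g, p)[thal_nodes]
  }
  structure(list(pc = pc, wmd = wmd,
                 pc_auc = apply(pc, 1L, auc, levels = levels),
                 wmd_auc = apply(wmd, 1L, auc, levels = levels),
                 levels = levels, nodes = node_names),
            class = "hub_metrics")
}

#' @export
print.hub_metrics <- function(x, ...) {
  cat("thalamic hub metrics (AUC over sparsity):\n")
  print(round(rbind(pc_auc = x$pc_auc, wmd_auc = x$wmd_auc), 4L))
  invisible(x)
}

#' ROI-wise thalamus-to-network functional connectivity
#'
#' Mean (Fisher-z averaged) correlation between a thalamic subdivision's
#' time course and every cortical parcel of its corresponding network.
#'
#' @param cortical_ts Cortical [parcel_ts()].
#' @param subdivision_ts Time-by-7 subdivision matrix.
#' @param partition Parcel-to-network assignment.
#' @param networks Networks to evaluate (default all seven).
#' @return Named numeric vector, one value per requested network (NA for
#'   missing subdivisions).
#' @export
roi_network_fc <- function(cortical_ts, subdivision_ts, partition,
                           networks = networks7()) {
  p <- as_partition(partition, ncol(cortical_ts))
  cort <- if (inherits(cortical_ts, "parcel_ts")) as_ts_matrix(cortical_ts) else as.matrix(cortical_ts)
  sub <- as.matrix(subdivision_ts)
  out <- setNames(rep(NA_real_, length(networks)), networks)
  for (n in networks) {
    j <- match(n, networks7())
    if (anyNA(sub[, j])) next
    rs <- cor(sub[, j], cort[, p == n, drop = FALSE])[1L, ]
    out[n] <- inverse_fisher_z(mean(fisher_z(rs)))
  }
  out
}
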