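graph_partition <- function(g, partition = NULL) {
  p <- partition %||% g$partition
  if (is.null(p)) stop("no node partition available")
  as_partition(p, nrow(g$adjacency))
}

#' Modularity Q of a binary graph under a fixed partition
#'
#' Newman's degree-corrected modularity evaluated on the a-priori
#' seven-network partition (no community detection):
#' `Q = (1/2E) * sum_ij (A_ij - k_i k_j / 2E) * delta(c_i, c_j)`.
#'
#' @param g A [proportional_threshold()] graph with at least one edge.
#' @param partition Node-to-module labels; defaults to the graph's own.
#' @return Q, in `[-1, 1]`.
#' @export
modularity_q <- function(g, partition = NULL) {
  p <- graph_partition(g, partition)
  A <- g$adjacency
  two_e <- sum(A)
  if (two_e == 0) stop("modularity is undefined on an edgeless graph")
  k <- rowSums(A)
  q <- 0
  for (m in levels(p)) {
    idx <- which(p == m)
    if (length(idx) == 0L) next
    q <- q + sum(A[idx, idx]) / two_e - (sum(k[idx]) / two_e)^2
  }
  q
}

#' Data-driven modularity cross-check
#'
#' Louvain community detection on the binary graph via igraph, returning
#' the detected-partition modularity. This is a sensitivity check on the
#' fixed-partition [modularity_q()], not the primary metric.
#'
#' @param g A binary graph.
#' @return List with `q` (modularity of the detected partition) and
#'   `membership`.
#' @export
modularity_q_detected <- function(g) {
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  comm <- igraph::cluster_louvain(ig)
  list(q = igraph::modularity(comm), membership = igraph::membership(comm))
}

#' Modular segregation index
#'
#' Per-module contrast of within- versus between-module connectivity on the
#' (unthresholded) weighted correlation matrix:
#' `MSI(m) = (Wbar - Bbar) / Wbar` where `Wbar` is the mean correlation
#' over node pairs within module m and `Bbar` the mean over pairs linking m
#' to any other module. Negative correlations are treated as zero.
#'
#' @param conn A [conn_matrix()].
#' @param partition Node-to-module labels; defaults to the matrix's own.
#' @param module Module label (one of `networks7()`), at least 2 nodes.
#' @return MSI value (1 = perfectly segregated, 0 = no segregation).
#' @export
modular_segregation_index <- function(conn, partition = NULL, module) {
  p <- as_partition(partition %||% attr(conn, "partition"), nrow(conn))
  if (!module %in% levels(p)) stop("unknown module: ", module)
  idx <- which(p == module)
  if (length(idx) < 2L) stop("module ", module, " has fewer than 2 nodes")
  w <- pmax(unclass(conn), 0)
  within <- w[idx, idx][upper.tri(diag(length(idx)))]
  between <- w[idx, -idx, drop = FALSE]
  w_bar <- mean(within)
  if (w_bar == 0) stop("MSI undefined: no positive within-module connectivity in ",
                       module)
  (w_bar - mean(between)) / w_bar
}

#' Count intramodular edges
#'
#' @param g A binary graph.
#' @param partition Node-to-module labels; defaults to the graph's own.
#' @param module Module label.
#' @return Number of edges with both endpoints inside `module`.
#' @export
intra_connections <- function(g, partition = NULL, module) {
  p <- graph_partition(g, partition)
  idx <- which(p == module)
  sum(g$adjacency[idx, idx]) / 2
}

#' Count intermodular edges between two modules
#'
#' @param g A binary graph.
#' @param partition Node-to-module labels; defaults to the graph's own.
#' @param m1,m2 Two distinct module labels.
#' @return Number of edges with one endpoint in each module.
#' @export
inter_connections <- function(g, partition = NULL, m1, m2) {
  if (identical(m1, m2)) {
    stop("m1 and m2 are the same module; use intra_connections()")
  }
  p <- graph_partition(g, partition)
  sum(g$adjacency[which(p == m1), which(p == m2), drop = FALSE])
}

#' Full modular report for one connectivity matrix
#'
#' Sweeps the sparsity levels and evaluates, per level, modularity Q and
#' the intra-/intermodular edge counts; the modular segregation index is
#' computed once on the unthresholded positive-weight matrix (and
#' replicated across levels so it, too, carries an AUC on the common axis).
#'
#' @param conn A [conn_matrix()].
#' @param levels Sparsity levels.
#' @param partition Node-to-module labels; defaults to the matrix's own.
#' @return Object of class `modular_report`: `q_curve` ([metric_curve()]),
#'   `msi` (named per-module values), `msi_curves`, `intra_curves` (7),
#'   `inter_curves` (21, named `"m1-m2"`), and `levels`.
#' @export
modular_report <- function(conn, levels = sparsity_levels(), partition = NULL) {
  p <- as_partition(partition %||% attr(conn, "partition"), nrow(conn))
  graphs <- threshold_sweep(conn_matrix(unclass(conn), p), levels)
  nets <- networks7()
  pairs <- module_pairs()

  q_vals <- vapply(graphs, modularity_q, numeric(1L), partition = p)
  intra <- vapply(graphs, function(g) {
    vapply(nets, function(m) intra_connections(g, p, m), numeric(1L))
  }, numeric(length(nets)))
  inter <- vapply(graphs, function(g) {
    vapply(seq_len(nrow(pairs)), function(k) {
      inter_connections(g, p, pairs$m1[k], pairs$m2[k])
    }, numeric(1L))
  }, numeric(nrow(pairs)))
  rownames(inter) <- paste(pairs$m1, pairs$m2, sep = "-")

  msi <- vapply(nets, function(m) {
    modular_segregation_index(conn, p, m)
  }, numeric(1L))

  structure(list(
    levels = levels,
    q_curve = metric_curve(q_vals, levels),
    msi = msi,
    msi_curves = lapply(setNames(nets, nets), function(m) {
      metric_curve(rep(msi[[m]], length(levels)), levels)
    }),
    intra_curves = lapply(setNames(nets, nets), function(m) {
      metric_curve(intra[m, ], levels)
    }),
    inter_curves = lapply(setNames(rownames(inter), rownames(inter)),
                          function(pp) metric_curve(inter[pp, ], levels)),
    n_edges = vapply(graphs, `[[`, numeric(1L), "n_edges")),
    class = "modular_report")
}

#' @export
print.modular_report <- function(x, ...) {
  cat(sprintf("modular report: Q AUC = %.4g; MSI range [%.3g, %.3g]\n",
              x$q_curve$auc, min(x$msi), max(x$msi)))
  invisible(x)
}
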