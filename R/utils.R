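# Shared internal helpers.

# Nearest-integer rounding, halves away from zero. R's round() rounds halves
# to even, which would change edge counts at exact .5 boundaries (e.g.
# round(0.1 * 21) for the 7x7 thalamic block).
round_half_up <- function(x) {
  floor(x + 0.5)
}

clamp <- function(x, lo, hi) {
  pmin(pmax(x, lo), hi)
}

`%||%` <- function(a, b) {
  if (is.null(a)) b else a
}

# All unordered module pairs in canonical order.
module_pairs <- function(nets = networks7()) {
  idx <- combn(seq_along(nets), 2L)
  data.frame(m1 = nets[idx[1L, ]], m2 = nets[idx[2L, ]],
             stringsAsFactors = FALSE)
}

# Validate a node partition against the fixed 7-network label set.
as_partition <- function(partition, n = NULL) {
  p <- as.character(partition)
  bad <- setdiff(unique(p), networks7())
  if (length(bad) > 0L) {
    stop("unknown module labels: ", paste(bad, collapse = ", "))
  }
  if (!is.null(n) && length(p) != n) {
    stop("partition has ", length(p), " labels but ", n, " nodes")
  }
  factor(p, levels = networks7())
}

#' Assign 200 cortical parcels to the seven networks
#'
#' Returns the fixed parcel-to-network partition used throughout the
#' package. For the default 200 parcels the per-network sizes (31, 37, 23,
#' 22, 13, 26, 48 for VIS, SMN, DAN, VAN, LIM, FPN, DMN) follow the familiar
#' distribution of a 200-parcel cortical atlas labelled with the
#' seven-network scheme; other parcel counts are split proportionally.
#'
#' @param n_parcels Number of cortical parcels (default 200).
#' @return Named factor of length `n_parcels`; levels are `networks7()`,
#'   names are parcel identifiers such as `"SMN_04"`.
#' @export
#' @examples
#' table(yeo7_partition())
yeo7_partition <- function(n_parcels = 200L) {
  stopifnot(n_parcels >= 7L)
  base <- c(VIS = 31L, SMN = 37L, DAN = 23L, VAN = 22L,
            LIM = 13L, FPN = 26L, DMN = 48L)
  if (n_parcels == 200L) {
    sizes <- base
  } else {
    raw <- base / 200 * n_parcels
    sizes <- floor(raw)
    rem <- n_parcels - sum(sizes)
    if (rem > 0L) {
      extra <- order(raw - sizes, decreasing = TRUE)[seq_len(rem)]
      sizes[extra] <- sizes[extra] + 1L
    }
    sizes <- pmax(sizes, 1L)
    # fix any overshoot from the floor of 1
    while (sum(sizes) > n_parcels) {
      i <- which.max(sizes)
      sizes[i] <- sizes[i] - 1L
    }
  }
  labels <- rep(names(sizes), times = sizes)
  ids <- unlist(lapply(sizes, seq_len), use.names = FALSE)
  out <- factor(labels, levels = networks7())
  names(out) <- sprintf("%s_%02d", labels, ids)
  out
}
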