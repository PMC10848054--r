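small_tc <- function(seed = 31L, n_timepoints = 150L) {
  spec <- tiny_spec(n_hc = 2L, n_ci = 0L, n_timepoints = n_timepoints,
                    seed = seed)
  cohort <- generate_cohort(spec)
  s <- cohort$subjects[[1L]]
  sub <- subdivision_timeseries(s$thalamic_ts, cohort$true_voxel_labels)
  list(cohort = cohort, subject = s,
       tc = build_thalamocortical(s$cortical_ts, sub, cohort$partition),
       sub = sub)
}

test_that("the thalamocortical matrix appends the 7 subdivisions to the cortex", {
  spec <- cohort_spec(n_per_group = c(HC = 1L, `TLE-CN` = 0L, `TLE-CI` = 0L),
                      n_timepoints = 120L, seed = 8L)
  cohort <- generate_cohort(spec)
  s <- cohort$subjects[[1L]]
  sub <- subdivision_timeseries(s$thalamic_ts, cohort$true_voxel_labels)
  tc <- build_thalamocortical(s$cortical_ts, sub, cohort$partition)
  expect_identical(dim(unclass(tc)), c(207L, 207L))
  expect_identical(attr(tc, "n_cortical"), 200L)
  expect_identical(as.character(attr(tc, "partition")[201:207]), networks7())
  # block consistency: cortical block equals the plain cortical FC
  fc <- pearson_fc(s$cortical_ts)
  expect_equal(unclass(tc)[1:200, 1:200], unclass(fc), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("building is equivariant to permuting the cortical input order", {
  fix <- small_tc()
  x <- as.matrix(fix$subject$cortical_ts)
  p <- as.character(fix$cohort$partition)
  perm <- sample(ncol(x))
  tc2 <- build_thalamocortical(parcel_ts(x[, perm]), fix$sub, p[perm])
  n <- ncol(x)
  expect_equal(unclass(tc2)[seq_len(n), seq_len(n)],
               unclass(fix$tc)[perm, perm], tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unclass(tc2)[seq_len(n), n + 3L],
               unclass(fix$tc)[perm, n + 3L], tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("missing subdivisions shrink the matrix and are recorded", {
  fix <- small_tc()
  sub <- fix$sub
  sub[, "tha_LIM"] <- NA_real_
  tc <- build_thalamocortical(fix$subject$cortical_ts, sub,
                              fix$cohort$partition)
  expect_identical(nrow(tc), ncol(fix$subject$cortical_ts) + 6L)
  expect_identical(attr(tc, "dropped_subdivisions"), "LIM")
})

test_that("two-step thresholding assigns each block its own edge budget", {
  tc <- adversarial_tc()
  g <- two_step_threshold(tc, 0.1)
  expect_equal(unname(g$block_edges),
               c(floor(0.1 * 19900 + 0.5), floor(0.1 * 21 + 0.5),
                 floor(0.1 * 1400 + 0.5)))
  expect_equal(unname(g$block_edges), c(1990, 2, 140))
  expect_identical(g$adjacency, t(g$adjacency))
  expect_identical(diag(g$adjacency), rep(0L, 207L))

  full <- two_step_threshold(tc, 1.0)
  expect_identical(full$n_edges, 207 * 206 / 2)  # all-positive matrix
})

test_that("two-step thresholding preserves bipartite edges that single-step drops", {
  tc <- adversarial_tc()
  bip_idx <- cbind(rep(201:207, each = 200L), rep(1:200, times = 7L))
  two <- two_step_threshold(tc, 0.1)
  one <- two_step_threshold(tc, 0.1, single_step = TRUE)
  expect_identical(sum(two$adjacency[bip_idx]), 140L)
  expect_identical(sum(one$adjacency[bip_idx]), 0L)
})

test_that("participation coefficient matches its closed forms", {
  # all edges within the own module -> 0
  adj <- matrix(0L, 5L, 5L)
  adj[1, 2:3] <- 1L; adj <- adj + t(adj)
  adj[4, 5] <- adj[5, 4] <- 1L
  p <- c("VIS", "VIS", "VIS", "SMN", "SMN")
  expect_equal(participation_coefficient(graph_from_adj(adj, p))[[1L]], 0)

  # degree 4 split evenly over 2 modules -> 0.5
  adj2 <- matrix(0L, 6L, 6L)
  adj2[1, c(2, 3, 4, 5)] <- 1L; adj2 <- adj2 + t(adj2)
  p2 <- c("VIS", "VIS", "VIS", "SMN", "SMN", "SMN")
  expect_equal(participation_coefficient(graph_from_adj(adj2, p2))[[1L]], 0.5)

  # degree 7, one edge per module over 7 modules -> 6/7
  adj3 <- matrix(0L, 8L, 8L)
  adj3[1, 2:8] <- 1L; adj3 <- adj3 + t(adj3)
  p3 <- c("VIS", networks7())
  expect_equal(participation_coefficient(graph_from_adj(adj3, p3))[[1L]],
               6 / 7, tolerance = 1e-12)

  # isolated node -> 0 by convention
  adj4 <- matrix(0L, 4L, 4L); adj4[2, 3] <- adj4[3, 2] <- 1L
  expect_equal(participation_coefficient(
    graph_from_adj(adj4, c("VIS", "VIS", "SMN", "SMN")))[[1L]], 0)
})

test_that("within-module degree z-score matches the hand-computed case", {
  # module VIS: within-degrees (2, 1, 1) -> z_1 = (2 - 4/3) / sqrt(2/9)
  adj <- matrix(0L, 5L, 5L)
  adj[1, 2] <- adj[2, 1] <- 1L
  adj[1, 3] <- adj[3, 1] <- 1L
  adj[4, 5] <- adj[5, 4] <- 1L
  p <- c("VIS", "VIS", "VIS", "SMN", "SMN")
  z <- within_module_degree_z(graph_from_adj(adj, p))
  expect_equal(z[[1L]], (2 - 4 / 3) / sqrt(2 / 9), tolerance = 1e-12)
  expect_equal(z[[1L]], sqrt(2), tolerance = 1e-4)
  # z-scores sum to zero within each module when sd > 0
  expect_equal(sum(z[1:3]), 0, tolerance = 1e-12)
  # equal within-degrees -> all zero
  expect_equal(unname(z[4:5]), c(0, 0))
  # singleton module errors
  expect_error(within_module_degree_z(
    graph_from_adj(adj[1:4, 1:4], c("VIS", "VIS", "VIS", "SMN"))),
    "singleton")
})

test_that("PC and WMD match exhaustive oracles on random graphs", {
  set.seed(33)
  for (rep_i in 1:60) {
    n <- sample(6:12, 1L)
    adj <- rand_adj(n)
    labels <- rand_partition(n, sample(2:3, 1L))
    g <- graph_from_adj(adj, labels)
    pc <- participation_coefficient(g)
    wmd <- within_module_degree_z(g)
    for (i in seq_len(n)) {
      expect_equal(pc[[i]], oracle_pc(adj, labels, i), tolerance = 1e-12)
      expect_equal(wmd[[i]], oracle_wmd(adj, labels, i), tolerance = 1e-12)
    }
    expect_true(all(pc < 1))
    expect_true(all(pc >= 0))
  }
})

test_that("hub metric curves cover every level and thalamic node", {
  fix <- small_tc()
  hm <- hub_metrics(fix$tc)
  expect_identical(dim(hm$pc), c(7L, 10L))
  expect_identical(dim(hm$wmd), c(7L, 10L))
  expect_identical(hm$nodes, paste0("tha_", networks7()))
  expect_true(all(hm$pc >= 0 & hm$pc < 1))
  expect_equal(hm$pc_auc[["tha_VIS"]], auc(hm$pc["tha_VIS", ]),
               tolerance = 1e-12)
})

test_that("ROI-network FC is near 1 for identical signals and near 0 under the null", {
  set.seed(34)
  n_t <- 300L
  p <- yeo7_partition(28L)
  cort <- matrix(rnorm(n_t * 28L), n_t)
  # SMN subdivision identical to every SMN parcel
  smn_sig <- rnorm(n_t)
  cort[, p == "SMN"] <- smn_sig
  sub <- matrix(rnorm(n_t * 7L), n_t,
                dimnames = list(NULL, paste0("tha_", networks7())))
  sub[, "tha_SMN"] <- smn_sig
  vals <- roi_network_fc(parcel_ts(cort), sub, p)
  expect_true(is.finite(vals[["SMN"]]))  # clipped z handling keeps it finite
  expect_equal(vals[["SMN"]], 1, tolerance = 1e-5)
  expect_lt(abs(vals[["DAN"]]), 0.15)  # independent white noise
  expect_identical(names(vals), networks7())
})

test_that("stronger thalamic coupling raises the ROI-network FC in expectation", {
  fc_at <- function(cc) {
    thal <- uniform_within(0.2)
    thal[, "SMN"] <- cc
    spec <- tiny_spec(n_hc = 3L, n_ci = 0L, n_timepoints = 200L, seed = 35L,
                      thal_coupling = thal,
                      thal_diffuse = uniform_within(0),
                      subject_sd = 0)
    cohort <- generate_cohort(spec)
    mean(vapply(cohort$subjects, function(s) {
      sub <- subdivision_timeseries(s$thalamic_ts, cohort$true_voxel_labels)
      roi_network_fc(s$cortical_ts, sub, cohort$partition)[["SMN"]]
    }, numeric(1L)))
  }
  expect_gt(fc_at(0.7), fc_at(0.2))
})
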