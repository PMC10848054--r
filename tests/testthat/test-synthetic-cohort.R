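test_that("same spec and seed give byte-identical cohorts", {
  spec <- tiny_spec()
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$subjects[[1]]$cortical_ts, b$subjects[[1]]$cortical_ts)
  expect_identical(a$subjects[[3]]$thalamic_ts, b$subjects[[3]]$thalamic_ts)
  expect_identical(a$mask_prob, b$mask_prob)
})

test_that("zero coupling yields a null correlation structure", {
  spec <- tiny_spec(n_hc = 1L, n_ci = 0L, n_timepoints = 200L,
                    within_coupling = uniform_within(0),
                    between_coupling = uniform_between(0),
                    parcel_coupling_spread = 0)
  cohort <- generate_cohort(spec)
  r <- cor(as.matrix(cohort$subjects[[1]]$cortical_ts))
  off <- abs(r[upper.tri(r)])
  expect_lt(mean(off), 3 / sqrt(200))
})

test_that("planted within-module correlation matches its target (Monte Carlo)", {
  # oracle: under x_i = sqrt(a) L + sqrt(1-a) e, corr(x_i, x_j) = a
  spec <- tiny_spec(n_hc = 1L, n_ci = 0L, n_timepoints = 500L,
                    n_parcels = 35L,
                    within_coupling = uniform_within(0.6),
                    between_coupling = uniform_between(0.1),
                    parcel_coupling_spread = 0, seed = 11L)
  cohort <- generate_cohort(spec)
  x <- as.matrix(cohort$subjects[[1]]$cortical_ts)
  dmn <- which(cohort$partition == "DMN")
  r <- cor(x[, dmn])
  expect_gt(mean(r[upper.tri(r)]), 0.55)
  expect_lt(mean(r[upper.tri(r)]), 0.65)
})

test_that("vanishing noise makes same-module parcels perfectly correlated", {
  spec <- tiny_spec(n_hc = 1L, n_ci = 0L,
                    within_coupling = uniform_within(0.999),
                    between_coupling = uniform_between(0.1),
                    parcel_coupling_spread = 0)
  cohort <- generate_cohort(spec)
  x <- as.matrix(cohort$subjects[[1]]$cortical_ts)
  vis <- which(cohort$partition == "VIS")
  r <- cor(x[, vis])
  expect_true(all(r[upper.tri(r)] > 0.99))
})

test_that("group-mean FC block structure recovers the planted partition", {
  for (sd_i in 1:3) {
    spec <- tiny_spec(n_hc = 6L, n_ci = 0L, n_timepoints = 300L,
                      n_parcels = 35L, seed = sd_i,
                      within_coupling = uniform_within(0.6),
                      between_coupling = uniform_between(0.2))
    cohort <- generate_cohort(spec)
    zbar <- Reduce(`+`, lapply(cohort$subjects, function(s) {
      r <- unclass(pearson_fc(s$cortical_ts))
      diag(r) <- 0
      fisher_z(r)
    })) / length(cohort$subjects)
    fc <- inverse_fisher_z(zbar)
    p <- cohort$partition
    for (m1 in networks7()) {
      idx1 <- which(p == m1)
      w <- fc[idx1, idx1][upper.tri(diag(length(idx1)))]
      for (m2 in setdiff(networks7(), m1)) {
        b <- fc[idx1, which(p == m2)]
        expect_gt(mean(w), mean(b))
      }
    }
  }
})

test_that("MoCA scores respect group categories and track thalamo-SMN coupling", {
  spec <- tiny_spec(n_hc = 30L, n_cn = 30L, n_ci = 200L, n_timepoints = 60L,
                    n_parcels = 14L, seed = 3L)
  cohort <- generate_cohort(spec)
  ph <- cohort$phenotypes
  expect_true(all(ph$moca >= 0 & ph$moca <= 30))
  expect_true(all(ph$moca[ph$group == "TLE-CI"] < 26))
  expect_true(all(ph$moca[ph$group == "TLE-CN"] >= 26))
  # HC rows have missing clinical fields
  hc <- ph[ph$group == "HC", ]
  expect_true(all(is.na(hc$onset_age)) && all(is.na(hc$duration)) &&
                all(is.na(hc$aed)))
  # positive slope on coupling shows up as positive sample correlation
  ci <- ph[ph$group == "TLE-CI", ]
  expect_gt(cor(ci$tha_smn_coupling, ci$moca), 0)
})

test_that("invalid coupling ordering is rejected with the offending pair named", {
  bad_between <- uniform_between(0.5)  # not below within = 0.45
  expect_error(tiny_spec(between_coupling = bad_between),
               "between_coupling\\(VIS, SMN\\)")
  expect_error(tiny_spec(n_timepoints = 40L), "at least 60")
  expect_error(tiny_spec(within_coupling = uniform_within(1.2)),
               "\\[0, 1\\)")
})

test_that("the synthetic thalamus mask and labels are block-shaped and mirrored", {
  spec <- tiny_spec()
  cohort <- generate_cohort(spec)
  expect_true(all(cohort$mask_prob >= 0 & cohort$mask_prob <= 1))
  mask <- cohort$mask_prob > 0.10
  expect_identical(sum(mask), as.integer(2L * prod(spec$thal_grid)))
  # hemispheric mirror symmetry of the planted labels
  vol <- cohort$true_label_volume
  gx <- spec$thal_grid[1L]
  left <- vol[seq_len(gx), , , drop = FALSE]
  right <- vol[(dim(vol)[1L] - gx + 1L):dim(vol)[1L], , , drop = FALSE]
  expect_identical(left, right[rev(seq_len(gx)), , , drop = FALSE])
  # labels defined exactly for in-mask voxels
  expect_identical(length(cohort$true_voxel_labels), sum(mask))
  expect_false(anyNA(cohort$true_voxel_labels))
})

test_that("cohorts round-trip through disk with manifest provenance", {
  spec <- tiny_spec(n_hc = 2L, n_ci = 1L, n_timepoints = 60L,
                    n_parcels = 14L, seed = 99L)
  cohort <- generate_cohort(spec)
  out <- tempfile("cohort_")
  write_cohort(cohort, out)

  ph <- read.table(file.path(out, "participants.tsv"), header = TRUE,
                   sep = "\t")
  expect_identical(nrow(ph), 3L)

  manifest <- jsonlite::read_json(file.path(out, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_identical(manifest$seed, 99L)

  back <- read_cohort(out)
  expect_equal(as.matrix(back$subjects[[1]]$cortical_ts),
               as.matrix(cohort$subjects[[1]]$cortical_ts),
               ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(write_cohort(cohort, out), "overwrite")
  expect_silent(write_cohort(cohort, out, overwrite = TRUE))
  unlink(out, recursive = TRUE)
})

test_that("Friston-24 expansion has the standard layout", {
  m6 <- matrix(rnorm(60), 10L, 6L)
  f24 <- friston24(m6)
  expect_identical(dim(f24), c(10L, 24L))
  expect_equal(f24[, 1:6], m6, ignore_attr = TRUE)
  expect_equal(f24[2:10, 7:12], m6[1:9, ], ignore_attr = TRUE)
  expect_equal(f24[, 13:18], m6^2, ignore_attr = TRUE)
  expect_error(friston24(m6[, 1:5]), "6 motion")
})
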