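cohort_groups <- function() c("HC", "TLE-CN", "TLE-CI")

# Default coupling tables. Rows are groups, columns the seven networks.
# Patient groups combine lowered within-module coupling in VAN and DMN with
# raised between-module coupling on pairs involving those networks (the two
# routes to reduced modular segregation), plus an altered thalamic coupling
# profile: somatomotor raised and made diffuse in the cognitively impaired
# group, default-mode lowered in both patient groups. Values are target
# Pearson correlations (see generate_cohort).
default_within_coupling <- function() {
  m <- matrix(0.45, nrow = 3L, ncol = 7L,
              dimnames = list(cohort_groups(), networks7()))
  m[c("TLE-CN", "TLE-CI"), c("VAN", "DMN")] <- 0.25
  m
}

default_between_coupling <- function() {
  hc <- matrix(0.15, 7L, 7L, dimnames = list(networks7(), networks7()))
  diag(hc) <- 0
  tle <- hc
  tle[, c("VAN", "DMN")] <- 0.20
  tle[c("VAN", "DMN"), ] <- 0.20
  tle["DAN", "DMN"] <- tle["DMN", "DAN"] <- 0.22
  diag(tle) <- 0
  list(`HC` = hc, `TLE-CN` = tle, `TLE-CI` = tle)
}

default_thal_coupling <- function() {
  m <- matrix(0.25, nrow = 3L, ncol = 7L,
              dimnames = list(cohort_groups(), networks7()))
  m["TLE-CN", "SMN"] <- 0.45
  m["TLE-CI", "SMN"] <- 0.75
  m[c("TLE-CN", "TLE-CI"), "DMN"] <- 0.20
  m
}

default_thal_diffuse <- function() {
  m <- matrix(0.05, nrow = 3L, ncol = 7L,
              dimnames = list(cohort_groups(), networks7()))
  m["TLE-CI", "SMN"] <- 0.20
  m
}

# Relative voxel budget of the seven thalamic subdivisions per hemisphere;
# the default-mode subdivision is the largest.
thal_label_weights <- function() {
  c(VIS = 24, SMN = 36, DAN = 24, VAN = 24, LIM = 20, FPN = 28, DMN = 60)
}

#' Specify a synthetic resting-state cohort
#'
#' Bundles and validates every parameter of the synthetic cohort generator:
#' group sizes, scan length, the parcel-to-network partition, the planted
#' within/between-module coupling structure, thalamic voxel-to-network
#' coupling, and the model linking cognitive scores (MoCA) to the
#' subject-level thalamo-somatomotor coupling.
#'
#' Couplings are expressed as target Pearson correlations: a parcel in
#' module m is built as `sqrt(a) * latent_m + sqrt(1-a) * noise`, so two
#' parcels of module m correlate at `a = within_coupling[group, m]`, and the
#' latent signals are correlated such that parcels in different modules m1,
#' m2 correlate at `between_coupling[[group]][m1, m2]`.
#'
#' @param n_per_group Named integer vector of subjects per group
#'   (`HC`, `TLE-CN`, `TLE-CI`).
#' @param n_timepoints Number of volumes per subject (post-stabilization).
#' @param tr_seconds Repetition time in seconds.
#' @param n_parcels Number of cortical parcels.
#' @param partition Parcel-to-network assignment (see [yeo7_partition()]).
#' @param thal_grid Integer dimensions of one hemisphere's synthetic
#'   thalamic voxel block.
#' @param within_coupling Group-by-network matrix of within-module target
#'   correlations, each in `[0, 1)`.
#' @param between_coupling Per-group list of symmetric 7x7 matrices of
#'   between-module target correlations; every entry must be strictly below
#'   the smaller of the two within-module values (or zero).
#' @param thal_coupling Group-by-network matrix of thalamic voxel-to-network
#'   coupling values in `[0, 1)`.
#' @param thal_diffuse Group-by-network matrix in `[0, 1)`: fraction of a
#'   voxel's latent drive shared diffusely across the other six networks
#'   (0 = voxel follows its own network's latent exclusively).
#' @param thal_label_noise_share Fraction (in `[0, 1)`) of a thalamic
#'   voxel's noise that is shared with the other voxels of its label — the
#'   local subdivision signal beyond the network coupling. With 0, voxel
#'   noise is purely independent and averages out of subdivision means.
#' @param parcel_coupling_spread Relative half-width (in `[0, 1)`) of the
#'   per-parcel coupling heterogeneity: parcel i's coupling is
#'   `a * mult_i` with `mult_i` uniform on `1 +/- spread`, drawn once per
#'   cohort so parcels keep their profile across subjects. Real cortical
#'   parcels differ in how strongly they load on their network; with 0 all
#'   parcels of a module are exchangeable and within-module blocks saturate
#'   unrealistically early under proportional thresholding.
#' @param subject_sd Between-subject SD of the thalamo-somatomotor coupling.
#' @param moca_model List with per-group `intercept`, a common `slope` on
#'   the subject-level thalamo-SMN coupling, and `noise_sd`.
#' @param seed Integer seed; the whole cohort is a deterministic function
#'   of the spec including this seed.
#' @return A validated object of class `cohort_spec`.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_per_group = c(HC = 37L, `TLE-CN` = 35L, `TLE-CI` = 18L),
                        n_timepoints = 230L,
                        tr_seconds = 2,
                        n_parcels = 200L,
                        partition = yeo7_partition(n_parcels),
                        thal_grid = c(6L, 6L, 6L),
                        within_coupling = default_within_coupling(),
                        between_coupling = default_between_coupling(),
                        thal_coupling = default_thal_coupling(),
                        thal_diffuse = default_thal_diffuse(),
                        thal_label_noise_share = 0.5,
                        parcel_coupling_spread = 0.3,
                        subject_sd = 0.10,
                        moca_model = list(intercept = c(HC = 25.3, `TLE-CN` = 21.8,
                                                        `TLE-CI` = 12.6),
                                          slope = 14, noise_sd = 1.2),
                        seed = 20230709L) {
  spec <- structure(list(n_per_group = n_per_group,
                         n_timepoints = as.integer(n_timepoints),
                         tr_seconds = tr_seconds,
                         n_parcels = as.integer(n_parcels),
                         partition = as_partition(partition, n_parcels),
                         thal_grid = as.integer(thal_grid),
                         within_coupling = within_coupling,
                         between_coupling = between_coupling,
                         thal_coupling = thal_coupling,
                         thal_diffuse = thal_diffuse,
                         thal_label_noise_share = thal_label_noise_share,
                         parcel_coupling_spread = parcel_coupling_spread,
                         subject_sd = subject_sd,
                         moca_model = moca_model,
                         seed = as.integer(seed)),
                    class = "cohort_spec")
  validate_cohort_spec(spec)
}

#' @rdname cohort_spec
#' @param spec A `cohort_spec` object.
#' @export
validate_cohort_spec <- function(spec) {
  groups <- cohort_groups()
  if (!all(groups %in% names(spec$n_per_group))) {
    stop("n_per_group must name all of: ", paste(groups, collapse = ", "))
  }
  if (any(spec$n_per_group < 0L)) stop("group sizes must be non-negative")
  if (spec$n_timepoints < 60L) stop("n_timepoints must be at least 60")
  if (spec$tr_seconds <= 0) stop("tr_seconds must be positive")
  if (length(spec$thal_grid) != 3L || any(spec$thal_grid < 1L)) {
    stop("thal_grid must be three positive integers")
  }
  check01 <- function(x, what) {
    if (any(x < 0 | x >= 1)) stop(what, " values must lie in [0, 1)")
  }
  check01(spec$within_coupling, "within_coupling")
  check01(spec$thal_coupling, "thal_coupling")
  check01(spec$thal_diffuse, "thal_diffuse")
  check01(spec$thal_label_noise_share %||% 0, "thal_label_noise_share")
  check01(spec$parcel_coupling_spread %||% 0, "parcel_coupling_spread")
  nets <- networks7()
  for (g in groups) {
    a <- spec$within_coupling[g, nets]
    b <- spec$between_coupling[[g]][nets, nets]
    if (any(abs(b - t(b)) > 1e-12)) {
      stop("between_coupling for group ", g, " is not symmetric")
    }
    check01(b, "between_coupling")
    pairs <- module_pairs()
    for (k in seq_len(nrow(pairs))) {
      m1 <- pairs$m1[k]; m2 <- pairs$m2[k]
      bk <- b[m1, m2]
      if (bk > 0 && bk >= min(a[m1], a[m2])) {
        stop(sprintf(
          "between_coupling(%s, %s) = %.3g for group %s is not below min(within) = %.3g",
          m1, m2, bk, g, min(a[m1], a[m2])))
      }
    }
  }
  mm <- spec$moca_model
  if (!all(groups %in% names(mm$intercept))) {
    stop("moca_model$intercept must be named for every group")
  }
  if (mm$noise_sd < 0) stop("moca_model$noise_sd must be non-negative")
  invisible(spec)
}

# 7x7 latent correlation matrix for a group: latents are correlated at
# b / sqrt(a1 * a2) so the PARCEL-level between-module correlation equals b.
latent_correlation <- function(a, b) {
  nets <- networks7()
  R <- diag(7L)
  dimnames(R) <- list(nets, nets)
  for (i in 1:6) {
    for (j in (i + 1):7) {
      denom <- sqrt(a[nets[i]] * a[nets[j]])
      rho <- if (denom > 0) b[nets[i], nets[j]] / denom else 0
      R[i, j] <- R[j, i] <- rho
    }
  }
  R
}

# Background volume layout: two hemisphere blocks separated by a gap of 2
# voxels along the first axis.
thal_volume_dims <- function(grid, gap = 2L) {
  c(2L * grid[1L] + gap, grid[2L], grid[3L])
}

# Probabilistic mask + mirrored ground-truth labels for the synthetic
# thalamus. Labels are integers 1..7 (networks7 order), 0 = background.
make_thalamus_volumes <- function(grid, gap = 2L) {
  dims <- thal_volume_dims(grid, gap)
  prob <- array(runif(prod(dims), 0, 0.05), dim = dims)
  gx <- grid[1L]
  left_x <- seq_len(gx)
  right_x <- (gx + gap + 1L):(2L * gx + gap)
  prob[left_x, , ] <- runif(prod(grid), 0.55, 0.95)
  prob[right_x, , ] <- runif(prod(grid), 0.55, 0.95)

  labels <- array(0L, dim = dims)
  w <- thal_label_weights()
  n_block <- prod(grid)
  counts <- floor(w / sum(w) * n_block)
  rem <- n_block - sum(counts)
  if (rem > 0L) {
    frac <- w / sum(w) * n_block - counts
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[add] <- counts[add] + 1L
  }
  block_labels <- rep(seq_len(7L), times = counts)
  # column-major fill of the left block; mirrored copy on the right
  left <- array(block_labels, dim = grid)
  labels[left_x, , ] <- left
  labels[right_x, , ] <- left[rev(seq_len(gx)), , ]
  list(prob = prob, labels = labels)
}

generate_subject_record <- function(group, subject_id, c_smn_subj, moca_model) {
  age_par <- switch(group,
                    `HC` = c(29.57, 7.75),
                    `TLE-CN` = c(29.49, 7.92),
                    `TLE-CI` = c(33.39, 9.47))
  age <- round(clamp(rnorm(1L, age_par[1L], age_par[2L]), 18, 60), 1L)
  p_male <- switch(group, `HC` = 16 / 37, `TLE-CN` = 8 / 35, `TLE-CI` = 6 / 18)
  sex <- if (runif(1L) < p_male) "M" else "F"
  edu_levels <- c(9L, 12L, 15L, 16L)
  edu_prob <- if (group == "TLE-CI") c(0.15, 0.45, 0.30, 0.10) else c(0.10, 0.30, 0.45, 0.15)
  education <- sample(edu_levels, 1L, prob = edu_prob)

  if (group == "HC") {
    onset <- duration <- seizure_freq <- NA_real_
    aed <- NA_character_
  } else {
    onset_par <- if (group == "TLE-CI") c(25.61, 10.32) else c(19.03, 9.40)
    onset <- round(clamp(rnorm(1L, onset_par[1L], onset_par[2L]), 1, age - 0.5), 1L)
    dur_med <- if (group == "TLE-CI") 6 else 10.5
    duration <- round(clamp(rlnorm(1L, log(dur_med), 0.6), 0.5, age - 1), 1L)
    freq_med <- if (group == "TLE-CI") 0.5 else 1
    seizure_freq <- round(rlnorm(1L, log(freq_med + 0.25), 0.9), 2L)
    p_mono <- if (group == "TLE-CI") 10 / 18 else 16 / 35
    aed <- if (runif(1L) < p_mono) "mono" else "poly"
  }

  moca_raw <- moca_model$intercept[[group]] +
    moca_model$slope * c_smn_subj +
    rnorm(1L, 0, moca_model$noise_sd)
  moca <- as.integer(round(clamp(moca_raw, 0, 30)))
  if (group == "TLE-CI") moca <- min(moca, 25L)
  if (group == "TLE-CN") moca <- max(moca, 26L)

  data.frame(subject_id = subject_id, group = group, age = age, sex = sex,
             education = education, onset_age = onset, duration = duration,
             seizure_freq = seizure_freq, aed = aed, moca = moca,
             tha_smn_coupling = c_smn_subj,
             stringsAsFactors = FALSE)
}

# Smoothed random-walk motion parameters, their Friston-24 expansion, and
# Power-style framewise displacement (50 mm head-radius rotation scaling).
generate_motion <- function(n_t) {
  steps <- cbind(matrix(rnorm(n_t * 3L, 0, 0.015), n_t, 3L),
                 matrix(rnorm(n_t * 3L, 0, 0.0003), n_t, 3L))
  motion6 <- apply(steps, 2L, cumsum)
  fd <- c(0, rowSums(abs(diff(motion6[, 1:3, drop = FALSE]))) +
            50 * rowSums(abs(diff(motion6[, 4:6, drop = FALSE]))))
  list(motion6 = motion6, fd = fd)
}

#' Expand six motion parameters to the Friston-24 set
#'
#' The 24-parameter head-motion model: the six realignment parameters, their
#' one-volume lags, and the squares of both.
#'
#' @param motion6 Time-by-6 numeric matrix of motion parameters.
#' @return Time-by-24 matrix.
#' @export
friston24 <- function(motion6) {
  motion6 <- as.matrix(motion6)
  if (ncol(motion6) != 6L) stop("expected 6 motion parameter columns")
  lagged <- rbind(0, motion6[-nrow(motion6), , drop = FALSE])
  out <- cbind(motion6, lagged, motion6^2, lagged^2)
  colnames(out) <- c(paste0("mot", 1:6), paste0("mot", 1:6, "_lag"),
                     paste0("mot", 1:6, "_sq"), paste0("mot", 1:6, "_lagsq"))
  out
}

#' Generate a synthetic cohort with planted modular structure
#'
#' Draws per-subject cortical parcel and thalamic voxel time series from the
#' latent-network mixing model described in [cohort_spec()], together with
#' nuisance regressors, framewise-displacement series, a probabilistic
#' thalamus mask volume, mirrored ground-truth voxel labels, and a phenotype
#' table. Each subject's seed derives from the spec seed, so the whole
#' cohort is reproducible and subjects are mutually independent.
#'
#' Per subject, seven latent network signals are drawn with the latent
#' correlation structure implied by `between_coupling`; a parcel of module m
#' is `sqrt(a) * latent_m + sqrt(1-a) * noise` with
#' `a = within_coupling[group, m]`, and a thalamic voxel assigned to network
#' n is `sqrt(c) * mix_n + sqrt(1-c) * noise` where `mix_n` is the (unit
#' variance) blend of the own-network latent with the other six controlled
#' by `thal_diffuse`. MoCA scores follow `moca_model` on the subject-level
#' thalamo-SMN coupling, clamped to `[0, 30]` and to the group's cognitive
#' category (impaired < 26).
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `synthetic_cohort`: list with `subjects` (each a
#'   list holding `record`, `cortical_ts`, `thalamic_ts`, `nuisance`, `fd`,
#'   `true_voxel_labels`, `latents`), `phenotypes` (one data frame),
#'   `mask_prob` and `true_label_volume` (3-D arrays), `voxel_coords`,
#'   `partition`, and the `spec`.
#' @export
#' @examples
#' spec <- cohort_spec(n_per_group = c(HC = 2, `TLE-CN` = 2, `TLE-CI` = 2),
#'                     n_timepoints = 80, n_parcels = 35)
#' cohort <- generate_cohort(spec)
#' length(cohort$subjects)
generate_cohort <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  vols <- make_thalamus_volumes(spec$thal_grid)
  mask <- vols$prob > 0.10
  voxel_idx <- which(mask)
  voxel_coords <- arrayInd(voxel_idx, dim(mask))
  true_labels <- factor(networks7()[vols$labels[voxel_idx]], levels = networks7())
  n_vox <- length(voxel_idx)

  # per-parcel coupling multipliers: a fixed cohort-level property, like the
  # heterogeneous network loading of real cortical parcels
  spread <- spec$parcel_coupling_spread %||% 0
  parcel_mult <- runif(spec$n_parcels, 1 - spread, 1 + spread)

  groups <- rep(cohort_groups(), times = spec$n_per_group[cohort_groups()])
  n_total <- length(groups)
  subject_seeds <- sample.int(.Machine$integer.max, n_total)
  nets <- networks7()
  module_idx <- as.integer(spec$partition)
  n_t <- spec$n_timepoints
  label_idx <- as.integer(true_labels)

  subjects <- vector("list", n_total)
  for (s in seq_len(n_total)) {
    g <- groups[s]
    set.seed(subject_seeds[s])
    a <- spec$within_coupling[g, nets]
    R7 <- latent_correlation(a, spec$between_coupling[[g]])
    U <- tryCatch(chol(R7), error = function(e) {
      stop("between_coupling structure for group ", g,
           " does not define a positive-definite latent correlation matrix")
    })
    L <- matrix(rnorm(n_t * 7L), n_t, 7L) %*% U
    colnames(L) <- nets

    a_parcel <- pmin(a[module_idx] * parcel_mult, 0.999)
    X <- sweep(L[, module_idx, drop = FALSE], 2L, sqrt(a_parcel), `*`) +
      sweep(matrix(rnorm(n_t * spec$n_parcels), n_t), 2L,
            sqrt(1 - a_parcel), `*`)
    colnames(X) <- names(spec$partition)

    # subject-level thalamo-SMN coupling (one latent scalar u drives both
    # the coupling strength and its diffuseness, and the MoCA model)
    u <- rnorm(1L)
    c_vec <- spec$thal_coupling[g, nets]
    d_vec <- spec$thal_diffuse[g, nets]
    c_vec["SMN"] <- clamp(c_vec["SMN"] + spec$subject_sd * u, 0.01, 0.95)
    d_vec["SMN"] <- clamp(d_vec["SMN"] + 0.8 * spec$subject_sd * u, 0, 0.90)

    # per-network unit-variance latent blends
    Wmix <- matrix(0, 7L, 7L, dimnames = list(nets, nets))
    for (n in seq_len(7L)) {
      w <- rep(sqrt(d_vec[n] / 6), 7L)
      w[n] <- sqrt(1 - d_vec[n])
      w <- w / sqrt(drop(crossprod(w, R7 %*% w)))
      Wmix[, n] <- w
    }
    LN <- L %*% Wmix

    # voxel noise: a per-label shared component (local subdivision signal)
    # plus an independent component
    h <- spec$thal_label_noise_share %||% 0
    eta <- matrix(rnorm(n_t * 7L), n_t, 7L)
    noise <- sqrt(h) * eta[, label_idx, drop = FALSE] +
      sqrt(1 - h) * matrix(rnorm(n_t * n_vox), n_t)
    thal <- sweep(LN[, label_idx, drop = FALSE], 2L, sqrt(c_vec[label_idx]), `*`) +
      sweep(noise, 2L, sqrt(1 - c_vec[label_idx]), `*`)
    colnames(thal) <- sprintf("V%04d", seq_len(n_vox))

    mot <- generate_motion(n_t)
    nuisance <- cbind(friston24(mot$motion6),
                      wm = rnorm(n_t, 0, 1) + 0.3 * sin(seq_len(n_t) / 40),
                      csf = rnorm(n_t, 0, 1) + 0.3 * cos(seq_len(n_t) / 55))

    subject_id <- sprintf("sub-%03d", s)
    record <- generate_subject_record(g, subject_id, unname(c_vec["SMN"]),
                                      spec$moca_model)

    subjects[[s]] <- list(
      record = record,
      cortical_ts = parcel_ts(X, tr_seconds = spec$tr_seconds),
      thalamic_ts = parcel_ts(thal, tr_seconds = spec$tr_seconds),
      nuisance = nuisance,
      fd = mot$fd,
      true_voxel_labels = true_labels,
      latents = L)
  }

  phenotypes <- do.call(rbind, lapply(subjects, `[[`, "record"))
  structure(list(subjects = subjects,
                 phenotypes = phenotypes,
                 mask_prob = vols$prob,
                 true_label_volume = vols$labels,
                 voxel_coords = voxel_coords,
                 true_voxel_labels = true_labels,
                 partition = spec$partition,
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("synthetic cohort: %d subjects (%s), %d volumes, %d parcels, %d thalamic voxels\n",
              length(x$subjects),
              paste(sprintf("%s n=%d", cohort_groups(),
                            table(factor(x$phenotypes$group, cohort_groups()))),
                    collapse = ", "),
              x$spec$n_timepoints, x$spec$n_parcels,
              length(x$true_voxel_labels)))
  invisible(x)
}

#' Write a synthetic cohort to disk
#'
#' Writes per-subject tab-separated time-series, nuisance, and framewise
#' displacement files, a `participants.tsv` phenotype table, the
#' probabilistic thalamus mask and ground-truth label volumes as NIfTI, and
#' a `manifest.json` recording the generating spec and seed.
#'
#' @param cohort A [generate_cohort()] result.
#' @param out_dir Output directory (created if needed).
#' @param overwrite Overwrite an existing cohort (identified by its
#'   manifest) in `out_dir`? Default `FALSE`: collision is an error.
#' @return `out_dir`, invisibly.
#' @export
write_cohort <- function(cohort, out_dir, overwrite = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  manifest_path <- file.path(out_dir, "manifest.json")
  if (file.exists(manifest_path) && !overwrite) {
    stop("a cohort manifest already exists in ", out_dir,
         "; use overwrite = TRUE to replace it")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  write_tsv <- function(x, path) {
    write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  for (subj in cohort$subjects) {
    id <- subj$record$subject_id
    write_tsv(as_ts_matrix(subj$cortical_ts),
              file.path(out_dir, paste0(id, "_ts.tsv")))
    write_tsv(as_ts_matrix(subj$thalamic_ts),
              file.path(out_dir, paste0(id, "_thal.tsv")))
    write_tsv(subj$nuisance, file.path(out_dir, paste0(id, "_nuisance.tsv")))
    write_tsv(data.frame(fd = subj$fd),
              file.path(out_dir, paste0(id, "_fd.tsv")))
  }
  write_tsv(cohort$phenotypes, file.path(out_dir, "participants.tsv"))

  RNifti::writeNifti(RNifti::asNifti(cohort$mask_prob),
                     file.path(out_dir, "thalamus_mask.nii.gz"))
  RNifti::writeNifti(RNifti::asNifti(cohort$true_label_volume + 0),
                     file.path(out_dir, "true_labels.nii.gz"))

  spec <- cohort$spec
  manifest <- list(
    package = "thalamod",
    seed = spec$seed,
    n_per_group = as.list(spec$n_per_group),
    n_timepoints = spec$n_timepoints,
    tr_seconds = spec$tr_seconds,
    n_parcels = spec$n_parcels,
    thal_grid = spec$thal_grid,
    within_coupling = spec$within_coupling,
    between_coupling = spec$between_coupling,
    thal_coupling = spec$thal_coupling,
    thal_diffuse = spec$thal_diffuse,
    thal_label_noise_share = spec$thal_label_noise_share,
    parcel_coupling_spread = spec$parcel_coupling_spread,
    subject_sd = spec$subject_sd,
    moca_model = spec$moca_model,
    networks = networks7(),
    label_codes = seq_len(7L))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Read a cohort written by [write_cohort()]
#'
#' @param dir Directory containing the cohort files.
#' @return List with `phenotypes`, per-subject `subjects` (cortical and
#'   thalamic series, nuisance, fd), `mask_prob`, `true_label_volume`, and
#'   the `manifest`.
#' @export
read_cohort <- function(dir) {
  manifest_path <- file.path(dir, "manifest.json")
  if (!file.exists(manifest_path)) stop("no manifest.json in ", dir)
  manifest <- jsonlite::read_json(manifest_path, simplifyVector = TRUE)
  phen <- read.table(file.path(dir, "participants.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
  tr <- manifest$tr_seconds %||% 2
  subjects <- lapply(phen$subject_id, function(id) {
    read_mat <- function(suffix) {
      as.matrix(read.table(file.path(dir, paste0(id, suffix)),
                           header = TRUE, sep = "\t", check.names = FALSE))
    }
    list(record = phen[phen$subject_id == id, , drop = FALSE],
         cortical_ts = parcel_ts(read_mat("_ts.tsv"), tr_seconds = tr),
         thalamic_ts = parcel_ts(read_mat("_thal.tsv"), tr_seconds = tr),
         nuisance = read_mat("_nuisance.tsv"),
         fd = read_mat("_fd.tsv")[, 1L])
  })
  mask_prob <- as.array(RNifti::readNifti(file.path(dir, "thalamus_mask.nii.gz")))
  labels <- as.array(RNifti::readNifti(file.path(dir, "true_labels.nii.gz")))
  list(phenotypes = phen, subjects = subjects, mask_prob = mask_prob,
       true_label_volume = labels, manifest = manifest)
}
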