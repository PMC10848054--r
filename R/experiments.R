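# Validation simulations: planted-truth experiments that exercise the whole
# analysis chain on synthetic cohorts. These back the package's recovery
# and direction-of-effect checks and are reused by the acceptance script.

# Compact spec for simulation studies; zero-size groups are allowed.
experiment_spec <- function(n_hc = 0L, n_cn = 0L, n_ci = 0L,
                            n_timepoints = 300L, seed = 1L, ...) {
  cohort_spec(n_per_group = c(HC = n_hc, `TLE-CN` = n_cn, `TLE-CI` = n_ci),
              n_timepoints = n_timepoints, seed = seed, ...)
}

subject_groups <- function(cohort) {
  cohort$phenotypes$group
}

#' Winner-take-all label recovery on planted cohorts
#'
#' Generates cohorts in which every thalamic voxel is coupled to one known
#' network latent, runs the seed-based winner-take-all parcellation on the
#' group-average connectivity, and scores the fraction of voxels whose
#' recovered label matches the planted one.
#'
#' @param n_subjects Subjects per cohort.
#' @param n_timepoints Volumes per subject.
#' @param coupling Voxel-to-network coupling used for every network.
#' @param seeds Integer seeds, one cohort per seed.
#' @return Data frame with one row per seed: `seed`, `recovery` (fraction
#'   of voxels correctly labelled).
#' @export
simulate_label_recovery <- function(n_subjects = 20L, n_timepoints = 300L,
                                    coupling = 0.5, seeds = 1:10) {
  thal <- default_thal_coupling()
  thal[] <- coupling
  diffuse <- default_thal_diffuse()
  diffuse[] <- 0
  out <- lapply(seeds, function(sd_i) {
    spec <- experiment_spec(n_hc = n_subjects, n_timepoints = n_timepoints,
                            seed = sd_i, thal_coupling = thal,
                            thal_diffuse = diffuse, subject_sd = 0)
    cohort <- generate_cohort(spec)
    maps <- lapply(cohort$subjects, function(s) {
      seed_fc_map(s$cortical_ts, cohort$partition, s$thalamic_ts,
                  voxel_coords = cohort$voxel_coords)
    })
    labels <- winner_take_all(group_average_fc(maps))
    data.frame(seed = sd_i,
               recovery = mean(labels$labels == cohort$true_voxel_labels))
  })
  do.call(rbind, out)
}

# Per-subject modular metrics needed by the group-effect experiments.
subject_modular_aucs <- function(cohort, levels = sparsity_levels()) {
  rows <- lapply(cohort$subjects, function(s) {
    fc <- pearson_fc(s$cortical_ts, partition = cohort$partition)
    rep_ <- modular_report(fc, levels)
    data.frame(subject_id = s$record$subject_id,
               group = s$record$group,
               q_auc = rep_$q_curve$auc,
               msi_van = rep_$msi[["VAN"]],
               msi_dmn = rep_$msi[["DMN"]])
  })
  do.call(rbind, rows)
}

# Per-subject thalamic hub AUCs (parcellation averaged over all subjects of
# the cohort, as in the primary analysis).
subject_hub_aucs <- function(cohort, levels = sparsity_levels()) {
  maps <- lapply(cohort$subjects, function(s) {
    seed_fc_map(s$cortical_ts, cohort$partition, s$thalamic_ts,
                voxel_coords = cohort$voxel_coords)
  })
  labels <- winner_take_all(group_average_fc(maps))
  rows <- lapply(cohort$subjects, function(s) {
    sub_ts <- subdivision_timeseries(s$thalamic_ts, labels)
    tc <- build_thalamocortical(s$cortical_ts, sub_ts, cohort$partition)
    hm <- hub_metrics(tc, levels)
    data.frame(subject_id = s$record$subject_id,
               group = s$record$group,
               moca = s$record$moca,
               pc_smn_auc = hm$pc_auc[["tha_SMN"]],
               wmd_smn_auc = hm$wmd_auc[["tha_SMN"]],
               wmd_dmn_auc = hm$wmd_auc[["tha_DMN"]])
  })
  do.call(rbind, rows)
}

#' Direction-of-effect recovery on synthetic cohorts
#'
#' Runs the group-comparison analysis on cohorts generated under the
#' package's default planted effects and records, per seed, whether each
#' expected effect direction is detected at p < 0.05 (pooled t-test):
#'
#' * `contrast = "modular"`: patients (lowered VAN/DMN within-module
#'   coupling) versus controls — lower modularity Q AUC and lower VAN and
#'   DMN segregation indices in patients.
#' * `contrast = "hub"`: cognitively impaired patients (raised, diffuse
#'   thalamo-SMN coupling) versus controls — higher tha_SMN participation
#'   coefficient and within-module degree AUCs in patients.
#'
#' @param contrast `"modular"` or `"hub"`.
#' @param n_per_group Subjects per group.
#' @param n_timepoints Volumes per subject.
#' @param seeds One cohort per seed.
#' @param levels Sparsity levels.
#' @return Data frame with one row per seed and metric: `seed`, `metric`,
#'   `p_value`, `direction_ok`, `detected`.
#' @export
simulate_group_effects <- function(contrast = c("modular", "hub"),
                                   n_per_group = 25L, n_timepoints = 300L,
                                   seeds = 1:20, levels = sparsity_levels()) {
  contrast <- match.arg(contrast)
  out <- lapply(seeds, function(sd_i) {
    if (contrast == "modular") {
      spec <- experiment_spec(n_hc = n_per_group, n_cn = n_per_group,
                              n_timepoints = n_timepoints, seed = sd_i,
                              thal_grid = c(2L, 2L, 2L))
      cohort <- generate_cohort(spec)
      aucs <- subject_modular_aucs(cohort, levels)
      patient <- aucs$group == "TLE-CN"
      metrics <- c("q_auc", "msi_van", "msi_dmn")
      expect_lower <- c(TRUE, TRUE, TRUE)
    } else {
      spec <- experiment_spec(n_hc = n_per_group, n_ci = n_per_group,
                              n_timepoints = n_timepoints, seed = sd_i)
      cohort <- generate_cohort(spec)
      aucs <- subject_hub_aucs(cohort, levels)
      patient <- aucs$group == "TLE-CI"
      metrics <- c("pc_smn_auc", "wmd_smn_auc")
      expect_lower <- c(FALSE, FALSE)
    }
    rows <- lapply(seq_along(metrics), function(k) {
      v <- aucs[[metrics[k]]]
      res <- student_t(v[patient], v[!patient])
      diff_ok <- if (expect_lower[k]) mean(v[patient]) < mean(v[!patient])
                 else mean(v[patient]) > mean(v[!patient])
      data.frame(seed = sd_i, metric = metrics[k], p_value = res$p_value,
                 direction_ok = diff_ok,
                 detected = diff_ok && res$p_value < 0.05,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  do.call(rbind, out)
}

#' Cognition-to-hub-metric linkage on synthetic impaired cohorts
#'
#' Generates cohorts of cognitively impaired patients whose MoCA scores
#' depend (with positive slope) on the subject-level thalamo-SMN coupling,
#' runs the full parcellation and hub-metric chain, and tests the
#' correlation between the tha_SMN participation-coefficient AUC and MoCA.
#'
#' @inheritParams simulate_group_effects
#' @param n_subjects Impaired-group size per seed.
#' @return Data frame with one row per seed: `seed`, `estimate`, `p_value`,
#'   `detected` (positive estimate with p < 0.05).
#' @export
simulate_moca_linkage <- function(n_subjects = 25L, n_timepoints = 300L,
                                  seeds = 1:20, levels = sparsity_levels()) {
  out <- lapply(seeds, function(sd_i) {
    spec <- experiment_spec(n_ci = n_subjects, n_timepoints = n_timepoints,
                            seed = sd_i)
    cohort <- generate_cohort(spec)
    aucs <- subject_hub_aucs(cohort, levels)
    res <- metric_moca_correlation(aucs$pc_smn_auc, aucs$moca)
    data.frame(seed = sd_i, estimate = res$estimate, p_value = res$p_value,
               detected = res$estimate > 0 && res$p_value < 0.05)
  })
  do.call(rbind, out)
}
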