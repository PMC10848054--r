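#' Configure an end-to-end analysis run
#'
#' Bundles every stage parameter of the simulate - preprocess - connectome -
#' parcellate - hubs - stats pipeline.
#'
#' @param cohort A [cohort_spec()] describing the synthetic cohort.
#' @param stages Character vector of stages to run, a subset of the default
#'   in order.
#' @param levels Sparsity levels for the threshold sweep.
#' @param mask_threshold Probability cutoff for the thalamus mask.
#' @param band Band-pass edges in Hz, or `NULL` to skip filtering.
#' @param drop_volumes Initial volumes to drop per subject.
#' @param out_dir Output directory.
#' @param seed Run seed; overrides the cohort spec's seed so one number
#'   controls the whole run.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_spec(),
                            stages = c("simulate", "preprocess", "connectome",
                                       "parcellate", "hubs", "stats"),
                            levels = sparsity_levels(),
                            mask_threshold = 0.10,
                            band = c(0.01, 0.08),
                            drop_volumes = 0L,
                            out_dir = tempfile("thalamod_run_"),
                            seed = 1L) {
  cohort$seed <- as.integer(seed)
  structure(list(cohort = cohort, stages = stages, levels = levels,
                 mask_threshold = mask_threshold, band = band,
                 drop_volumes = as.integer(drop_volumes),
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Accepts a YAML file whose keys mirror the [pipeline_config()] arguments;
#' cohort parameters sit under a `cohort` key (group sizes under
#' `n_per_group`, coupling overrides as scalars applied uniformly).
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  y <- yaml::read_yaml(path)
  ch <- y$cohort %||% list()
  spec_args <- list()
  if (!is.null(ch$n_per_group)) {
    spec_args$n_per_group <- unlist(ch$n_per_group)
  }
  for (fld in c("n_timepoints", "tr_seconds", "n_parcels", "seed")) {
    if (!is.null(ch[[fld]])) spec_args[[fld]] <- ch[[fld]]
  }
  spec <- do.call(cohort_spec, spec_args)
  args <- list(cohort = spec)
  for (fld in c("stages", "levels", "mask_threshold", "band",
                "drop_volumes", "out_dir", "seed")) {
    if (!is.null(y[[fld]])) args[[fld]] <- y[[fld]]
  }
  do.call(pipeline_config, args)
}

#' Validate a pipeline configuration
#'
#' Schema and cross-field checks: sparsity levels inside `(0, 1]` and
#' strictly increasing, band-pass edges below the Nyquist frequency of the
#' cohort's repetition time, stage dependencies (hub metrics require the
#' parcellation; everything requires simulate), and the cohort spec's own
#' coupling invariants.
#'
#' @param config A [pipeline_config()].
#' @return Character vector of findings; empty when the configuration is
#'   clean.
#' @export
validate_config <- function(config) {
  findings <- character(0)
  known <- c("simulate", "preprocess", "connectome", "parcellate", "hubs",
             "stats")
  unknown <- setdiff(config$stages, known)
  if (length(unknown) > 0L) {
    findings <- c(findings, paste0("unknown stage(s): ",
                                   paste(unknown, collapse = ", ")))
  }
  if ("hubs" %in% config$stages && !"parcellate" %in% config$stages) {
    findings <- c(findings, "stage 'hubs' requires stage 'parcellate'")
  }
  if (any(c("connectome", "parcellate", "hubs", "stats") %in% config$stages) &&
      !"simulate" %in% config$stages) {
    findings <- c(findings, "downstream stages require stage 'simulate'")
  }
  if (length(config$levels) < 2L || any(diff(config$levels) <= 0) ||
      any(config$levels <= 0 | config$levels > 1)) {
    findings <- c(findings,
                  "sparsity levels must be strictly increasing within (0, 1]")
  }
  if (!is.null(config$band)) {
    nyquist <- 1 / (2 * config$cohort$tr_seconds)
    if (config$band[2L] >= nyquist) {
      findings <- c(findings, sprintf(
        "band-pass high edge %.3g Hz is not below Nyquist %.3g Hz",
        config$band[2L], nyquist))
    }
    if (config$band[1L] <= 0 || config$band[1L] >= config$band[2L]) {
      findings <- c(findings, "band-pass edges must satisfy 0 < low < high")
    }
  }
  if (config$mask_threshold < 0 || config$mask_threshold >= 1) {
    findings <- c(findings, "mask threshold must lie in [0, 1)")
  }
  spec_check <- tryCatch({
    validate_cohort_spec(config$cohort)
    NULL
  }, error = function(e) conditionMessage(e))
  if (!is.null(spec_check)) findings <- c(findings, spec_check)
  findings
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in order: synthetic-cohort simulation,
#' temporal preprocessing with motion exclusion, cortical connectome and
#' modular metrics, winner-take-all thalamic parcellation (group average
#' over all included subjects), thalamocortical hub metrics and ROI-wise
#' thalamus-network connectivity, and the group-statistics layer with
#' Bonferroni-corrected families. Outputs (TSV tables and a `summary.json`
#' carrying seed and configuration provenance) are written under
#' `config$out_dir`. Re-running the same configuration is deterministic.
#'
#' @param config A [pipeline_config()]; validated before any compute.
#' @return Invisibly, a list with the cohort phenotypes, per-subject metric
#'   tables, label counts, group statistics, and the path of the output
#'   directory.
#' @export
run_pipeline <- function(config) {
  findings <- validate_config(config)
  if (length(findings) > 0L) {
    stop("invalid pipeline configuration:\n  - ",
         paste(findings, collapse = "\n  - "))
  }
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  levels <- config$levels
  nets <- networks7()

  cohort <- generate_cohort(config$cohort)
  write.table(cohort$phenotypes, file.path(config$out_dir, "participants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  included <- rep(TRUE, length(cohort$subjects))
  if ("preprocess" %in% config$stages) {
    for (i in seq_along(cohort$subjects)) {
      s <- cohort$subjects[[i]]
      ms <- motion_summary(s$nuisance[, 1:6], s$fd)
      if (motion_exclude(ms$max_translation_mm, ms$max_rotation_deg,
                         ms$mean_fd_mm)) {
        included[i] <- FALSE
        next
      }
      band_on <- !is.null(config$band)
      low <- if (band_on) config$band[1L] else 0.01
      high <- if (band_on) config$band[2L] else 0.08
      cohort$subjects[[i]]$cortical_ts <- preprocess_ts(
        s$cortical_ts, nuisance = s$nuisance, drop_k = config$drop_volumes,
        low_hz = low, high_hz = high, band = band_on)
      cohort$subjects[[i]]$thalamic_ts <- preprocess_ts(
        s$thalamic_ts, nuisance = s$nuisance, drop_k = config$drop_volumes,
        low_hz = low, high_hz = high, band = band_on)
    }
    cohort$subjects <- cohort$subjects[included]
    cohort$phenotypes <- cohort$phenotypes[included, , drop = FALSE]
  }

  result <- list(phenotypes = cohort$phenotypes,
                 n_excluded = sum(!included),
                 out_dir = config$out_dir)

  if ("connectome" %in% config$stages) {
    modular <- subject_modular_aucs(cohort, levels)
    write.table(modular, file.path(config$out_dir, "modular_aucs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    result$modular <- modular
  }

  if ("parcellate" %in% config$stages) {
    maps <- lapply(cohort$subjects, function(s) {
      seed_fc_map(s$cortical_ts, cohort$partition, s$thalamic_ts,
                  voxel_coords = cohort$voxel_coords)
    })
    labels <- winner_take_all(group_average_fc(maps))
    vol <- label_volume(labels, dim(cohort$mask_prob))
    RNifti::writeNifti(RNifti::asNifti(vol + 0),
                       file.path(config$out_dir, "thalamus_labels.nii.gz"))
    jsonlite::write_json(
      list(networks = nets, codes = seq_len(7L),
           voxel_counts = as.list(labels$voxel_counts)),
      file.path(config$out_dir, "thalamus_labels.json"),
      auto_unbox = TRUE)
    result$label_counts <- labels$voxel_counts
    result$labels <- labels
  }

  if ("hubs" %in% config$stages) {
    hub_rows <- lapply(cohort$subjects, function(s) {
      sub_ts <- subdivision_timeseries(s$thalamic_ts, result$labels)
      tc <- build_thalamocortical(s$cortical_ts, sub_ts, cohort$partition)
      hm <- hub_metrics(tc, levels)
      roi <- roi_network_fc(s$cortical_ts, sub_ts, cohort$partition)
      cbind(data.frame(subject_id = s$record$subject_id,
                       group = s$record$group, moca = s$record$moca),
            as.data.frame(as.list(setNames(hm$pc_auc,
                                           paste0("pc_", nets, "_auc")))),
            as.data.frame(as.list(setNames(hm$wmd_auc,
                                           paste0("wmd_", nets, "_auc")))),
            as.data.frame(as.list(setNames(roi, paste0("fc_", nets)))))
    })
    hubs <- do.call(rbind, hub_rows)
    write.table(hubs, file.path(config$out_dir, "hub_aucs.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    result$hubs <- hubs
  }

  if ("stats" %in% config$stages) {
    result$table1 <- tryCatch(run_table1(cohort$phenotypes),
                              error = function(e) NULL)
    comparisons <- list()
    compare_metric <- function(df, col, family_id) {
      groups_present <- intersect(cohort_groups(), unique(df$group))
      if (length(groups_present) < 2L) return(NULL)
      pairs <- combn(groups_present, 2L)
      res <- lapply(seq_len(ncol(pairs)), function(j) {
        a <- df[[col]][df$group == pairs[1L, j]]
        b <- df[[col]][df$group == pairs[2L, j]]
        if (length(a) < 2L || length(b) < 2L) return(NULL)
        r <- student_t(a, b)
        data.frame(metric = col, group1 = pairs[1L, j], group2 = pairs[2L, j],
                   statistic = r$statistic, p_value = r$p_value,
                   family_id = family_id, stringsAsFactors = FALSE)
      })
      do.call(rbind, res)
    }
    if (!is.null(result$modular)) {
      for (col in c("q_auc", "msi_van", "msi_dmn")) {
        comparisons[[col]] <- compare_metric(result$modular, col, "modular")
      }
    }
    if (!is.null(result$hubs)) {
      for (col in grep("_auc$", names(result$hubs), value = TRUE)) {
        comparisons[[col]] <- compare_metric(result$hubs, col, "hub")
      }
    }
    comparisons <- do.call(rbind, comparisons)
    if (!is.null(comparisons) && nrow(comparisons) > 0L) {
      comparisons$corrected_p <- NA_real_
      for (fam in unique(comparisons$family_id)) {
        idx <- comparisons$family_id == fam
        comparisons$corrected_p[idx] <- bonferroni(comparisons$p_value[idx])
      }
      write.table(comparisons,
                  file.path(config$out_dir, "group_comparisons.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    result$comparisons <- comparisons

    if (!is.null(result$hubs)) {
      cors <- lapply(c("TLE-CI", "TLE-CN"), function(g) {
        df <- result$hubs[result$hubs$group == g, , drop = FALSE]
        if (nrow(df) < 5L || sd(df$pc_SMN_auc) == 0) return(NULL)
        r <- metric_moca_correlation(df$pc_SMN_auc, df$moca)
        data.frame(group = g, metric = "pc_SMN_auc", test = r$test,
                   estimate = r$estimate, p_value = r$p_value,
                   stringsAsFactors = FALSE)
      })
      cors <- do.call(rbind, cors)
      if (!is.null(cors) && nrow(cors) > 0L) {
        cors$corrected_p <- bonferroni(cors$p_value)
        write.table(cors, file.path(config$out_dir, "correlations.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        result$correlations <- cors
      }
    }
  }

  summary <- list(
    seed = config$seed,
    stages = config$stages,
    levels = config$levels,
    n_subjects = nrow(cohort$phenotypes),
    n_excluded = result$n_excluded,
    group_sizes = as.list(table(factor(cohort$phenotypes$group,
                                       cohort_groups()))),
    q_auc_group_means = if (!is.null(result$modular)) {
      lapply(split(result$modular$q_auc, result$modular$group), mean)
    },
    pc_smn_auc_group_means = if (!is.null(result$hubs)) {
      lapply(split(result$hubs$pc_SMN_auc, result$hubs$group), mean)
    },
    label_counts = if (!is.null(result$label_counts)) {
      as.list(result$label_counts)
    })
  jsonlite::write_json(summary, file.path(config$out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(result)
}
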