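#' Published demographic summaries of the reference TLE cohort
#'
#' Group-level summary statistics (means, SDs, group sizes, and sex /
#' therapy counts) of the published temporal-lobe-epilepsy cohort this
#' package's analysis design follows: 18 patients with cognitive impairment
#' (TLE-CI), 35 with normal cognition (TLE-CN), and 37 healthy controls.
#' Raw data were never released; these printed summaries are the inputs to
#' the summary-statistic test entry points ([student_t_summary()],
#' [one_way_anova_summary()], [chi_square()]), which lets the reported
#' statistics be recomputed and checked.
#'
#' @return List with elements:
#'   * `groups`: data frame of per-group `n`, `age_mean`/`age_sd`,
#'     `moca_mean`/`moca_sd`, `onset_mean`/`onset_sd` (NA for HC),
#'     `male`/`female` counts.
#'   * `published`: data frame of the printed test statistics for
#'     reference.
#' @export
#' @examples
#' ref <- table1_reference()
#' with(ref$groups, one_way_anova_summary(
#'   data.frame(moca_mean, moca_sd, n)))
table1_reference <- function() {
  groups <- data.frame(
    group = c("TLE-CI", "TLE-CN", "TLE", "HC"),
    n = c(18L, 35L, 53L, 37L),
    age_mean = c(33.39, 29.49, 30.81, 29.57),
    age_sd = c(9.47, 7.92, 8.59, 7.75),
    moca_mean = c(23.11, 28.14, 26.43, 28.84),
    moca_sd = c(2.78, 1.19, 3.04, 1.34),
    onset_mean = c(25.61, 19.03, 21.26, NA),
    onset_sd = c(10.32, 9.40, 10.12, NA),
    male = c(6L, 8L, 14L, 16L),
    female = c(12L, 27L, 39L, 21L),
    stringsAsFactors = FALSE)
  published <- data.frame(
    quantity = c("anova_f_age", "anova_f_moca", "chisq_sex_3group",
                 "chisq_sex_tle_hc", "t_age_tle_hc", "t_moca_tle_hc",
                 "t_onset_ci_cn"),
    value = c(1.607, 75.762, 3.364, 2.777, 0.703, -4.505, 2.336),
    stringsAsFactors = FALSE)
  list(groups = groups, published = published)
}

#' Recompute the reference cohort's summary statistics
#'
#' Re-derives, from the published group summaries alone, the demographic
#' test statistics of the reference cohort: chi-square tests on the sex
#' tables (no continuity correction), one-way ANOVA F for age and MoCA
#' across the three groups, and pooled-variance t statistics for
#' age-at-onset (impaired vs normal-cognition patients) and for age and
#' MoCA (all patients vs controls).
#'
#' @return Named numeric vector of the recomputed statistics, using the
#'   same quantity names as `table1_reference()$published`.
#' @export
recompute_table1_statistics <- function() {
  ref <- table1_reference()$groups
  row <- function(g) ref[ref$group == g, ]
  ci <- row("TLE-CI"); cn <- row("TLE-CN"); tle <- row("TLE"); hc <- row("HC")

  sex3 <- rbind(male = c(ci$male, cn$male, hc$male),
                female = c(ci$female, cn$female, hc$female))
  sex2 <- rbind(male = c(tle$male, hc$male),
                female = c(tle$female, hc$female))

  c(anova_f_age = one_way_anova_summary(list(
      c(ci$age_mean, ci$age_sd, ci$n),
      c(cn$age_mean, cn$age_sd, cn$n),
      c(hc$age_mean, hc$age_sd, hc$n)))$statistic,
    anova_f_moca = one_way_anova_summary(list(
      c(ci$moca_mean, ci$moca_sd, ci$n),
      c(cn$moca_mean, cn$moca_sd, cn$n),
      c(hc$moca_mean, hc$moca_sd, hc$n)))$statistic,
    chisq_sex_3group = chi_square(sex3)$statistic,
    chisq_sex_tle_hc = chi_square(sex2)$statistic,
    t_age_tle_hc = student_t_summary(tle$age_mean, tle$age_sd, tle$n,
                                     hc$age_mean, hc$age_sd, hc$n)$statistic,
    t_moca_tle_hc = student_t_summary(tle$moca_mean, tle$moca_sd, tle$n,
                                      hc$moca_mean, hc$moca_sd, hc$n)$statistic,
    t_onset_ci_cn = student_t_summary(ci$onset_mean, ci$onset_sd, ci$n,
                                      cn$onset_mean, cn$onset_sd, cn$n)$statistic)
}
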