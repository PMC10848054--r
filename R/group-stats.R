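stat_result <- function(test, statistic, p_value, df = NA_real_, n = NA_real_,
                        extra = list()) {
  structure(c(list(test = test,
                   statistic = unname(statistic),
                   p_value = unname(p_value),
                   df = unname(df),
                   n = unname(n),
                   corrected_p = NA_real_,
                   family_id = NA_character_),
              extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g%s\n", x$test, x$statistic,
              x$p_value,
              if (!is.na(x$corrected_p)) sprintf(" (corrected %.4g)", x$corrected_p)
              else ""))
  invisible(x)
}

#' Classify a MoCA score as cognitively impaired or normal
#'
#' The Montreal Cognitive Assessment cutoff: scores below 26 denote
#' cognitive impairment.
#'
#' @param score Integer MoCA score(s) in `[0, 30]`.
#' @return Factor with levels `CI`, `CN`.
#' @export
#' @examples
#' classify_moca(c(25, 26, 30))
classify_moca <- function(score) {
  if (any(score < 0 | score > 30)) stop("MoCA scores must lie in [0, 30]")
  factor(ifelse(score < 26, "CI", "CN"), levels = c("CI", "CN"))
}

#' One-sample Kolmogorov-Smirnov normality check
#'
#' Tests a sample against a normal distribution with the sample's own mean
#' and SD; the sample counts as normally distributed when p >= 0.05. Used
#' to gate parametric versus rank-based group tests.
#'
#' @param x Numeric sample, n >= 5.
#' @return List with the `stat_result` (`result`) and `is_normal`.
#' @export
ks_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 5L) stop("need at least 5 observations")
  if (sd(x) == 0) {
    return(list(result = stat_result("ks_normality", NA_real_, 0,
                                     n = length(x)),
                is_normal = FALSE, constant = TRUE))
  }
  kt <- suppressWarnings(ks.test(x, "pnorm", mean(x), sd(x)))
  list(result = stat_result("ks_normality", kt$statistic, kt$p.value,
                            n = length(x)),
       is_normal = kt$p.value >= 0.05, constant = FALSE)
}

#' Pooled-variance two-sample t-test
#'
#' Student's t with pooled variance, two-sided. `student_t_summary()` is
#' the identical algebra driven by group means, SDs and sizes, so printed
#' summary tables can be re-tested without raw data.
#'
#' @param x,y Numeric samples (n >= 2 each).
#' @return A `stat_result` with `test = "student_t"`.
#' @export
student_t <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per group")
  if (sd(x) == 0 && sd(y) == 0) stop("zero variance in both groups")
  tt <- t.test(x, y, var.equal = TRUE)
  stat_result("student_t", tt$statistic, tt$p.value, df = tt$parameter,
              n = length(x) + length(y))
}

#' @rdname student_t
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summary statistics.
#' @export
student_t_summary <- function(mean1, sd1, n1, mean2, sd2, n2) {
  if (n1 < 2L || n2 < 2L) stop("need n >= 2 per group")
  if (sd1 <= 0 && sd2 <= 0) stop("zero variance in both groups")
  df <- n1 + n2 - 2
  sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
  t_stat <- (mean1 - mean2) / sqrt(sp2 * (1 / n1 + 1 / n2))
  stat_result("student_t", t_stat, 2 * pt(-abs(t_stat), df), df = df,
              n = n1 + n2)
}

#' One-way analysis of variance
#'
#' Classic equal-variance F test across k groups; the summary entry point
#' reconstructs the between/within sums of squares from group means, SDs
#' and sizes.
#'
#' @param groups List of numeric samples (>= 2 groups, each n >= 2).
#' @return A `stat_result` with `test = "one_way_anova"`.
#' @export
one_way_anova <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1L)) < 2L)) stop("each group needs n >= 2")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1L))))
  if (all(vapply(groups, sd, numeric(1L)) == 0)) {
    stop("within-group variance is zero; F undefined")
  }
  ow <- oneway.test(y ~ g, var.equal = TRUE)
  stat_result("one_way_anova", ow$statistic, ow$p.value,
              df = unname(ow$parameter), n = length(y))
}

#' @rdname one_way_anova
#' @param summaries List (or 3-column matrix/data.frame) of `(mean, sd, n)`
#'   per group.
#' @export
one_way_anova_summary <- function(summaries) {
  if (is.data.frame(summaries) || is.matrix(summaries)) {
    summaries <- lapply(seq_len(nrow(summaries)), function(i) as.numeric(summaries[i, 1:3]))
  }
  k <- length(summaries)
  if (k < 2L) stop("need at least 2 groups")
  means <- vapply(summaries, `[`, numeric(1L), 1L)
  sds <- vapply(summaries, `[`, numeric(1L), 2L)
  ns <- vapply(summaries, `[`, numeric(1L), 3L)
  if (any(ns < 2)) stop("each group needs n >= 2")
  n_tot <- sum(ns)
  grand <- sum(ns * means) / n_tot
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((ns - 1) * sds^2)
  if (ss_within == 0) stop("within-group variance is zero; F undefined")
  df1 <- k - 1
  df2 <- n_tot - k
  f_stat <- (ss_between / df1) / (ss_within / df2)
  stat_result("one_way_anova", f_stat,
              stats::pf(f_stat, df1, df2, lower.tail = FALSE),
              df = c(df1, df2), n = n_tot)
}

#' Mann-Whitney U test
#'
#' Rank-sum test reported as the tie-corrected normal-approximation
#' z-statistic (two-sided), the form summary tables usually print. For
#' small samples without ties an exact p-value by complete enumeration of
#' group assignments is available.
#'
#' @param x,y Numeric samples.
#' @param exact Use exact enumeration (default when `n1 + n2 <= 10` and no
#'   ties are present).
#' @return A `stat_result` with `test = "mann_whitney_u"`, `statistic` = z,
#'   and the U statistic in `$u`.
#' @export
mann_whitney_u <- function(x, y, exact = NULL) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  n1 <- length(x); n2 <- length(y)
  if (n1 < 1L || n2 < 1L) stop("both groups need at least one observation")
  pooled <- c(x, y)
  has_ties <- anyDuplicated(pooled) > 0L
  if (is.null(exact)) exact <- (n1 + n2 <= 10L) && !has_ties
  rk <- rank(pooled)
  r1 <- sum(rk[seq_len(n1)])
  u1 <- r1 - n1 * (n1 + 1) / 2
  n <- n1 + n2
  tie_tab <- table(pooled)
  tie_term <- sum(tie_tab^3 - tie_tab) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  z <- if (sigma2 > 0) (u1 - n1 * n2 / 2) / sqrt(sigma2) else 0

  if (exact && !has_ties) {
    combs <- combn(n, n1)
    u_all <- apply(combs, 2L, function(idx) {
      sum(rank(pooled)[idx]) - n1 * (n1 + 1) / 2
    })
    dev <- abs(u_all - n1 * n2 / 2)
    p <- mean(dev >= abs(u1 - n1 * n2 / 2) - 1e-9)
  } else {
    p <- 2 * pnorm(-abs(z))
  }
  stat_result("mann_whitney_u", z, min(p, 1), n = n,
              extra = list(u = unname(u1), exact = exact && !has_ties))
}

#' Kruskal-Wallis H test
#'
#' Tie-corrected H statistic with a chi-square reference (df = k - 1). For
#' tiny samples an exact permutation p-value by complete enumeration of
#' label orderings is available.
#'
#' @param groups List of numeric samples (>= 2 groups).
#' @param exact Use exact enumeration (only feasible for total n <= 8;
#'   default `FALSE`).
#' @return A `stat_result` with `test = "kruskal_wallis_h"`.
#' @export
kruskal_wallis <- function(groups, exact = FALSE) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2L) stop("need at least 2 groups")
  y <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1L))))
  kt <- kruskal.test(y, g)
  p <- kt$p.value
  if (exact) {
    n <- length(y)
    if (n > 8L) stop("exact enumeration limited to n <= 8")
    h_of <- function(perm) {
      yy <- y[perm]
      suppressWarnings(kruskal.test(yy, g)$statistic)
    }
    perms <- all_permutations(n)
    h_all <- apply(perms, 1L, h_of)
    p <- mean(h_all >= kt$statistic - 1e-9)
  }
  stat_result("kruskal_wallis_h", kt$statistic, p, df = kt$parameter,
              n = length(y))
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow(sub) * n, n)
  row <- 1L
  for (pos in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      out[row, ] <- append(sub[r, ], n, after = pos - 1L)
      row <- row + 1L
    }
  }
  out
}

#' Pearson chi-square test on a contingency table
#'
#' `sum (O - E)^2 / E` without continuity correction,
#' df = (r - 1)(c - 1). Applied to categorical demographics (sex,
#' mono-/polytherapy).
#'
#' @param tab r-by-c matrix of non-negative counts with positive margins.
#' @return A `stat_result` with `test = "chi_square"`.
#' @export
#' @examples
#' chi_square(rbind(male = c(6, 8, 16), female = c(12, 27, 21)))
chi_square <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0)) stop("counts must be non-negative")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("contingency table has a zero margin")
  }
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  stat <- sum((tab - expected)^2 / expected)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  stat_result("chi_square", stat, pchisq(stat, df, lower.tail = FALSE),
              df = df, n = sum(tab))
}

#' Bonferroni correction over a test family
#'
#' Multiplies each member's p-value by the family size m (capped at 1).
#'
#' @param results List of `stat_result` objects (or a numeric p-value
#'   vector).
#' @param family_id Label recorded on each corrected result.
#' @param m Family size; defaults to the number of members.
#' @return The input with `corrected_p` and `family_id` filled in (numeric
#'   vector in, numeric vector out).
#' @export
#' @examples
#' bonferroni(c(0.01, 0.001), m = 7)
bonferroni <- function(results, family_id = "family", m = NULL) {
  if (is.numeric(results)) {
    m <- m %||% length(results)
    return(pmin(1, results * m))
  }
  m <- m %||% length(results)
  lapply(results, function(r) {
    r$corrected_p <- min(1, r$p_value * m)
    r$family_id <- family_id
    r
  })
}

#' Correlate a network metric with MoCA scores
#'
#' Pearson correlation when both variables pass the KS normality check,
#' Spearman otherwise; two-sided. Used to relate metric AUCs (e.g. the
#' thalamo-SMN participation coefficient) to cognitive performance within a
#' patient group.
#'
#' @param metric Numeric metric values (e.g. per-subject AUCs).
#' @param moca MoCA scores, same length.
#' @return A `stat_result` with `test` `"pearson_r"` or `"spearman_rho"`
#'   and the coefficient in `$estimate`.
#' @export
metric_moca_correlation <- function(metric, moca) {
  keep <- !is.na(metric) & !is.na(moca)
  metric <- metric[keep]; moca <- moca[keep]
  if (length(metric) < 5L) stop("need at least 5 paired observations")
  if (sd(metric) == 0) stop("metric is constant; correlation undefined")
  normal <- ks_normality(metric)$is_normal && ks_normality(moca)$is_normal
  method <- if (normal) "pearson" else "spearman"
  ct <- suppressWarnings(cor.test(metric, moca, method = method,
                                  exact = FALSE))
  stat_result(if (normal) "pearson_r" else "spearman_rho",
              ct$estimate, ct$p.value, n = length(metric),
              extra = list(estimate = unname(ct$estimate)))
}

table1_variables <- function() {
  c("age", "sex", "education", "onset_age", "duration", "seizure_freq",
    "aed", "moca")
}

#' Demographic and clinical test battery
#'
#' Reproduces the standard cohort-description battery on a phenotype
#' table: for each continuous variable a three-group comparison (ANOVA when
#' every group passes the KS normality check, Kruskal-Wallis otherwise) and
#' a patients-versus-controls comparison (pooled t or Mann-Whitney), and
#' chi-square tests for categorical variables. Clinical variables observed
#' only in patients are compared between the impaired and normal-cognition
#' patient groups.
#'
#' @param phenotypes Data frame with columns `group` (HC / TLE-CN /
#'   TLE-CI), `age`, `sex`, `education`, `onset_age`, `duration`,
#'   `seizure_freq`, `aed`, `moca`.
#' @return Data frame with one row per (variable, comparison): test name,
#'   statistic, p-value.
#' @export
run_table1 <- function(phenotypes) {
  needed <- c("group", table1_variables())
  missing_cols <- setdiff(needed, names(phenotypes))
  if (length(missing_cols) > 0L) {
    stop("phenotype table lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  grp <- phenotypes$group
  is_tle <- grp %in% c("TLE-CN", "TLE-CI")

  three_groups <- function(v) {
    lapply(c("TLE-CI", "TLE-CN", "HC"), function(g) v[grp == g])
  }
  all_normal <- function(samples) {
    all(vapply(samples, function(s) {
      s <- s[!is.na(s)]
      length(s) >= 5L && ks_normality(s)$is_normal
    }, logical(1L)))
  }
  rows <- list()
  add <- function(variable, comparison, res) {
    rows[[length(rows) + 1L]] <<- data.frame(
      variable = variable, comparison = comparison, test = res$test,
      statistic = res$statistic, p_value = res$p_value,
      stringsAsFactors = FALSE)
  }

  continuous_battery <- function(var, three_way = TRUE, tle_vs_hc = TRUE,
                                 ci_vs_cn = FALSE) {
    v <- phenotypes[[var]]
    if (three_way) {
      gs <- three_groups(v)
      res <- if (all_normal(gs)) one_way_anova(gs) else kruskal_wallis(gs)
      add(var, "TLE-CI vs TLE-CN vs HC", res)
    }
    if (tle_vs_hc) {
      a <- v[is_tle]; b <- v[grp == "HC"]
      res <- if (all_normal(list(a, b))) student_t(a, b) else mann_whitney_u(a, b)
      add(var, "TLE vs HC", res)
    }
    if (ci_vs_cn) {
      a <- v[grp == "TLE-CI"]; b <- v[grp == "TLE-CN"]
      res <- if (all_normal(list(a, b))) student_t(a, b) else mann_whitney_u(a, b)
      add(var, "TLE-CI vs TLE-CN", res)
    }
  }

  continuous_battery("age")
  continuous_battery("education")
  continuous_battery("moca")
  continuous_battery("onset_age", three_way = FALSE, tle_vs_hc = FALSE,
                     ci_vs_cn = TRUE)
  continuous_battery("duration", three_way = FALSE, tle_vs_hc = FALSE,
                     ci_vs_cn = TRUE)
  continuous_battery("seizure_freq", three_way = FALSE, tle_vs_hc = FALSE,
                     ci_vs_cn = TRUE)

  sex_3 <- table(phenotypes$sex, factor(grp, c("TLE-CI", "TLE-CN", "HC")))
  add("sex", "TLE-CI vs TLE-CN vs HC", chi_square(sex_3))
  sex_2 <- table(phenotypes$sex, factor(ifelse(is_tle, "TLE", "HC"),
                                        c("TLE", "HC")))
  add("sex", "TLE vs HC", chi_square(sex_2))
  aed_tab <- table(phenotypes$aed[is_tle],
                   factor(grp[is_tle], c("TLE-CI", "TLE-CN")))
  if (all(dim(aed_tab) >= 2L)) {
    add("aed", "TLE-CI vs TLE-CN", chi_square(aed_tab))
  }

  do.call(rbind, rows)
}
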