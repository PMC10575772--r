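#' Change scores between two visits
#'
#' Longitudinal change is the simple difference `T2 - T1`; all clinical
#' scores used here are already age-normed, so no further norming is applied.
#'
#' @param score_t1,score_t2 numeric vectors of equal length.
#' @return `score_t2 - score_t1`.
#' @export
change_score <- function(score_t1, score_t2) {
  if (length(score_t1) != length(score_t2))
    stop("score_t1 and score_t2 must have equal length")
  if (any(!is.finite(score_t1)) || any(!is.finite(score_t2)))
    stop("missing or non-finite score: subjects without both visits must be excluded upstream")
  score_t2 - score_t1
}

#' Outcome labels
#' @return Factor levels used for MCID outcome groups.
#' @export
outcome_levels <- function() c("Decreaser", "No-changer", "Increaser")

#' MCID-based outcome classification
#'
#' Classifies a change score against a minimal clinically important
#' difference (MCID). With the default `mcid = 4` (Vineland composite
#' standard-score points): change `>= 4` is an Increaser, `<= -4` a
#' Decreaser, and strictly between `-4` and `4` a No-changer. The boundary
#' values belong to the changer groups.
#'
#' @param delta numeric vector of change scores.
#' @param mcid positive threshold.
#' @param basis optional name of the score the change was computed from
#'   (stored as an attribute, for bookkeeping of alternative stratifications).
#' @return Factor with levels `Decreaser`, `No-changer`, `Increaser` and
#'   attributes `mcid` and `basis`.
#' @export
classify_outcome <- function(delta, mcid = 4, basis = "vabs_standard") {
  if (!is.numeric(mcid) || length(mcid) != 1L || mcid <= 0)
    stop("mcid must be a single positive number")
  if (any(!is.finite(delta))) stop("non-finite change score")
  lab <- ifelse(delta >= mcid, "Increaser",
                ifelse(delta <= -mcid, "Decreaser", "No-changer"))
  out <- factor(lab, levels = outcome_levels())
  attr(out, "mcid") <- mcid
  attr(out, "basis") <- basis
  out
}

#' Add an outcome column to a phenotype table
#'
#' Computes the change score for the given basis (e.g. `"vabs_standard"`
#' uses columns `vabs_standard_t1` / `vabs_standard_t2`) for autistic rows
#' and appends a column `outcome_<basis>`. Neurotypical rows get `NA`.
#'
#' @param phenotypes data frame with the longitudinal score columns.
#' @param basis base name of the score pair.
#' @param mcid threshold passed to [classify_outcome()].
#' @return The phenotype table with one added factor column.
#' @export
add_outcome_labels <- function(phenotypes, basis = "vabs_standard", mcid = 4) {
  c1 <- paste0(basis, "_t1"); c2 <- paste0(basis, "_t2")
  if (!all(c(c1, c2) %in% names(phenotypes)))
    stop("phenotypes lack columns ", c1, " / ", c2)
  aut <- phenotypes$diagnosis == "autistic"
  lab <- factor(rep(NA_character_, nrow(phenotypes)), levels = outcome_levels())
  lab[aut] <- classify_outcome(
    change_score(phenotypes[[c1]][aut], phenotypes[[c2]][aut]),
    mcid = mcid, basis = basis)
  phenotypes[[paste0("outcome_", basis)]] <- lab
  phenotypes
}

#' One-way ANOVA from printed group summaries
#'
#' Fixed-effects one-way ANOVA F statistic recovered from per-group means,
#' SDs and ns alone: the between-group sum of squares is taken about the
#' weighted grand mean and the within-group sum of squares is
#' `sum((n_i - 1) sd_i^2)`. This reproduces published cohort-table test
#' statistics from the printed summaries without raw data.
#'
#' @param means,sds,ns equal-length numeric vectors (k >= 2 groups).
#' @return List with `F`, `df1`, `df2`, `p`.
#' @export
anova_f_from_summary <- function(means, sds, ns) {
  k <- length(means)
  if (length(sds) != k || length(ns) != k)
    stop("means, sds and ns must have equal length")
  if (k < 2L) stop("need at least two groups")
  if (any(ns < 2)) stop("all group sizes must be >= 2")
  if (any(sds <= 0)) stop("all SDs must be positive")
  N <- sum(ns)
  grand <- sum(ns * means) / N
  ss_between <- sum(ns * (means - grand)^2)
  ss_within <- sum((ns - 1) * sds^2)
  df1 <- k - 1L
  df2 <- N - k
  Fv <- (ss_between / df1) / (ss_within / df2)
  list(F = Fv, df1 = df1, df2 = df2,
       p = stats::pf(Fv, df1, df2, lower.tail = FALSE))
}

#' Pearson chi-square for an r x c count table
#'
#' Plain Pearson chi-square without continuity correction (the convention
#' used for cohort demographic tables).
#'
#' @param table matrix of non-negative counts; no all-zero row or column.
#' @return List with `statistic`, `df`, `p`.
#' @export
pearson_chi_square <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("table has an all-zero row or column margin")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value)
}

#' Sensitivity filters on a phenotype table
#'
#' Row-subsetting used by the sensitivity analyses: exclusion of subjects
#' with intellectual disability, exclusion of medicated subjects, and
#' restriction to an age band `[low, high)` on age at T1. The number of rows
#' removed by each filter is reported via `message()`.
#'
#' @param phenotypes phenotype data frame.
#' @param exclude_id,exclude_medicated logical switches.
#' @param age_band `NULL` or numeric `c(low, high)`; keeps `low <= age_t1 < high`.
#' @param outcome_col outcome column checked for surviving comparison groups.
#' @return Filtered phenotype table.
#' @export
apply_filters <- function(phenotypes, exclude_id = FALSE,
                          exclude_medicated = FALSE, age_band = NULL,
                          outcome_col = "outcome_vabs_standard") {
  out <- phenotypes
  if (exclude_id) {
    drop <- out$id_flag %in% TRUE
    message(sprintf("exclude_id: removed %d rows", sum(drop)))
    out <- out[!drop, , drop = FALSE]
  }
  if (exclude_medicated) {
    drop <- out$medication_flag %in% TRUE
    message(sprintf("exclude_medicated: removed %d rows", sum(drop)))
    out <- out[!drop, , drop = FALSE]
  }
  if (!is.null(age_band)) {
    stopifnot(length(age_band) == 2L, age_band[1] < age_band[2])
    keep <- out$age_t1 >= age_band[1] & out$age_t1 < age_band[2]
    message(sprintf("age_band [%g, %g): removed %d rows",
                    age_band[1], age_band[2], sum(!keep)))
    out <- out[keep, , drop = FALSE]
  }
  if (nrow(out) == 0L) stop("filters removed every subject")
  if (!any(out$diagnosis == "neurotypical"))
    stop("filters removed the entire group: neurotypical")
  if (outcome_col %in% names(out)) {
    before <- levels(phenotypes[[outcome_col]])
    gone <- setdiff(before, as.character(stats::na.omit(out[[outcome_col]])))
    pres <- intersect(before,
                      as.character(stats::na.omit(phenotypes[[outcome_col]])))
    gone <- intersect(gone, pres)
    if (length(gone))
      stop("filters removed the entire group: ", paste(gone, collapse = ", "))
  }
  out
}

#' Cohort summary table
#'
#' Per-measure group summaries in the layout of a clinical cohort table:
#' mean and SD per group with the one-way ANOVA F (via
#' [anova_f_from_summary()] applied to the table's own summaries) for
#' numeric measures, and counts with the Pearson chi-square for categorical
#' ones. P values are not corrected for multiple comparisons.
#'
#' @param phenotypes phenotype table with outcome labels already assigned.
#' @param grouping `"subgroups"` (the three autistic outcome groups) or
#'   `"diagnosis"` (autistic vs neurotypical).
#' @param outcome_col outcome column used when `grouping = "subgroups"`.
#' @return Data frame, one row per measure: per-group `mean`, `sd`, `n`
#'   (or counts), `test` (`F` or `chisq`), `statistic`, `df1`, `df2`, `p`.
#' @export
build_cohort_table <- function(phenotypes, grouping = c("subgroups", "diagnosis"),
                               outcome_col = "outcome_vabs_standard") {
  grouping <- match.arg(grouping)
  if (grouping == "subgroups") {
    ph <- phenotypes[!is.na(phenotypes[[outcome_col]]), , drop = FALSE]
    g <- droplevels(ph[[outcome_col]])
  } else {
    ph <- phenotypes
    g <- factor(ph$diagnosis, levels = c("autistic", "neurotypical"))
  }
  if (nlevels(g) < 2L)
    stop("grouping yields fewer than two non-empty groups")
  if (any(table(g) == 0L)) stop("empty group in cohort table")

  num_meas <- intersect(c("age_t1", "fsiq", "delta_t", "total_sa_t1",
                          "mean_ct_t1",
                          "vabs_comm_t1", "vabs_daily_t1", "vabs_social_t1",
                          "vabs_standard_t1",
                          "vabs_comm_t2", "vabs_daily_t2", "vabs_social_t2",
                          "vabs_standard_t2",
                          "ados_sa_css_t1", "ados_rrb_css_t1",
                          "ados_total_css_t1"),
                        names(ph))
  cat_meas <- intersect(c("sex", "id_flag", "medication_flag"), names(ph))

  rows <- list()
  for (m in num_meas) {
    x <- ph[[m]]
    ok <- is.finite(x)
    sm <- tapply(x[ok], g[ok], mean)
    ss <- tapply(x[ok], g[ok], stats::sd)
    sn <- tapply(x[ok], g[ok], length)
    if (any(is.na(sm)) || any(sn < 2)) next
    tst <- anova_f_from_summary(as.numeric(sm), as.numeric(ss), as.numeric(sn))
    row <- data.frame(measure = m, test = "F", statistic = tst$F,
                      df1 = tst$df1, df2 = tst$df2, p = tst$p)
    for (lv in levels(g)) {
      row[[paste0("mean_", lv)]] <- unname(sm[lv])
      row[[paste0("sd_", lv)]] <- unname(ss[lv])
      row[[paste0("n_", lv)]] <- unname(sn[lv])
    }
    rows[[m]] <- row
  }
  for (m in cat_meas) {
    x <- ph[[m]]
    tab <- table(x, g)
    if (nrow(tab) < 2L || any(colSums(tab) == 0)) next
    tst <- pearson_chi_square(tab)
    row <- data.frame(measure = m, test = "chisq", statistic = tst$statistic,
                      df1 = tst$df, df2 = NA_real_, p = tst$p)
    for (lv in levels(g)) {
      row[[paste0("mean_", lv)]] <- NA_real_
      row[[paste0("sd_", lv)]] <- NA_real_
      row[[paste0("n_", lv)]] <- sum(tab[, lv])
      row[[paste0("counts_", lv)]] <- paste(rownames(tab), tab[, lv],
                                            sep = "=", collapse = ";")
    }
    rows[[m]] <- row
  }
  all_cols <- unique(unlist(lapply(rows, names)))
  rows <- lapply(rows, function(r) {
    for (cl in setdiff(all_cols, names(r))) r[[cl]] <- NA
    r[all_cols]
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "grouping") <- grouping
  attr(out, "group_ns") <- as.integer(table(g))
  out
}
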