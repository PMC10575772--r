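#' Reference cohort summary statistics
#'
#' Printed summary statistics (group means, SDs, ns and categorical counts)
#' of the longitudinal autism cohort the synthetic generator emulates:
#' 161 autistic individuals stratified by Vineland composite change into
#' Decreasers (n = 53), No-changers (n = 42) and Increasers (n = 66), and
#' 172 neurotypicals, aged 6-30, with roughly 1.6 years between visits.
#' These marginals seed [cohort_spec()] defaults and let the
#' summary-statistic tests ([anova_f_from_summary()],
#' [pearson_chi_square()]) reproduce the published cohort-table values
#' without any raw data.
#'
#' @return Named list:
#' \describe{
#'   \item{numeric}{data frame with `measure`, `group`, `mean`, `sd`, `n`.}
#'   \item{sex}{data frame of female/male counts per group.}
#'   \item{id}{data frame of intellectual-disability counts per group.}
#' }
#' @export
reference_cohort_summaries <- function() {
  grp <- c("Decreaser", "No-changer", "Increaser", "autistic", "neurotypical")
  num <- rbind(
    data.frame(measure = "age_t1", group = grp,
               mean = c(17.07, 14.68, 18.10, 16.87, 16.35),
               sd   = c(6.7, 4.3, 4.7, 5.5, 5.7)),
    data.frame(measure = "fsiq", group = grp,
               mean = c(95.75, 105.06, 104.63, 101.82, 107.05),
               sd   = c(18.9, 22.6, 17.8, 19.8, 16.5)),
    data.frame(measure = "mean_ct_t1", group = grp,
               mean = c(2.68, 2.71, 2.67, 2.69, 2.69),
               sd   = c(0.1, 0.1, 0.1, 0.1, 0.1)),
    data.frame(measure = "delta_t", group = grp,
               mean = c(1.60, 1.60, 1.64, 1.62, 1.59),
               sd   = c(0.3, 0.3, 0.2, 0.3, 0.3)),
    data.frame(measure = "total_sa_t1", group = grp,
               mean = c(2230.11, 2349.98, 2308.22, 2293.40, 2316.47),
               sd   = c(271.08, 159.96, 228.0, 232.0, 225.0)),
    data.frame(measure = "vabs_comm_t1", group = grp,
               mean = c(81.60, 77.00, 73.74, 77.18, NA),
               sd   = c(18.3, 12.5, 13.5, 15.3, NA)),
    data.frame(measure = "vabs_daily_t1", group = grp,
               mean = c(77.98, 76.90, 71.86, 75.19, NA),
               sd   = c(18.7, 15.4, 12.4, 15.6, NA)),
    data.frame(measure = "vabs_social_t1", group = grp,
               mean = c(73.38, 71.98, 70.55, 71.85, NA),
               sd   = c(14.9, 11.2, 15.4, 14.2, NA)),
    data.frame(measure = "vabs_standard_t1", group = grp,
               mean = c(75.60, 73.31, 69.50, 72.50, NA),
               sd   = c(15.2, 10.1, 11.0, 12.5, NA)),
    data.frame(measure = "vabs_comm_delta", group = grp,
               mean = c(-15.06, -2.55, 9.15, -1.87, NA),
               sd   = c(13.1, 6.8, 13.0, 15.6, NA)),
    data.frame(measure = "vabs_daily_delta", group = grp,
               mean = c(-10.40, 0.14, 8.59, 0.14, NA),
               sd   = c(8.5, 7.4, 8.7, 11.6, NA)),
    data.frame(measure = "vabs_social_delta", group = grp,
               mean = c(-7.83, 2.45, 12.36, 3.13, NA),
               sd   = c(9.9, 7.8, 10.1, 12.8, NA)),
    data.frame(measure = "vabs_standard_delta", group = grp,
               mean = c(-11.23, 0.05, 9.86, 0.36, NA),
               sd   = c(8.0, 2.0, 5.5, 10.8, NA)),
    data.frame(measure = "vabs_standard_t2", group = grp,
               mean = c(64.38, 73.36, 79.36, 72.86, NA),
               sd   = c(18.7, 10.8, 11.0, 15.3, NA)),
    data.frame(measure = "vabs_social_t2", group = grp,
               mean = c(65.55, 74.43, 82.91, 74.98, NA),
               sd   = c(19.9, 11.0, 13.7, 17.1, NA)),
    data.frame(measure = "ados_total_css_t1", group = grp,
               mean = c(5.35, 5.60, 4.83, 5.20, NA),
               sd   = c(2.9, 2.8, 2.5, 2.74, NA)),
    data.frame(measure = "ados_sa_css_t1", group = grp,
               mean = c(6.02, 6.25, 5.48, 5.86, NA),
               sd   = c(2.8, 2.6, 2.5, 2.7, NA)),
    data.frame(measure = "ados_rrb_css_t1", group = grp,
               mean = c(4.77, 4.63, 4.29, 4.54, NA),
               sd   = c(2.8, 2.7, 2.9, 2.8, NA)))
  num$n <- rep(c(53L, 42L, 66L, 161L, 172L), nrow(num) / 5L)
  sex <- data.frame(group = grp,
                    female = c(25L, 6L, 19L, 50L, 64L),
                    male = c(28L, 36L, 47L, 111L, 108L))
  id <- data.frame(group = grp,
                   id = c(9L, 5L, 5L, 19L, 11L),
                   no_id = c(44L, 37L, 61L, 142L, 161L))
  list(numeric = num, sex = sex, id = id)
}
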