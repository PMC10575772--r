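#' Specification of a synthetic two-timepoint cohort
#'
#' Bundles every parameter of the synthetic cohort generator. Defaults
#' reproduce the marginal structure of the reference longitudinal autism
#' cohort (see [reference_cohort_summaries()]): 161 autistic participants in
#' outcome subgroups of 53 Decreasers, 42 No-changers and 66 Increasers,
#' 172 neurotypicals, ages 6-30 at baseline, inter-visit interval
#' 1.6 +/- 0.3 years, and subgroup-specific Vineland composite change
#' (Delta V) distributions truncated to their MCID intervals.
#'
#' @param n_nt neurotypical sample size.
#' @param subgroup_sizes integer vector `(Decreaser, No-changer, Increaser)`.
#' @param age_range uniform baseline-age range in years.
#' @param delta_t_mean,delta_t_sd inter-visit interval (years), normal,
#'   truncated below at 0.25 y.
#' @param vabs_t1_mean,vabs_t1_sd baseline Vineland composite standard score.
#' @param delta_v_params named list of `(mean, sd)` per subgroup; each mean
#'   must lie inside its subgroup's MCID interval.
#' @param fsiq_params named list of `(mean, sd)` per diagnosis.
#' @param sex_proportions fraction female per subgroup and for neurotypicals.
#' @param id_rates,medication_rates Bernoulli rates of the intellectual
#'   disability and psychotropic-medication flags.
#' @param n_sites number of acquisition sites (round-robin allocation).
#' @param mcid MCID threshold defining the subgroup truncation intervals.
#' @param noise_fwhm smoothness (mm FWHM) of the spatial noise fields.
#' @param ct_params,sa_params per-feature map-model parameters; see
#'   Details.
#' @param seed integer RNG seed.
#'
#' @details Map model (per feature, per subject `s`, timepoint `t`, vertex
#' `v`):
#' `mu(v) + beta_age (age_st - 18) + beta_sex male_s + site_s + u_s + e_st(v)`
#' where `u_s` is a scalar subject intercept and `e_st(v)` a spatially
#' smooth field (white vertex noise smoothed to `noise_fwhm`). Cortical
#' thickness uses an absolute mean of 2.69 mm; surface area uses a
#' per-vertex mean scaled so the map total matches `sa_params$total_mean`
#' cm^2. Planted group effects are added on top (see [effect_spec()]).
#'
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_nt = 172L,
                        subgroup_sizes = c(Decreaser = 53L, `No-changer` = 42L,
                                           Increaser = 66L),
                        age_range = c(6, 30),
                        delta_t_mean = 1.6, delta_t_sd = 0.3,
                        vabs_t1_mean = 72.5, vabs_t1_sd = 12.5,
                        delta_v_params = list(Decreaser = c(-11.23, 8.0),
                                              `No-changer` = c(0.05, 2.0),
                                              Increaser = c(9.86, 5.5)),
                        fsiq_params = list(autistic = c(101.82, 19.8),
                                           neurotypical = c(107.05, 16.5)),
                        sex_proportions = c(Decreaser = 25 / 53,
                                            `No-changer` = 6 / 42,
                                            Increaser = 19 / 66,
                                            neurotypical = 64 / 172),
                        id_rates = c(Decreaser = 9 / 53, `No-changer` = 5 / 42,
                                     Increaser = 5 / 66,
                                     neurotypical = 11 / 172),
                        medication_rates = c(autistic = 0.3,
                                             neurotypical = 0.02),
                        n_sites = 4L, mcid = 4,
                        noise_fwhm = 10,
                        ct_params = list(mean = 2.69, age_slope = -0.010,
                                         sex_effect = 0.02, subject_sd = 0.09,
                                         vertex_noise_sd = 0.25,
                                         site_sd = 0.03),
                        sa_params = list(total_mean = 2293.4, age_slope_rel = -0.002,
                                         sex_effect_rel = 0.07,
                                         subject_sd_rel = 0.09,
                                         vertex_noise_sd_rel = 0.25,
                                         site_sd_rel = 0.02),
                        seed = 1L) {
  spec <- list(n_nt = as.integer(n_nt),
               subgroup_sizes = subgroup_sizes, age_range = age_range,
               delta_t_mean = delta_t_mean, delta_t_sd = delta_t_sd,
               vabs_t1_mean = vabs_t1_mean, vabs_t1_sd = vabs_t1_sd,
               delta_v_params = delta_v_params, fsiq_params = fsiq_params,
               sex_proportions = sex_proportions, id_rates = id_rates,
               medication_rates = medication_rates,
               n_sites = as.integer(n_sites), mcid = mcid,
               noise_fwhm = noise_fwhm, ct_params = ct_params,
               sa_params = sa_params, seed = as.integer(seed))
  class(spec) <- "cohort_spec"
  validate_cohort_spec(spec)
  spec
}

validate_cohort_spec <- function(spec) {
  if (any(spec$subgroup_sizes < 0) || spec$n_nt < 0)
    stop("group sizes must be non-negative")
  if (spec$delta_t_mean <= 0) stop("delta_t_mean must be positive")
  if (spec$mcid <= 0) stop("mcid must be positive")
  iv <- mcid_intervals(spec$mcid)
  for (g in names(spec$delta_v_params)) {
    m <- spec$delta_v_params[[g]][1]
    if (m < iv[[g]][1] || m > iv[[g]][2])
      stop(sprintf("delta_v mean for %s (%g) lies outside its MCID interval [%g, %g]",
                   g, m, iv[[g]][1], iv[[g]][2]))
  }
  invisible(spec)
}

mcid_intervals <- function(mcid) {
  list(Decreaser = c(-Inf, -mcid), `No-changer` = c(-mcid, mcid),
       Increaser = c(mcid, Inf))
}

# truncated-normal sampling by rejection; intervals always contain
# non-negligible mass here (validated by cohort_spec)
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  mass <- stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd)
  if (mass < 1e-8)
    stop(sprintf("truncation interval [%g, %g] has negligible mass under N(%g, %g)",
                 lower, upper, mean, sd))
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(2L * ceiling((n - length(out)) / mass), mean, sd)
    out <- c(out, x[x >= lower & x <= upper])
  }
  out[seq_len(n)]
}

# strictly-open truncation for the No-changer interval: the boundary points
# have probability zero under a continuous draw, but guard anyway so the
# classification round-trip is exact
rtrunc_norm_open <- function(n, mean, sd, lower, upper) {
  x <- rtrunc_norm(n, mean, sd, lower, upper)
  while (any(bad <- (x <= lower | x >= upper)))
    x[bad] <- rtrunc_norm(sum(bad), mean, sd, lower, upper)
  x
}

#' Generate a synthetic phenotype table
#'
#' Draws the clinical/demographic table of a synthetic cohort: outcome
#' labels are fixed first (at the sizes in the spec) and each autistic
#' subject's Vineland composite change is then drawn from a normal
#' distribution truncated to the label's MCID interval, so re-classification
#' by the MCID rule always returns the generated label. Vineland T2 scores
#' are `T1 + change` (all scores already age-normed). Neurotypicals carry no
#' Vineland/ADOS scores.
#'
#' @param spec a [cohort_spec()].
#' @return Data frame, one row per subject, with demographics, site, flags,
#'   Vineland domain and composite scores at both timepoints and ADOS
#'   calibrated severity scores; plus the generated `outcome_generated`
#'   label. Total-brain columns are filled by [generate_cohort()].
#' @export
generate_phenotypes <- function(spec) {
  validate_cohort_spec(spec)
  set.seed(spec$seed)
  ref <- reference_cohort_summaries()$numeric
  sg <- names(spec$subgroup_sizes)
  n_aut <- sum(spec$subgroup_sizes)
  n <- n_aut + spec$n_nt
  grp <- c(rep(sg, spec$subgroup_sizes), rep("neurotypical", spec$n_nt))
  diagnosis <- ifelse(grp == "neurotypical", "neurotypical", "autistic")

  iv <- mcid_intervals(spec$mcid)
  p_female <- spec$sex_proportions[grp]
  p_id <- spec$id_rates[grp]
  p_med <- spec$medication_rates[diagnosis]

  ph <- data.frame(
    subject_id = sprintf("sub-%04d", seq_len(n)),
    diagnosis = diagnosis,
    outcome_generated = factor(ifelse(grp == "neurotypical", NA, grp),
                               levels = outcome_levels()),
    sex = ifelse(stats::runif(n) < p_female, "F", "M"),
    site = paste0("site", (seq_len(n) - 1L) %% spec$n_sites + 1L),
    age_t1 = stats::runif(n, spec$age_range[1], spec$age_range[2]),
    fsiq = NA_real_, id_flag = stats::runif(n) < p_id,
    medication_flag = stats::runif(n) < p_med,
    stringsAsFactors = FALSE)
  ph$delta_t <- rtrunc_norm(n, spec$delta_t_mean, spec$delta_t_sd, lower = 0.25)
  ph$age_t2 <- ph$age_t1 + ph$delta_t
  for (d in names(spec$fsiq_params)) {
    idx <- diagnosis == d
    ph$fsiq[idx] <- stats::rnorm(sum(idx), spec$fsiq_params[[d]][1],
                                 spec$fsiq_params[[d]][2])
  }

  ref_row <- function(measure, group) {
    r <- ref[ref$measure == measure & ref$group == group, ]
    c(r$mean, r$sd)
  }
  aut <- which(diagnosis == "autistic")
  # composite: T1 normal, change truncated to the subgroup MCID interval
  ph$vabs_standard_t1 <- NA_real_
  ph$vabs_standard_t1[aut] <- stats::rnorm(n_aut, spec$vabs_t1_mean,
                                           spec$vabs_t1_sd)
  dv <- rep(NA_real_, n)
  for (g in sg) {
    idx <- which(grp == g)
    pr <- spec$delta_v_params[[g]]
    dv[idx] <- if (g == "No-changer")
      rtrunc_norm_open(length(idx), pr[1], pr[2], iv[[g]][1], iv[[g]][2])
    else rtrunc_norm(length(idx), pr[1], pr[2], iv[[g]][1], iv[[g]][2])
  }
  ph$vabs_standard_t2 <- ph$vabs_standard_t1 + dv
  # domains: subgroup-specific T1 and change distributions, no truncation
  for (dom in c("comm", "daily", "social")) {
    t1 <- paste0("vabs_", dom, "_t1"); t2 <- paste0("vabs_", dom, "_t2")
    ph[[t1]] <- NA_real_; ph[[t2]] <- NA_real_
    for (g in sg) {
      idx <- which(grp == g)
      p1 <- ref_row(paste0("vabs_", dom, "_t1"), g)
      pd <- ref_row(paste0("vabs_", dom, "_delta"), g)
      ph[[t1]][idx] <- stats::rnorm(length(idx), p1[1], p1[2])
      ph[[t2]][idx] <- ph[[t1]][idx] + stats::rnorm(length(idx), pd[1], pd[2])
    }
  }
  for (sc in c("sa", "rrb", "total")) {
    t1 <- paste0("ados_", sc, "_css_t1"); t2 <- paste0("ados_", sc, "_css_t2")
    ph[[t1]] <- NA_real_; ph[[t2]] <- NA_real_
    for (g in sg) {
      idx <- which(grp == g)
      p1 <- ref_row(paste0("ados_", sc, "_css_t1"), g)
      ph[[t1]][idx] <- pmax(1, pmin(10, stats::rnorm(length(idx), p1[1], p1[2])))
      ph[[t2]][idx] <- pmax(1, pmin(10, ph[[t1]][idx] +
                                      stats::rnorm(length(idx), 0, 1.5)))
    }
  }
  ph$total_sa_t1 <- NA_real_; ph$total_sa_t2 <- NA_real_
  ph$mean_ct_t1 <- NA_real_; ph$mean_ct_t2 <- NA_real_
  ph
}

#' Planted group-difference effect on the surface
#'
#' Describes one planted effect cell: a geodesic disc of vertices where one
#' autistic outcome subgroup differs from neurotypicals in one feature for
#' one analysis type. Effect size is Cohen's d in units of the per-vertex
#' within-group SD of the generated (pre-effect) maps. `analysis = "T1"`
#' effects are persistent (added at both timepoints), `"delta"` and `"T2"`
#' effects are added at T2 only.
#'
#' @param feature `"SA"` or `"CT"`.
#' @param analysis `"T1"`, `"delta"` or `"T2"`.
#' @param subgroup the affected outcome subgroup.
#' @param seed_vertices 1-based vertex ids seeding the cluster.
#' @param cluster_radius geodesic radius in edge hops.
#' @param effect_size Cohen's d.
#' @return Object of class `effect_spec`.
#' @export
effect_spec <- function(feature = c("CT", "SA"),
                        analysis = c("T1", "delta", "T2"),
                        subgroup = "Decreaser",
                        seed_vertices = 1L, cluster_radius = 3L,
                        effect_size = 1.0) {
  feature <- match.arg(feature)
  analysis <- match.arg(analysis)
  structure(list(feature = feature, analysis = analysis, subgroup = subgroup,
                 seed_vertices = as.integer(seed_vertices),
                 cluster_radius = as.integer(cluster_radius),
                 effect_size = effect_size),
            class = "effect_spec")
}

#' Subjects-by-vertices metric stack
#'
#' @param values numeric `subjects x vertices` matrix.
#' @param feature `"SA"` or `"CT"`.
#' @param timepoint `"T1"`, `"T2"` or `"delta"`.
#' @param subject_ids character vector, one per row.
#' @return `vertex_metric_stack`: the matrix with row names set to the
#'   subject ids and `feature` / `timepoint` attributes.
#' @export
vertex_metric_stack <- function(values, feature, timepoint, subject_ids) {
  values <- as.matrix(values)
  stopifnot(length(subject_ids) == nrow(values))
  rownames(values) <- subject_ids
  attr(values, "feature") <- feature
  attr(values, "timepoint") <- timepoint
  class(values) <- c("vertex_metric_stack", class(values))
  values
}

#' Generate a full synthetic cohort
#'
#' Generates phenotypes ([generate_phenotypes()]) plus two-timepoint
#' vertex-wise surface-area and cortical-thickness maps on a spherical mesh,
#' with age/sex/site covariate structure, scalar subject intercepts,
#' spatially smooth noise and any planted effects. Total surface area
#' (cm^2) and mean cortical thickness (mm) per subject and timepoint are
#' computed from the generated maps and written into the phenotype table, so
#' the downstream total-brain covariates are internally consistent.
#'
#' @param spec a [cohort_spec()].
#' @param mesh a spherical `surface_mesh` (e.g. [build_icosphere()]).
#' @param effects list of [effect_spec()] objects.
#' @param features which metric stacks to generate.
#' @return List with `phenotypes`, `stacks` (nested `stacks$CT$T1` etc.,
#'   each a [vertex_metric_stack()]), `mesh`, and `planted` (per effect:
#'   affected vertices and the absolute planted magnitude per vertex).
#' @export
generate_cohort <- function(spec, mesh, effects = list(),
                            features = c("SA", "CT")) {
  if (!inherits(mesh, "surface_mesh")) stop("mesh must be a surface_mesh")
  if (!is_spherical(mesh))
    stop("mesh must be a (topologically and geometrically) spherical surface")
  ph <- generate_phenotypes(spec)       # seeds the RNG with spec$seed
  n <- nrow(ph)
  V <- nrow(mesh$vertices)
  male <- as.numeric(ph$sex == "M")
  site_ix <- as.integer(factor(ph$site))
  grp <- as.character(ph$outcome_generated)

  stacks <- list()
  planted <- list()
  for (feat in features) {
    if (feat == "CT") {
      pr <- spec$ct_params
      mu <- rep(pr$mean, V)
      scale_v <- rep(1, V)
    } else {
      pr <- spec$sa_params
      mu <- mesh$vertex_areas / mesh$total_area * pr$total_mean * 100  # mm^2
      scale_v <- mu
      pr <- list(mean = NA, age_slope = pr$age_slope_rel,
                 sex_effect = pr$sex_effect_rel,
                 subject_sd = pr$subject_sd_rel,
                 vertex_noise_sd = pr$vertex_noise_sd_rel,
                 site_sd = pr$site_sd_rel)
    }
    site_off <- stats::rnorm(spec$n_sites, 0, pr$site_sd)
    subj_int <- stats::rnorm(n, 0, pr$subject_sd)
    maps <- list()
    for (tp in c("T1", "T2")) {
      age <- if (tp == "T1") ph$age_t1 else ph$age_t2
      noise <- matrix(stats::rnorm(n * V, 0, pr$vertex_noise_sd), n, V)
      noise <- smooth_vertex_map(mesh, noise, spec$noise_fwhm)
      lin <- pr$age_slope * (age - 18) + pr$sex_effect * (male - 0.5) +
        site_off[site_ix] + subj_int
      maps[[tp]] <- matrix(mu, n, V, byrow = TRUE) +
        (outer(lin, rep(1, V)) + noise) * matrix(scale_v, n, V, byrow = TRUE)
    }
    # plant effects in within-group-SD units of the pre-effect T1 maps
    for (ef in effects) {
      if (ef$feature != feat) next
      verts <- sort(unique(unlist(lapply(ef$seed_vertices, function(v)
        vertex_neighborhood(mesh, v, ef$cluster_radius)))))
      sd_v <- apply(maps$T1[, verts, drop = FALSE], 2L, stats::sd)
      rows <- which(grp %in% ef$subgroup)
      if (!length(rows)) stop("planted effect targets an empty subgroup: ",
                              ef$subgroup)
      bump <- ef$effect_size * sd_v
      tps <- if (ef$analysis == "T1") c("T1", "T2") else "T2"
      for (tp in tps)
        maps[[tp]][rows, verts] <- maps[[tp]][rows, verts] +
          matrix(bump, length(rows), length(verts), byrow = TRUE)
      planted[[length(planted) + 1L]] <-
        list(feature = feat, analysis = ef$analysis, subgroup = ef$subgroup,
             vertices = verts, magnitude = bump)
    }
    stacks[[feat]] <- list(
      T1 = vertex_metric_stack(maps$T1, feat, "T1", ph$subject_id),
      T2 = vertex_metric_stack(maps$T2, feat, "T2", ph$subject_id))
    if (feat == "SA") {
      ph$total_sa_t1 <- rowSums(maps$T1) / 100
      ph$total_sa_t2 <- rowSums(maps$T2) / 100
    } else {
      ph$mean_ct_t1 <- rowMeans(maps$T1)
      ph$mean_ct_t2 <- rowMeans(maps$T2)
    }
  }
  list(phenotypes = ph, stacks = stacks, mesh = mesh, planted = planted)
}
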