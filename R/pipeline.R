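#' Pipeline run configuration
#'
#' One JSON-serializable document holding everything a pipeline run needs:
#' the simulation specifications (or input paths), the analysis grid, the
#' sensitivity switches and the statistical knobs. Unknown keys are
#' rejected, so a stale or misspelled config fails loudly.
#'
#' @param seed master seed; every stage derives its own stream from it.
#' @param mesh list: `subdivisions`, `radius` for [build_icosphere()], or
#'   `path` to an ASCII PLY surface.
#' @param cohort list of [cohort_spec()] arguments (simulation mode), or
#'   `list(path = ..., stacks = list(SA = c(T1 = ..., T2 = ...), ...))` for
#'   file inputs.
#' @param effects list of [effect_spec()] argument lists.
#' @param atlas list of [atlas_spec()] arguments, or `list(path = ...)`.
#' @param features,timepoints,comparisons the contrast grid; defaults are
#'   the full 3 subgroups x 2 features x 3 timepoints (18 contrasts).
#' @param total_brain,medication covariate toggles of the GLM designs.
#' @param exclude_id,exclude_medicated,age_band sensitivity filters.
#' @param stratify_basis,mcid outcome stratification rule.
#' @param alpha_form,alpha_cluster RFT thresholds (two-tailed).
#' @param n_spins,alpha_decode decoding knobs.
#' @return Object of class `run_config`.
#' @export
run_config <- function(seed = 1L,
                       mesh = list(subdivisions = 3L, radius = 50),
                       cohort = list(),
                       effects = list(),
                       atlas = list(n_genes = 500L, n_parcels = 100L),
                       features = c("SA", "CT"),
                       timepoints = c("T1", "delta", "T2"),
                       comparisons = c("Decreaser", "No-changer", "Increaser"),
                       total_brain = TRUE, medication = FALSE,
                       exclude_id = FALSE, exclude_medicated = FALSE,
                       age_band = NULL,
                       stratify_basis = "vabs_standard", mcid = 4,
                       alpha_form = 0.01, alpha_cluster = 0.01,
                       n_spins = 1000L, alpha_decode = 0.05) {
  cfg <- list(seed = as.integer(seed), mesh = mesh, cohort = cohort,
              effects = effects, atlas = atlas, features = features,
              timepoints = timepoints, comparisons = comparisons,
              total_brain = total_brain, medication = medication,
              exclude_id = exclude_id, exclude_medicated = exclude_medicated,
              age_band = age_band, stratify_basis = stratify_basis,
              mcid = mcid, alpha_form = alpha_form,
              alpha_cluster = alpha_cluster, n_spins = as.integer(n_spins),
              alpha_decode = alpha_decode)
  class(cfg) <- "run_config"
  cfg
}

#' Read / write a run configuration as JSON
#' @param config a [run_config()].
#' @param path JSON path.
#' @return `write_run_config` returns `path` invisibly; `read_run_config` a
#'   validated `run_config` (unknown keys are an error).
#' @export
write_run_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  do.call(run_config, raw)
}

contrast_id <- function(comparison, feature, timepoint) {
  paste(gsub("[^A-Za-z0-9]", "", comparison), feature, timepoint, sep = "_")
}

#' Run the full analysis pipeline
#'
#' End-to-end orchestration: simulate (or load) the cohort, derive outcome
#' labels, fit the vertex-wise GLM of every cell of the contrast grid,
#' apply RFT cluster correction per contrast (never pooling across features
#' or subgroups), decode each contrast's t-map against the expression
#' atlas, and test gene-set enrichment with one BH correction across all
#' contrast-by-set pairs. All outputs are plain text under `out_dir` with
#' fixed file names, and a `manifest.json` records the config, seed,
#' package version and per-stage counts. Two runs with the same config are
#' byte-identical.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_full_pipeline <- function(config, out_dir) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed

  ## --- inputs: simulate or load -------------------------------------------
  mesh <- if (!is.null(config$mesh$path)) read_ply(config$mesh$path)
          else build_icosphere(config$mesh$subdivisions, config$mesh$radius)
  stage <- function(...) message(sprintf(...))
  if (is.null(config$cohort$path)) {
    cargs <- config$cohort
    if (is.null(cargs$seed)) cargs$seed <- seed + 1L
    cspec <- do.call(cohort_spec, cargs)
    effects <- lapply(config$effects, function(e) do.call(effect_spec, e))
    stage("simulating cohort (n = %d)",
          sum(cspec$subgroup_sizes) + cspec$n_nt)
    cohort <- generate_cohort(cspec, mesh, effects,
                              features = config$features)
    ph <- cohort$phenotypes
    write_phenotypes(ph, file.path(out_dir, "phenotypes.csv"), spec = cspec)
  } else {
    ph <- read_phenotypes(config$cohort$path)
    cohort <- list(phenotypes = ph, stacks = list(), planted = list())
    for (feat in config$features)
      for (tp in c("T1", "T2"))
        cohort$stacks[[feat]][[tp]] <-
          read_stack(config$cohort$stacks[[feat]][[tp]], feat, tp)
  }

  ## --- stratify ------------------------------------------------------------
  ph <- add_outcome_labels(ph, basis = config$stratify_basis,
                           mcid = config$mcid)
  outcome_col <- paste0("outcome_", config$stratify_basis)
  ph <- apply_filters(ph, exclude_id = isTRUE(config$exclude_id),
                      exclude_medicated = isTRUE(config$exclude_medicated),
                      age_band = config$age_band, outcome_col = outcome_col)
  stage("stratified: %s", paste(names(table(ph[[outcome_col]])),
                                table(ph[[outcome_col]]), collapse = ", ",
                                sep = "="))

  ## --- GLM + RFT per contrast ---------------------------------------------
  contrasts <- list()
  tmaps <- list()
  for (comp in config$comparisons)
    for (feat in config$features)
      for (tp in config$timepoints) {
        id <- contrast_id(comp, feat, tp)
        stk <- if (tp == "delta")
          compute_change_stack(cohort$stacks[[feat]]$T1,
                               cohort$stacks[[feat]]$T2)
        else cohort$stacks[[feat]][[tp]]
        ds <- design_spec(feature = feat, analysis = tp, comparison = comp,
                          total_brain = isTRUE(config$total_brain),
                          medication = isTRUE(config$medication),
                          outcome_col = outcome_col)
        dsn <- tryCatch(make_design(ph, ds), error = function(e)
          stop("stage glm, contrast ", id, ": ", conditionMessage(e)))
        fit <- fit_vertex_glm(stk, dsn)
        cl <- tryCatch(
          rft_cluster_correct(fit, mesh, alpha_form = config$alpha_form,
                              alpha_cluster = config$alpha_cluster),
          error = function(e)
            stop("stage rft, contrast ", id, ": ", conditionMessage(e)))
        write_vertex_map(fit$t_map, file.path(out_dir,
                                              paste0("tmap_", id, ".tsv")))
        write_cluster_table(cl, file.path(out_dir,
                                          paste0("clusters_", id, ".csv")))
        tmaps[[id]] <- fit$t_map
        contrasts[[id]] <- list(
          comparison = comp, feature = feat, timepoint = tp,
          n_subjects = length(dsn$subject_ids), df = fit$df,
          n_clusters = nrow(cl), n_significant = sum(cl$significant),
          global_fwhm = attr(cl, "global_fwhm"))
        stage("contrast %s: %d clusters (%d significant)", id, nrow(cl),
              sum(cl$significant))
      }

  ## --- transcriptomic decoding + enrichment --------------------------------
  enrichment_file <- NULL
  decode_counts <- list()
  if (!is.null(config$atlas)) {
    if (is.null(config$atlas$path)) {
      aargs <- config$atlas
      if (is.null(aargs$seed)) aargs$seed <- seed + 2L
      aspec <- do.call(atlas_spec, aargs)
      parc <- build_parcellation(mesh, aspec$n_parcels, seed = seed + 3L)
      effect_maps <- list()
      for (pl in cohort$planted) {
        vmap <- numeric(nrow(mesh$vertices))
        vmap[pl$vertices] <- pl$magnitude
        effect_maps[[paste(pl$feature, pl$analysis, pl$subgroup, sep = "_")]] <-
          parcel_mean_map(vmap, parc)
      }
      gen <- generate_expression_atlas(aspec, mesh, parc, effect_maps)
      atlas <- gen$atlas
      gene_sets <- gen$gene_sets
      write_atlas(atlas, file.path(out_dir, "atlas.tsv"))
      if (length(gene_sets))
        write_gmt(gene_sets, file.path(out_dir, "gene_sets.gmt"))
    } else {
      atlas <- read_atlas(config$atlas$path, mesh)
      gene_sets <- if (!is.null(config$atlas$gene_sets))
        read_gmt(config$atlas$gene_sets) else list()
      parc <- atlas$parcellation
    }
    spins <- generate_spins(parc, config$n_spins, seed = seed + 4L)
    decoded_lists <- list()
    for (id in names(tmaps)) {
      pm <- parcel_mean_map(tmaps[[id]], parc)
      dec <- tryCatch(
        spatial_decode(pm, atlas, alpha = config$alpha_decode, spins = spins),
        error = function(e)
          stop("stage decode, contrast ", id, ": ", conditionMessage(e)))
      utils::write.csv(as.data.frame(dec),
                       file.path(out_dir, paste0("decoding_", id, ".csv")),
                       row.names = FALSE)
      decoded_lists[[id]] <- decoded_genes(dec)
      decode_counts[[id]] <- length(decoded_lists[[id]])
    }
    if (length(gene_sets)) {
      enr <- enrichment_table(decoded_lists, gene_sets, atlas$background,
                              alpha = 0.05)
      enrichment_file <- file.path(out_dir, "enrichment.csv")
      utils::write.csv(enr, enrichment_file, row.names = FALSE)
      stage("enrichment: %d pairs, %d significant", nrow(enr),
            sum(enr$significant))
    }
  }

  manifest <- list(
    config = unclass(config),
    package_version = as.character(utils::packageVersion("adaptsurf")),
    n_subjects = nrow(ph),
    n_autistic = sum(ph$diagnosis == "autistic"),
    n_neurotypical = sum(ph$diagnosis == "neurotypical"),
    subgroup_ns = as.list(table(ph[[outcome_col]])),
    contrasts = contrasts,
    decoded_counts = decode_counts,
    correction_pooling = list(
      across_features = "none", across_subgroups = "none",
      enrichment = "BH across all contrast x gene-set pairs"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(manifest)
}
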