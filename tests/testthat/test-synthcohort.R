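test_that("a fixed seed reproduces phenotypes and maps exactly", {
  m <- test_mesh3()
  spec <- small_cohort_spec(seed = 42)
  a <- generate_cohort(spec, m, features = "CT")
  b <- generate_cohort(spec, m, features = "CT")
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(unclass(a$stacks$CT$T1), unclass(b$stacks$CT$T1))
  expect_identical(unclass(a$stacks$CT$T2), unclass(b$stacks$CT$T2))
})

test_that("generated cohorts hit the requested group sizes", {
  ph <- generate_phenotypes(cohort_spec(seed = 2))
  expect_equal(sum(ph$diagnosis == "autistic"), 161L)
  expect_equal(sum(ph$diagnosis == "neurotypical"), 172L)
  expect_equal(as.integer(table(ph$outcome_generated)), c(53L, 42L, 66L))
  expect_true(all(ph$age_t2 > ph$age_t1))
})

test_that("generated composite change always respects the label's MCID interval", {
  for (s in 1:10) {
    ph <- generate_phenotypes(small_cohort_spec(seed = 100 + s))
    aut <- ph$diagnosis == "autistic"
    dv <- ph$vabs_standard_t2[aut] - ph$vabs_standard_t1[aut]
    lab <- ph$outcome_generated[aut]
    expect_true(all(dv[lab == "Decreaser"] <= -4))
    expect_true(all(dv[lab == "Increaser"] >= 4))
    expect_true(all(abs(dv[lab == "No-changer"]) < 4))
  }
})

test_that("labels round-trip through generation and MCID classification", {
  mismatches <- 0L
  for (s in 1:30) {
    ph <- add_outcome_labels(generate_phenotypes(small_cohort_spec(seed = s)))
    aut <- ph$diagnosis == "autistic"
    mismatches <- mismatches +
      sum(as.character(ph$outcome_generated[aut]) !=
            as.character(ph$outcome_vabs_standard[aut]))
  }
  expect_identical(mismatches, 0L)
})

test_that("subgroup change-score means match the truncated-normal expectation", {
  spec <- cohort_spec(seed = 1)
  iv <- list(Decreaser = c(-Inf, -4), `No-changer` = c(-4, 4),
             Increaser = c(4, Inf))
  draws <- list(Decreaser = c(), `No-changer` = c(), Increaser = c())
  for (s in 1:40) {
    ph <- generate_phenotypes(cohort_spec(seed = 1000 + s))
    aut <- ph$diagnosis == "autistic"
    dv <- ph$vabs_standard_t2[aut] - ph$vabs_standard_t1[aut]
    for (g in names(draws))
      draws[[g]] <- c(draws[[g]], dv[ph$outcome_generated[aut] == g])
  }
  for (g in names(draws)) {
    pars <- spec$delta_v_params[[g]]
    expected <- trunc_norm_mean(pars[1], pars[2], iv[[g]][1], iv[[g]][2])
    se <- sd(draws[[g]]) / sqrt(length(draws[[g]]))
    expect_lt(abs(mean(draws[[g]]) - expected), 3 * se)
  }
})

test_that("total-brain covariates are computed from the generated maps", {
  m <- test_mesh3()
  coh <- generate_cohort(small_cohort_spec(seed = 9), m)
  ph <- coh$phenotypes
  expect_equal(ph$total_sa_t1, rowSums(unclass(coh$stacks$SA$T1)) / 100,
               ignore_attr = TRUE)
  expect_equal(ph$mean_ct_t2, rowMeans(unclass(coh$stacks$CT$T2)),
               ignore_attr = TRUE)
  # plausible scales: thickness in mm, total area in cm^2
  expect_true(all(ph$mean_ct_t1 > 2 & ph$mean_ct_t1 < 3.5))
  expect_lt(abs(mean(ph$total_sa_t1) - 2293.4) / 2293.4, 0.05)
})

test_that("planted effects shift the target subgroup by the recorded magnitude", {
  m <- test_mesh3()
  eff <- effect_spec("CT", "T1", "Decreaser", seed_vertices = 50L,
                     cluster_radius = 4L, effect_size = 1.5)
  coh <- generate_cohort(small_cohort_spec(seed = 13), m,
                         effects = list(eff), features = "CT")
  pl <- coh$planted[[1]]
  ph <- coh$phenotypes
  Y <- unclass(coh$stacks$CT$T1)
  dec <- which(!is.na(ph$outcome_generated) & ph$outcome_generated == "Decreaser")
  nt <- which(ph$diagnosis == "neurotypical")
  dec_m <- rowMeans(Y[dec, pl$vertices, drop = FALSE])
  nt_m <- rowMeans(Y[nt, pl$vertices, drop = FALSE])
  gap <- mean(dec_m) - mean(nt_m)
  se <- sqrt(var(dec_m) / length(dec_m) + var(nt_m) / length(nt_m))
  # observed group gap approximates the planted magnitude (3-SE band)
  expect_lt(abs(gap - mean(pl$magnitude)), 3 * se)
  expect_error(generate_cohort(small_cohort_spec(seed = 1), m,
                               effects = list(effect_spec(subgroup = "Nope"))),
               "empty subgroup")
})

test_that("invalid cohort specs are rejected", {
  expect_error(cohort_spec(delta_t_mean = -1), "positive")
  expect_error(cohort_spec(delta_v_params = list(
    Decreaser = c(2, 8), `No-changer` = c(0, 2), Increaser = c(9.9, 5.5))),
    "MCID interval")
  expect_error(generate_cohort(small_cohort_spec(),
                               mesh = structure(list(), class = "list")),
               "surface_mesh")
})

test_that("expression atlas realizes the target correlations and writes GMT", {
  m <- test_mesh3()
  parc <- build_parcellation(m, 200, seed = 2)
  set.seed(5)
  target <- parcel_mean_map(smooth_vertex_map(m, rnorm(642), 20), parc)
  spec <- atlas_spec(n_genes = 1000, n_parcels = 200,
                     signal_sets = list(list(name = "sig", size = 50, r = 0.8,
                                             effect = "tgt"),
                                        list(name = "null", size = 50, r = 0,
                                             effect = "tgt")),
                     seed = 6)
  gen <- generate_expression_atlas(spec, m, parc, list(tgt = target))
  expect_equal(dim(gen$atlas$expr), c(1000L, 200L))
  # standardized rows
  expect_equal(unname(rowMeans(gen$atlas$expr)[1:5]), rep(0, 5),
               tolerance = 1e-12)
  zt <- as.numeric(scale(target))
  rr <- as.numeric(gen$atlas$expr %*% zt) / 199
  sig <- gen$atlas$genes %in% gen$gene_sets$sig
  nul <- gen$atlas$genes %in% gen$gene_sets$null
  expect_gt(mean(rr[sig]), 0.7)
  expect_lt(mean(rr[sig]), 0.9)
  expect_lt(abs(mean(rr[nul])), 3 * sd(rr[nul]) / sqrt(sum(nul)))
  # GMT bookkeeping round trip
  path <- tempfile(fileext = ".gmt")
  on.exit(unlink(path))
  write_gmt(gen$gene_sets, path)
  back <- read_gmt(path)
  expect_identical(back, gen$gene_sets)
  expect_length(back$sig, 50L)
  expect_true(all(back$sig %in% gen$atlas$genes))
})
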