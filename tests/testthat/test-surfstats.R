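test_that("design matrices carry the covariates of each analysis type", {
  ph <- add_outcome_labels(generate_phenotypes(small_cohort_spec(seed = 2)))
  ph$total_sa_t1 <- 2300 + rnorm(nrow(ph), 0, 50)
  ph$total_sa_t2 <- ph$total_sa_t1 + rnorm(nrow(ph), 0, 5)
  ph$mean_ct_t1 <- 2.7 + rnorm(nrow(ph), 0, 0.05)
  ph$mean_ct_t2 <- ph$mean_ct_t1 - 0.01

  d <- make_design(ph, design_spec("SA", "T1", "Decreaser"))
  expect_setequal(colnames(d$X),
                  c("intercept", "group", "sex", "age_t1", "fsiq",
                    "total_sa_t1", "site_site2", "site_site3", "site_site4"))
  expect_false("age_t1_sq" %in% colnames(d$X))  # SA has linear age only
  expect_equal(names(which(d$contrast == 1)), "group")

  d2 <- make_design(ph, design_spec("CT", "delta", "No-changer"))
  expect_true(all(c("age_t1_sq", "delta_t", "age_x_delta_t", "mean_ct_t1")
                  %in% colnames(d2$X)))
  d3 <- make_design(ph, design_spec("CT", "T2", "Increaser"))
  expect_true(all(c("age_t2", "age_t2_sq", "mean_ct_t2") %in% colnames(d3$X)))
  expect_false("age_t1" %in% colnames(d3$X))

  # covariate toggles drop exactly their columns
  d4 <- make_design(ph, design_spec("SA", "T1", "Decreaser",
                                    total_brain = FALSE))
  expect_setequal(setdiff(colnames(d$X), colnames(d4$X)), "total_sa_t1")
  d5 <- make_design(ph, design_spec("SA", "T1", "Decreaser",
                                    medication = TRUE))
  expect_true("medication" %in% colnames(d5$X))

  # only comparison rows are retained
  expect_equal(length(d$subject_ids),
               sum(ph$diagnosis == "neurotypical") +
                 sum(ph$outcome_vabs_standard %in% "Decreaser"))
  # dimensional design regresses on the continuous change within autism
  dd <- make_design(ph, design_spec("SA", "T1", "dimensional"))
  expect_equal(length(dd$subject_ids), sum(ph$diagnosis == "autistic"))
  expect_equal(names(which(dd$contrast == 1)), "delta_v")
})

test_that("collinear designs fail loudly naming the offending column", {
  ph <- add_outcome_labels(generate_phenotypes(small_cohort_spec(seed = 3)))
  ph$total_sa_t1 <- 1; ph$total_sa_t2 <- 1
  ph$mean_ct_t1 <- 2; ph$mean_ct_t2 <- 2
  ph$fsiq <- 2 * ph$age_t1   # exactly collinear with age after centring
  expect_error(make_design(ph, design_spec("CT", "T1", "Decreaser",
                                           total_brain = FALSE)),
               "collinear.*fsiq")
})

test_that("vertex-wise OLS matches an independent least-squares oracle", {
  m <- build_icosphere(1, 50)   # 42 vertices
  set.seed(8)
  n <- 25
  X <- cbind(intercept = 1, group = rep(0:1, length.out = n),
             age = rnorm(n), cov = rnorm(n))
  design <- list(X = X, contrast = c(0, 1, 0, 0),
                 subject_ids = sprintf("s%04d", 1:n))
  stk <- noise_stack(m, n)
  fit <- fit_vertex_glm(stk, design)
  expect_equal(fit$df, n - 4L)
  for (v in c(1L, 17L, 42L)) {
    orc <- ols_oracle(X, unclass(stk)[, v], design$contrast)
    expect_equal(fit$beta_map[v], orc$beta, tolerance = 1e-10)
    expect_equal(fit$t_map[v], orc$t, tolerance = 1e-10)
  }
  # residuals orthogonal to the design columns
  expect_lt(max(abs(crossprod(X, fit$residuals_std))), 1e-8)
})

test_that("constant responses give zero t and are flagged", {
  m <- build_icosphere(1, 50)
  n <- 12
  design <- plain_two_group_design(6)
  stk <- vertex_metric_stack(matrix(5, n, nrow(m$vertices)), "CT", "T1",
                             design$subject_ids)
  fit <- fit_vertex_glm(stk, design)
  expect_true(all(fit$t_map == 0))
  expect_length(fit$flagged, nrow(m$vertices))
})

test_that("with no covariates the vertex t equals the pooled two-sample t", {
  m <- build_icosphere(1, 50)
  set.seed(9)
  design <- plain_two_group_design(15)
  stk <- noise_stack(m, 30)
  fit <- fit_vertex_glm(stk, design)
  Y <- unclass(stk)
  for (v in c(3L, 30L)) {
    tt <- stats::t.test(Y[16:30, v], Y[1:15, v], var.equal = TRUE)
    expect_equal(fit$t_map[v], unname(tt$statistic), tolerance = 1e-10)
  }
})

test_that("t-maps are invariant to affine rescaling of covariates", {
  m <- test_mesh3()
  coh <- generate_cohort(small_cohort_spec(seed = 4), m, features = "CT")
  ph <- add_outcome_labels(coh$phenotypes)
  f1 <- fit_vertex_glm(coh$stacks$CT$T1,
                       make_design(ph, design_spec("CT", "T1", "Decreaser")))
  ph2 <- ph
  ph2$fsiq <- ph2$fsiq * 1000 - 77
  ph2$age_t1 <- ph2$age_t1 / 3 + 2
  f2 <- fit_vertex_glm(coh$stacks$CT$T1,
                       make_design(ph2, design_spec("CT", "T1", "Decreaser")))
  expect_equal(f1$t_map, f2$t_map, tolerance = 1e-8)
})

test_that("site dummies absorb planted site offsets", {
  m <- test_mesh3()
  base <- small_cohort_spec(seed = 21)
  noisy <- small_cohort_spec(seed = 21,
                             ct_params = list(mean = 2.69, age_slope = -0.010,
                                              sex_effect = 0.02,
                                              subject_sd = 0.09,
                                              vertex_noise_sd = 0.25,
                                              site_sd = 0.5))
  c1 <- generate_cohort(base, m, features = "CT")
  c2 <- generate_cohort(noisy, m, features = "CT")
  p1 <- add_outcome_labels(c1$phenotypes)
  p2 <- add_outcome_labels(c2$phenotypes)
  t1 <- fit_vertex_glm(c1$stacks$CT$T1,
                       make_design(p1, design_spec("CT", "T1", "Decreaser")))$t_map
  t2 <- fit_vertex_glm(c2$stacks$CT$T1,
                       make_design(p2, design_spec("CT", "T1", "Decreaser")))$t_map
  # same seed, same noise; huge site offsets change the group t-map only
  # marginally once site enters the model
  expect_gt(cor(t1, t2), 0.95)
  expect_lt(mean(abs(t1 - t2)), 0.35)
})

test_that("change stacks subtract timepoints and recover planted change effects", {
  m <- test_mesh3()
  stk1 <- noise_stack(m, 8)
  expect_true(all(unclass(compute_change_stack(stk1, stk1)) == 0))
  stk2 <- vertex_metric_stack(unclass(stk1) + 1, "CT", "T2", rownames(stk1))
  expect_equal(max(abs(unclass(compute_change_stack(stk1, stk2)) - 1)), 0,
               tolerance = 1e-12)
  bad <- vertex_metric_stack(unclass(stk1), "CT", "T2",
                             rev(rownames(stk1)))
  expect_error(compute_change_stack(stk1, bad), "misaligned")

  eff <- effect_spec("CT", "delta", "Increaser", seed_vertices = 111L,
                     cluster_radius = 4L, effect_size = 1)
  coh <- generate_cohort(small_cohort_spec(seed = 6), m,
                         effects = list(eff), features = "CT")
  dstk <- compute_change_stack(coh$stacks$CT$T1, coh$stacks$CT$T2)
  pl <- coh$planted[[1]]
  ph <- coh$phenotypes
  inc <- which(!is.na(ph$outcome_generated) & ph$outcome_generated == "Increaser")
  D <- unclass(dstk)[inc, , drop = FALSE]
  inside <- rowMeans(D[, pl$vertices, drop = FALSE])
  outside <- rowMeans(D[, -pl$vertices, drop = FALSE])
  se <- sqrt(var(inside) / length(inside) + var(outside) / length(outside))
  expect_lt(abs(mean(inside) - mean(outside) - mean(pl$magnitude)), 3 * se)
})
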