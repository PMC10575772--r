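# shared fixtures, built once per test run
.fix <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

test_mesh3 <- function() cached("mesh3", function() build_icosphere(3, 50))
test_mesh4 <- function() cached("mesh4", function() build_icosphere(4, 50))
test_mesh4_r30 <- function() cached("mesh4_r30", function() build_icosphere(4, 30))

# small but fully structured cohort for fast pipeline-level tests
small_cohort_spec <- function(seed = 1L, ...) {
  cohort_spec(n_nt = 40L,
              subgroup_sizes = c(Decreaser = 20L, `No-changer` = 15L,
                                 Increaser = 25L),
              sex_proportions = c(Decreaser = 0.4, `No-changer` = 0.3,
                                  Increaser = 0.3, neurotypical = 0.4),
              id_rates = c(Decreaser = 0.15, `No-changer` = 0.1,
                           Increaser = 0.1, neurotypical = 0.05),
              seed = seed, ...)
}

# manual two-column (intercept + group) design, for closed-form checks
plain_two_group_design <- function(n_per_group) {
  n <- 2L * n_per_group
  list(X = cbind(intercept = rep(1, n),
                 group = rep(c(0, 1), each = n_per_group)),
       contrast = c(intercept = 0, group = 1),
       subject_ids = sprintf("s%04d", seq_len(n)))
}

noise_stack <- function(mesh, n, fwhm = 0, sd = 1,
                        ids = sprintf("s%04d", seq_len(n))) {
  V <- nrow(mesh$vertices)
  Y <- matrix(stats::rnorm(n * V, 0, sd), n, V)
  if (fwhm > 0) Y <- smooth_vertex_map(mesh, Y, fwhm)
  vertex_metric_stack(Y, "CT", "T1", ids)
}
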