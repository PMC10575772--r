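#' Specification of one vertex-wise GLM design
#'
#' One comparison cell of the analysis grid: one autistic outcome subgroup
#' versus neurotypicals (or the continuous change score within autism) for
#' one cortical feature and one analysis type. The design follows the
#' study's covariate scheme: group and sex as factors; linear age (plus
#' quadratic age for cortical thickness); IQ; the total brain measure
#' matched to the feature (total surface area for SA, mean cortical
#' thickness for CT); site dummies. The change ("delta") design additionally
#' includes the inter-visit interval and its interaction with baseline age;
#' the T2 design uses age at T2.
#'
#' @param feature `"SA"` or `"CT"`.
#' @param analysis `"T1"`, `"delta"` or `"T2"`.
#' @param comparison an outcome-subgroup name (vs neurotypicals) or
#'   `"dimensional"` (continuous Vineland composite change within autism).
#' @param total_brain include the matched total-brain covariate.
#' @param medication include the medication flag.
#' @param site include site fixed-effect dummies.
#' @param outcome_col phenotype column holding the outcome labels.
#' @return Object of class `design_spec`.
#' @export
design_spec <- function(feature = c("CT", "SA"),
                        analysis = c("T1", "delta", "T2"),
                        comparison = "Decreaser",
                        total_brain = TRUE, medication = FALSE, site = TRUE,
                        outcome_col = "outcome_vabs_standard") {
  feature <- match.arg(feature)
  analysis <- match.arg(analysis)
  structure(list(feature = feature, analysis = analysis,
                 comparison = comparison, total_brain = total_brain,
                 medication = medication, site = site,
                 outcome_col = outcome_col),
            class = "design_spec")
}

#' Build a design matrix and contrast for one comparison
#'
#' Retains only the rows in the comparison (the subgroup plus all
#' neurotypicals, or autistic subjects only for the dimensional analysis)
#' and assembles the covariate columns for the requested analysis type.
#' Continuous covariates are mean-centred within the retained rows and the
#' quadratic age term is the square of the centred age, so the group
#' contrast is unaffected by covariate location. A rank-deficient design is
#' an error naming the collinear columns.
#'
#' @param phenotypes phenotype table with outcome labels assigned.
#' @param spec a [design_spec()].
#' @return List: `X` (design matrix), `contrast` (vector selecting the
#'   group/dimensional column), `subject_ids`, `spec`.
#' @export
make_design <- function(phenotypes, spec) {
  oc <- spec$outcome_col
  if (!oc %in% names(phenotypes))
    stop("phenotypes lack outcome column ", oc, "; run add_outcome_labels()")
  dimensional <- identical(spec$comparison, "dimensional")
  if (dimensional) {
    rows <- which(phenotypes$diagnosis == "autistic")
  } else {
    in_grp <- !is.na(phenotypes[[oc]]) &
      phenotypes[[oc]] == spec$comparison
    rows <- which(in_grp | phenotypes$diagnosis == "neurotypical")
    if (!any(in_grp)) stop("empty comparison group: ", spec$comparison)
  }
  ph <- phenotypes[rows, , drop = FALSE]
  n <- nrow(ph)

  ctr <- function(x) x - mean(x)
  need <- function(cols) {
    bad <- cols[!vapply(cols, function(cl) all(is.finite(ph[[cl]])), logical(1))]
    if (length(bad))
      stop("missing values in design columns: ", paste(bad, collapse = ", "))
  }

  cols <- list(intercept = rep(1, n))
  if (dimensional) {
    need(c("vabs_standard_t1", "vabs_standard_t2"))
    cols$delta_v <- ctr(change_score(ph$vabs_standard_t1, ph$vabs_standard_t2))
    cname <- "delta_v"
  } else {
    cols$group <- as.numeric(!is.na(ph[[oc]]) & ph[[oc]] == spec$comparison)
    cname <- "group"
  }
  need(c("age_t1", "age_t2", "delta_t", "fsiq"))
  cols$sex <- as.numeric(ph$sex == "M")
  age <- switch(spec$analysis, T1 = ph$age_t1, delta = ph$age_t1,
                T2 = ph$age_t2)
  age_name <- if (spec$analysis == "T2") "age_t2" else "age_t1"
  cols[[age_name]] <- ctr(age)
  if (spec$feature == "CT") cols[[paste0(age_name, "_sq")]] <- ctr(age)^2
  if (spec$analysis == "delta") {
    cols$delta_t <- ctr(ph$delta_t)
    cols$age_x_delta_t <- ctr(age) * ctr(ph$delta_t)
  }
  cols$fsiq <- ctr(ph$fsiq)
  if (isTRUE(spec$total_brain)) {
    tb <- if (spec$feature == "SA") {
      if (spec$analysis == "T2") "total_sa_t2" else "total_sa_t1"
    } else {
      if (spec$analysis == "T2") "mean_ct_t2" else "mean_ct_t1"
    }
    need(tb)
    cols[[tb]] <- ctr(ph[[tb]])
  }
  if (isTRUE(spec$medication)) {
    if (any(is.na(ph$medication_flag)))
      stop("missing values in design columns: medication_flag")
    cols$medication <- as.numeric(ph$medication_flag)
  }
  if (isTRUE(spec$site)) {
    sf <- factor(ph$site)
    if (nlevels(sf) > 1L)
      for (lv in levels(sf)[-1L])
        cols[[paste0("site_", lv)]] <- as.numeric(sf == lv)
  }
  X <- do.call(cbind, cols)
  colnames(X) <- names(cols)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dropped <- colnames(X)[qx$pivot[(qx$rank + 1L):ncol(X)]]
    stop("rank-deficient design; collinear columns: ",
         paste(dropped, collapse = ", "))
  }
  contrast <- as.numeric(names(cols) == cname)
  names(contrast) <- names(cols)
  list(X = X, contrast = contrast, subject_ids = ph$subject_id, spec = spec)
}

#' Vertex-wise ordinary least squares
#'
#' Fits the same design independently at every vertex by ordinary least
#' squares and returns the contrast t-map, effect map, and standardized
#' residuals for smoothness estimation. Residuals are scaled to unit
#' empirical variance per vertex, which makes the downstream smoothness
#' estimate invariant to any rescaling of the data. Vertices with exactly
#' zero residual variance get a `+/-Inf` (or 0) t sentinel and are flagged
#' rather than dropped.
#'
#' @param stack a [vertex_metric_stack()] whose rows cover the design rows.
#' @param design result of [make_design()].
#' @return Object of class `contrast_result`: `t_map`, `beta_map`, `df`,
#'   `residuals_std` (`n x V`), `flagged` (zero-variance vertices),
#'   `design`.
#' @export
fit_vertex_glm <- function(stack, design) {
  ids <- design$subject_ids
  miss <- setdiff(ids, rownames(stack))
  if (length(miss))
    stop("metric stack lacks subjects: ", paste(utils::head(miss, 3L),
                                                collapse = ", "))
  Y <- unclass(stack)[ids, , drop = FALSE]
  X <- design$X
  n <- nrow(X)
  p <- ncol(X)
  df <- n - p
  if (df <= 0) stop("non-positive residual degrees of freedom")
  XtXi <- chol2inv(chol(crossprod(X)))
  B <- XtXi %*% crossprod(X, Y)
  E <- Y - X %*% B
  ss <- colSums(E^2)
  cvec <- design$contrast
  beta <- as.numeric(cvec %*% B)
  cse <- sqrt(as.numeric(t(cvec) %*% XtXi %*% cvec))
  # zero residual variance up to numerical noise from the fit itself
  zerovar <- ss <= 1e-20 * pmax(colSums(Y^2), 1)
  flagged <- which(zerovar)
  sigma <- sqrt(ss / df)
  eps <- sqrt(1e-20 * pmax(colSums(Y^2), 1))
  t_map <- ifelse(!zerovar, beta / (sigma * cse),
                  ifelse(abs(beta) <= eps, 0, sign(beta) * Inf))
  sd_emp <- sqrt(ss / n)
  U <- sweep(E, 2L, ifelse(zerovar, 1, sd_emp), "/")
  structure(list(t_map = t_map, beta_map = beta, df = df,
                 residuals_std = U, flagged = flagged, design = design),
            class = "contrast_result")
}

#' Longitudinal change stack
#'
#' Elementwise `T2 - T1` metric change per subject and vertex. Interval
#' variation is handled downstream by the age-by-interval covariate, so the
#' change is deliberately left un-annualised.
#'
#' @param stack_t1,stack_t2 aligned [vertex_metric_stack()] objects.
#' @return A `vertex_metric_stack` with `timepoint = "delta"`.
#' @export
compute_change_stack <- function(stack_t1, stack_t2) {
  if (!identical(rownames(stack_t1), rownames(stack_t2)))
    stop("subject ids of the two stacks are misaligned")
  if (!identical(dim(stack_t1), dim(stack_t2)))
    stop("stack dimensions differ")
  vertex_metric_stack(unclass(stack_t2) - unclass(stack_t1),
                      attr(stack_t1, "feature"), "delta", rownames(stack_t1))
}
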