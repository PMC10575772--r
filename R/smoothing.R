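#' Surface smoothing by damped neighbour averaging
#'
#' Scalar fields on a mesh are smoothed by iterating the damped averaging
#' step `x <- (1 - relax) * x + relax * mean(neighbours of x)`. Iterating a
#' small-step local average approximates heat-kernel (Gaussian) smoothing on
#' the surface without any volumetric resampling; the iteration count is
#' calibrated so that a point impulse attains the requested full width at
#' half maximum (FWHM).
#'
#' @name smoothing
NULL

smoothing_operator <- function(mesh, relax = 0.1) {
  V <- nrow(mesh$vertices)
  deg <- lengths(mesh$neighbors)
  S <- Matrix::sparseMatrix(i = seq_len(V), j = seq_len(V), x = 1 - relax,
                            dims = c(V, V)) +
    Matrix::Diagonal(x = relax / deg) %*% mesh$adjacency
  methods::as(S, "CsparseMatrix")
}

# Gaussian-equivalent FWHM of a non-negative impulse response x centred at
# vertex v0, from its second spatial moment: for a 2-D Gaussian kernel
# E[d^2] = 2 sigma^2 and FWHM = sqrt(8 ln 2) sigma = sqrt(4 ln 2 E[d^2]).
impulse_fwhm <- function(x, d2) {
  p <- x / sum(x)
  sqrt(4 * log(2) * sum(p * d2))
}

#' Iteration count reaching a target FWHM
#'
#' Empirically calibrates the damped-averaging smoother: an impulse is placed
#' at a vertex and smoothed step by step, and the number of iterations whose
#' impulse response has Gaussian-equivalent FWHM closest to `fwhm_mm` is
#' returned. Calibration is deterministic (no randomness) and cached per
#' mesh geometry within a session.
#'
#' @param mesh a `surface_mesh`.
#' @param fwhm_mm target FWHM in mm; 0 returns 0 iterations.
#' @param relax damping weight of the averaging step, in (0, 1].
#' @return Integer iteration count.
#' @export
smoothing_iterations <- function(mesh, fwhm_mm, relax = 0.1) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  if (fwhm_mm == 0) return(0L)
  key <- sprintf("%d|%.6g|%.6g|%.4g", nrow(mesh$vertices), mesh$total_area,
                 fwhm_mm, relax)
  hit <- .smooth_cache[[key]]
  if (!is.null(hit)) return(hit)
  S <- smoothing_operator(mesh, relax)
  deg <- lengths(mesh$neighbors)
  v0 <- which.max(deg)  # a regular (maximum-degree) vertex
  V <- nrow(mesh$vertices)
  d2 <- rowSums((mesh$vertices -
                 matrix(mesh$vertices[v0, ], V, 3L, byrow = TRUE))^2)
  x <- numeric(V); x[v0] <- 1
  fw_prev <- 0
  kmax <- 100000L
  for (k in seq_len(kmax)) {
    x <- as.numeric(S %*% x)
    fw <- impulse_fwhm(x, d2)
    if (fw >= fwhm_mm) {
      k_star <- if (abs(fw_prev - fwhm_mm) < abs(fw - fwhm_mm)) k - 1L else k
      .smooth_cache[[key]] <- k_star
      return(k_star)
    }
    fw_prev <- fw
  }
  stop("requested FWHM not reachable (mesh too small relative to fwhm_mm)")
}

.smooth_cache <- new.env(parent = emptyenv())

#' Smooth one or many vertex maps
#'
#' @param mesh a `surface_mesh`.
#' @param values numeric vector of length `V`, or a `subjects x V` matrix
#'   (one map per row).
#' @param fwhm_mm target smoothing FWHM in mm; 0 is the identity.
#' @param relax damping weight passed to [smoothing_iterations()].
#' @return Smoothed values, same shape as the input. The map mean is
#'   preserved (the averaging operator is nearly doubly stochastic on
#'   quasi-uniform meshes) and the variance is non-increasing.
#' @export
smooth_vertex_map <- function(mesh, values, fwhm_mm, relax = 0.1) {
  if (fwhm_mm < 0) stop("fwhm_mm must be non-negative")
  k <- smoothing_iterations(mesh, fwhm_mm, relax)
  if (k == 0L) return(values)
  S <- smoothing_operator(mesh, relax)
  if (is.matrix(values)) {
    if (ncol(values) != nrow(mesh$vertices))
      stop("values must have one column per mesh vertex")
    St <- Matrix::t(S)
    out <- values
    for (i in seq_len(k)) out <- as.matrix(out %*% St)
    dimnames(out) <- dimnames(values)
    out
  } else {
    if (length(values) != nrow(mesh$vertices))
      stop("values must have one entry per mesh vertex")
    out <- values
    for (i in seq_len(k)) out <- as.numeric(S %*% out)
    out
  }
}
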