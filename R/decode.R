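#' Spin-test rotations of a parcellation
#'
#' Precomputes the parcel permutations used by the spin test: for each of
#' `n_spins` uniform random 3-D rotations (quaternion method), every parcel
#' centroid is rotated and re-assigned to the nearest original centroid.
#' Applying one permutation to a parcel map yields a null map with the same
#' spatial autocorrelation. One rotation sequence is shared by all genes
#' (and, in the pipeline, all contrasts) of a run, preserving gene-gene
#' dependence under the null.
#'
#' @param parcellation a [build_parcellation()] result.
#' @param n_spins number of rotations (>= 100).
#' @param seed RNG seed.
#' @return Integer matrix `n_parcels x n_spins` of source-parcel indices.
#' @export
generate_spins <- function(parcellation, n_spins, seed = 1L) {
  if (n_spins < 100L) stop("n_spins must be at least 100")
  set.seed(seed)
  C <- parcellation$centroids
  Cu <- C / sqrt(rowSums(C^2))
  P <- nrow(C)
  spins <- matrix(0L, P, n_spins)
  for (s in seq_len(n_spins)) {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    Rm <- rbind(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y)),
                c(2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x)),
                c(2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)))
    rot <- Cu %*% t(Rm)
    # value at parcel i comes from the parcel whose rotated centroid is nearest
    spins[, s] <- max.col(Cu %*% t(rot), ties.method = "first")
  }
  spins
}

#' Transcriptomic decoding of a brain map
#'
#' Correlates a parcel-level contrast map with every gene's spatial
#' expression pattern and assigns each gene a spin-test p-value: the null
#' distribution of |r| is built by recomputing the correlation against
#' spherically rotated versions of the map (the same rotations for all
#' genes), which preserves the map's spatial autocorrelation. The decoded
#' list is the set of genes with Benjamini-Hochberg q below `alpha`.
#'
#' @param map numeric parcel-level map (e.g. [parcel_mean_map()] of a
#'   t-map); must not be constant.
#' @param atlas an `expression_atlas`.
#' @param n_spins number of rotations (used when `spins` is NULL).
#' @param seed RNG seed for the rotations.
#' @param alpha BH-FDR threshold of the selection rule.
#' @param spins optional precomputed [generate_spins()] matrix, so several
#'   decodings can share one rotation sequence.
#' @return Object of class `decoding_result`: data frame with `gene`, `r`,
#'   `p_spin`, `q`, `decoded`; attributes `n_spins`, `alpha`.
#' @export
spatial_decode <- function(map, atlas, n_spins = 1000L, seed = 1L,
                           alpha = 0.05, spins = NULL) {
  if (length(map) != atlas$parcellation$n_parcels)
    stop("map length does not match the atlas parcellation")
  if (stats::sd(map) == 0)
    stop("constant map: correlation with expression is undefined")
  if (is.null(spins)) spins <- generate_spins(atlas$parcellation, n_spins, seed)
  n_spins <- ncol(spins)
  P <- length(map)
  Z <- atlas$expr                     # genes x parcels, rows standardized
  zm <- as.numeric(scale(map))
  r_obs <- as.numeric(Z %*% zm) / (P - 1)
  ZM <- apply(spins, 2L, function(ix) as.numeric(scale(map[ix])))
  r_null <- abs(Z %*% ZM) / (P - 1)   # genes x spins
  exceed <- rowSums(r_null >= abs(r_obs))
  p <- (1 + exceed) / (1 + n_spins)
  q <- bh_fdr(p)
  out <- data.frame(gene = atlas$genes, r = r_obs, p_spin = p, q = q,
                    decoded = q < alpha, stringsAsFactors = FALSE)
  structure(out, class = c("decoding_result", "data.frame"),
            n_spins = n_spins, alpha = alpha)
}

#' Decoded gene list of a decoding result
#' @param decoding a `decoding_result`.
#' @return Character vector of decoded gene ids.
#' @export
decoded_genes <- function(decoding) decoding$gene[decoding$decoded]

# two-sided Fisher exact p via the hypergeometric tail: sum of the
# probabilities of all tables (fixed margins) no more probable than the
# observed one, with the customary relative tolerance on ties
fisher_p2 <- function(a, b, c_, d) {
  K <- a + c_          # gene-set size
  n_dec <- a + b       # decoded size
  N <- a + b + c_ + d
  lo <- max(0L, n_dec - (N - K))
  hi <- min(K, n_dec)
  xs <- lo:hi
  dp <- stats::dhyper(xs, K, N - K, n_dec)
  p_obs <- stats::dhyper(a, K, N - K, n_dec)
  sum(dp[dp <= p_obs * (1 + 1e-7)])
}

#' Fisher odds-ratio enrichment of a decoded gene list
#'
#' Builds the 2x2 table of decoded-by-set membership over the background
#' universe, with `a` = decoded-and-in-set, `b` = decoded-not-in-set,
#' `c` = in-set-not-decoded, `d` = neither. The odds ratio is the sample
#' cross-product ratio `ad / bc` (0 when `a = 0`; `Inf` when `bc = 0` with
#' `ad > 0`) and the p-value is the two-sided Fisher exact test. An empty
#' decoded list or gene set yields an undefined OR and `p = 1`.
#'
#' @param decoded character vector of decoded genes (subset of background).
#' @param gene_set character vector (subset of background).
#' @param background character vector: the gene universe.
#' @return One-row data frame: `a`, `b`, `c`, `d`, `odds_ratio`, `p`,
#'   `or_defined`.
#' @export
fisher_enrichment <- function(decoded, gene_set, background) {
  decoded <- unique(decoded)
  gene_set <- unique(gene_set)
  if (length(setdiff(decoded, background)))
    decoded <- intersect(decoded, background)
  if (length(setdiff(gene_set, background)))
    gene_set <- intersect(gene_set, background)
  a <- length(intersect(decoded, gene_set))
  b <- length(setdiff(decoded, gene_set))
  c_ <- length(setdiff(gene_set, decoded))
  d <- length(background) - a - b - c_
  if (length(decoded) == 0L || length(gene_set) == 0L)
    return(data.frame(a = a, b = b, c = c_, d = d, odds_ratio = NA_real_,
                      p = 1, or_defined = FALSE))
  or <- if (a == 0) 0
        else if (b * c_ == 0) Inf
        else (a * d) / (b * c_)
  data.frame(a = a, b = b, c = c_, d = d, odds_ratio = or,
             p = fisher_p2(a, b, c_, d), or_defined = TRUE)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment,
#' `q_(i) = min_{j >= i} p_(j) m / j`, applied jointly to whatever family of
#' p-values is passed in; the pipeline passes every contrast-by-gene-set
#' pair of a run as one family.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return Vector of q-values, same order as `p`.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Joint enrichment table across contrasts and gene sets
#'
#' Runs [fisher_enrichment()] for every (contrast, gene set) pair and
#' applies one Benjamini-Hochberg correction across all pairs jointly.
#'
#' @param decoded_lists named list: decoded gene vector per contrast.
#' @param gene_sets named list of gene sets.
#' @param background the gene universe.
#' @param alpha significance threshold on q.
#' @return Data frame with `contrast`, `gene_set`, the 2x2 cells,
#'   `odds_ratio`, `p`, `q`, `significant`.
#' @export
enrichment_table <- function(decoded_lists, gene_sets, background,
                             alpha = 0.05) {
  rows <- list()
  for (ct in names(decoded_lists))
    for (gs in names(gene_sets)) {
      r <- fisher_enrichment(decoded_lists[[ct]], gene_sets[[gs]], background)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(contrast = ct, gene_set = gs,
                         stringsAsFactors = FALSE), r)
    }
  out <- do.call(rbind, rows)
  out$q <- bh_fdr(out$p)
  out$significant <- out$q < alpha
  rownames(out) <- NULL
  out
}
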