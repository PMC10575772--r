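#' Parcellate a spherical mesh
#'
#' Splits the vertices into `n_parcels` spatially compact parcels by
#' k-means on the vertex coordinates (deterministic given `seed`). Parcel
#' centroids are projected back onto the sphere; they are the coordinates
#' rotated by the spin test.
#'
#' @param mesh a spherical `surface_mesh`.
#' @param n_parcels number of parcels.
#' @param seed RNG seed for the k-means initialisation.
#' @return Object of class `parcellation`: `assignment` (vertex -> parcel),
#'   `centroids` (`n_parcels x 3`, on the sphere), `sizes`, `n_parcels`.
#' @export
build_parcellation <- function(mesh, n_parcels, seed = 1L) {
  V <- nrow(mesh$vertices)
  if (n_parcels < 2L || n_parcels > V) stop("invalid n_parcels")
  set.seed(seed)
  # a not-fully-converged k-means is still a valid compact partition, which
  # is all a parcellation needs; convergence chatter is not actionable here
  km <- suppressWarnings(stats::kmeans(mesh$vertices, centers = n_parcels,
                                       nstart = 5L, iter.max = 500L))
  cen <- km$centers
  r <- mean(sqrt(rowSums(mesh$vertices^2)))
  cen <- cen / sqrt(rowSums(cen^2)) * r
  structure(list(assignment = as.integer(km$cluster), centroids = cen,
                 sizes = as.integer(table(factor(km$cluster,
                                                 levels = seq_len(n_parcels)))),
                 n_parcels = as.integer(n_parcels)),
            class = "parcellation")
}

#' Reduce a vertex map to parcel means
#'
#' @param values numeric vector over vertices.
#' @param parcellation a [build_parcellation()] result.
#' @return Numeric vector of unweighted per-parcel means.
#' @export
parcel_mean_map <- function(values, parcellation) {
  if (length(values) != length(parcellation$assignment))
    stop("values length does not match the parcellation")
  if (any(parcellation$sizes == 0L)) stop("parcellation has an empty parcel")
  as.numeric(rowsum(values, parcellation$assignment, reorder = TRUE)) /
    parcellation$sizes
}

#' Specification of a synthetic expression atlas
#'
#' Parameters of the synthetic genes-by-parcels expression matrix. Signal
#' gene sets are built so each member gene's spatial expression pattern has
#' expected Pearson correlation `r` with a designated effect map; background
#' genes are independent spatially smooth random maps.
#'
#' @param n_genes,n_parcels atlas dimensions.
#' @param signal_sets list of `list(name, size, r, effect)` where `effect`
#'   names an entry of the `effect_maps` passed to
#'   [generate_expression_atlas()].
#' @param background_sets list of `list(name, size)`: control gene sets
#'   drawn from the non-signal genes.
#' @param expr_fwhm spatial smoothness (mm FWHM) of the per-gene noise maps.
#' @param seed RNG seed.
#' @return Object of class `atlas_spec`.
#' @export
atlas_spec <- function(n_genes = 1000L, n_parcels = 200L,
                       signal_sets = list(), background_sets = list(),
                       expr_fwhm = 20, seed = 1L) {
  spec <- structure(list(n_genes = as.integer(n_genes),
                         n_parcels = as.integer(n_parcels),
                         signal_sets = signal_sets,
                         background_sets = background_sets,
                         expr_fwhm = expr_fwhm, seed = as.integer(seed)),
                    class = "atlas_spec")
  sizes <- vapply(c(signal_sets, background_sets),
                  function(s) as.integer(s$size), integer(1))
  if (any(sizes > spec$n_genes)) stop("gene-set size exceeds n_genes")
  if (sum(vapply(signal_sets, function(s) as.integer(s$size), integer(1))) >
      spec$n_genes)
    stop("signal sets exceed the gene universe")
  rr <- vapply(signal_sets, function(s) s$r, numeric(1))
  if (length(rr) && any(abs(rr) >= 1)) stop("|target correlation| must be < 1")
  spec
}

#' Generate a synthetic expression atlas and gene sets
#'
#' Builds a genes-by-parcels expression matrix standardized per gene
#' (row mean 0, SD 1). Each signal-set gene is a mixture
#' `r * z(map) + sqrt(1 - r^2) * z(noise)` of the standardized target effect
#' map and an independent smooth noise map, so its correlation with the map
#' has expectation `r`; all remaining genes are smooth noise. Gene sets are
#' returned as a named list (writable as GMT, [write_gmt()]).
#'
#' @param spec an [atlas_spec()].
#' @param mesh the `surface_mesh` the noise fields live on.
#' @param parcellation parcellation matching `spec$n_parcels`.
#' @param effect_maps named list of parcel-level numeric vectors referenced
#'   by the signal sets.
#' @return List with `atlas` (an `expression_atlas`: `genes`, `expr`,
#'   `parcellation`, `background`) and `gene_sets`.
#' @export
generate_expression_atlas <- function(spec, mesh, parcellation,
                                      effect_maps = list()) {
  if (parcellation$n_parcels != spec$n_parcels)
    stop("parcellation does not match spec$n_parcels")
  if (spec$n_parcels < 10L)
    stop("target correlations are not estimable with so few parcels")
  set.seed(spec$seed)
  P <- spec$n_parcels
  G <- spec$n_genes
  V <- nrow(mesh$vertices)
  genes <- sprintf("G%05d", seq_len(G))

  std_rows <- function(M) {
    M <- t(scale(t(M)))
    attr(M, "scaled:center") <- NULL
    attr(M, "scaled:scale") <- NULL
    M
  }
  noise <- matrix(stats::rnorm(G * V), G, V)
  noise <- smooth_vertex_map(mesh, noise, spec$expr_fwhm)
  expr <- t(apply(noise, 1L, parcel_mean_map, parcellation = parcellation))
  expr <- std_rows(expr)  # per-gene mean 0, sd 1

  gene_sets <- list()
  next_gene <- 1L
  for (s in spec$signal_sets) {
    if (is.null(effect_maps[[s$effect]]))
      stop("signal set '", s$name, "' references unknown effect map '",
           s$effect, "'")
    zmap <- as.numeric(scale(effect_maps[[s$effect]]))
    if (!all(is.finite(zmap))) stop("constant effect map for set '", s$name, "'")
    idx <- next_gene:(next_gene + s$size - 1L)
    next_gene <- next_gene + as.integer(s$size)
    mix <- s$r * matrix(zmap, s$size, P, byrow = TRUE) +
      sqrt(1 - s$r^2) * expr[idx, , drop = FALSE]
    expr[idx, ] <- std_rows(mix)
    gene_sets[[s$name]] <- genes[idx]
  }
  pool <- setdiff(seq_len(G), seq_len(next_gene - 1L))
  for (s in spec$background_sets) {
    if (s$size > length(pool)) stop("background set larger than gene pool")
    pick <- sort(sample(pool, s$size))
    gene_sets[[s$name]] <- genes[pick]
  }
  rownames(expr) <- genes
  atlas <- structure(list(genes = genes, expr = expr,
                          parcellation = parcellation, background = genes),
                     class = "expression_atlas")
  list(atlas = atlas, gene_sets = gene_sets)
}

#' Restrict the gene universe of an atlas
#'
#' Returns the atlas with its background universe (and expression rows)
#' reduced to the given gene list, e.g. a cortically-expressed gene list for
#' the background sensitivity analysis. Decoding and enrichment run against
#' the reduced universe recompute all 2x2 margins accordingly.
#'
#' @param atlas an `expression_atlas`.
#' @param genes character vector; must intersect the atlas genes.
#' @return The reduced `expression_atlas`.
#' @export
restrict_background <- function(atlas, genes) {
  keep <- intersect(atlas$genes, genes)
  if (!length(keep)) stop("empty intersection with the atlas gene universe")
  atlas$expr <- atlas$expr[keep, , drop = FALSE]
  atlas$genes <- keep
  atlas$background <- keep
  atlas
}

#' Read and write GMT gene-set files
#'
#' Standard tab-separated GMT: one set per line, `name<TAB>description<TAB>`
#' then member genes.
#'
#' @param gene_sets named list of character vectors.
#' @param path file path.
#' @return `write_gmt` returns `path` invisibly; `read_gmt` the named list.
#' @export
write_gmt <- function(gene_sets, path) {
  lines <- vapply(names(gene_sets), function(nm)
    paste(c(nm, nm, gene_sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_gmt
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    f[-(1:2)]
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1), USE.NAMES = FALSE)
  out
}
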