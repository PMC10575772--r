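#' JSON sidecar for generated artefacts
#'
#' Every writer for generated data drops a `<file>.json` sidecar recording
#' the generating specification and seed, so any file on disk can be traced
#' back to its exact generating parameters.
#'
#' @param path path of the data file the sidecar describes.
#' @param spec the generating specification (any JSON-serializable list).
#' @param seed the seed used.
#' @return The sidecar path, invisibly.
#' @export
write_sidecar <- function(path, spec, seed = NULL) {
  side <- paste0(path, ".json")
  payload <- list(file = basename(path),
                  spec = unclass(spec),
                  seed = if (is.null(seed)) spec$seed else seed,
                  package = "adaptsurf",
                  version = as.character(utils::packageVersion("adaptsurf")))
  jsonlite::write_json(payload, side, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(side)
}

#' Phenotype table CSV I/O
#'
#' @param phenotypes phenotype data frame.
#' @param path CSV path.
#' @param spec optional generating [cohort_spec()] recorded in a sidecar.
#' @return `write_phenotypes` returns `path` invisibly; `read_phenotypes`
#'   the data frame (outcome columns restored as factors).
#' @export
write_phenotypes <- function(phenotypes, path, spec = NULL) {
  utils::write.csv(phenotypes, path, row.names = FALSE)
  if (!is.null(spec)) write_sidecar(path, spec)
  invisible(path)
}

#' @rdname write_phenotypes
#' @export
read_phenotypes <- function(path) {
  ph <- utils::read.csv(path, stringsAsFactors = FALSE)
  for (cl in grep("^outcome_", names(ph), value = TRUE))
    ph[[cl]] <- factor(ph[[cl]], levels = outcome_levels())
  ph
}

#' Vertex metric stack TSV I/O
#'
#' Subjects-by-vertices TSV: header row of vertex ids (`v1 ... vV`), first
#' column `subject_id`.
#'
#' @param stack a [vertex_metric_stack()].
#' @param path TSV path.
#' @return `write_stack` returns `path` invisibly; `read_stack` the stack.
#' @export
write_stack <- function(stack, path) {
  m <- unclass(stack)
  df <- data.frame(subject_id = rownames(m), m, check.names = FALSE)
  colnames(df) <- c("subject_id", paste0("v", seq_len(ncol(m))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_stack
#' @param feature,timepoint metadata restored on read.
#' @export
read_stack <- function(path, feature, timepoint) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  vertex_metric_stack(m, feature, timepoint, df[[1L]])
}

#' Write a per-vertex map as TSV
#' @param values numeric vector over vertices.
#' @param path TSV path (columns `vertex`, `value`).
#' @return `path`, invisibly.
#' @export
write_vertex_map <- function(values, path) {
  utils::write.table(data.frame(vertex = seq_along(values), value = values),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cluster table CSV
#' @param clusters a `cluster_table` from [rft_cluster_correct()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_cluster_table <- function(clusters, path) {
  df <- as.data.frame(clusters)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Expression atlas TSV I/O
#'
#' Genes-by-parcels TSV (first column `gene`), plus a parcel-assignment TSV
#' (`vertex`, `parcel`) written alongside as `<path>.parcels.tsv`.
#'
#' @param atlas an `expression_atlas`.
#' @param path TSV path.
#' @return `write_atlas` returns `path` invisibly; `read_atlas` the atlas
#'   (with a parcellation of assignment and sizes only; centroids are
#'   recomputed from the mesh by the caller if spins are needed).
#' @export
write_atlas <- function(atlas, path) {
  df <- data.frame(gene = atlas$genes, atlas$expr, check.names = FALSE)
  colnames(df) <- c("gene", paste0("p", seq_len(ncol(atlas$expr))))
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.table(
    data.frame(vertex = seq_along(atlas$parcellation$assignment),
               parcel = atlas$parcellation$assignment),
    paste0(path, ".parcels.tsv"), sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_atlas
#' @param mesh optional `surface_mesh` used to rebuild parcel centroids.
#' @export
read_atlas <- function(path, mesh = NULL) {
  df <- utils::read.delim(path, check.names = FALSE)
  expr <- as.matrix(df[, -1L, drop = FALSE])
  rownames(expr) <- df$gene
  pa <- utils::read.delim(paste0(path, ".parcels.tsv"))
  n_parcels <- ncol(expr)
  assignment <- as.integer(pa$parcel)
  cen <- NULL
  if (!is.null(mesh)) {
    cen <- rowsum(mesh$vertices, assignment, reorder = TRUE) /
      as.integer(table(factor(assignment, levels = seq_len(n_parcels))))
    r <- mean(sqrt(rowSums(mesh$vertices^2)))
    cen <- cen / sqrt(rowSums(cen^2)) * r
  }
  parc <- structure(list(assignment = assignment, centroids = cen,
                         sizes = as.integer(table(factor(assignment,
                                                levels = seq_len(n_parcels)))),
                         n_parcels = as.integer(n_parcels)),
                    class = "parcellation")
  structure(list(genes = df$gene, expr = expr, parcellation = parc,
                 background = df$gene),
            class = "expression_atlas")
}
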