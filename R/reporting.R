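# Normalisation, clustering and summary exports: RPM and row Z-score
# transforms, complete-linkage cityblock (L1) hierarchical clustering of
# samples, per-chromosome DMR distribution, and a heatmap-ready bundle.

#' Reads-per-million normalisation
#'
#' `RPM = 1e6 * count / sample_total`.
#' @param counts a `medseq_counts`, or a numeric matrix with `totals`
#'   supplied.
#' @param totals per-sample totals (required for a bare matrix).
#' @return numeric matrix of RPM values.
#' @export
rpm_normalize <- function(counts, totals = NULL) {
  if (inherits(counts, "medseq_counts")) {
    m <- counts$counts
    totals <- stats::setNames(counts$samples$total,
                              counts$samples$sample)[colnames(m)]
  } else {
    m <- as.matrix(counts)
    if (is.null(totals)) stop("`totals` required for a bare matrix",
                              call. = FALSE)
    if (!is.null(colnames(m)) && !is.null(names(totals)))
      totals <- totals[colnames(m)]
  }
  if (length(totals) != ncol(m))
    stop("need one total per sample", call. = FALSE)
  bad <- which(totals <= 0 | is.na(totals))
  if (length(bad))
    stop("zero or missing total for sample(s): ",
         paste(colnames(m)[bad], collapse = ", "), call. = FALSE)
  sweep(m, 2, unname(totals), function(x, t) 1e6 * x / t)
}

#' Row-wise Z-scores
#'
#' Per row: `(x - mean) / sd` with the population (divide-by-n) standard
#' deviation. Rows with zero variance are dropped with a warning.
#'
#' @param m numeric matrix with >= 2 columns.
#' @return matrix of Z-scores (possibly fewer rows); attribute
#'   `dropped_rows` lists dropped row indices.
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L)
    stop("Z-scoring needs at least 2 columns", call. = FALSE)
  mu <- rowMeans(m)
  sd_pop <- sqrt(rowMeans((m - mu)^2))
  zero <- sd_pop == 0 | is.na(sd_pop)
  if (any(zero))
    warning(sum(zero), " zero-variance row(s) dropped", call. = FALSE)
  z <- (m[!zero, , drop = FALSE] - mu[!zero]) / sd_pop[!zero]
  attr(z, "dropped_rows") <- which(zero)
  z
}

#' Complete-linkage cityblock hierarchical clustering of samples
#'
#' Agglomerative clustering of the matrix columns (samples) under L1
#' (cityblock/Manhattan) distance with complete linkage, via
#' [stats::hclust()]. Complete linkage guarantees monotone merge heights.
#'
#' @param m numeric matrix (rows = DMRs/regions, columns = samples), with
#'   no missing values and >= 2 columns.
#' @return a `medseq_clustering`: list with `hclust` (the stats::hclust
#'   object), `merge`, `height`, `leaf_order` (sample names in dendrogram
#'   order) and `cophenetic` (matrix of cophenetic heights).
#' @export
hierarchical_cluster <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2L) stop("clustering needs >= 2 samples", call. = FALSE)
  if (anyNA(m)) stop("matrix contains missing values", call. = FALSE)
  d <- stats::dist(t(m), method = "manhattan")
  hc <- stats::hclust(d, method = "complete")
  structure(list(
    hclust = hc,
    merge = hc$merge,
    height = hc$height,
    leaf_order = colnames(m)[hc$order],
    cophenetic = as.matrix(stats::cophenetic(hc))
  ), class = "medseq_clustering")
}

#' @export
print.medseq_clustering <- function(x, ...) {
  cat("Hierarchical clustering of", length(x$leaf_order),
      "samples (complete linkage, cityblock); max height",
      round(max(x$height), 3), "\n")
  invisible(x)
}

#' Cut a clustering into k groups
#' @param clustering a `medseq_clustering`.
#' @param k number of groups.
#' @return named integer vector of cluster labels per sample.
#' @export
cut_clusters <- function(clustering, k) {
  stats::cutree(clustering$hclust, k = k)
}

#' Per-chromosome DMR distribution
#'
#' @param dmrs DMR data.frame (optionally with a `group` column; absent,
#'   all DMRs form one group).
#' @param chrom_lengths optional named vector fixing the chromosome order
#'   (chromosomes with zero DMRs are included).
#' @return data.frame: group, chrom, n, percent (percentages sum to 100
#'   per group).
#' @export
chromosome_distribution <- function(dmrs, chrom_lengths = NULL) {
  if (!nrow(dmrs))
    return(data.frame(group = character(), chrom = character(),
                      n = integer(), percent = numeric()))
  group <- if ("group" %in% names(dmrs)) dmrs$group else "all"
  chroms <- if (!is.null(chrom_lengths)) names(chrom_lengths)
            else sort(unique(dmrs$chrom))
  out <- do.call(rbind, lapply(split(seq_len(nrow(dmrs)), group),
                               function(idx) {
    tab <- table(factor(dmrs$chrom[idx], levels = chroms))
    data.frame(group = group[idx[1]], chrom = names(tab),
               n = as.integer(tab),
               percent = 100 * as.integer(tab) / length(idx),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Export a heatmap-ready bundle
#'
#' Writes the Z-value matrix as TSV (rows/columns in dendrogram order)
#' and a JSON bundle with row order, leaf order, the linkage merge table
#' and heights. The pair round-trips losslessly via
#' [read_heatmap_bundle()].
#'
#' @param m normalised (Z-scored) matrix.
#' @param clustering a `medseq_clustering` of the matrix columns.
#' @param path output stem; writes `<path>.tsv` and `<path>.json`.
#' @export
export_heatmap_data <- function(m, clustering, path) {
  stopifnot(inherits(clustering, "medseq_clustering"))
  m <- as.matrix(m)
  if (!setequal(colnames(m), clustering$leaf_order))
    stop("matrix columns and clustering leaves differ", call. = FALSE)
  ord <- m[, clustering$leaf_order, drop = FALSE]
  df <- data.frame(row = if (is.null(rownames(m)))
    seq_len(nrow(m)) else rownames(m), ord, check.names = FALSE)
  utils::write.table(df, paste0(path, ".tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE)
  bundle <- list(
    columns = clustering$leaf_order,
    rows = df$row,
    merge = clustering$merge,
    height = clustering$height
  )
  jsonlite::write_json(bundle, paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' Read a heatmap bundle written by [export_heatmap_data()]
#' @param path the stem passed to [export_heatmap_data()].
#' @return list with `matrix` (columns in stored leaf order), `columns`,
#'   `merge`, `height`.
#' @export
read_heatmap_bundle <- function(path) {
  tab <- utils::read.table(paste0(path, ".tsv"), header = TRUE,
                           sep = "\t", check.names = FALSE)
  bundle <- jsonlite::read_json(paste0(path, ".json"),
                                simplifyVector = TRUE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  list(matrix = m, columns = bundle$columns,
       merge = bundle$merge, height = bundle$height)
}
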