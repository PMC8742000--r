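# Synthetic differential-expression table, wired to the planted DMRs so
# that methylation-expression concordance is controllable, plus the JSON
# truth manifest that records all planted ground truth.

#' Generate an expression table matched to planted DMRs
#'
#' For a controllable fraction of the genes whose promoter (TSS) or gene
#' body overlaps a planted DMR, the gene is made differentially expressed
#' with the direction the concordance rule expects (hypomethylated promoter
#' or hypermethylated gene body -> upregulated; hypermethylated promoter or
#' hypomethylated gene body -> downregulated) at `|log2FC| >= de_lfc` and
#' FDR < 0.05. All remaining genes receive null log2FC (small noise, below
#' the DE threshold) and FDR >= 0.05.
#'
#' @param region_set a `medseq_regions` (supplies the gene universe).
#' @param manifest planted-DMR data.frame (`profile$planted` from
#'   [plant_methylation()]) or a `medseq_profile`.
#' @param concordant_fraction fraction of DMR-overlapping genes made
#'   concordantly DE, in `[0, 1]`.
#' @param de_lfc magnitude of the DE log2 fold change (>= 1.5 so DE calls
#'   pass the default threshold).
#' @param seed integer seed.
#' @return list with `table` (data.frame gene_id, log2FC, FDR),
#'   `dmr_gene` (data.frame linking each gene-overlapping planted DMR to
#'   its gene, region kind, and whether it was made concordant).
#' @export
generate_expression_table <- function(region_set, manifest,
                                      concordant_fraction, de_lfc = 2,
                                      seed) {
  stopifnot(inherits(region_set, "medseq_regions"))
  if (inherits(manifest, "medseq_profile")) manifest <- manifest$planted
  concordant_fraction <- check_scalar(concordant_fraction,
                                      "concordant_fraction", 0, 1)
  de_lfc <- check_scalar(de_lfc, "de_lfc", min = 1.5)
  genes <- unique(region_set$regions$gene_id)
  genes <- genes[nzchar(genes)]
  if (!length(genes)) stop("region set contains no genes", call. = FALSE)

  links <- planted_dmr_genes(region_set, manifest)
  with_seed(seed, {
    n_conc <- round(concordant_fraction * nrow(links))
    conc_rows <- if (nrow(links)) sample(seq_len(nrow(links)), n_conc)
                 else integer()
    links$concordant <- seq_len(nrow(links)) %in% conc_rows

    log2fc <- stats::rnorm(length(genes), 0, 0.3)
    log2fc <- pmin(pmax(log2fc, -1.2), 1.2)  # keep null genes below DE lfc
    fdr <- stats::runif(length(genes), 0.05, 1)
    names(log2fc) <- names(fdr) <- genes
    for (k in which(links$concordant)) {
      g <- links$gene_id[k]
      log2fc[g] <- links$expected_sign[k] *
        (de_lfc + abs(stats::rnorm(1, 0, 0.25)))
      fdr[g] <- stats::runif(1, 0.0005, 0.04)
    }
    list(
      table = data.frame(gene_id = genes, log2FC = unname(log2fc[genes]),
                         FDR = unname(fdr[genes]),
                         stringsAsFactors = FALSE),
      dmr_gene = links
    )
  })
}

# link each planted DMR to the gene it overlaps (TSS preferred over body)
# and the expression sign the concordance rule expects for that overlap
#' @noRd
planted_dmr_genes <- function(region_set, planted) {
  empty <- data.frame(dmr = integer(), gene_id = character(),
                      kind = character(), direction = character(),
                      expected_sign = integer(), stringsAsFactors = FALSE)
  if (is.null(planted) || nrow(planted) == 0) return(empty)
  r <- region_set$regions
  genic <- r[r$kind %in% c("TSS", "gene_body"), , drop = FALSE]
  if (!nrow(genic)) return(empty)
  dmr_gr <- GenomicRanges::GRanges(planted$chrom,
                                   IRanges::IRanges(planted$start + 1L,
                                                    planted$end))
  reg_gr <- GenomicRanges::GRanges(genic$chrom,
                                   IRanges::IRanges(genic$start + 1L,
                                                    genic$end))
  hits <- GenomicRanges::findOverlaps(dmr_gr, reg_gr)
  if (!length(hits)) return(empty)
  df <- data.frame(dmr = S4Vectors::queryHits(hits),
                   gene_id = genic$gene_id[S4Vectors::subjectHits(hits)],
                   kind = genic$kind[S4Vectors::subjectHits(hits)],
                   stringsAsFactors = FALSE)
  # one link per DMR: prefer the promoter overlap when both exist
  df <- df[order(df$dmr, df$kind != "TSS"), , drop = FALSE]
  df <- df[!duplicated(df$dmr), , drop = FALSE]
  # one link per gene: a gene hit by two planted DMRs with conflicting
  # expectations would be ill-posed
  df <- df[!duplicated(df$gene_id), , drop = FALSE]
  df$direction <- planted$direction[df$dmr]
  df$expected_sign <- ifelse(
    (df$direction == "hypo" & df$kind == "TSS") |
      (df$direction == "hyper" & df$kind == "gene_body"), 1L, -1L)
  rownames(df) <- NULL
  df
}

#' Write an expression table as TSV (gene_id, log2FC, FDR)
#' @param table expression data.frame.
#' @param path output TSV.
#' @export
write_expression <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read an expression TSV (gene_id, log2FC, FDR)
#' @param path TSV path.
#' @export
read_expression <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Assemble and write a JSON truth manifest beside generated fixtures
#'
#' Records the planted DMRs (with direction and target fold change), the
#' planted DE genes with signed log2FC, per-sample library sizes and the
#' seeds used — the machine-readable ground truth downstream tests
#' compare against.
#'
#' @param profile a `medseq_profile`.
#' @param counts optional `medseq_counts`.
#' @param expression optional result of [generate_expression_table()].
#' @param path output JSON path; `NULL` returns the manifest invisibly
#'   without writing.
#' @export
write_truth_manifest <- function(profile, counts = NULL, expression = NULL,
                                 path = NULL) {
  stopifnot(inherits(profile, "medseq_profile"))
  manifest <- list(
    seed = profile$seed,
    baseline = profile$baseline,
    groups = profile$groups,
    planted_dmrs = profile$planted
  )
  if (!is.null(counts))
    manifest$samples <- counts$samples
  if (!is.null(expression)) {
    de <- expression$table[abs(expression$table$log2FC) >= 1.5 &
                             expression$table$FDR < 0.05, , drop = FALSE]
    manifest$planted_de_genes <- de
    manifest$dmr_gene_links <- expression$dmr_gene
  }
  if (!is.null(path))
    jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
  invisible(manifest)
}
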