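# Directional integration of DMRs with differential gene expression.
#
# The concordance rule: methylation of a promoter represses, methylation
# of a gene body accompanies transcription — so a hypomethylated promoter
# or hypermethylated gene body is matched to an upregulated gene, and a
# hypermethylated promoter or hypomethylated gene body to a downregulated
# gene.

#' Flag differentially expressed genes
#'
#' A gene is DE iff `|log2FC| >= lfc_threshold` (non-strict: "at least")
#' and `FDR < fdr_threshold` (strict).
#'
#' @param table data.frame with `gene_id`, `log2FC`, `FDR` (one row per
#'   gene; duplicates are an error).
#' @param lfc_threshold minimum |log2FC| (default 1.5).
#' @param fdr_threshold FDR cutoff (default 0.05).
#' @return the table with `de` (logical) and `sign` ("up"/"down"/NA)
#'   columns added.
#' @export
call_de_genes <- function(table, lfc_threshold = 1.5,
                          fdr_threshold = 0.05) {
  need <- c("gene_id", "log2FC", "FDR")
  if (!all(need %in% names(table)))
    stop("expression table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  dup <- table$gene_id[duplicated(table$gene_id)]
  if (length(dup))
    stop("duplicate gene_id in expression table: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (any(table$FDR < 0 | table$FDR > 1, na.rm = TRUE))
    stop("FDR values must lie in [0, 1]", call. = FALSE)
  table$de <- abs(table$log2FC) >= lfc_threshold &
    table$FDR < fdr_threshold
  table$sign <- ifelse(table$de, ifelse(table$log2FC > 0, "up", "down"),
                       NA_character_)
  table
}

#' Match DMRs to expression changes
#'
#' Each DMR is matched to the genes whose promoter (TSS) or gene body it
#' overlaps (from [annotate_dmrs()]). A DMR is concordant iff any
#' (direction, region kind, DE sign) combination fires the rule:
#' hypo+TSS+up, hyper+gene_body+up, hyper+TSS+down, or
#' hypo+gene_body+down. A CpG-island-only overlap is mapped to the
#' containing gene's promoter when the island overlaps a TSS region, else
#' the DMR is intergenic (`no_gene`). Genes absent from the expression
#' table yield `gene_not_DE` with a warning.
#'
#' @param dmrs annotated DMR data.frame (with `overlaps` list column).
#' @param expr expression table from [call_de_genes()] (or raw; thresholds
#'   applied with defaults).
#' @param regions optional `medseq_regions`, used to resolve
#'   CpG-island-only overlaps to promoters.
#' @return a `medseq_concordance`: list with `per_dmr` (data.frame: one
#'   row per DMR with verdict in {concordant, discordant, gene_not_DE,
#'   no_gene}, matched genes) and `pairs` (one row per DMR x gene).
#' @export
match_dmr_expression <- function(dmrs, expr, regions = NULL) {
  if (!"de" %in% names(expr)) expr <- call_de_genes(expr)
  if (!"overlaps" %in% names(dmrs))
    stop("DMRs must carry region overlaps (run annotate_dmrs first)",
         call. = FALSE)
  verdicts <- character(nrow(dmrs))
  genes_of <- character(nrow(dmrs))
  pairs <- list()
  missing_genes <- character()
  for (i in seq_len(nrow(dmrs))) {
    ov <- dmrs$overlaps[[i]]
    genic <- ov[ov$kind %in% c("TSS", "gene_body") & nzchar(ov$gene_id), ,
                drop = FALSE]
    if (!nrow(genic) && !is.null(regions) && nrow(ov))
      genic <- resolve_cpg_overlaps(ov, regions)
    if (!nrow(genic)) {
      verdicts[i] <- "no_gene"
      next
    }
    genic <- unique(genic[c("kind", "gene_id")])
    genes_of[i] <- paste(sort(unique(genic$gene_id)), collapse = ",")
    dmr_verdict <- "gene_not_DE"
    for (k in seq_len(nrow(genic))) {
      g <- genic$gene_id[k]
      row <- expr[expr$gene_id == g, , drop = FALSE]
      if (!nrow(row)) {
        missing_genes <- c(missing_genes, g)
        pair_verdict <- "gene_not_DE"
      } else if (!row$de) {
        pair_verdict <- "gene_not_DE"
      } else {
        pair_verdict <- if (concordance_rule(dmrs$direction[i],
                                             genic$kind[k], row$sign))
          "concordant" else "discordant"
      }
      pairs[[length(pairs) + 1L]] <- data.frame(
        dmr = i, gene_id = g, kind = genic$kind[k],
        direction = dmrs$direction[i], verdict = pair_verdict,
        stringsAsFactors = FALSE)
      # concordant if any rule fires; discordant beats gene_not_DE
      if (pair_verdict == "concordant") dmr_verdict <- "concordant"
      else if (pair_verdict == "discordant" &&
               dmr_verdict != "concordant") dmr_verdict <- "discordant"
    }
    verdicts[i] <- dmr_verdict
  }
  if (length(missing_genes))
    warning("gene(s) in DMR overlap absent from expression table: ",
            paste(unique(missing_genes), collapse = ", "), call. = FALSE)
  per_dmr <- data.frame(
    dmr = seq_len(nrow(dmrs)),
    chrom = dmrs$chrom, start = dmrs$start, end = dmrs$end,
    direction = dmrs$direction, genes = genes_of, verdict = verdicts,
    stringsAsFactors = FALSE)
  structure(list(per_dmr = per_dmr,
                 pairs = if (length(pairs)) do.call(rbind, pairs)
                         else data.frame()),
            class = "medseq_concordance")
}

#' The directional concordance rule
#'
#' TRUE iff (hypo, TSS, up), (hyper, gene_body, up), (hyper, TSS, down)
#' or (hypo, gene_body, down).
#' @param direction "hyper" or "hypo" (w.r.t. the focal group).
#' @param kind "TSS" or "gene_body".
#' @param sign "up" or "down".
#' @export
concordance_rule <- function(direction, kind, sign) {
  (direction == "hypo" & kind == "TSS" & sign == "up") |
    (direction == "hyper" & kind == "gene_body" & sign == "up") |
    (direction == "hyper" & kind == "TSS" & sign == "down") |
    (direction == "hypo" & kind == "gene_body" & sign == "down")
}

# CpG-island-only overlap: adopt the promoter of any gene whose TSS region
# the island intersects
#' @noRd
resolve_cpg_overlaps <- function(ov, regions) {
  empty <- data.frame(kind = character(), gene_id = character(),
                      stringsAsFactors = FALSE)
  cpg_ids <- ov$region_id[ov$kind == "CpG_island"]
  if (!length(cpg_ids)) return(empty)
  r <- regions$regions
  cpg <- r[r$region_id %in% cpg_ids, , drop = FALSE]
  tss <- r[r$kind == "TSS", , drop = FALSE]
  if (!nrow(tss)) return(empty)
  hits <- GenomicRanges::findOverlaps(
    GenomicRanges::GRanges(cpg$chrom,
                           IRanges::IRanges(cpg$start + 1L, cpg$end)),
    GenomicRanges::GRanges(tss$chrom,
                           IRanges::IRanges(tss$start + 1L, tss$end)))
  if (!length(hits)) return(empty)
  data.frame(kind = "TSS",
             gene_id = unique(tss$gene_id[S4Vectors::subjectHits(hits)]),
             stringsAsFactors = FALSE)
}

#' Summarise DMR-expression association
#'
#' Reports the fraction of all DMRs that are intergenic (`no_gene`), the
#' fraction of all DMRs concordant with a DE gene (the headline
#' "associated" fraction), the same fraction restricted to
#' gene-overlapping DMRs, and counts per verdict.
#'
#' @param report a `medseq_concordance`.
#' @return list with `n_dmrs`, `counts` (per verdict),
#'   `fraction_intergenic`, `fraction_associated` (denominator: all
#'   DMRs), `fraction_associated_genic` (denominator: gene-overlapping
#'   DMRs).
#' @export
summarize_association <- function(report) {
  stopifnot(inherits(report, "medseq_concordance"))
  v <- report$per_dmr$verdict
  if (!length(v)) stop("empty concordance report", call. = FALSE)
  counts <- table(factor(v, levels = c("concordant", "discordant",
                                       "gene_not_DE", "no_gene")))
  n <- length(v)
  n_genic <- sum(v != "no_gene")
  list(
    n_dmrs = n,
    counts = as.list(counts),
    fraction_intergenic = unname(counts["no_gene"]) / n,
    fraction_associated = unname(counts["concordant"]) / n,
    fraction_associated_genic =
      if (n_genic) unname(counts["concordant"]) / n_genic else NA_real_
  )
}

#' Write a concordance report (pairs TSV + JSON summary)
#' @param report a `medseq_concordance`.
#' @param path output stem; writes `<path>.tsv` and `<path>.json`.
#' @export
write_concordance <- function(report, path) {
  utils::write.table(report$per_dmr, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(summarize_association(report),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
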