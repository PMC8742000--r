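# Annotated region universe: promoter (TSS +/- 1 kb), gene body
# (1 kb downstream of the TSS to the TES) and CpG islands, plus the
# site -> region assignment used for region-level testing.

#' Build promoter, gene-body and CpG-island regions
#'
#' For a + strand gene spanning `[s, e)` the promoter (TSS) region is
#' `[s - tss_flank, s + tss_flank)` and the gene body `[s + tss_flank, e)`;
#' for a - strand gene the TSS region is `[e - tss_flank, e + tss_flank)`
#' and the body `[s, e - tss_flank)`. Gene bodies with non-positive length
#' are dropped with a warning. CpG islands pass through unchanged. Genes
#' with multiple records (transcripts) are collapsed to their union span per
#' `gene_id` before region construction. TSS regions extending past
#' chromosome ends are clipped to `[0, chrom_length)` when lengths are
#' supplied.
#'
#' @param genes a data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `gene_id`, `strand`, or a path to a BED6 (converted as-is)
#'   or GTF file (1-based closed coordinates converted on ingestion;
#'   gene/transcript features used).
#' @param cpg_islands optional data.frame with `chrom`, `start`, `end`, or a
#'   BED path; may be `NULL`.
#' @param tss_flank promoter half-width in bp (default 1000).
#' @param chrom_lengths optional named vector used to clip regions.
#' @return a `medseq_regions` object: data.frame `regions` with columns
#'   `region_id`, `chrom`, `start`, `end`, `kind` (TSS, gene_body,
#'   CpG_island), `gene_id`, `strand`.
#' @export
build_regions <- function(genes, cpg_islands = NULL, tss_flank = 1000,
                          chrom_lengths = NULL) {
  tss_flank <- check_count(tss_flank, "tss_flank", min = 1L)
  genes <- read_gene_table(genes)
  if (any(genes$start >= genes$end))
    stop("gene records must satisfy start < end", call. = FALSE)
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene records must carry strand '+' or '-'", call. = FALSE)

  # collapse multi-transcript genes to their union span
  key <- paste(genes$gene_id, genes$chrom, genes$strand, sep = "\r")
  genes <- do.call(rbind, lapply(split(genes, key), function(g) {
    data.frame(chrom = g$chrom[1], start = min(g$start), end = max(g$end),
               gene_id = g$gene_id[1], strand = g$strand[1],
               stringsAsFactors = FALSE)
  }))
  rownames(genes) <- NULL

  plus <- genes$strand == "+"
  tss_anchor <- ifelse(plus, genes$start, genes$end)
  tss <- data.frame(chrom = genes$chrom,
                    start = tss_anchor - tss_flank,
                    end = tss_anchor + tss_flank,
                    kind = "TSS", gene_id = genes$gene_id,
                    strand = genes$strand, stringsAsFactors = FALSE)
  body <- data.frame(chrom = genes$chrom,
                     start = ifelse(plus, genes$start + tss_flank,
                                    genes$start),
                     end = ifelse(plus, genes$end,
                                  genes$end - tss_flank),
                     kind = "gene_body", gene_id = genes$gene_id,
                     strand = genes$strand, stringsAsFactors = FALSE)
  empty_body <- body$end <= body$start
  if (any(empty_body)) {
    warning(sum(empty_body), " gene body region(s) of non-positive length ",
            "dropped (gene shorter than tss_flank): ",
            paste(utils::head(body$gene_id[empty_body], 5), collapse = ", "),
            call. = FALSE)
    body <- body[!empty_body, , drop = FALSE]
  }
  regions <- rbind(tss, body)
  if (!is.null(cpg_islands)) {
    cpg <- read_bed_intervals(cpg_islands)
    if (nrow(cpg))
      regions <- rbind(regions,
                       data.frame(chrom = cpg$chrom, start = cpg$start,
                                  end = cpg$end, kind = "CpG_island",
                                  gene_id = "", strand = ".",
                                  stringsAsFactors = FALSE))
  }
  regions$start <- pmax(regions$start, 0L)
  if (!is.null(chrom_lengths)) {
    len <- chrom_lengths[regions$chrom]
    clip <- !is.na(len)
    regions$end[clip] <- pmin(regions$end[clip], len[clip])
  }
  regions <- regions[order(regions$chrom, regions$start, regions$end,
                           regions$kind), , drop = FALSE]
  rownames(regions) <- NULL
  regions <- cbind(region_id = seq_len(nrow(regions)), regions)
  structure(list(regions = regions, tss_flank = tss_flank),
            class = "medseq_regions")
}

#' @export
print.medseq_regions <- function(x, ...) {
  cat("Region set:", nrow(x$regions), "regions (",
      paste(names(table(x$regions$kind)), table(x$regions$kind),
            collapse = ", "), ")\n")
  invisible(x)
}

#' @noRd
read_gene_table <- function(genes) {
  if (is.data.frame(genes)) {
    need <- c("chrom", "start", "end", "gene_id", "strand")
    if (!all(need %in% names(genes)))
      stop("gene data.frame needs columns: ", paste(need, collapse = ", "),
           call. = FALSE)
    return(genes[need])
  }
  if (!(is.character(genes) && length(genes) == 1L && file.exists(genes)))
    stop("`genes` must be a data.frame or an existing BED/GTF path",
         call. = FALSE)
  if (grepl("\\.gtf(\\.gz)?$", genes, ignore.case = TRUE)) {
    gr <- rtracklayer::import(genes, format = "gtf")
    gr <- gr[gr$type %in% c("gene", "transcript")]
    if (!length(gr)) stop("no gene/transcript features in GTF",
                          call. = FALSE)
    ids <- if (!is.null(gr$gene_id)) gr$gene_id else gr$gene_name
    return(data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                      start = BiocGenerics::start(gr) - 1L,  # 1-based -> 0-based
                      end = BiocGenerics::end(gr),
                      gene_id = ids,
                      strand = as.character(GenomicRanges::strand(gr)),
                      stringsAsFactors = FALSE))
  }
  gr <- rtracklayer::import(genes, format = "bed")
  if (is.null(gr$name))
    stop("BED gene annotation needs a name column (gene_id)", call. = FALSE)
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr),
             gene_id = gr$name,
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @noRd
read_bed_intervals <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    return(x[c("chrom", "start", "end")])
  }
  gr <- rtracklayer::import(x, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = BiocGenerics::start(gr) - 1L,
             end = BiocGenerics::end(gr), stringsAsFactors = FALSE)
}

#' @noRd
regions_granges <- function(region_set) {
  r <- region_set$regions
  GenomicRanges::GRanges(r$chrom,
                         IRanges::IRanges(r$start + 1L, r$end))
}

#' Assign catalogue sites to regions
#'
#' A site belongs to a region iff its motif start lies in `[start, end)`.
#' One site may belong to multiple regions; sites in no region map to the
#' empty set.
#'
#' @param catalog a `medseq_catalog`.
#' @param regions a `medseq_regions`.
#' @return a `medseq_sitemap`: list with `map` (data.frame `site_id`,
#'   `region_id`) and `region_sites` (list of site row indices per region,
#'   named by region_id).
#' @export
assign_sites <- function(catalog, regions) {
  stopifnot(inherits(catalog, "medseq_catalog"),
            inherits(regions, "medseq_regions"))
  s <- catalog$sites
  missing_chrom <- setdiff(unique(s$chrom), unique(regions$regions$chrom))
  site_gr <- GenomicRanges::GRanges(s$chrom,
                                    IRanges::IRanges(s$pos + 1L, width = 1L))
  hits <- GenomicRanges::findOverlaps(site_gr, regions_granges(regions))
  map <- data.frame(
    site_id = s$site_id[S4Vectors::queryHits(hits)],
    region_id = regions$regions$region_id[S4Vectors::subjectHits(hits)]
  )
  region_sites <- split(S4Vectors::queryHits(hits),
                        regions$regions$region_id[S4Vectors::subjectHits(hits)])
  structure(list(map = map, region_sites = region_sites,
                 n_sites = nrow(s)),
            class = "medseq_sitemap")
}

#' Write a region set as BED6 (name = kind:gene_id)
#' @param region_set a `medseq_regions`.
#' @param path output BED file.
#' @export
write_regions_bed <- function(region_set, path) {
  r <- region_set$regions
  gr <- GenomicRanges::GRanges(
    r$chrom, IRanges::IRanges(r$start + 1L, r$end),
    strand = ifelse(r$strand %in% c("+", "-"), r$strand, "*")
  )
  gr$name <- paste0(r$kind, ":", r$gene_id)
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}
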