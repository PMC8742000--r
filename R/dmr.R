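# The statistical core: chi-squared testing of pooled group read counts,
# multiple-testing correction, RPM fold changes, region-level tests, the
# genome-wide sliding-window DMR detector, and one-vs-rest group-unique
# DMR calling.
#
# Counts are pooled across the samples of each group before testing (the
# contrast compares the total reads generated per group); per-sample
# dispersion is deliberately not modelled.

#' DMR detection configuration
#'
#' Defaults follow the standard MeD-seq analysis: Bonferroni-corrected
#' per-site chi-squared at alpha 0.05, a two-fold change threshold for the
#' general analysis (five-fold is used when selecting rows for
#' hierarchical clustering), a minimum of ten significant LpnPI sites
#' spanning at least 100 bp, and window extension over at most 50
#' neighbouring sites per side within 1000 bp of the seed site.
#'
#' @param alpha significance level after correction.
#' @param correction "bonferroni" or "bh".
#' @param fc_threshold minimum fold change (must be > 1).
#' @param min_sites minimum significant sites per DMR.
#' @param min_span_bp minimum DMR span in bp.
#' @param max_neighbors maximum catalogue sites examined per side of a
#'   seed during window extension.
#' @param max_distance_bp maximum distance from the seed site's position.
#' @param pseudocount RPM pseudocount used in fold changes.
#' @export
dmr_config <- function(alpha = 0.05, correction = c("bonferroni", "bh"),
                       fc_threshold = 2, min_sites = 10, min_span_bp = 100,
                       max_neighbors = 50, max_distance_bp = 1000,
                       pseudocount = 0.5) {
  correction <- match.arg(correction)
  structure(list(
    alpha = check_scalar(alpha, "alpha", 0, 1, strict_min = TRUE),
    correction = correction,
    fc_threshold = check_scalar(fc_threshold, "fc_threshold", 1,
                                strict_min = TRUE),
    min_sites = check_count(min_sites, "min_sites", min = 1L),
    min_span_bp = check_count(min_span_bp, "min_span_bp", min = 1L),
    max_neighbors = check_count(max_neighbors, "max_neighbors", min = 1L),
    max_distance_bp = check_count(max_distance_bp, "max_distance_bp",
                                  min = 1L),
    pseudocount = check_scalar(pseudocount, "pseudocount", min = 0)
  ), class = "medseq_dmr_config")
}

#' Define a two-group contrast over a count matrix
#'
#' @param counts a `medseq_counts`.
#' @param group_a focal group name, or a character vector of sample names.
#' @param group_b rest group; defaults to all remaining samples
#'   (one-vs-rest).
#' @param name contrast label.
#' @export
group_contrast <- function(counts, group_a, group_b = NULL, name = NULL) {
  stopifnot(inherits(counts, "medseq_counts"))
  sm <- counts$samples
  pick <- function(x) {
    if (all(x %in% sm$group)) sm$sample[sm$group %in% x]
    else if (all(x %in% sm$sample)) x
    else stop("unknown sample or group: ",
              paste(setdiff(x, c(sm$group, sm$sample)), collapse = ", "),
              call. = FALSE)
  }
  samples_a <- pick(group_a)
  samples_b <- if (is.null(group_b)) setdiff(sm$sample, samples_a)
               else pick(group_b)
  if (length(intersect(samples_a, samples_b)))
    stop("contrast groups must be disjoint", call. = FALSE)
  if (!length(samples_a) || !length(samples_b))
    stop("both sides of the contrast need at least one sample",
         call. = FALSE)
  if (is.null(name))
    name <- paste0(if (length(group_a) == 1 && group_a[1] %in% sm$group)
                     group_a else "A", "_vs_rest")
  structure(list(name = name, samples_a = samples_a,
                 samples_b = samples_b), class = "medseq_contrast")
}

#' Pearson chi-squared test on a 2x2 read-count table
#'
#' Tests `[[a, total_a - a], [b, total_b - b]]` with 1 df and no
#' continuity correction. Returns statistic 0 and p 1 when any marginal is
#' zero. Vectorised over `a`/`b` (totals recycled).
#'
#' @param a,b reads in the site/region per pooled group.
#' @param total_a,total_b total reads per pooled group.
#' @return list with `statistic` and `p`.
#' @export
chi_squared_2x2 <- function(a, total_a, b, total_b) {
  if (any(c(a, b, total_a, total_b) < 0))
    stop("counts must be non-negative", call. = FALSE)
  if (any(total_a < a) || any(total_b < b))
    stop("totals must be >= counts", call. = FALSE)
  if (any(total_a + total_b <= 0))
    stop("total_a + total_b must be > 0", call. = FALSE)
  a2 <- total_a - a
  b2 <- total_b - b
  n <- total_a + total_b
  col1 <- a + b
  col2 <- a2 + b2
  stat <- ifelse(col1 == 0 | col2 == 0 | total_a == 0 | total_b == 0, 0,
                 n * (a * b2 - a2 * b)^2 /
                   (as.numeric(total_a) * total_b * col1 * col2))
  list(statistic = stat,
       p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Multiple-testing correction
#'
#' Thin wrapper over [stats::p.adjust()] restricted to the two procedures
#' used in the pipeline.
#' @param p vector of p-values in `[0, 1]`.
#' @param method "bonferroni" or "bh".
#' @export
adjust_pvalues <- function(p, method = c("bonferroni", "bh")) {
  method <- match.arg(method)
  if (!length(p)) return(numeric())
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = if (method == "bh") "BH" else "bonferroni")
}

#' RPM fold change between pooled groups
#'
#' `FC = (RPM_a + pc) / (RPM_b + pc)` with `RPM_x = 1e6 * x / total_x`;
#' the pseudocount (in RPM units) keeps the ratio finite at zero counts.
#' @param a,b counts; `total_a`,`total_b` pooled totals (> 0).
#' @param pseudocount RPM pseudocount (default 0.5).
#' @export
fold_change <- function(a, total_a, b, total_b, pseudocount = 0.5) {
  if (any(total_a <= 0) || any(total_b <= 0))
    stop("totals must be > 0", call. = FALSE)
  (1e6 * a / total_a + pseudocount) / (1e6 * b / total_b + pseudocount)
}

# pooled per-row counts and totals for a contrast (no RNG)
#' @noRd
pool_contrast <- function(counts, contrast) {
  stopifnot(inherits(counts, "medseq_counts"),
            inherits(contrast, "medseq_contrast"))
  missing <- setdiff(c(contrast$samples_a, contrast$samples_b),
                     counts$samples$sample)
  if (length(missing))
    stop("unknown sample(s) in contrast: ",
         paste(missing, collapse = ", "), call. = FALSE)
  ca <- rowSums(counts$counts[, contrast$samples_a, drop = FALSE])
  cb <- rowSums(counts$counts[, contrast$samples_b, drop = FALSE])
  ta <- sum(counts$samples$total[counts$samples$sample %in%
                                   contrast$samples_a])
  tb <- sum(counts$samples$total[counts$samples$sample %in%
                                   contrast$samples_b])
  if (ta <= 0 || tb <= 0)
    stop("pooled totals must be > 0 on both sides", call. = FALSE)
  list(c_a = ca, c_b = cb, t_a = ta, t_b = tb)
}

#' Region-level differential methylation tests
#'
#' Pools member-site counts per region and group, tests each region with
#' the 2x2 chi-squared against the pooled group totals, and corrects
#' across all tested regions of the same kind (BH by default for
#' region-level analysis). Regions with no assigned site are reported with
#' NA and excluded from correction.
#'
#' @param counts a `medseq_counts`.
#' @param sitemap a `medseq_sitemap` from [assign_sites()].
#' @param regions the `medseq_regions` the sitemap was built from.
#' @param contrast a `medseq_contrast`.
#' @param config a `dmr_config()`; region testing defaults to BH.
#' @return data.frame with one row per region: counts, FC, p, p_adj,
#'   direction, significant.
#' @export
test_regions <- function(counts, sitemap, regions, contrast,
                         config = dmr_config(correction = "bh")) {
  stopifnot(inherits(sitemap, "medseq_sitemap"),
            inherits(regions, "medseq_regions"))
  pooled <- pool_contrast(counts, contrast)
  r <- regions$regions
  ids <- as.character(r$region_id)
  agg <- function(v) vapply(ids, function(id) {
    idx <- sitemap$region_sites[[id]]
    if (is.null(idx)) NA_real_ else sum(v[idx])
  }, numeric(1))
  count_a <- agg(pooled$c_a)
  count_b <- agg(pooled$c_b)
  res <- data.frame(r, count_a = count_a, count_b = count_b,
                    n_sites = vapply(ids, function(id)
                      length(sitemap$region_sites[[id]]), integer(1)),
                    fc = NA_real_, p = NA_real_, p_adj = NA_real_,
                    direction = NA_character_, significant = FALSE,
                    row.names = NULL)
  has <- !is.na(count_a)
  if (any(has)) {
    test <- chi_squared_2x2(count_a[has], pooled$t_a, count_b[has],
                            pooled$t_b)
    res$p[has] <- test$p
    res$fc[has] <- fold_change(count_a[has], pooled$t_a, count_b[has],
                               pooled$t_b, config$pseudocount)
    res$direction[has] <- ifelse(res$fc[has] >= 1, "hyper", "hypo")
    # correction family: all tested regions of the same kind
    for (kind in unique(res$kind[has])) {
      sel <- has & res$kind == kind
      res$p_adj[sel] <- adjust_pvalues(res$p[sel], config$correction)
    }
    res$significant[has] <- res$p_adj[has] < config$alpha &
      (res$fc[has] >= config$fc_threshold |
         res$fc[has] <= 1 / config$fc_threshold)
  }
  res
}

#' Neighbouring catalogue sites examined during window extension
#'
#' For a seed site, the window spans at most `max_neighbors` catalogue
#' sites upstream and `max_neighbors` downstream whose position lies
#' within `max_distance_bp` of the seed site's position. Exposed so the
#' extension geometry is testable in isolation.
#'
#' @param positions sorted site positions on one chromosome.
#' @param seed_idx index of the seed site in `positions`.
#' @param max_neighbors per-side site budget.
#' @param max_distance_bp distance limit from the seed position.
#' @return list with `upstream` and `downstream` integer index vectors
#'   (excluding the seed itself).
#' @export
window_neighbors <- function(positions, seed_idx, max_neighbors = 50,
                             max_distance_bp = 1000) {
  p0 <- positions[seed_idx]
  up <- seq_len(seed_idx - 1L)
  up <- rev(up)[seq_len(min(max_neighbors, length(up)))]
  up <- up[p0 - positions[up] <= max_distance_bp]
  down <- seq(seed_idx + 1L, length.out = length(positions) - seed_idx)
  down <- down[seq_len(min(max_neighbors, length(down)))]
  down <- down[positions[down] - p0 <= max_distance_bp]
  list(upstream = sort(up), downstream = down)
}

#' Genome-wide sliding-window DMR detection
#'
#' Per-site chi-squared tests on pooled group counts are Bonferroni
#' corrected across all sites with nonzero pooled count (the correction
#' family excludes sites that cannot be tested a priori); a site is
#' significant iff its adjusted p is below `alpha` and its RPM fold change
#' is beyond `fc_threshold` in either direction. Each significant site
#' seeds a window collecting same-direction significant sites among at
#' most `max_neighbors` catalogue sites per side within `max_distance_bp`
#' of the seed. Candidates with at least `min_sites` significant sites
#' spanning at least `min_span_bp` are kept; candidates sharing any site
#' are merged, and pooled counts, fold change and p are recomputed over
#' all catalogue sites in the merged span (not only the significant
#' ones). Emitted DMRs are sorted, deduplicated, and all satisfy the
#' configured thresholds.
#'
#' @param counts a `medseq_counts` (carries its catalogue).
#' @param contrast a `medseq_contrast`.
#' @param config a `dmr_config()`.
#' @param annotation optional `medseq_regions`; when supplied, emitted
#'   DMRs are annotated with overlapping region kinds and gene ids (any
#'   overlap, partial or total).
#' @return data.frame of DMRs: chrom, start, end (half-open, first to
#'   last member-site motif), n_sites, n_significant, count_a, count_b,
#'   fc, direction, p, p_adj, and (with annotation) region_kinds,
#'   gene_ids; member site_ids attached as a list column `sites`.
#' @export
detect_dmrs <- function(counts, contrast, config = dmr_config(),
                        annotation = NULL) {
  stopifnot(inherits(counts, "medseq_counts"),
            inherits(config, "medseq_dmr_config"))
  catalog <- counts$catalog
  s <- catalog$sites
  mlen <- catalog$motif_length
  pooled <- pool_contrast(counts, contrast)

  # (1) per-site testing
  testable <- which(pooled$c_a + pooled$c_b > 0)
  p_site <- rep(NA_real_, nrow(s))
  if (length(testable)) {
    test <- chi_squared_2x2(pooled$c_a[testable], pooled$t_a,
                            pooled$c_b[testable], pooled$t_b)
    p_adj <- adjust_pvalues(test$p, "bonferroni")
    p_site[testable] <- p_adj
  }
  fc_site <- fold_change(pooled$c_a, pooled$t_a, pooled$c_b, pooled$t_b,
                         config$pseudocount)
  sig <- !is.na(p_site) & p_site < config$alpha &
    (fc_site >= config$fc_threshold | fc_site <= 1 / config$fc_threshold)
  dir_site <- ifelse(fc_site >= 1, "hyper", "hypo")

  empty <- dmr_frame(NULL, annotation)
  seeds <- which(sig)
  if (!length(seeds)) return(empty)

  # (2)-(3) window extension per seed, per chromosome
  candidates <- list()
  for (cn in unique(s$chrom[seeds])) {
    on_chrom <- which(s$chrom == cn)
    positions <- s$pos[on_chrom]
    sig_local <- sig[on_chrom]
    dir_local <- dir_site[on_chrom]
    for (k in which(sig_local)) {
      nb <- window_neighbors(positions, k, config$max_neighbors,
                             config$max_distance_bp)
      members <- c(nb$upstream, k, nb$downstream)
      members <- members[sig_local[members] &
                           dir_local[members] == dir_local[k]]
      if (length(members) < config$min_sites) next
      span <- positions[max(members)] + mlen - positions[min(members)]
      if (span < config$min_span_bp) next
      candidates[[length(candidates) + 1L]] <-
        list(chrom = cn, idx = on_chrom[members],
             direction = dir_local[k])
    }
  }
  if (!length(candidates)) return(empty)

  # (4) merge candidates sharing any site (union-find over site sets)
  merged <- merge_candidates(candidates)

  # recompute on the merged span over all catalogue sites
  rows <- lapply(merged, function(cand) {
    cn <- cand$chrom
    lo <- min(s$pos[cand$idx])
    hi <- max(s$pos[cand$idx]) + mlen
    span_idx <- which(s$chrom == cn & s$pos >= lo & s$pos + mlen <= hi)
    ca <- sum(pooled$c_a[span_idx])
    cb <- sum(pooled$c_b[span_idx])
    test <- chi_squared_2x2(ca, pooled$t_a, cb, pooled$t_b)
    fc <- fold_change(ca, pooled$t_a, cb, pooled$t_b, config$pseudocount)
    data.frame(chrom = cn, start = lo, end = hi,
               n_sites = length(span_idx),
               n_significant = sum(sig[span_idx]),
               count_a = ca, count_b = cb, fc = fc,
               direction = if (fc >= 1) "hyper" else "hypo",
               p = test$p, sites = I(list(s$site_id[span_idx])),
               stringsAsFactors = FALSE)
  })
  dmrs <- do.call(rbind, rows)
  # (5) enforce thresholds on the merged DMRs and emit sorted
  keep <- dmrs$n_significant >= config$min_sites &
    (dmrs$end - dmrs$start) >= config$min_span_bp &
    (dmrs$fc >= config$fc_threshold |
       dmrs$fc <= 1 / config$fc_threshold)
  dmrs <- dmrs[keep, , drop = FALSE]
  if (!nrow(dmrs)) return(empty)
  dmrs <- dmrs[order(dmrs$chrom, dmrs$start, dmrs$end), , drop = FALSE]
  dmrs <- dmrs[!duplicated(dmrs[c("chrom", "start", "end")]), ,
               drop = FALSE]
  dmrs$p_adj <- adjust_pvalues(dmrs$p, config$correction)
  rownames(dmrs) <- NULL
  dmrs$contrast <- contrast$name
  if (!is.null(annotation)) dmrs <- annotate_dmrs(dmrs, annotation)
  dmrs
}

#' @noRd
dmr_frame <- function(x, annotation) {
  out <- data.frame(chrom = character(), start = integer(),
                    end = integer(), n_sites = integer(),
                    n_significant = integer(), count_a = numeric(),
                    count_b = numeric(), fc = numeric(),
                    direction = character(), p = numeric(),
                    sites = I(list()), p_adj = numeric(),
                    contrast = character(), stringsAsFactors = FALSE)
  if (!is.null(annotation)) {
    out$region_kinds <- character()
    out$gene_ids <- character()
  }
  out
}

# merge candidate site sets that share any member (transitive closure)
#' @noRd
merge_candidates <- function(candidates) {
  n <- length(candidates)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1L, n)) {
      if (candidates[[i]]$chrom != candidates[[j]]$chrom) next
      if (length(intersect(candidates[[i]]$idx, candidates[[j]]$idx))) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[rj] <- ri
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(split(seq_len(n), roots), function(grp) {
    list(chrom = candidates[[grp[1]]]$chrom,
         idx = sort(unique(unlist(lapply(candidates[grp],
                                         function(c) c$idx)))))
  })
}

#' Annotate DMRs with overlapping regions
#'
#' Any overlap (partial or total) with a TSS, gene-body or CpG-island
#' region is reported.
#' @param dmrs a DMR data.frame from [detect_dmrs()].
#' @param regions a `medseq_regions`.
#' @return the DMR data.frame with `region_kinds`, `gene_ids` (comma
#'   separated) and an `overlaps` list column of per-DMR data.frames.
#' @export
annotate_dmrs <- function(dmrs, regions) {
  stopifnot(inherits(regions, "medseq_regions"))
  r <- regions$regions
  if (!nrow(dmrs)) {
    dmrs$region_kinds <- character()
    dmrs$gene_ids <- character()
    dmrs$overlaps <- I(list())
    return(dmrs)
  }
  dmr_gr <- GenomicRanges::GRanges(dmrs$chrom,
                                   IRanges::IRanges(dmrs$start + 1L,
                                                    dmrs$end))
  reg_gr <- GenomicRanges::GRanges(r$chrom,
                                   IRanges::IRanges(r$start + 1L, r$end))
  hits <- GenomicRanges::findOverlaps(dmr_gr, reg_gr)
  q <- S4Vectors::queryHits(hits)
  overlaps <- lapply(seq_len(nrow(dmrs)), function(i) {
    sub <- S4Vectors::subjectHits(hits)[q == i]
    data.frame(kind = r$kind[sub], gene_id = r$gene_id[sub],
               region_id = r$region_id[sub], stringsAsFactors = FALSE)
  })
  dmrs$region_kinds <- vapply(overlaps, function(o)
    paste(sort(unique(o$kind)), collapse = ","), character(1))
  dmrs$gene_ids <- vapply(overlaps, function(o)
    paste(sort(unique(o$gene_id[nzchar(o$gene_id)])), collapse = ","),
    character(1))
  dmrs$overlaps <- I(overlaps)
  dmrs
}

#' One-vs-rest group-unique DMR calling
#'
#' A DMR is unique to group `g` iff it was emitted by `g`'s one-vs-rest
#' contrast and has zero bp overlap with any DMR emitted by any other
#' contrast. The resulting per-group sets are disjoint by construction.
#'
#' @param dmrs_by_contrast named list (group -> DMR data.frame from that
#'   group's one-vs-rest contrast); needs >= 2 contrasts.
#' @return named list of DMR data.frames (unique DMRs per group).
#' @export
call_group_unique_dmrs <- function(dmrs_by_contrast) {
  if (length(dmrs_by_contrast) < 2L)
    stop("need at least 2 contrasts", call. = FALSE)
  all_chroms <- unique(unlist(lapply(dmrs_by_contrast, `[[`, "chrom")))
  grs <- lapply(dmrs_by_contrast, function(d) {
    gr <- if (!nrow(d)) GenomicRanges::GRanges()
          else GenomicRanges::GRanges(d$chrom,
                                      IRanges::IRanges(d$start + 1L, d$end))
    GenomeInfoDb::seqlevels(gr) <- all_chroms
    gr
  })
  out <- list()
  for (g in names(dmrs_by_contrast)) {
    d <- dmrs_by_contrast[[g]]
    if (!nrow(d)) {
      out[[g]] <- d
      next
    }
    other <- do.call(c, unname(grs[setdiff(names(grs), g)]))
    keep <- if (!length(other)) rep(TRUE, nrow(d))
            else !IRanges::overlapsAny(grs[[g]], other)
    out[[g]] <- d[keep, , drop = FALSE]
  }
  out
}

#' Write DMRs as BED6+ and TSV
#'
#' BED columns: chrom, start, end, name (DMR id), score
#' (-log10 adjusted p, capped at 1000), strand "."; extra columns in the
#' companion TSV: n_sites, n_significant, fc, direction, region overlaps
#' and gene ids.
#' @param dmrs DMR data.frame.
#' @param path output path (BED written to `path`, full table to
#'   `<path>.tsv`).
#' @export
write_dmrs_bed <- function(dmrs, path) {
  score <- ifelse(is.na(dmrs$p_adj) | dmrs$p_adj <= 0, 1000,
                  pmin(1000, -log10(dmrs$p_adj)))
  bed <- data.frame(dmrs$chrom, dmrs$start, dmrs$end,
                    sprintf("DMR_%04d", seq_len(nrow(dmrs))),
                    round(score, 3), ".")
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  flat <- dmrs[setdiff(names(dmrs), c("sites", "overlaps"))]
  utils::write.table(flat, paste0(path, ".tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
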