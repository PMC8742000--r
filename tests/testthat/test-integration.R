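# Directional DMR-expression integration and association summaries.

test_that("DE calling applies the |log2FC| >= 1.5 and FDR < 0.05 rule", {
  tab <- data.frame(
    gene_id = paste0("g", 1:5),
    log2FC = c(2.0, 1.4, -1.5, 1.5, -2.2),
    FDR = c(0.01, 0.001, 0.05, 0.049, 0.2))
  de <- call_de_genes(tab)
  expect_equal(de$de, c(TRUE, FALSE, FALSE, TRUE, FALSE))
  # (2.0, 0.01) -> DE up; (-1.5, 0.05) fails the strict FDR bound;
  # (1.5, 0.049) passes the non-strict lfc bound
  expect_equal(de$sign[1], "up")
  expect_equal(de$sign[4], "up")
  expect_error(call_de_genes(rbind(tab, tab[1, ])), "duplicate")
  expect_error(call_de_genes(transform(tab, FDR = FDR + 1)), "\\[0, 1\\]")
})

test_that("the concordance rule table is exhaustive over all 8 combinations", {
  grid <- expand.grid(direction = c("hyper", "hypo"),
                      kind = c("TSS", "gene_body"),
                      sign = c("up", "down"),
                      stringsAsFactors = FALSE)
  got <- with(grid, concordance_rule(direction, kind, sign))
  expected <- with(grid,
    (direction == "hypo" & kind == "TSS" & sign == "up") |
    (direction == "hyper" & kind == "gene_body" & sign == "up") |
    (direction == "hyper" & kind == "TSS" & sign == "down") |
    (direction == "hypo" & kind == "gene_body" & sign == "down"))
  expect_equal(got, expected)
  expect_equal(sum(got), 4)  # exactly half the table is concordant
  # and flipping the expression sign flips every verdict
  flipped <- with(grid, concordance_rule(
    direction, kind, ifelse(sign == "up", "down", "up")))
  expect_equal(flipped, !got)
})

make_dmr <- function(direction, kind, gene = "g1", chrom = "chr1",
                     start = 100, end = 400) {
  ov <- if (is.na(kind)) {
    data.frame(kind = character(), gene_id = character(),
               region_id = integer())
  } else {
    data.frame(kind = kind, gene_id = gene, region_id = 1L)
  }
  data.frame(chrom = chrom, start = start, end = end,
             direction = direction, overlaps = I(list(ov)),
             stringsAsFactors = FALSE)
}

test_that("DMR-expression matching assigns the four verdicts", {
  expr <- data.frame(gene_id = c("down_g", "up_g", "flat_g"),
                     log2FC = c(-2, 2, 0.1), FDR = c(0.01, 0.01, 0.9))
  dmrs <- rbind(
    make_dmr("hyper", "TSS", "down_g"),     # concordant
    make_dmr("hyper", "TSS", "up_g"),       # discordant
    make_dmr("hypo", "gene_body", "down_g"),# concordant
    make_dmr("hyper", "TSS", "flat_g"),     # gene_not_DE
    make_dmr("hyper", NA))                  # no_gene (intergenic)
  rep <- match_dmr_expression(dmrs, expr)
  expect_equal(rep$per_dmr$verdict,
               c("concordant", "discordant", "concordant",
                 "gene_not_DE", "no_gene"))
  # gene absent from the table -> gene_not_DE with a warning
  expect_warning(
    rep2 <- match_dmr_expression(make_dmr("hyper", "TSS", "ghost"), expr),
    "absent")
  expect_equal(rep2$per_dmr$verdict, "gene_not_DE")
})

test_that("a DMR overlapping both region kinds is concordant if any rule fires", {
  expr <- data.frame(gene_id = "g1", log2FC = 2, FDR = 0.01)
  both <- data.frame(
    chrom = "chr1", start = 100, end = 400, direction = "hyper",
    overlaps = I(list(data.frame(kind = c("TSS", "gene_body"),
                                 gene_id = "g1", region_id = 1:2))),
    stringsAsFactors = FALSE)
  rep <- match_dmr_expression(both, expr)
  # hyper+TSS+up is discordant but hyper+gene_body+up fires -> concordant
  expect_equal(rep$per_dmr$verdict, "concordant")
})

test_that("CpG-island-only overlaps resolve to promoters through the region set", {
  regions <- build_regions(
    data.frame(chrom = "chr1", start = 5000, end = 9000,
               gene_id = "g1", strand = "+"),
    cpg_islands = data.frame(chrom = "chr1", start = 4200, end = 4700))
  r <- regions$regions
  cpg_id <- r$region_id[r$kind == "CpG_island"]
  dmr <- data.frame(
    chrom = "chr1", start = 4250, end = 4600, direction = "hyper",
    overlaps = I(list(data.frame(kind = "CpG_island", gene_id = "",
                                 region_id = cpg_id))),
    stringsAsFactors = FALSE)
  expr <- data.frame(gene_id = "g1", log2FC = -2, FDR = 0.01)
  rep <- match_dmr_expression(dmr, expr, regions = regions)
  expect_equal(rep$per_dmr$verdict, "concordant")  # hyper promoter + down
  # without the region set the island overlap cannot be resolved
  rep0 <- match_dmr_expression(dmr, expr)
  expect_equal(rep0$per_dmr$verdict, "no_gene")
})

test_that("association summary partitions all DMRs and reports both denominators", {
  expr <- data.frame(gene_id = c("a", "b"), log2FC = c(-2, 0),
                     FDR = c(0.01, 0.9))
  dmrs <- rbind(
    make_dmr("hyper", "TSS", "a"),   # concordant
    make_dmr("hypo", "TSS", "a"),    # discordant
    make_dmr("hyper", "TSS", "b"),   # gene_not_DE
    make_dmr("hyper", NA),           # no_gene
    make_dmr("hyper", NA))           # no_gene
  s <- summarize_association(match_dmr_expression(dmrs, expr))
  expect_equal(s$n_dmrs, 5)
  expect_equal(sum(unlist(s$counts)), 5)
  expect_equal(s$fraction_intergenic, 2 / 5)
  expect_equal(s$fraction_associated, 1 / 5)
  expect_equal(s$fraction_associated_genic, 1 / 3)
})

test_that("generated concordant fraction is recovered by the integration summary", {
  # ~250 genes, each with a planted DMR in its promoter or body
  n_genes <- 250
  gene_start <- seq(2000, by = 12000, length.out = n_genes)
  genes <- data.frame(chrom = "chr1", start = gene_start,
                      end = gene_start + 8000,
                      gene_id = paste0("g", seq_len(n_genes)),
                      strand = "+")
  regions <- build_regions(genes)
  # planted DMRs alternate promoter/body placement and direction
  in_tss <- seq_len(n_genes) %% 2 == 0
  planted <- data.frame(
    chrom = "chr1",
    start = ifelse(in_tss, gene_start - 500, gene_start + 2000),
    end = ifelse(in_tss, gene_start + 100, gene_start + 2600),
    group = "A",
    direction = rep(c("hyper", "hypo"), length.out = n_genes),
    fc = 4, stringsAsFactors = FALSE)
  f <- 0.6
  ex <- generate_expression_table(regions, planted,
                                  concordant_fraction = f, seed = 17)
  dmrs <- data.frame(chrom = planted$chrom, start = planted$start,
                     end = planted$end, direction = planted$direction,
                     stringsAsFactors = FALSE)
  dmrs <- annotate_dmrs(dmrs, regions)
  rep <- match_dmr_expression(dmrs, ex$table)
  s <- summarize_association(rep)
  expect_gte(sum(rep$per_dmr$verdict != "no_gene"), 200)
  expect_lt(abs(s$fraction_associated_genic - f), 0.05)
})

test_that("concordance report writes a TSV and JSON summary", {
  expr <- data.frame(gene_id = "a", log2FC = -2, FDR = 0.01)
  rep <- match_dmr_expression(make_dmr("hyper", "TSS", "a"), expr)
  stem <- tempfile()
  write_concordance(rep, stem)
  expect_true(file.exists(paste0(stem, ".tsv")))
  back <- jsonlite::read_json(paste0(stem, ".json"))
  expect_equal(back$fraction_associated, 1)
})
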