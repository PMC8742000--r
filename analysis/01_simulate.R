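#!/usr/bin/env Rscript
# Stage 1 — build the synthetic study.
#
# Emulates a three-group methylome cohort (BAP1 / SF3B1 / EIF1AX mutated
# tumours) at toy scale: a two-chromosome genome with recognition sites
# every ~100 bp, group-specific planted DMRs, a per-site count matrix
# (8 samples per group, 100k filtered reads each), a gene + CpG-island
# annotation, and an expression table in which 60% of the genes carrying
# a planted promoter/gene-body DMR respond in the direction the
# concordance rule expects.

suppressMessages(library(medseqr))
dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
set_seed <- 20260930  # master seed for the whole workflow

message("generating toy genome ...")
genome <- generate_toy_genome(n_chrom = 2, chrom_length = 100000,
                              target_site_spacing = 100, seed = set_seed)
print(genome)
write_genome_fasta(genome, "results/data/genome.fa")
write_catalog(genome$catalog, "results/data/sites.tsv")

message("planting group-specific DMRs ...")
groups <- c("BAP1", "SF3B1", "EIF1AX")
# Two planted tiers. The moderate tier (effect 2.5) drives the
# group-unique analysis: its one-vs-rest "echo" (a focal group's private
# hypermethylation seen as mild hypomethylation from the other two
# contrasts, FC ~ 2/(2.5+1)) stays inside the two-fold dead band, so
# uniqueness is decidable. The strong tier (effect 8) provides the
# five-fold-change rows the clustering stage selects.
# Hypermethylation dominates, as in tumour methylomes.
profile <- plant_methylation(
  genome, groups, n_dmrs = 12, dmr_sites = 12,
  effect_fc = c(rep(2.5, 9), rep(8, 3)),
  baseline = 0.1, seed = set_seed + 1,
  directions = c("hyper", "hyper", "hypo",
                 "hypo", "hyper", "hyper",
                 "hyper", "hypo", "hyper",
                 rep("hyper", 3)),
  affected_groups = rep(groups, 4))
print(profile$planted)

message("simulating per-site counts ...")
counts <- simulate_count_matrix(profile, samples_per_group = 8,
                                mean_library_size = 1e5,
                                dispersion = 0.05, seed = set_seed + 2)
print(counts)
write_counts(counts, "results/data/counts.tsv")

message("building annotation ...")
# 6 kb genes every 10 kb on both strands; CpG islands at every third TSS
gene_start <- as.integer(outer(seq(3000, 90000, by = 10000),
                               c(0, 0), "+"))
genes <- data.frame(
  chrom = rep(c("chr1", "chr2"), each = 9),
  start = rep(seq(3000, 83000, by = 10000), 2),
  end = rep(seq(3000, 83000, by = 10000), 2) + 6000,
  gene_id = sprintf("gene%02d", 1:18),
  strand = rep(c("+", "-"), 9))
cpg <- data.frame(chrom = genes$chrom[seq(1, 18, by = 3)],
                  start = genes$start[seq(1, 18, by = 3)] - 300,
                  end = genes$start[seq(1, 18, by = 3)] + 300)
utils::write.table(
  cbind(genes[c("chrom", "start", "end", "gene_id")], score = 0,
        strand = genes$strand),
  "results/data/genes.bed", sep = "\t", quote = FALSE,
  row.names = FALSE, col.names = FALSE)
utils::write.table(cpg, "results/data/cpg_islands.bed", sep = "\t",
                   quote = FALSE, row.names = FALSE, col.names = FALSE)
regions <- build_regions(genes, cpg,
                         chrom_lengths = genome$catalog$chrom_lengths)
print(regions)

message("generating expression table ...")
expression <- generate_expression_table(regions, profile,
                                        concordant_fraction = 0.6,
                                        de_lfc = 2, seed = set_seed + 3)
write_expression(expression$table, "results/data/expression.tsv")
n_de <- sum(call_de_genes(expression$table)$de)
message("  ", nrow(expression$table), " genes, ", n_de, " DE, ",
        sum(expression$dmr_gene$concordant),
        " concordant with planted DMRs")

write_truth_manifest(profile, counts, expression,
                     path = "results/data/truth.json")
message("stage 1 done: fixtures and truth manifest in results/data/")
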