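# The synthetic-data generator: toy genomes, planted methylation,
# count simulation, digest reads, expression tables.

test_that("toy genome round-trips through the site scanner and hits the target density", {
  g <- fixture_genome()
  rescanned <- scan_sites(g$chromosomes, g$motif)
  expect_identical(rescanned$sites, g$catalog$sites)
  density <- nrow(g$catalog$sites) / (20000 / 100)
  expect_gt(density, 0.8)
  expect_lt(density, 1.2)
  expect_true(all(strsplit(as.character(g$chromosomes[[1]]), "")[[1]] %in%
                    c("A", "C", "G", "T")))
})

test_that("toy genome generation is deterministic and sorted per chromosome", {
  a <- generate_toy_genome(2, 5000, 100, seed = 1)
  b <- generate_toy_genome(2, 5000, 100, seed = 1)
  expect_identical(as.character(a$chromosomes), as.character(b$chromosomes))
  expect_identical(a$catalog$sites, b$catalog$sites)
  for (cn in c("chr1", "chr2")) {
    p <- a$catalog$sites$pos[a$catalog$sites$chrom == cn]
    expect_false(is.unsorted(p))
  }
  expect_error(generate_toy_genome(0, 5000, 100, seed = 1), "n_chrom")
  expect_error(generate_toy_genome(1, 500, 100, seed = 1), "chrom_length")
})

test_that("every recorded site carries the motif at the stated offset and strand", {
  g <- generate_toy_genome(1, 10000, 100, seed = 7)
  s <- g$catalog$sites
  expect_gt(nrow(s), 0)
  chrom <- g$chromosomes[[1]]
  for (i in seq_len(nrow(s))) {
    frag <- as.character(Biostrings::subseq(chrom, s$pos[i] + 1,
                                            s$pos[i] + 4))
    if (s$strand[i] == "-")
      frag <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(frag)))
    expect_match(frag, "^CC[AGT]G$")
  }
})

test_that("planted DMRs are disjoint, sized, and hit the target fold change", {
  g <- fixture_genome()
  prof <- plant_methylation(g, c("A", "B"), n_dmrs = 5, dmr_sites = 12,
                            effect_fc = 4, baseline = 0.1, seed = 3,
                            affected_groups = "A")
  expect_equal(nrow(prof$planted), 5)
  expect_true(all(prof$planted$n_sites >= 12))
  expect_true(all(prof$planted$end - prof$planted$start >= 100))
  # disjoint
  o <- order(prof$planted$start)
  p <- prof$planted[o, ]
  expect_true(all(utils::head(p$end, -1) <= utils::tail(p$start, -1)))
  # group-A mean probability ratio ~ effect_fc inside each planted DMR
  s <- g$catalog$sites
  for (k in seq_len(nrow(p))) {
    idx <- which(s$chrom == p$chrom[k] & s$pos >= p$start[k] &
                   s$pos < p$end[k])
    ratio <- mean(prof$prob[idx, "A"]) / mean(prof$prob[idx, "B"])
    expected <- if (p$direction[k] == "hyper") 4 else 1 / 4
    expect_equal(ratio, expected, tolerance = 1e-12)
  }
  expect_error(plant_methylation(g, c("A", "B"), 5, 12, 1.0, 0.1, seed = 3),
               "effect_fc")
  expect_error(plant_methylation(g, c("A", "B"), 500, 12, 4, 0.1, seed = 3),
               "capacity")
})

test_that("simulated counts track library sizes and are Poisson at zero dispersion", {
  g <- fixture_genome()
  prof <- plant_methylation(g, c("A", "B"), 2, 12, 4, 0.1, seed = 3)
  cm <- simulate_count_matrix(prof, 6, 1e5, dispersion = 0.05, seed = 11)
  expect_identical(cm$counts,
                   simulate_count_matrix(prof, 6, 1e5, 0.05,
                                         seed = 11)$counts)
  expect_true(all(abs(colSums(cm$counts) - cm$samples$library_size) /
                    cm$samples$library_size < 0.15))
  # Poisson limit: across many replicate samples, per-site variance ~ mean
  flat <- methylation_profile(g$catalog,
                              cbind(A = rep(0.2, nrow(g$catalog$sites)),
                                    B = rep(0.2, nrow(g$catalog$sites))))
  cp <- simulate_count_matrix(flat, 50, 1e5, dispersion = 0, seed = 2,
                              library_size_cv = 0)
  mu <- rowMeans(cp$counts)
  v <- apply(cp$counts, 1, stats::var)
  # variance/mean ratio concentrates around 1 for Poisson
  expect_equal(mean(v / mu), 1, tolerance = 0.1)
})

test_that("pooled RPM ratio inside planted DMRs recovers the target fold change", {
  # large catalogue, one small planted DMR -> negligible normalisation
  # dilution from the planted mass
  cc <- make_cluster_catalog(400, sites_per_cluster = 12,
                             n_background = 2000,
                             background_spacing = 150)
  prof <- two_group_profile(cc$catalog, cc$cluster_idx, fc = 4)
  cm <- simulate_count_matrix(prof, 6, 1e5, 0.05, seed = 5)
  idx <- cc$cluster_idx[[1]]
  a_samples <- cm$samples$sample[cm$samples$group == "A"]
  b_samples <- cm$samples$sample[cm$samples$group == "B"]
  rpm_a <- 1e6 * sum(cm$counts[idx, a_samples]) /
    sum(cm$samples$total[cm$samples$group == "A"])
  rpm_b <- 1e6 * sum(cm$counts[idx, b_samples]) /
    sum(cm$samples$total[cm$samples$group == "B"])
  expect_equal(rpm_a / rpm_b, 4, tolerance = 0.4)
})

test_that("digest reads are 32 bp after adapter removal and pass the filter", {
  g <- fixture_genome()
  prof <- plant_methylation(g, c("A", "B"), 2, 12, 4, 0.1, seed = 3)
  rd <- simulate_digest_reads(g, prof, "A", 1000, read_length = 50,
                              adapter = ILLUMINA_ADAPTER, seed = 5)
  expect_equal(sum(rd$truth), 1000)
  expect_true(all(nchar(rd$reads$seq) == 50))
  trimmed <- trim_adapter(rd$reads$seq, ILLUMINA_ADAPTER, rd$reads$qual)
  expect_true(all(nchar(trimmed$seq) == 32))
  expect_true(all(position_filter(trimmed$seq)$pass))
  # empty case
  rd0 <- simulate_digest_reads(g, prof, "A", 0, seed = 5)
  expect_equal(nrow(rd0$reads), 0)
  expect_equal(sum(rd0$truth), 0)
  expect_error(simulate_digest_reads(g, prof, "nope", 10, seed = 1),
               "not found in profile")
})

test_that("identical seeds give byte-identical FASTQ", {
  g <- fixture_genome()
  prof <- plant_methylation(g, c("A", "B"), 2, 12, 4, 0.1, seed = 3)
  f1 <- tempfile(fileext = ".fastq")
  f2 <- tempfile(fileext = ".fastq")
  write_fastq(simulate_digest_reads(g, prof, "A", 200, seed = 9)$reads, f1)
  write_fastq(simulate_digest_reads(g, prof, "A", 200, seed = 9)$reads, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("generated DE genes obey the thresholds and concordant fraction 0 means none", {
  g <- fixture_genome()
  genes <- data.frame(
    chrom = "chr1",
    start = seq(0, 16000, by = 4000),
    end = seq(0, 16000, by = 4000) + 3500,
    gene_id = paste0("g", 1:5), strand = "+")
  regions <- build_regions(genes, tss_flank = 1000,
                           chrom_lengths = g$catalog$chrom_lengths)
  prof <- plant_methylation(g, c("A", "B"), 3, 12, 4, 0.1, seed = 3)
  ex1 <- generate_expression_table(regions, prof, concordant_fraction = 1,
                                   de_lfc = 2, seed = 4)
  de <- call_de_genes(ex1$table)
  expect_true(all(abs(de$log2FC[de$de]) >= 1.5))
  expect_true(all(de$FDR[de$de] < 0.05))
  expect_true(all(ex1$dmr_gene$concordant))
  ex0 <- generate_expression_table(regions, prof, concordant_fraction = 0,
                                   de_lfc = 2, seed = 4)
  expect_false(any(ex0$dmr_gene$concordant))
  expect_false(any(call_de_genes(ex0$table)$de))
  expect_error(generate_expression_table(regions, prof, 1.2, seed = 1),
               "concordant_fraction")
})

test_that("truth manifest serialises planted ground truth as JSON", {
  g <- fixture_genome()
  prof <- plant_methylation(g, c("A", "B"), 2, 12, 4, 0.1, seed = 3)
  cm <- simulate_count_matrix(prof, 3, 1e5, 0, seed = 1)
  path <- tempfile(fileext = ".json")
  write_truth_manifest(prof, cm, path = path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$seed, 3)
  expect_equal(nrow(back$planted_dmrs), 2)
  expect_setequal(back$samples$sample, cm$samples$sample)
})
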