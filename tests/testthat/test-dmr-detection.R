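# The statistical core: 2x2 chi-squared, corrections, fold change,
# region tests, the sliding-window detector and group-unique calling.

test_that("2x2 chi-squared matches the closed form and handles degenerate margins", {
  # identical proportions -> no signal
  r <- chi_squared_2x2(10, 1000, 10, 1000)
  expect_equal(r$statistic, 0)
  expect_equal(r$p, 1)
  # hand-computed Pearson: [[10, 0], [0, 10]] -> N (ad-bc)^2 / products = 20
  r <- chi_squared_2x2(10, 10, 0, 10)
  expect_equal(r$statistic, 20)
  expect_equal(r$p, stats::pchisq(20, 1, lower.tail = FALSE))
  # zero marginal -> (0, 1)
  expect_equal(chi_squared_2x2(0, 100, 0, 200)$statistic, 0)
  expect_equal(chi_squared_2x2(100, 100, 200, 200)$p, 1)
  # preconditions
  expect_error(chi_squared_2x2(0, 0, 0, 0), "> 0")
  expect_error(chi_squared_2x2(-1, 10, 0, 10), "non-negative")
  expect_error(chi_squared_2x2(11, 10, 0, 10), ">=")
})

test_that("chi-squared agrees with stats::chisq.test on 1000 random tables", {
  set.seed(99)
  for (i in 1:1000) {
    a <- sample(1:500, 1); b <- sample(1:500, 1)
    ta <- a + sample(1:5000, 1); tb <- b + sample(1:5000, 1)
    ours <- chi_squared_2x2(a, ta, b, tb)
    ref <- suppressWarnings(
      stats::chisq.test(matrix(c(a, ta - a, b, tb - b), 2, byrow = TRUE),
                        correct = FALSE))
    expect_lt(abs(ours$statistic - unname(ref$statistic)), 1e-9)
    expect_lt(abs(ours$p - ref$p.value), 1e-9)
  }
})

test_that("multiple-testing corrections match hand-computed vectors", {
  expect_equal(adjust_pvalues(c(0.01, 0.4), "bonferroni"), c(0.02, 0.8))
  # BH step-up by hand: 0.04*4/4, 0.03*4/3, 0.02*4/2, 0.01*4/1 ->
  # cummin from the largest rank gives 0.04 for all
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03, 0.04), "bh"),
               rep(0.04, 4))
  # hand-computed BH on an uneven vector
  p <- c(0.005, 0.011, 0.02, 0.04, 0.8)
  expect_equal(adjust_pvalues(p, "bh"),
               c(0.025, 0.0275, 0.03333333333333333, 0.05, 0.8),
               tolerance = 1e-12)
  expect_equal(adjust_pvalues(1, "bonferroni"), 1)
  expect_equal(adjust_pvalues(numeric(), "bh"), numeric())
  expect_error(adjust_pvalues(c(0.5, 1.2), "bh"), "\\[0, 1\\]")
})

test_that("fold change is RPM-based, pseudocounted and library-size invariant", {
  expect_equal(fold_change(20, 1e6, 10, 1e6, pseudocount = 0), 2)
  expect_equal(fold_change(0, 1e6, 0, 1e6, pseudocount = 0.5), 1)
  # library-size invariance
  expect_equal(fold_change(40, 2e6, 10, 1e6, pseudocount = 0), 2)
  expect_error(fold_change(1, 0, 1, 10), "> 0")
})

test_that("region-level tests flag planted regions and respect zero regions", {
  cc <- make_cluster_catalog(c(400, 400), sites_per_cluster = 12,
                             n_background = 150)
  prof <- two_group_profile(cc$catalog, cc$cluster_idx[1], fc = 4)
  cm <- simulate_count_matrix(prof, 6, 1e5, 0.05, seed = 21)
  s <- cc$catalog$sites
  genes <- data.frame(
    chrom = "chr1",
    start = c(s$pos[cc$cluster_idx[[1]][1]] - 1000,
              s$pos[cc$cluster_idx[[2]][1]] - 1000),
    end = c(s$pos[tail(cc$cluster_idx[[1]], 1)[1]] + 1000,
            s$pos[tail(cc$cluster_idx[[2]], 1)[1]] + 1000),
    gene_id = c("planted", "flat"), strand = "+")
  regions <- build_regions(genes)
  sm <- assign_sites(cc$catalog, regions)
  ctr <- group_contrast(cm, "A")
  res <- test_regions(cm, sm, regions, ctr)
  planted_rows <- res[res$gene_id == "planted", ]
  flat_rows <- res[res$gene_id == "flat", ]
  expect_true(any(planted_rows$significant))
  expect_equal(planted_rows$direction[planted_rows$significant][1], "hyper")
  expect_false(any(flat_rows$significant))
  # contrast with overlapping sample sets is rejected
  expect_error(group_contrast(cm, cm$samples$sample[1:6],
                              cm$samples$sample[6:12]), "disjoint")
})

test_that("window extension honours the neighbour and distance budgets", {
  pos <- seq(0, by = 5, length.out = 200)
  nb <- window_neighbors(pos, 100, max_neighbors = 50,
                         max_distance_bp = 1000)
  expect_equal(length(nb$upstream), 50)
  expect_equal(length(nb$downstream), 50)
  expect_equal(nb$upstream, 50:99)
  expect_equal(nb$downstream, 101:150)
  # distance limit binds before the budget on a sparse catalogue
  sparse <- seq(0, by = 400, length.out = 50)
  nb2 <- window_neighbors(sparse, 25, 50, 1000)
  expect_equal(length(nb2$upstream), 2)
  expect_equal(length(nb2$downstream), 2)
  # edges
  nb3 <- window_neighbors(pos, 1, 50, 1000)
  expect_equal(length(nb3$upstream), 0)
})

test_that("sliding-window detector recovers planted DMRs with correct direction", {
  cc <- make_cluster_catalog(c(400, 300, 500), sites_per_cluster = 12,
                             n_background = 300)
  prof <- two_group_profile(cc$catalog, cc$cluster_idx, fc = 4,
                            directions = c("hyper", "hypo", "hyper"))
  cm <- simulate_count_matrix(prof, 6, 1e5, 0.05, seed = 31)
  dmrs <- detect_dmrs(cm, group_contrast(cm, "A"))
  expect_equal(nrow(dmrs), 3)
  s <- cc$catalog$sites
  for (k in 1:3) {
    planted_lo <- s$pos[cc$cluster_idx[[k]][1]]
    planted_hi <- s$pos[tail(cc$cluster_idx[[k]], 1)] + 4
    hit <- which(dmrs$start < planted_hi & dmrs$end > planted_lo)
    expect_length(hit, 1)
    # >= 50% reciprocal overlap
    ov <- min(dmrs$end[hit], planted_hi) - max(dmrs$start[hit], planted_lo)
    expect_gte(ov / (planted_hi - planted_lo), 0.5)
    expect_gte(ov / (dmrs$end[hit] - dmrs$start[hit]), 0.5)
    expect_equal(dmrs$direction[hit],
                 c("hyper", "hypo", "hyper")[k])
  }
})

test_that("emitted DMRs always satisfy the configured thresholds", {
  # clusters below the site-count or span thresholds are never emitted
  cc <- make_cluster_catalog(c(60, 400, 200), sites_per_cluster = 12,
                             n_background = 200)
  # third cluster gets only 8 elevated sites
  raised <- list(cc$cluster_idx[[1]], cc$cluster_idx[[2]],
                 cc$cluster_idx[[3]][1:8])
  prof <- two_group_profile(cc$catalog, raised, fc = 4)
  cm <- simulate_count_matrix(prof, 6, 1e5, 0.05, seed = 41)
  dmrs <- detect_dmrs(cm, group_contrast(cm, "A"))
  cfg <- dmr_config()
  expect_true(all(dmrs$n_significant >= cfg$min_sites))
  expect_true(all(dmrs$end - dmrs$start >= cfg$min_span_bp))
  expect_true(all(dmrs$fc >= cfg$fc_threshold |
                    dmrs$fc <= 1 / cfg$fc_threshold))
  # only the 400-bp / 12-site cluster qualifies: the 60-bp span fails the
  # 100-bp rule and the 8-site cluster fails the ten-site rule
  expect_equal(nrow(dmrs), 1)
  s <- cc$catalog$sites
  expect_lt(abs(dmrs$start - s$pos[cc$cluster_idx[[2]][1]]), 50)
})

test_that("raising the fold-change threshold never yields more DMRs", {
  cc <- make_cluster_catalog(c(400, 300), sites_per_cluster = 12,
                             n_background = 200)
  prof <- two_group_profile(cc$catalog, cc$cluster_idx, fc = 3)
  cm <- simulate_count_matrix(prof, 6, 1e5, 0.05, seed = 51)
  ctr <- group_contrast(cm, "A")
  n2 <- nrow(detect_dmrs(cm, ctr, dmr_config(fc_threshold = 2)))
  n5 <- nrow(detect_dmrs(cm, ctr, dmr_config(fc_threshold = 5)))
  expect_lte(n5, n2)
})

test_that("pooling is invariant to sample order within groups", {
  cc <- make_cluster_catalog(400, sites_per_cluster = 12,
                             n_background = 100)
  prof <- two_group_profile(cc$catalog, cc$cluster_idx, fc = 4)
  cm <- simulate_count_matrix(prof, 6, 1e5, 0.05, seed = 61)
  ctr1 <- group_contrast(cm, "A")
  perm <- structure(ctr1, class = "medseq_contrast")
  perm$samples_a <- rev(ctr1$samples_a)
  perm$samples_b <- sample(ctr1$samples_b)
  d1 <- detect_dmrs(cm, ctr1)
  d2 <- detect_dmrs(cm, perm)
  expect_equal(d1[setdiff(names(d1), "sites")],
               d2[setdiff(names(d2), "sites")])
})

test_that("null data yields fewer than one false-positive DMR per run", {
  cc <- make_cluster_catalog(integer(0), n_background = 400,
                             background_spacing = 100)
  prof <- two_group_profile(cc$catalog, list(), fc = 1)
  fp <- vapply(1:20, function(seed) {
    cm <- simulate_count_matrix(prof, 6, 1e5, 0.05, seed = seed)
    nrow(detect_dmrs(cm, group_contrast(cm, "A")))
  }, numeric(1))
  expect_lt(mean(fp), 1)
})

test_that("group-unique DMRs require zero overlap with other contrasts", {
  mk <- function(chrom, start, end) {
    data.frame(chrom = chrom, start = start, end = end,
               direction = "hyper", stringsAsFactors = FALSE)
  }
  by_contrast <- list(
    BAP1 = mk("chr1", c(100, 5000), c(400, 5400)),
    SF3B1 = mk("chr1", c(399, 9000), c(700, 9200)),
    EIF1AX = mk("chr2", 100, 300)
  )
  uniq <- call_group_unique_dmrs(by_contrast)
  # BAP1 [100,400) overlaps SF3B1 [399,700) by 1 bp -> excluded from both
  expect_equal(uniq$BAP1$start, 5000)
  expect_equal(uniq$SF3B1$start, 9000)
  expect_equal(uniq$EIF1AX$start, 100)
  # abutting intervals (zero bp shared) are NOT overlapping
  ab <- list(A = mk("chr1", 100, 200), B = mk("chr1", 200, 300))
  u2 <- call_group_unique_dmrs(ab)
  expect_equal(nrow(u2$A), 1)
  expect_equal(nrow(u2$B), 1)
  expect_error(call_group_unique_dmrs(by_contrast[1]), "2 contrasts")
})

test_that("group-exclusive planted DMRs are recovered as group-unique", {
  # three groups; each has one private planted cluster. Effect 2.5 keeps
  # the one-vs-rest "echo" (the focal group's cluster seen as mild
  # hypomethylation from the other contrasts, FC ~ 2/(2.5+1) ~ 0.57)
  # inside the (1/2, 2) dead band, so uniqueness is decidable.
  cc <- make_cluster_catalog(c(400, 400, 400), sites_per_cluster = 12,
                             n_background = 200)
  n <- nrow(cc$catalog$sites)
  base <- 0.1
  prob <- cbind(BAP1 = rep(base, n), SF3B1 = rep(base, n),
                EIF1AX = rep(base, n))
  for (k in 1:3) prob[cc$cluster_idx[[k]], k] <- base * 2.5
  prof <- methylation_profile(cc$catalog, prob, baseline = base)
  cm <- simulate_count_matrix(prof, 4, 1e5, 0.05, seed = 71)
  by_contrast <- lapply(stats::setNames(colnames(prob), colnames(prob)),
                        function(g)
                          detect_dmrs(cm, group_contrast(cm, g)))
  uniq <- call_group_unique_dmrs(by_contrast)
  s <- cc$catalog$sites
  for (k in 1:3) {
    g <- colnames(prob)[k]
    lo <- s$pos[cc$cluster_idx[[k]][1]]
    expect_true(any(abs(uniq[[g]]$start - lo) < 100),
                info = paste("group", g))
  }
})
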