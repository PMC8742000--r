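# Shared fixtures and independent oracles used across the suite.

ILLUMINA_ADAPTER <- "AGATCGGAAGAGCACACGTCTGAACTCCAGTCA"

# a small cached genome so repeated tests don't regenerate it
fixture_genome <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_toy_genome(1, 20000, 100, seed = 7)
    cache
  }
})

# evenly spaced clusters of sites plus sparse background, as a catalogue;
# returns list(catalog, cluster_idx = list of site-row indices per cluster)
make_cluster_catalog <- function(cluster_spans, sites_per_cluster = 12,
                                 cluster_gap = 3000, n_background = 200,
                                 background_spacing = 200) {
  pos <- integer()
  cluster_idx <- list()
  cursor <- 1000L
  for (span in cluster_spans) {
    p <- cursor + round(seq(0, span - 4, length.out = sites_per_cluster))
    cluster_idx[[length(cluster_idx) + 1L]] <-
      seq(length(pos) + 1L, length(pos) + sites_per_cluster)
    pos <- c(pos, p)
    cursor <- cursor + span + cluster_gap
  }
  bg <- seq(cursor + cluster_gap,
            by = background_spacing, length.out = n_background)
  pos <- c(pos, bg)
  list(catalog = catalog_from_positions("chr1", pos),
       cluster_idx = cluster_idx)
}

# two-group profile over a catalogue: group A raised (or lowered) by
# `fc` inside the given site-index sets
two_group_profile <- function(catalog, raised_idx = list(), fc = 4,
                              baseline = 0.1,
                              directions = rep("hyper",
                                               length(raised_idx))) {
  n <- nrow(catalog$sites)
  pa <- rep(baseline, n)
  for (k in seq_along(raised_idx)) {
    pa[raised_idx[[k]]] <- if (directions[k] == "hyper")
      baseline * fc else baseline / fc
  }
  methylation_profile(catalog,
                      cbind(A = pa, B = rep(baseline, n)),
                      baseline = baseline)
}

# brute-force agglomerative clustering oracle: complete linkage, L1
# distance over columns; returns merge heights (sorted) and the partition
# at each k as canonical labellings
oracle_complete_l1 <- function(m) {
  n <- ncol(m)
  d <- as.matrix(stats::dist(t(m), method = "manhattan"))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- c(Inf, NA, NA)
    for (i in seq_len(length(clusters) - 1)) {
      for (j in seq(i + 1, length(clusters))) {
        h <- max(d[clusters[[i]], clusters[[j]]])
        if (h < best[1]) best <- c(h, i, j)
      }
    }
    i <- best[2]; j <- best[3]
    clusters[[i]] <- c(clusters[[i]], clusters[[j]])
    clusters[[j]] <- NULL
    heights <- c(heights, best[1])
    partitions[[length(partitions) + 1L]] <-
      canonical_partition(clusters, n)
  }
  list(heights = heights, partitions = partitions)
}

canonical_partition <- function(clusters, n) {
  lab <- integer(n)
  for (k in seq_along(clusters)) lab[clusters[[k]]] <- k
  # relabel by first occurrence so labellings are comparable
  match(lab, unique(lab))
}

# partition of hclust cut into canonical labels
canonical_cut <- function(hc, k) {
  match(stats::cutree(hc, k = k), unique(stats::cutree(hc, k = k)))
}

rand_same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}
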