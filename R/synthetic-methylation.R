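# Group methylation profiles with planted DMRs, and the count-level
# simulator that turns a profile into a per-site read-count matrix.

#' Plant differentially methylated regions into a methylation profile
#'
#' Builds a per-site, per-group methylation probability profile at a flat
#' baseline and plants `n_dmrs` disjoint DMRs, each covering at least
#' `dmr_sites` consecutive catalogue sites and spanning at least
#' `min_span` bp. In a hyper DMR the affected group's probability is
#' `baseline * effect_fc`; in a hypo DMR it is `baseline / effect_fc`.
#' Directions alternate hyper/hypo and affected groups cycle unless
#' overridden. Planted intervals are separated by a guard gap so they
#' cannot merge during detection.
#'
#' @param fixture a `medseq_genome` or `medseq_catalog`.
#' @param groups character vector of group names (>= 2).
#' @param n_dmrs number of DMRs to plant.
#' @param dmr_sites consecutive catalogue sites per DMR (>= 10, so planted
#'   DMRs are detectable at the ten-site threshold).
#' @param effect_fc target fold change, scalar or one value per DMR
#'   (> 1; `baseline * effect_fc` must be <= 1 for hyper DMRs).
#' @param baseline background methylation probability in (0, 1].
#' @param seed integer seed.
#' @param directions optional vector over DMRs ("hyper"/"hypo"); default
#'   alternates starting at "hyper".
#' @param affected_groups optional vector over DMRs; default cycles
#'   through `groups`.
#' @param min_span minimum planted span in bp (default 100).
#' @param guard_gap minimum bp between planted DMRs (default 2000, so
#'   windows from adjacent DMRs never touch).
#' @return a `medseq_profile`: list with `catalog`, `prob` (sites x groups
#'   matrix), `groups`, `baseline`, `planted` (data.frame chrom, start,
#'   end, group, direction, fc, first_site, last_site, n_sites), `seed`.
#' @export
plant_methylation <- function(fixture, groups, n_dmrs, dmr_sites, effect_fc,
                              baseline, seed, directions = NULL,
                              affected_groups = NULL, min_span = 100,
                              guard_gap = 2000) {
  catalog <- if (inherits(fixture, "medseq_genome")) fixture$catalog
             else fixture
  stopifnot(inherits(catalog, "medseq_catalog"))
  if (length(groups) < 2L || anyDuplicated(groups))
    stop("`groups` must be >= 2 distinct group names", call. = FALSE)
  n_dmrs <- check_count(n_dmrs, "n_dmrs", min = 0L)
  dmr_sites <- check_count(dmr_sites, "dmr_sites", min = 10L)
  if (!is.numeric(effect_fc) || !length(effect_fc) ||
      any(is.na(effect_fc)) || any(effect_fc <= 1))
    stop("`effect_fc` must be > 1 (scalar or one value per DMR)",
         call. = FALSE)
  effect_fc <- rep(effect_fc, length.out = max(n_dmrs, 1L))
  baseline <- check_scalar(baseline, "baseline", min = 0, max = 1,
                           strict_min = TRUE)
  if (is.null(directions))
    directions <- rep(c("hyper", "hypo"), length.out = n_dmrs)
  directions <- rep(directions, length.out = n_dmrs)
  if (!all(directions %in% c("hyper", "hypo")))
    stop("directions must be 'hyper' or 'hypo'", call. = FALSE)
  if (any(directions == "hyper" &
            baseline * effect_fc[seq_len(n_dmrs)] > 1))
    stop("baseline * effect_fc must be <= 1 for hyper DMRs", call. = FALSE)
  if (is.null(affected_groups))
    affected_groups <- rep(groups, length.out = n_dmrs)
  affected_groups <- rep(affected_groups, length.out = n_dmrs)
  if (!all(affected_groups %in% groups))
    stop("affected_groups must be a subset of groups", call. = FALSE)

  s <- catalog$sites
  mlen <- catalog$motif_length
  prob <- matrix(baseline, nrow = nrow(s), ncol = length(groups),
                 dimnames = list(NULL, groups))

  planted <- with_seed(seed, {
    place_dmr_runs(s, n_dmrs, dmr_sites, min_span, guard_gap, mlen)
  })
  if (n_dmrs > 0) {
    planted$group <- affected_groups
    planted$direction <- directions
    planted$fc <- effect_fc[seq_len(n_dmrs)]
    for (k in seq_len(nrow(planted))) {
      idx <- seq(planted$first_idx[k], planted$last_idx[k])
      g <- planted$group[k]
      prob[idx, g] <- if (planted$direction[k] == "hyper")
        baseline * planted$fc[k] else baseline / planted$fc[k]
    }
    planted$first_idx <- planted$last_idx <- NULL
  }
  structure(list(catalog = catalog, prob = prob, groups = groups,
                 baseline = baseline, planted = planted, seed = seed),
            class = "medseq_profile")
}

# choose n disjoint runs of `k` consecutive sites with span >= min_span,
# separated by >= guard_gap bp (consumes RNG)
#' @noRd
place_dmr_runs <- function(sites, n, k, min_span, guard_gap, motif_len) {
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), first_site = integer(),
                      last_site = integer(), n_sites = integer(),
                      first_idx = integer(), last_idx = integer())
  if (n == 0) return(empty)
  # candidate run starts: k consecutive sites on one chromosome, span ok
  cand <- which(vapply(seq_len(nrow(sites) - k + 1L), function(i) {
    j <- i + k - 1L
    sites$chrom[i] == sites$chrom[j] &&
      (sites$pos[j] + motif_len - sites$pos[i]) >= min_span
  }, logical(1)))
  chosen <- integer()
  cand <- sample(cand)
  for (i in cand) {
    if (length(chosen) == n) break
    j <- i + k - 1L
    ok <- all(vapply(chosen, function(c0) {
      c1 <- c0 + k - 1L
      sites$chrom[c0] != sites$chrom[i] ||
        sites$pos[i] > sites$pos[c1 + 0L] + guard_gap + motif_len ||
        sites$pos[c1] < sites$pos[i] - guard_gap ||
        (sites$pos[c0] - (sites$pos[j] + motif_len)) > guard_gap ||
        (sites$pos[i] - (sites$pos[c1] + motif_len)) > guard_gap
    }, logical(1)))
    # the disjointness test above is permissive; re-check strictly
    ok <- all(vapply(chosen, function(c0) {
      c1 <- c0 + k - 1L
      if (sites$chrom[c0] != sites$chrom[i]) return(TRUE)
      lo <- sites$pos[c0] - guard_gap
      hi <- sites$pos[c1] + motif_len + guard_gap
      sites$pos[j] + motif_len <= lo || sites$pos[i] >= hi
    }, logical(1)))
    if (ok) chosen <- c(chosen, i)
  }
  if (length(chosen) < n)
    stop("capacity error: cannot place ", n, " disjoint DMRs of ", k,
         " sites in this catalogue", call. = FALSE)
  chosen <- sort(chosen)
  data.frame(
    chrom = sites$chrom[chosen],
    start = sites$pos[chosen],
    end = sites$pos[chosen + k - 1L] + motif_len,
    first_site = sites$site_id[chosen],
    last_site = sites$site_id[chosen + k - 1L],
    n_sites = k,
    first_idx = chosen,
    last_idx = chosen + k - 1L,
    stringsAsFactors = FALSE
  )
}

#' Build a methylation profile from an explicit probability matrix
#'
#' Low-level constructor for simulations that need full control over
#' per-site probabilities (e.g. clusters below the detection thresholds,
#' which [plant_methylation()] refuses to plant).
#'
#' @param catalog a `medseq_catalog`.
#' @param prob numeric matrix, sites x groups, values in `[0, 1]`; column
#'   names are the group names.
#' @param baseline background probability recorded in the manifest.
#' @param planted optional planted-DMR data.frame (may be NULL).
#' @param seed seed recorded in the manifest (NA if not applicable).
#' @export
methylation_profile <- function(catalog, prob, baseline = NA_real_,
                                planted = NULL, seed = NA) {
  stopifnot(inherits(catalog, "medseq_catalog"))
  prob <- as.matrix(prob)
  if (nrow(prob) != nrow(catalog$sites))
    stop("`prob` must have one row per catalogue site", call. = FALSE)
  if (is.null(colnames(prob)) || anyDuplicated(colnames(prob)))
    stop("`prob` needs unique column names (the groups)", call. = FALSE)
  if (any(prob < 0 | prob > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  structure(list(catalog = catalog, prob = prob,
                 groups = colnames(prob), baseline = baseline,
                 planted = planted, seed = seed),
            class = "medseq_profile")
}

#' @export
print.medseq_profile <- function(x, ...) {
  cat("Methylation profile:", nrow(x$prob), "sites x",
      ncol(x$prob), "groups;", nrow(x$planted), "planted DMR(s)\n")
  invisible(x)
}

#' Simulate a per-site read-count matrix from a methylation profile
#'
#' Counts are drawn per site and sample with expectation
#' `library_size * p_site / sum(p_group)` — the multinomial rate implied by
#' treating methylation probability as fragment-emission probability.
#' Negative-binomial noise (size = 1/dispersion) models biological
#' replicate variability; `dispersion = 0` gives Poisson counts.
#'
#' @param profile a `medseq_profile`.
#' @param samples_per_group samples per group (>= 2).
#' @param mean_library_size mean filtered reads per sample (>= 10000).
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param seed integer seed.
#' @param library_size_cv coefficient of variation of the per-sample
#'   library sizes (default 0.1).
#' @return a `medseq_counts`: list with `counts` (sites x samples integer
#'   matrix), `samples` (data.frame sample, group, total, library_size),
#'   `catalog`.
#' @export
simulate_count_matrix <- function(profile, samples_per_group,
                                  mean_library_size, dispersion, seed,
                                  library_size_cv = 0.1) {
  stopifnot(inherits(profile, "medseq_profile"))
  samples_per_group <- check_count(samples_per_group, "samples_per_group",
                                   min = 2L)
  mean_library_size <- check_count(mean_library_size, "mean_library_size",
                                   min = 10000L)
  dispersion <- check_scalar(dispersion, "dispersion", min = 0)
  groups <- profile$groups
  sample_names <- unlist(lapply(groups, function(g)
    paste0(g, "_s", seq_len(samples_per_group))))
  sample_groups <- rep(groups, each = samples_per_group)
  n_sites <- nrow(profile$prob)

  out <- with_seed(seed, {
    lib <- pmax(round(stats::rnorm(length(sample_names), mean_library_size,
                                   library_size_cv * mean_library_size)),
                round(mean_library_size / 2))
    counts <- matrix(0L, nrow = n_sites, ncol = length(sample_names),
                     dimnames = list(NULL, sample_names))
    for (j in seq_along(sample_names)) {
      p <- profile$prob[, sample_groups[j]]
      mu <- lib[j] * p / sum(p)
      counts[, j] <- if (dispersion == 0)
        stats::rpois(n_sites, mu)
      else
        stats::rnbinom(n_sites, mu = mu, size = 1 / dispersion)
    }
    list(lib = lib, counts = counts)
  })
  samples <- data.frame(sample = sample_names, group = sample_groups,
                        total = colSums(out$counts),
                        library_size = out$lib,
                        stringsAsFactors = FALSE)
  structure(list(counts = out$counts, samples = samples,
                 catalog = profile$catalog),
            class = "medseq_counts")
}

#' @export
print.medseq_counts <- function(x, ...) {
  cat("Site count matrix:", nrow(x$counts), "sites x", ncol(x$counts),
      "samples; groups:",
      paste(unique(x$samples$group), collapse = ", "), "\n")
  invisible(x)
}

#' Write a count matrix as TSV (site_id, chrom, pos, then one column per
#' sample) plus a companion `<path>.samples.tsv` with the group map and
#' totals.
#' @param counts a `medseq_counts`.
#' @param path output TSV.
#' @export
write_counts <- function(counts, path) {
  stopifnot(inherits(counts, "medseq_counts"))
  tab <- cbind(counts$catalog$sites[c("site_id", "chrom", "pos")],
               as.data.frame(counts$counts))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(counts$samples, paste0(path, ".samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a count matrix written by [write_counts()]
#' @param path TSV path (expects `<path>.samples.tsv` beside it).
#' @param catalog the `medseq_catalog` the matrix is keyed to.
#' @export
read_counts <- function(path, catalog) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)
  samples <- utils::read.table(paste0(path, ".samples.tsv"), header = TRUE,
                               sep = "\t", stringsAsFactors = FALSE)
  if (!identical(tab$site_id, catalog$sites$site_id))
    stop("count matrix site_ids do not match the catalogue", call. = FALSE)
  counts <- as.matrix(tab[, samples$sample, drop = FALSE])
  structure(list(counts = counts, samples = samples, catalog = catalog),
            class = "medseq_counts")
}
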