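# From raw reads to a per-site count matrix: adapter trimming, the
# 13-17 bp restriction-site position filter, exact-match mapping against a
# toy genome, and SAM/BAM ingestion for externally aligned data.

#' Trim 3' adapter sequence from reads
#'
#' Removes the longest 3' suffix of each read that exactly matches a
#' prefix of the adapter, provided the overlap is at least `min_overlap`
#' bases. Qualities are trimmed in lockstep. Reads shorter than
#' `min_overlap` pass through unchanged.
#'
#' @param seq character vector of read sequences.
#' @param adapter adapter sequence (non-empty).
#' @param qual optional parallel vector of quality strings.
#' @param min_overlap minimum adapter overlap to trim (default 3).
#' @return list with `seq` and `qual` (NULL if `qual` was NULL).
#' @export
trim_adapter <- function(seq, adapter, qual = NULL, min_overlap = 3) {
  if (!nzchar(adapter)) stop("`adapter` must be non-empty", call. = FALSE)
  min_overlap <- check_count(min_overlap, "min_overlap", min = 1L)
  keep <- vapply(seq, function(s) {
    L <- nchar(s)
    for (k in seq(min(L, nchar(adapter)), min_overlap)) {
      if (k > L) next
      if (substr(s, L - k + 1L, L) == substr(adapter, 1L, k))
        return(L - k)
    }
    L
  }, integer(1), USE.NAMES = FALSE)
  out_seq <- substr(seq, 1L, keep)
  out_qual <- if (!is.null(qual)) substr(qual, 1L, keep) else NULL
  list(seq = out_seq, qual = out_qual)
}

#' MeD-seq restriction-site position filter
#'
#' A read passes iff some occurrence of the recognition motif (in either
#' orientation) lies 13-17 bp (inclusive, configurable) from the 5' or the
#' 3' end of the read: for an occurrence occupying read positions
#' `[s, s + m)` (0-based), `d5 = s` and `d3 = len - (s + m)`, and the read
#' passes when `d5` or `d3` falls in `[min_offset, max_offset]`. The
#' qualifying occurrence with the smallest `s` is recorded.
#'
#' @param seq character vector of read sequences.
#' @param motif IUPAC motif (default [MEDSEQ_MOTIF]).
#' @param min_offset,max_offset inclusive offset band in bp (defaults 13
#'   and 17).
#' @return data.frame with one row per read: `pass`, `offset5` (d5 of the
#'   qualifying occurrence, NA if none), `offset3`, `end` ("5p", "3p" or
#'   NA — which end qualified; 5' wins when both do).
#' @export
position_filter <- function(seq, motif = MEDSEQ_MOTIF, min_offset = 13,
                            max_offset = 17) {
  motif <- check_iupac(motif)
  min_offset <- check_count(min_offset, "min_offset")
  max_offset <- check_count(max_offset, "max_offset", min = min_offset)
  m <- nchar(motif)
  n <- length(seq)
  out <- data.frame(pass = logical(n), offset5 = NA_integer_,
                    offset3 = NA_integer_, end = NA_character_)
  if (!n) return(out)
  lens <- nchar(seq)
  nonempty <- which(lens >= m)
  if (!length(nonempty)) return(out)
  subj <- Biostrings::DNAStringSet(seq[nonempty])
  fwd <- Biostrings::DNAString(motif)
  rev <- Biostrings::reverseComplement(fwd)
  hits_f <- Biostrings::vmatchPattern(fwd, subj, fixed = FALSE)
  hits_r <- Biostrings::vmatchPattern(rev, subj, fixed = FALSE)
  for (i in seq_along(nonempty)) {
    ri <- nonempty[i]
    starts <- sort(unique(c(BiocGenerics::start(hits_f[[i]]),
                            BiocGenerics::start(hits_r[[i]])))) - 1L
    if (!length(starts)) next
    d5 <- starts
    d3 <- lens[ri] - (starts + m)
    ok <- (d5 >= min_offset & d5 <= max_offset) |
      (d3 >= min_offset & d3 <= max_offset)
    if (!any(ok)) next
    j <- which(ok)[1]  # smallest s on tie
    out$pass[ri] <- TRUE
    out$offset5[ri] <- d5[j]
    out$offset3[ri] <- d3[j]
    out$end[ri] <- if (d5[j] >= min_offset && d5[j] <= max_offset) "5p"
                   else "3p"
  }
  out
}

#' Map filtered reads exactly and count per catalogue site
#'
#' The toy exact-match mapper: each read (already trimmed and
#' position-filtered) is matched with no mismatches against the genome in
#' both orientations; every catalogued site whose motif lies 13-17 bp from
#' either end of a matched interval receives one count per matching
#' location (multi-mapper convention; `fractional = TRUE` gives 1/n per
#' location instead). Reads matching no location are tallied as
#' unassigned. Per-sample totals are the number of input (filtered) reads.
#'
#' @param read_sets named list (one element per sample) of read
#'   data.frames (`id`, `seq`, ...) or FASTQ paths.
#' @param catalog a `medseq_catalog`.
#' @param genome the genome the catalogue was scanned from (any form
#'   accepted by [scan_sites()]).
#' @param groups named character vector mapping sample -> group.
#' @param min_offset,max_offset site-offset band (defaults 13, 17).
#' @param fractional weight multi-mapped reads 1/n per location.
#' @return a `medseq_counts` with a `qc` data.frame attached (reads_in,
#'   mapped, assigned, unassigned per sample).
#' @export
assign_and_count <- function(read_sets, catalog, genome, groups,
                             min_offset = 13, max_offset = 17,
                             fractional = FALSE) {
  stopifnot(inherits(catalog, "medseq_catalog"))
  seqs <- as_dna_set(genome)
  if (is.null(names(read_sets)))
    stop("`read_sets` must be a named list (names = samples)",
         call. = FALSE)
  if (!all(names(read_sets) %in% names(groups)))
    stop("every sample needs a group in `groups`", call. = FALSE)
  s <- catalog$sites
  mlen <- catalog$motif_length
  pos_by_chrom <- split(seq_len(nrow(s)), s$chrom)

  counts <- matrix(0, nrow = nrow(s), ncol = length(read_sets),
                   dimnames = list(NULL, names(read_sets)))
  qc <- data.frame(sample = names(read_sets), reads_in = 0L, mapped = 0L,
                   assigned = 0L, unassigned = 0L,
                   stringsAsFactors = FALSE)
  for (j in seq_along(read_sets)) {
    reads <- read_sets[[j]]
    if (is.character(reads)) reads <- read_fastq(reads)
    qc$reads_in[j] <- nrow(reads)
    if (!nrow(reads)) next
    agg <- count_sample_reads(reads$seq, seqs, s, pos_by_chrom, mlen,
                              min_offset, max_offset, fractional)
    counts[, j] <- agg$site_counts
    qc$mapped[j] <- agg$n_mapped
    qc$assigned[j] <- agg$n_assigned
    qc$unassigned[j] <- agg$n_unassigned
  }
  samples <- data.frame(sample = names(read_sets),
                        group = unname(groups[names(read_sets)]),
                        total = qc$reads_in, stringsAsFactors = FALSE)
  out <- structure(list(counts = counts, samples = samples,
                        catalog = catalog, qc = qc),
                   class = "medseq_counts")
  out
}

# exact matching and site-offset counting for one sample (no RNG)
#' @noRd
count_sample_reads <- function(read_seqs, genome_seqs, sites, pos_by_chrom,
                               mlen, min_offset, max_offset, fractional) {
  uniq <- table(read_seqs)
  useq <- names(uniq)
  mult <- as.integer(uniq)
  site_counts <- numeric(nrow(sites))
  n_locs <- integer(length(useq))          # genome locations per unique seq
  hit_sites <- vector("list", length(useq))
  widths <- nchar(useq)
  for (w in unique(widths)) {
    idx <- which(widths == w)
    dict_f <- Biostrings::DNAStringSet(useq[idx])
    dict_r <- Biostrings::reverseComplement(dict_f)
    for (cn in names(genome_seqs)) {
      chrom_sites <- pos_by_chrom[[cn]]
      site_pos <- if (is.null(chrom_sites)) integer()
                  else sites$pos[chrom_sites]
      for (orient in c("f", "r")) {
        d <- if (orient == "f") dict_f else dict_r
        hits <- Biostrings::matchPDict(Biostrings::PDict(d),
                                       genome_seqs[[cn]])
        for (k in seq_along(idx)) {
          st <- BiocGenerics::start(hits[[k]]) - 1L  # 0-based interval start
          if (!length(st)) next
          n_locs[idx[k]] <- n_locs[idx[k]] + length(st)
          if (!length(site_pos)) next
          for (a0 in st) {
            # sites with motif 13-17 bp from either interval end
            in_band <- chrom_sites[
              (site_pos >= a0 + min_offset & site_pos <= a0 + max_offset) |
                (site_pos >= a0 + w - max_offset - mlen &
                   site_pos <= a0 + w - min_offset - mlen)]
            if (length(in_band))
              hit_sites[[idx[k]]] <- c(hit_sites[[idx[k]]], in_band)
          }
        }
      }
    }
  }
  n_mapped <- sum(mult[n_locs > 0])
  n_assigned <- 0L
  for (k in seq_along(useq)) {
    hs <- hit_sites[[k]]
    if (is.null(hs)) next
    n_assigned <- n_assigned + mult[k]
    wgt <- if (fractional) mult[k] / n_locs[k] else mult[k]
    tb <- table(hs)
    site_counts[as.integer(names(tb))] <-
      site_counts[as.integer(names(tb))] + as.integer(tb) * wgt
  }
  list(site_counts = site_counts, n_mapped = n_mapped,
       n_assigned = n_assigned, n_unassigned = sum(mult) - n_mapped)
}

#' Ingest SAM/BAM alignments into a per-site count matrix
#'
#' Each mapped record contributes to every catalogued site whose motif
#' lies 13-17 bp from either end of the record's reference interval.
#' Secondary alignments are included (multi-mapper convention);
#' supplementary and unmapped records are excluded. Records on reference
#' names absent from the catalogue are skipped with a warning.
#'
#' @param files named vector/list of SAM or BAM paths (names = samples).
#' @param catalog a `medseq_catalog`.
#' @param groups named character vector mapping sample -> group.
#' @param min_offset,max_offset site-offset band (defaults 13, 17).
#' @return a `medseq_counts` (totals = number of usable mapped records).
#' @export
ingest_alignments <- function(files, catalog, groups, min_offset = 13,
                              max_offset = 17) {
  stopifnot(inherits(catalog, "medseq_catalog"))
  if (is.null(names(files)))
    stop("`files` must be named (names = samples)", call. = FALSE)
  s <- catalog$sites
  mlen <- catalog$motif_length
  pos_by_chrom <- split(seq_len(nrow(s)), s$chrom)
  counts <- matrix(0, nrow = nrow(s), ncol = length(files),
                   dimnames = list(NULL, names(files)))
  totals <- integer(length(files))
  for (j in seq_along(files)) {
    path <- files[[j]]
    if (grepl("\\.sam$", path, ignore.case = TRUE)) {
      path <- Rsamtools::asBam(path,
                               destination = tempfile(fileext = ""),
                               overwrite = TRUE, indexDestination = FALSE)
    }
    flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                   isSupplementaryAlignment = FALSE)
    param <- Rsamtools::ScanBamParam(
      flag = flag, what = c("rname", "pos", "cigar"))
    rec <- Rsamtools::scanBam(path, param = param)[[1]]
    keep <- !is.na(rec$pos)
    rname <- as.character(rec$rname)[keep]
    start0 <- rec$pos[keep] - 1L
    width <- GenomicAlignments::cigarWidthAlongReferenceSpace(
      rec$cigar[keep])
    known <- rname %in% names(pos_by_chrom) |
      rname %in% unique(s$chrom)
    if (any(!known))
      warning(sum(!known), " record(s) on reference name(s) absent from ",
              "the catalogue were skipped", call. = FALSE)
    totals[j] <- sum(known)
    for (i in which(known)) {
      chrom_sites <- pos_by_chrom[[rname[i]]]
      if (is.null(chrom_sites)) next
      site_pos <- s$pos[chrom_sites]
      a0 <- start0[i]
      w <- width[i]
      in_band <- chrom_sites[
        (site_pos >= a0 + min_offset & site_pos <= a0 + max_offset) |
          (site_pos >= a0 + w - max_offset - mlen &
             site_pos <= a0 + w - min_offset - mlen)]
      counts[in_band, j] <- counts[in_band, j] + 1
    }
  }
  samples <- data.frame(sample = names(files),
                        group = unname(groups[names(files)]),
                        total = totals, stringsAsFactors = FALSE)
  structure(list(counts = counts, samples = samples, catalog = catalog),
            class = "medseq_counts")
}
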