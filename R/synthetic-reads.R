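# In-silico LpnPI digestion: emit 32-bp fragments around methylated
# recognition sites, optionally padded with adapter to the sequencer read
# length, exactly mirroring the geometry the position filter expects.

# LpnPI cuts a fixed distance from its methylated recognition site, so a
# digest yields 32-bp snippets with the motif 13-17 bp from one fragment end.
FRAGMENT_LENGTH <- 32L
OFFSET_MIN <- 13L
OFFSET_MAX <- 17L

#' Simulate digest reads for one sample
#'
#' Sites are sampled with probability proportional to the group's
#' methylation probability (methylation probability acts as
#' fragment-emission probability; hemi-methylation is not modelled). Each
#' fragment is a 32-bp genomic window containing exactly one sampled site,
#' with the motif placed uniformly over the offsets that leave it 13-17 bp
#' from one fragment end. Minus-strand sites yield the reverse complement
#' of the window so the motif reads in its recognition orientation. When
#' `read_length` exceeds 32 and an adapter is given, fragments are 3'-padded
#' with adapter sequence (sequencing proceeds into the adapter); with no
#' adapter, reads are the bare fragments.
#'
#' Sites too close to a chromosome end to accommodate every allowed
#' placement are excluded from emission (their probability is zeroed).
#'
#' @param fixture a `medseq_genome`.
#' @param profile a `medseq_profile` built on the fixture's catalogue.
#' @param group group name whose methylation profile drives emission.
#' @param n_reads number of reads to emit.
#' @param read_length sequencer read length in bp (>= 32).
#' @param adapter adapter sequence used for 3' padding ("" = none).
#' @param seed integer seed.
#' @param sample_name name used in read ids (default `group`).
#' @return list with `reads` (data.frame id, seq, qual), `truth`
#'   (integer vector of per-site emitted fragment counts, parallel to the
#'   catalogue), `sample`, `group`.
#' @export
simulate_digest_reads <- function(fixture, profile, group, n_reads,
                                  read_length = 50, adapter = "", seed,
                                  sample_name = group) {
  stopifnot(inherits(fixture, "medseq_genome"),
            inherits(profile, "medseq_profile"))
  if (!group %in% profile$groups)
    stop("group '", group, "' not found in profile (groups: ",
         paste(profile$groups, collapse = ", "), ")", call. = FALSE)
  n_reads <- check_count(n_reads, "n_reads")
  read_length <- check_count(read_length, "read_length",
                             min = FRAGMENT_LENGTH)
  catalog <- fixture$catalog
  s <- catalog$sites
  mlen <- catalog$motif_length
  chrom_len <- catalog$chrom_lengths
  # motif 13-17 bp from one end of a 32-bp fragment:
  # 5' offsets d with d in [13,17] or (32 - mlen - d) in [13,17]
  d5_all <- 0:(FRAGMENT_LENGTH - mlen)
  d3_all <- FRAGMENT_LENGTH - mlen - d5_all
  allowed_d5 <- d5_all[(d5_all >= OFFSET_MIN & d5_all <= OFFSET_MAX) |
                         (d3_all >= OFFSET_MIN & d3_all <= OFFSET_MAX)]
  max_d5 <- max(allowed_d5)
  max_d3 <- FRAGMENT_LENGTH - mlen - min(allowed_d5)

  emit_p <- profile$prob[, group]
  # exclude sites whose full placement range would run off the chromosome
  len_here <- chrom_len[s$chrom]
  edge <- (s$pos < max(max_d5, max_d3)) |
    (s$pos + mlen + max(max_d5, max_d3) > len_here)
  emit_p[edge] <- 0
  truth <- integer(nrow(s))
  if (n_reads == 0L) {
    reads <- data.frame(id = character(), seq = character(),
                        qual = character(), stringsAsFactors = FALSE)
    return(list(reads = reads, truth = truth, sample = sample_name,
                group = group))
  }
  if (sum(emit_p) <= 0)
    stop("no sites available for emission in group '", group, "'",
         call. = FALSE)

  res <- with_seed(seed, {
    idx <- sample.int(nrow(s), n_reads, replace = TRUE, prob = emit_p)
    d5 <- sample(allowed_d5, n_reads, replace = TRUE)
    list(idx = idx, d5 = d5)
  })
  tb <- tabulate(res$idx, nbins = nrow(s))
  truth <- as.integer(tb)

  pos <- s$pos[res$idx]
  strand <- s$strand[res$idx]
  chroms <- s$chrom[res$idx]
  # forward window start such that the motif sits at read offset d5
  wstart <- ifelse(strand == "+",
                   pos - res$d5,
                   pos + mlen + res$d5 - FRAGMENT_LENGTH)
  frags <- character(n_reads)
  for (cn in unique(chroms)) {
    sel <- chroms == cn
    v <- Biostrings::Views(fixture$chromosomes[[cn]],
                           start = wstart[sel] + 1L,
                           width = FRAGMENT_LENGTH)
    fr <- as.character(v)
    flip <- strand[sel] == "-"
    if (any(flip))
      fr[flip] <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(fr[flip])))
    frags[sel] <- fr
  }
  if (nzchar(adapter) && read_length > FRAGMENT_LENGTH) {
    pad_len <- read_length - FRAGMENT_LENGTH
    if (nchar(adapter) < pad_len)
      stop("adapter (", nchar(adapter), " bp) is shorter than the ",
           pad_len, " bp read-through; sequencing past a 32-bp insert ",
           "reads into the adapter, so the adapter must cover ",
           "read_length - 32 bp", call. = FALSE)
    frags <- paste0(frags, substr(adapter, 1L, pad_len))
  }
  reads <- data.frame(
    id = sprintf("%s:%06d:site%d", sample_name, seq_len(n_reads),
                 s$site_id[res$idx]),
    seq = frags,
    qual = strrep("I", nchar(frags[1])),
    stringsAsFactors = FALSE
  )
  list(reads = reads, truth = truth, sample = sample_name, group = group)
}

#' Write reads as FASTQ (Sanger / Phred+33 qualities)
#' @param reads data.frame with id, seq, qual (as returned in
#'   `simulate_digest_reads()$reads`).
#' @param path output FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0L) {
    file.create(path)
    return(invisible(path))
  }
  lines <- as.vector(rbind(paste0("@", reads$id), reads$seq, "+",
                           reads$qual))
  writeLines(lines, path)
  invisible(path)
}

#' Read a FASTQ file into the package's read table
#' @param path FASTQ path (gzip allowed).
#' @return data.frame with id, seq, qual.
#' @export
read_fastq <- function(path) {
  if (file.size(path) == 0)
    return(data.frame(id = character(), seq = character(),
                      qual = character(), stringsAsFactors = FALSE))
  seqs <- Biostrings::readDNAStringSet(path, format = "fastq",
                                       with.qualities = TRUE)
  data.frame(id = names(seqs), seq = as.character(seqs),
             qual = as.character(S4Vectors::mcols(seqs)$qualities),
             row.names = NULL, stringsAsFactors = FALSE)
}
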