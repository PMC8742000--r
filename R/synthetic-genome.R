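# Toy genome generation for pipeline testing.
#
# Real MeD-seq data is scored against the human reference; here a small
# genome is synthesised with recognition sites planted at a controlled
# density so that every downstream stage (scanning, filtering, counting,
# DMR detection) is testable against known ground truth.

#' Generate a toy genome with controlled recognition-site density
#'
#' Background sequence is drawn uniformly over A/C/G/T, scrubbed of all
#' chance motif occurrences (on either strand), and concrete motif
#' instances are then planted at jittered intervals averaging
#' `target_site_spacing` bp. The recorded site list is obtained by
#' re-scanning the final sequence, so it is exact by construction
#' (planting junctions occasionally create an extra overlapping site;
#' these are genuine occurrences and are recorded).
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length chromosome length in bp (>= 1000).
#' @param target_site_spacing mean spacing between planted sites in bp
#'   (>= 50); realised density is within +/-20% of 1 site per
#'   `target_site_spacing` bp.
#' @param seed integer seed; output is deterministic given the seed.
#' @param motif IUPAC recognition motif (default [MEDSEQ_MOTIF]).
#' @return a `medseq_genome`: list with `chromosomes` (DNAStringSet),
#'   `catalog` (a `medseq_catalog` from re-scanning), and `seed`.
#' @export
generate_toy_genome <- function(n_chrom, chrom_length, target_site_spacing,
                                seed, motif = MEDSEQ_MOTIF) {
  n_chrom <- check_count(n_chrom, "n_chrom", min = 1L)
  chrom_length <- check_count(chrom_length, "chrom_length", min = 1000L)
  target_site_spacing <- check_count(target_site_spacing,
                                     "target_site_spacing", min = 50L)
  motif <- check_iupac(motif)
  m <- nchar(motif)
  seqs <- with_seed(seed, {
    lapply(seq_len(n_chrom), function(i) {
      s <- scrub_motif(random_dna(chrom_length), motif)
      # plant concrete instances at jittered spacings
      jitter <- round(stats::runif(ceiling(2 * chrom_length /
                                             target_site_spacing),
                                   0.8, 1.2) * target_site_spacing)
      pos <- cumsum(c(round(target_site_spacing / 2), jitter))
      pos <- pos[pos + m <= chrom_length - 1L]
      chars <- strsplit(s, "")[[1]]
      for (p in pos) {
        inst <- concrete_motif(motif)
        chars[(p + 1):(p + m)] <- strsplit(inst, "")[[1]]
        # a G immediately 3' of a planted CCAG/CCTG instance would create
        # an overlapping minus-strand occurrence (CAGG/CTGG matches the
        # reverse complement of CCDG); keep planted sites singletons
        if (p + m + 1L <= chrom_length && chars[p + m + 1L] == "G")
          chars[p + m + 1L] <- "T"
      }
      paste(chars, collapse = "")
    })
  })
  names(seqs) <- paste0("chr", seq_len(n_chrom))
  chromosomes <- Biostrings::DNAStringSet(unlist(seqs))
  catalog <- scan_sites(chromosomes, motif)
  structure(list(chromosomes = chromosomes, catalog = catalog,
                 motif = motif, seed = seed),
            class = "medseq_genome")
}

# draw one concrete instance of an IUPAC motif (consumes RNG).
# Ambiguous positions avoid G where allowed: a planted CCGG is its own
# reverse-complement match (a strand-symmetric double site), which would
# double the realised site density relative to the target.
#' @noRd
concrete_motif <- function(motif) {
  paste(vapply(strsplit(motif, "")[[1]], function(ch) {
    opts <- strsplit(IUPAC_CODES[[ch]], "")[[1]]
    if (length(opts) > 2L) opts <- setdiff(opts, "G")
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1)), collapse = "")
}

# mutate away all occurrences of motif (both strands) in a sequence
#' @noRd
scrub_motif <- function(s, motif) {
  fwd <- Biostrings::DNAString(motif)
  rev <- Biostrings::reverseComplement(fwd)
  for (iter in 1:50) {
    subject <- Biostrings::DNAString(s)
    starts <- c(
      BiocGenerics::start(Biostrings::matchPattern(fwd, subject,
                                                   fixed = FALSE)),
      BiocGenerics::start(Biostrings::matchPattern(rev, subject,
                                                   fixed = FALSE))
    )
    if (!length(starts)) return(s)
    chars <- strsplit(s, "")[[1]]
    # the third base is A/G/T in a forward match (D) and G in a reverse
    # match; setting it to C breaks the occurrence on both strands
    for (st in unique(starts)) chars[st + 2L] <- "C"
    s <- paste(chars, collapse = "")
  }
  stop("failed to scrub motif occurrences from background sequence",
       call. = FALSE)
}

#' @export
print.medseq_genome <- function(x, ...) {
  cat("Toy genome:", length(x$chromosomes), "chromosome(s),",
      sum(Biostrings::width(x$chromosomes)), "bp,",
      nrow(x$catalog$sites), "recognition sites\n")
  invisible(x)
}

#' Write a toy genome as FASTA
#' @param genome a `medseq_genome`.
#' @param path output FASTA path.
#' @export
write_genome_fasta <- function(genome, path) {
  stopifnot(inherits(genome, "medseq_genome"))
  Biostrings::writeXStringSet(genome$chromosomes, path)
  invisible(path)
}
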