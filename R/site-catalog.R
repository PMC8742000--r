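# LpnPI recognition-site catalogue: genome-wide motif scan and TSV round-trip.
#
# The catalogue is the coordinate backbone of all counting: every read and
# every region score is keyed to a recognition-site position. Coordinates are
# 0-based half-open throughout the package; conversion to the 1-based closed
# convention happens only at the Biostrings/IRanges boundary.

#' Default LpnPI recognition motif
#'
#' The methylation-dependent restriction enzyme LpnPI recognises a CCDG-class
#' site (IUPAC D = A/G/T) containing a CpG. The motif is a parameter
#' everywhere it is used, so an alternative recognition sequence can be
#' substituted without code changes.
#' @export
MEDSEQ_MOTIF <- "CCDG"

#' Scan a genome for recognition sites
#'
#' Finds every occurrence of an IUPAC motif on the forward strand and every
#' occurrence of its reverse complement on the forward sequence (recorded as
#' minus strand). Overlapping occurrences are all reported.
#'
#' @param genome a named `DNAStringSet`, a named character vector of
#'   chromosome sequences, or the path to a FASTA file.
#' @param motif IUPAC motif string (default [MEDSEQ_MOTIF]).
#' @return an object of class `medseq_catalog`: a list with `sites`
#'   (data.frame `site_id` (dense integers from 0), `chrom`, `pos`
#'   (0-based motif start on the forward strand), `strand`), `motif`,
#'   `motif_length` and `chrom_lengths`.
#' @export
scan_sites <- function(genome, motif = MEDSEQ_MOTIF) {
  motif <- check_iupac(motif)
  if (nchar(motif) < 3L)
    stop("motif length must be >= 3", call. = FALSE)
  seqs <- as_dna_set(genome)
  fwd <- Biostrings::DNAString(motif)
  rev <- Biostrings::reverseComplement(fwd)
  per_chrom <- lapply(seq_along(seqs), function(i) {
    subject <- seqs[[i]]
    hit_f <- Biostrings::matchPattern(fwd, subject, fixed = FALSE)
    hit_r <- Biostrings::matchPattern(rev, subject, fixed = FALSE)
    n_f <- length(hit_f)
    n_r <- length(hit_r)
    data.frame(
      chrom = rep(names(seqs)[i], n_f + n_r),
      pos = c(BiocGenerics::start(hit_f), BiocGenerics::start(hit_r)) - 1L,
      strand = rep(c("+", "-"), c(n_f, n_r)),
      stringsAsFactors = FALSE
    )
  })
  sites <- do.call(rbind, per_chrom)
  sites <- sites[order(sites$chrom, sites$pos, sites$strand), , drop = FALSE]
  sites <- sites[!duplicated(sites[c("chrom", "pos", "strand")]), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  sites <- cbind(site_id = seq_len(nrow(sites)) - 1L, sites)
  structure(
    list(sites = sites, motif = motif, motif_length = nchar(motif),
         chrom_lengths = stats::setNames(Biostrings::width(seqs),
                                         names(seqs))),
    class = "medseq_catalog"
  )
}

#' @noRd
as_dna_set <- function(genome) {
  if (methods::is(genome, "DNAStringSet")) {
    seqs <- genome
  } else if (is.character(genome) && length(genome) == 1L &&
             file.exists(genome)) {
    seqs <- Biostrings::readDNAStringSet(genome)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
  } else if (is.character(genome) && !is.null(names(genome))) {
    seqs <- Biostrings::DNAStringSet(genome)
  } else if (inherits(genome, "medseq_genome")) {
    seqs <- genome$chromosomes
  } else {
    stop("`genome` must be a DNAStringSet, a named character vector, ",
         "a medseq_genome, or a FASTA path", call. = FALSE)
  }
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("genome sequences must carry unique names", call. = FALSE)
  seqs
}

#' @export
print.medseq_catalog <- function(x, ...) {
  cat("LpnPI site catalogue: ", nrow(x$sites), " sites (motif ", x$motif,
      ") on ", length(x$chrom_lengths), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' Write a site catalogue as TSV
#'
#' Columns: site_id, chrom, pos (0-based), strand.
#' @param catalog a `medseq_catalog`.
#' @param path output file.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "medseq_catalog"))
  utils::write.table(catalog$sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a site catalogue written by [write_catalog()]
#'
#' @param path TSV file.
#' @param motif motif the catalogue was built with.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @export
read_catalog <- function(path, motif = MEDSEQ_MOTIF, chrom_lengths = NULL) {
  sites <- utils::read.table(path, header = TRUE, sep = "\t",
                             stringsAsFactors = FALSE,
                             colClasses = c("integer", "character",
                                            "integer", "character"))
  if (is.null(chrom_lengths)) {
    agg <- tapply(sites$pos, sites$chrom, max)
    chrom_lengths <- stats::setNames(as.integer(agg + nchar(motif)),
                                     names(agg))
  }
  structure(
    list(sites = sites, motif = check_iupac(motif),
         motif_length = nchar(motif), chrom_lengths = chrom_lengths),
    class = "medseq_catalog"
  )
}

#' Build a catalogue directly from site positions
#'
#' Used by simulations and tests that need full control over site spacing
#' without generating a sequence first.
#' @param chrom,pos,strand parallel vectors of site coordinates (0-based).
#' @param chrom_lengths named vector; defaults to max(pos) + motif length.
#' @param motif motif string (fixes the motif length used in span
#'   arithmetic).
#' @export
catalog_from_positions <- function(chrom, pos, strand = "+",
                                   chrom_lengths = NULL,
                                   motif = MEDSEQ_MOTIF) {
  motif <- check_iupac(motif)
  n <- length(pos)
  sites <- data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
                      strand = rep_len(strand, n), stringsAsFactors = FALSE)
  sites <- sites[order(sites$chrom, sites$pos, sites$strand), , drop = FALSE]
  if (anyDuplicated(sites[c("chrom", "pos", "strand")]))
    stop("duplicate (chrom, pos, strand) site records", call. = FALSE)
  rownames(sites) <- NULL
  sites <- cbind(site_id = seq_len(nrow(sites)) - 1L, sites)
  if (is.null(chrom_lengths)) {
    agg <- tapply(sites$pos, sites$chrom, max)
    chrom_lengths <- stats::setNames(as.integer(agg + nchar(motif) + 1000L),
                                     names(agg))
  }
  structure(
    list(sites = sites, motif = motif, motif_length = nchar(motif),
         chrom_lengths = chrom_lengths),
    class = "medseq_catalog"
  )
}
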