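# Internal helpers shared across modules.

IUPAC_CODES <- c(
  A = "A", C = "C", G = "G", T = "T",
  R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
  B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT"
)

#' @noRd
check_iupac <- function(motif) {
  if (!is.character(motif) || length(motif) != 1L || is.na(motif))
    stop("`motif` must be a single character string", call. = FALSE)
  motif <- toupper(motif)
  bad <- setdiff(strsplit(motif, "")[[1]], names(IUPAC_CODES))
  if (length(bad))
    stop("non-IUPAC characters in motif: ", paste(bad, collapse = ", "),
         call. = FALSE)
  motif
}

#' @noRd
check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != as.integer(x))
    stop("`", name, "` must be a single integer >= ", min, call. = FALSE)
  as.integer(x)
}

#' @noRd
check_scalar <- function(x, name, min = -Inf, max = Inf, strict_min = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict_min) x > min else x >= min) && x <= max
  if (!ok)
    stop("`", name, "` must be a single number ",
         if (strict_min) "> " else ">= ", min,
         if (is.finite(max)) paste0(" and <= ", max) else "", call. = FALSE)
  as.numeric(x)
}

# All randomness flows through explicit seed arguments; no function touches
# the caller's RNG state.
#' @noRd
with_seed <- function(seed, code) {
  seed <- check_count(seed, "seed")
  withr::with_seed(seed, code)
}

#' @noRd
random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
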