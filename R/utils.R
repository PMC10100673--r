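#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the `A`/`C`/`G`/`T`/`N` alphabet.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @examples
#' revcomp("CCCTAA") # "TTAGGG"
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- NULL
  out
}

#' All cyclic rotations of a string
#' @param x A single string.
#' @return Character vector of `nchar(x)` rotations (including `x` itself).
#' @keywords internal
rotations <- function(x) {
  n <- nchar(x)
  if (n <= 1L) return(x)
  doubled <- paste0(x, x)
  vapply(seq_len(n), function(i) substr(doubled, i, i + n - 1L), character(1))
}

random_dna <- function(n) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# deterministic 31-bit sub-seed derivation for per-chromosome/per-end streams
derive_seed <- function(seed, ...) {
  h <- as.double(seed) %% 2147483647
  for (x in c(...)) h <- (h * 69069 + as.double(x) + 1) %% 2147483647
  as.integer(h)
}

is_dna_motif <- function(x) {
  length(x) == 1L && is.character(x) && nchar(x) >= 1L &&
    !grepl("[^ACGT]", x)
}

check_motif <- function(motif) {
  if (!is_dna_motif(motif)) {
    abort("`motif` must be a single string over A/C/G/T.", class = "telomotif_bad_motif")
  }
  invisible(motif)
}
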