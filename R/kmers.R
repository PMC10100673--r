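#' Enumerate candidate kmers in a terminal window
#'
#' For each length `k` in `[kmin, kmax]`, every distinct N-free k-substring of
#' the window is a candidate repeat unit. Its `repeat_times` is the number of
#' maximal non-overlapping left-to-right occurrences in the window, and its
#' score is `S = k * repeat_times`. Kmers overlapping an `N` are never
#' counted.
#'
#' @param window A window tibble row from [terminal_windows()] or a plain
#'   sequence string.
#' @param kmin,kmax Candidate unit length range (defaults 5 and 30, the range
#'   spanned by known telomeric motifs).
#' @param min_count Keep only kmers occurring at least this many times
#'   (default 1, i.e. everything).
#' @return Tibble with columns `kmer`, `k`, `repeat_times`, `score`.
#' @examples
#' enumerate_kmers(strrep("TTAGGG", 3), kmin = 6, kmax = 6)
#' @export
enumerate_kmers <- function(window, kmin = 5L, kmax = 30L, min_count = 1L) {
  seq <- if (is.data.frame(window)) window$seq[1] else window
  stopifnot(kmin >= 1L, kmax >= kmin, min_count >= 1L)
  if (nchar(seq) < kmin) {
    inform("Window shorter than `kmin`; no kmers enumerated.")
    return(tibble(kmer = character(), k = integer(),
                  repeat_times = integer(), score = integer()))
  }
  res <- cpp_enumerate_kmers(seq, as.integer(kmin), as.integer(kmax),
                             as.integer(min_count))
  tibble(kmer = res$kmer, k = res$k, repeat_times = res$repeat_times,
         score = res$k * res$repeat_times)
}

#' Kmer score
#'
#' The score of a candidate repeat unit is its length multiplied by its
#' repeat count in the window.
#'
#' @param kmer Character vector of kmers.
#' @param repeat_times Integer vector of repeat counts.
#' @return Integer vector of scores.
#' @examples
#' score_kmer("TTAGGG", 50) # 300
#' @export
score_kmer <- function(kmer, repeat_times) {
  stopifnot(all(repeat_times >= 1))
  as.integer(nchar(kmer) * repeat_times)
}

#' Pairwise tournament value of two kmers on one window
#'
#' The base value is `S1 - S2`. When one kmer is a proper substring of the
#' other, the shorter kmer is additionally penalised by the number of its
#' counted occurrences that lie inside counted occurrences of the longer
#' kmer, multiplied by its own length (those occurrences are already
#' explained by the longer unit). `kmer1` wins the pairing iff the returned
#' value is positive; zero is a draw.
#'
#' @param window Window tibble row or sequence string.
#' @param kmer1,kmer2 The two competing kmers.
#' @return A double: the (possibly penalised) value of `kmer1` against
#'   `kmer2`.
#' @examples
#' pairwise_value("TTAGGTTAGGTTAGG", "TTAGG", "TTAGGTTAGG") # -5
#' @export
pairwise_value <- function(window, kmer1, kmer2) {
  seq <- if (is.data.frame(window)) window$seq[1] else window
  occ <- cpp_occurrences(seq, c(kmer1, kmer2))
  s1 <- nchar(kmer1) * length(occ[[1]])
  s2 <- nchar(kmer2) * length(occ[[2]])
  v <- s1 - s2
  pen_inside <- function(short_occ, ks, long_occ, kl) {
    if (!length(short_occ) || !length(long_occ)) return(0L)
    sum(vapply(short_occ, function(t) {
      any(long_occ <= t & t + ks <= long_occ + kl)
    }, logical(1)))
  }
  if (nchar(kmer1) < nchar(kmer2) && grepl(kmer1, kmer2, fixed = TRUE)) {
    v <- v - pen_inside(occ[[1]], nchar(kmer1), occ[[2]], nchar(kmer2)) * nchar(kmer1)
  } else if (nchar(kmer2) < nchar(kmer1) && grepl(kmer2, kmer1, fixed = TRUE)) {
    v <- v + pen_inside(occ[[2]], nchar(kmer2), occ[[1]], nchar(kmer1)) * nchar(kmer2)
  }
  as.double(v)
}

#' Reduce a kmer to its minimal repeat unit
#'
#' Returns the shortest prefix whose tandem repetition reconstructs the kmer
#' (e.g. a winning 30-mer that is five perfect copies of a 6-nt unit reduces
#' to that unit). Primitive kmers are returned unchanged.
#'
#' @param kmer Character vector.
#' @return Character vector of minimal units.
#' @examples
#' reduce_to_minimal_unit("TTAGGGTTAGGG") # "TTAGGG"
#' @export
reduce_to_minimal_unit <- function(kmer) {
  vapply(kmer, function(x) {
    n <- nchar(x)
    for (p in seq_len(n)) {
      if (n %% p != 0L) next
      unit <- substr(x, 1L, p)
      if (strrep(unit, n %/% p) == x) return(unit)
    }
    x
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical rotation class of a motif
#'
#' Telomeric arrays at the two chromosome ends carry the same motif in
#' opposite orientations: C-rich at the left end (e.g. `CCCTAA`), G-rich at
#' the right (e.g. `TTAGGG`), and the phase in which a rotationally periodic
#' motif is reported is arbitrary (`TTAGTCAGGG` and `CAGGGTTAGT` are the same
#' unit). The canonical class key is obtained by reverse-complementing
#' left-end units into the G-rich orientation and taking the
#' lexicographically smallest rotation.
#'
#' @param kmer Character vector of primitive repeat units.
#' @param end `"left"` or `"right"`: which chromosome end each unit was
#'   observed at (left-end units are reverse-complemented first). Recycled.
#' @return Character vector of canonical class keys.
#' @examples
#' canonical_rotation("TTAGTCAGGG") == canonical_rotation("CAGGGTTAGT")
#' canonical_rotation("CCCTAA", end = "left") == canonical_rotation("TTAGGG")
#' @export
canonical_rotation <- function(kmer, end = "right") {
  end <- rep_len(end, length(kmer))
  oriented <- ifelse(end == "left", revcomp(kmer), kmer)
  vapply(oriented, function(x) min(rotations(x)), character(1), USE.NAMES = FALSE)
}
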