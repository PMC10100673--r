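#' Run the all-pairs kmer tournament on one window
#'
#' Every unordered pair of candidate kmers is compared once with
#' [pairwise_value()]; each kmer tallies one win per pairing it takes
#' (positive value), and the window's recommendation is the kmer with the
#' most wins. Ties are broken by higher score `S`, then shorter minimal
#' repeat unit, then lexicographically. A window with no kmer repeated at
#' least twice yields no candidate.
#'
#' @param window Window tibble row from [terminal_windows()] or a sequence
#'   string.
#' @param kmers Optional kmer tibble from [enumerate_kmers()]; enumerated
#'   from the window with `kmin`/`kmax`/`min_count` when omitted.
#' @param kmin,kmax,min_count Enumeration parameters used when `kmers` is
#'   missing (see [enumerate_kmers()]).
#' @return A one-row tibble (`chrom_id`, `end`, `winner`, `k`,
#'   `repeat_times`, `score`, `win_times`, `winner_value`, `n_kmers`), or a
#'   zero-row tibble for a candidate-free window.
#' @examples
#' run_tournament(strrep("TTAGGG", 20), kmin = 5, kmax = 8)
#' @export
run_tournament <- function(window, kmers = NULL, kmin = 5L, kmax = 30L,
                           min_count = 1L) {
  if (is.data.frame(window)) {
    seq <- window$seq[1]
    chrom_id <- window$chrom_id[1] %||% "window"
    end <- window$end[1] %||% "right"
  } else {
    seq <- window
    chrom_id <- "window"
    end <- "right"
  }
  if (is.null(kmers)) {
    kmers <- enumerate_kmers(seq, kmin = kmin, kmax = kmax, min_count = min_count)
  }
  empty <- tibble(
    chrom_id = character(), end = character(), winner = character(),
    k = integer(), repeat_times = integer(), score = integer(),
    win_times = integer(), winner_value = double(), n_kmers = integer()
  )
  if (nrow(kmers) == 0L || max(kmers$repeat_times) < 2L) {
    return(empty)
  }
  res <- cpp_tournament(seq, kmers$kmer, as.integer(kmers$score))
  wt <- res$win_times
  best <- which(wt == max(wt))
  if (length(best) > 1L) {
    cand <- kmers[best, ]
    unit_len <- nchar(reduce_to_minimal_unit(cand$kmer))
    o <- order(-cand$score, unit_len, cand$kmer)
    best <- best[o[1]]
  }
  tibble(
    chrom_id = chrom_id, end = end,
    winner = kmers$kmer[best], k = kmers$k[best],
    repeat_times = kmers$repeat_times[best], score = kmers$score[best],
    win_times = as.integer(wt[best]), winner_value = res$value_sum[best],
    n_kmers = nrow(kmers)
  )
}
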