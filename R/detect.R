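#' Detection parameters
#'
#' Bundles the tunable parameters of the motif search. Defaults follow the
#' standard settings for telomere discovery: 1000-nt terminal windows and
#' candidate unit lengths between 5 and 30 nt (the range spanned by known
#' telomeric motifs).
#'
#' @param window_n Terminal window length in nt.
#' @param kmin,kmax Candidate repeat-unit length range.
#' @param ends Which chromosome ends to search.
#' @param min_repeats Minimum repeat count of the top candidate for a
#'   `DETECTED` verdict.
#' @param min_suppchr Minimum number of supporting chromosome ends for a
#'   `DETECTED` verdict.
#' @param min_count Minimum in-window occurrence count for a kmer to enter
#'   the tournament (2 by default: a repeat unit recurs by definition, and
#'   singleton kmers carry no repeat evidence).
#' @param group_rotations Group window winners across rotation phases (and
#'   across the left-end reverse complement) into one candidate class.
#' @return A list of class `detection_params`.
#' @export
detection_params <- function(window_n = 1000L, kmin = 5L, kmax = 30L,
                             ends = c("left", "right"), min_repeats = 3L,
                             min_suppchr = 2L, min_count = 2L,
                             group_rotations = TRUE) {
  ends <- match.arg(ends, c("left", "right"), several.ok = TRUE)
  stopifnot(kmin >= 1L, kmin <= kmax, kmax <= window_n, min_repeats >= 2L,
            min_count >= 1L)
  structure(
    list(window_n = as.integer(window_n), kmin = as.integer(kmin),
         kmax = as.integer(kmax), ends = ends,
         min_repeats = as.integer(min_repeats),
         min_suppchr = as.integer(min_suppchr),
         min_count = as.integer(min_count),
         group_rotations = isTRUE(group_rotations)),
    class = "detection_params"
  )
}

#' Aggregate per-window tournament winners into ranked motif candidates
#'
#' Window winners are reduced to their minimal repeat units, canonicalised
#' into rotation classes (left-end winners via the reverse complement), and
#' ranked by the number of supporting chromosome ends (`suppchr_ends`,
#' breaking ties by the maximum winner value, then alphabetically). The
#' report is `DETECTED` when the top class has at least `min_repeats` repeats
#' on its best window and at least `min_suppchr` supporting ends.
#'
#' @param tournaments Tibble of per-window winners from [run_tournament()]
#'   (rows from candidate-free windows simply absent).
#' @param params A [detection_params()] object.
#' @param mode `"genome"` or `"reads"` (affects only bookkeeping; in read
#'   mode every supporting "end" is one read).
#' @return A `motif_report` object: list with `candidates`, `windows`,
#'   `params`, `status`, `mode`.
#' @export
aggregate_candidates <- function(tournaments, params = detection_params(),
                                 mode = "genome") {
  if (nrow(tournaments) == 0L) {
    report <- list(candidates = empty_candidates(), windows = tournaments,
                   params = params, status = "NO_DETECTABLE_TELOMERE",
                   mode = mode)
    return(structure(report, class = "motif_report"))
  }
  w <- mutate(tournaments,
    unit = reduce_to_minimal_unit(.data$winner),
    unit_grich = ifelse(.data$end == "left", revcomp(.data$unit), .data$unit),
    canonical = if (params$group_rotations) {
      canonical_rotation(.data$unit, .data$end)
    } else {
      .data$unit_grich
    }
  )
  cand <- w |>
    group_by(.data$canonical) |>
    summarise(
      motif_length = nchar(.data$canonical[1]),
      suppchr_ends = dplyr::n(),
      suppchr_chromosomes = dplyr::n_distinct(.data$chrom_id),
      max_value = max(.data$winner_value),
      best_repeat_times = max(.data$repeat_times),
      supporting_ends = paste(
        paste(.data$chrom_id, .data$end, .data$unit_grich, .data$repeat_times,
              sep = ":"),
        collapse = ";"),
      .groups = "drop"
    ) |>
    arrange(desc(.data$suppchr_ends), desc(.data$max_value), .data$canonical) |>
    rename(canonical_motif = "canonical")
  status <- if (cand$best_repeat_times[1] >= params$min_repeats &&
                cand$suppchr_ends[1] >= params$min_suppchr) {
    "DETECTED"
  } else {
    "NO_DETECTABLE_TELOMERE"
  }
  structure(
    list(candidates = cand, windows = w, params = params, status = status,
         mode = mode),
    class = "motif_report"
  )
}

empty_candidates <- function() {
  tibble(canonical_motif = character(), motif_length = integer(),
         suppchr_ends = integer(), suppchr_chromosomes = integer(),
         max_value = double(), best_repeat_times = integer(),
         supporting_ends = character())
}

#' Detect the telomeric repeat motif of a genome or read set
#'
#' Genome mode extracts a terminal window from each requested end of every
#' chromosome, runs the kmer tournament on each window, and aggregates the
#' winners into ranked rotation-canonical candidates. Read mode treats every
#' read as one window, searching both the read and its reverse complement
#' and keeping the better orientation, so support is counted in reads.
#'
#' @param x A genome tibble (columns `id`, `seq`; see [read_genome_fasta()]
#'   or [simulate_genome()]), a read tibble (columns `read_id`, `seq`; see
#'   [load_unmapped_reads()]), or a path to a FASTA file.
#' @param params A [detection_params()] object.
#' @param mode `"auto"` (guessed from columns), `"genome"` or `"reads"`.
#' @return A `motif_report`; see [aggregate_candidates()]. Use [tidy()] for
#'   the ranked candidate tibble and [glance()] for a one-row summary.
#' @examples
#' sim <- simulate_genome("TTAGGG", n_chromosomes = 2, copies_per_end = 60,
#'                        seed = 1)
#' rep <- detect_motif(sim$genome)
#' glance(rep)
#' @export
detect_motif <- function(x, params = detection_params(), mode = "auto") {
  if (is.character(x) && length(x) == 1L) {
    x <- read_genome_fasta(x)
  }
  if (mode == "auto") {
    mode <- if ("read_id" %in% names(x)) "reads" else "genome"
  }
  if (mode == "genome") {
    wins <- terminal_windows(x, window_n = params$window_n, ends = params$ends)
    tours <- purrr::map(seq_len(nrow(wins)), function(i) {
      run_tournament(wins[i, ], kmin = params$kmin, kmax = params$kmax,
                     min_count = params$min_count)
    })
    return(aggregate_candidates(bind_rows(tours), params, mode = "genome"))
  }
  # read mode: best orientation per read, everything pooled G-rich
  tours <- purrr::map(seq_len(nrow(x)), function(i) {
    fwd <- run_tournament(
      tibble(chrom_id = x$read_id[i], end = "right", seq = x$seq[i]),
      kmin = params$kmin, kmax = params$kmax, min_count = params$min_count)
    rev <- run_tournament(
      tibble(chrom_id = x$read_id[i], end = "right", seq = revcomp(x$seq[i])),
      kmin = params$kmin, kmax = params$kmax, min_count = params$min_count)
    best <- if (nrow(fwd) == 0L) rev
      else if (nrow(rev) == 0L) fwd
      else if (rev$score > fwd$score ||
               (rev$score == fwd$score && rev$win_times > fwd$win_times)) rev
      else fwd
    if (nrow(best)) {
      # pool into G-rich orientation: a C-rich winner is flagged as a
      # left-end observation so aggregation reverse-complements it
      unit <- reduce_to_minimal_unit(best$winner)
      if (stringr::str_count(unit, "G") < stringr::str_count(unit, "C")) {
        best$end <- "left"
      }
    }
    best
  })
  aggregate_candidates(bind_rows(tours), params, mode = "reads")
}

#' @export
print.motif_report <- function(x, ...) {
  cat("<motif_report>  status:", x$status, " mode:", x$mode, "\n")
  cat("  windows searched:", nrow(x$windows), "\n")
  if (nrow(x$candidates)) {
    top <- x$candidates[1, ]
    cat("  top candidate:", top$canonical_motif,
        sprintf("(length %d, ends %d, chromosomes %d, max value %g)\n",
                top$motif_length, top$suppchr_ends, top$suppchr_chromosomes,
                top$max_value))
  }
  invisible(x)
}

#' Tidy a motif report into its ranked candidate table
#' @param x A `motif_report`.
#' @param ... Unused.
#' @return The candidates tibble (one row per rotation-canonical class).
#' @export
tidy.motif_report <- function(x, ...) x$candidates

#' One-row summary of a motif report
#' @param x A `motif_report`.
#' @param ... Unused.
#' @return A one-row tibble: status, top motif and its support.
#' @export
glance.motif_report <- function(x, ...) {
  if (nrow(x$candidates) == 0L) {
    return(tibble(status = x$status, mode = x$mode, top_motif = NA_character_,
                  motif_length = NA_integer_, suppchr_ends = 0L,
                  suppchr_chromosomes = 0L, max_value = NA_real_,
                  n_windows = nrow(x$windows)))
  }
  top <- x$candidates[1, ]
  tibble(status = x$status, mode = x$mode, top_motif = top$canonical_motif,
         motif_length = top$motif_length, suppchr_ends = top$suppchr_ends,
         suppchr_chromosomes = top$suppchr_chromosomes,
         max_value = top$max_value, n_windows = nrow(x$windows))
}
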