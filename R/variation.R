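# All (possibly overlapping) 1-based match starts of an ACGT pattern.
all_starts <- function(seq, pat) {
  m <- gregexpr(paste0("(?=", pat, ")"), seq, perl = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Locate the assembled telomeric array at one chromosome end
#'
#' Starting from the terminus and proceeding inward, finds exact occurrences
#' of the motif in whatever rotation phase the outermost match fixes, and
#' extends the array occurrence by occurrence as long as no inter-occurrence
#' gap exceeds `motif length + 1` nt (so every counted gap stays in the
#' single-base-variation regime). Both ends are analysed in the G-rich
#' orientation: a left-end window is reverse-complemented first, so left-end
#' events come out already normalised to right-end motif coordinates.
#'
#' @param window One-row window tibble from [terminal_windows()] (or a plain
#'   string, treated as a right-end window).
#' @param motif Primitive telomeric motif in G-rich (right-end) orientation.
#' @return A `telomere_region` object (list with `chrom_id`, `end`, `phase`,
#'   `phase_shift`, `orientation`, genomic `start`/`stop`, `assembled_length`,
#'   an `occurrences` tibble and a `gaps` tibble), or `NULL` when fewer than
#'   two exact occurrences are found (telomere too short to analyse).
#' @examples
#' locate_telomere_region(strrep("TTAGGG", 10), "TTAGGG")$assembled_length
#' @export
locate_telomere_region <- function(window, motif) {
  check_motif(motif)
  if (reduce_to_minimal_unit(motif) != motif) {
    abort("`motif` must be primitive (use reduce_to_minimal_unit()).",
          class = "telomotif_bad_motif")
  }
  if (!is.data.frame(window)) {
    window <- tibble(chrom_id = "window", end = "right", seq = window,
                     genomic_start = 0L, genomic_stop = nchar(window))
  }
  end <- window$end[1]
  W <- nchar(window$seq[1])
  seq_g <- if (end == "left") revcomp(window$seq[1]) else window$seq[1]
  L <- nchar(motif)
  rots <- rotations(motif)

  # outermost exact match over all rotation phases fixes the phase
  starts_by_rot <- purrr::map(rots, ~ all_starts(seq_g, .x))
  last_end <- purrr::map_int(starts_by_rot,
                             ~ if (length(.x)) max(.x) + L - 1L else -1L)
  if (max(last_end) < 0L) return(NULL)
  r <- which.max(last_end) - 1L            # rotation shift of the phase
  phase <- rots[r + 1L]
  ss <- starts_by_rot[[r + 1L]]

  # greedy inward walk: nearest previous occurrence, gaps capped at L + 1
  cur <- max(ss)
  occ <- cur
  repeat {
    cand <- ss[ss + L <= cur]
    if (!length(cand)) break
    nxt <- max(cand)
    if (cur - (nxt + L) > L + 1L) break
    occ <- c(occ, nxt)
    cur <- nxt
  }
  if (length(occ) < 2L) return(NULL)
  occ <- rev(occ)                           # ascending in the G-rich frame

  # map a closed 1-based G-frame interval to 0-based half-open genomic coords
  to_genomic <- function(a, b) {
    gs <- window$genomic_start[1]
    if (end == "left") c(gs + W - b, gs + W - a + 1L) else c(gs + a - 1L, gs + b)
  }

  occ_gen <- t(vapply(occ, function(s) to_genomic(s, s + L - 1L), numeric(2)))
  occurrences <- tibble(
    frame_start = occ, frame_stop = occ + L,
    genomic_start = as.integer(occ_gen[, 1]), genomic_stop = as.integer(occ_gen[, 2])
  )

  gi <- which(diff(occ) > L)                # gaps with positive length
  gaps <- purrr::map(gi, function(i) {
    a <- occ[i] + L; b <- occ[i + 1L] - 1L  # closed frame interval of the gap
    gg <- to_genomic(a, b)
    tibble(seq = substr(seq_g, a, b), left_occ_index = i,
           right_occ_index = i + 1L, frame_start = a,
           genomic_start = as.integer(gg[1]), genomic_stop = as.integer(gg[2]))
  })
  gaps <- if (length(gaps)) bind_rows(gaps) else
    tibble(seq = character(), left_occ_index = integer(),
           right_occ_index = integer(), frame_start = integer(),
           genomic_start = integer(), genomic_stop = integer())

  reg_gen <- to_genomic(occ[1], occ[length(occ)] + L - 1L)
  structure(
    list(chrom_id = window$chrom_id[1], end = end,
         orientation = if (end == "left") "C_RICH" else "G_RICH",
         motif = motif, phase = phase, phase_shift = as.integer(r),
         start = as.integer(reg_gen[1]), stop = as.integer(reg_gen[2]),
         assembled_length = as.integer(reg_gen[2] - reg_gen[1]),
         occurrences = occurrences, gaps = gaps),
    class = "telomere_region"
  )
}

#' @export
print.telomere_region <- function(x, ...) {
  cat("<telomere_region>", x$chrom_id, x$end, "\n")
  cat(sprintf("  phase %s (shift %d), %d occurrences, %d gaps, %d nt assembled [%d, %d)\n",
              x$phase, x$phase_shift, nrow(x$occurrences), nrow(x$gaps),
              x$assembled_length, x$start, x$stop))
  invisible(x)
}

#' Gap sequences of a telomeric array
#'
#' @param region A `telomere_region` from [locate_telomere_region()].
#' @return Tibble of gap sequences (G-rich orientation) strictly between
#'   consecutive exact motif occurrences, ordered by genomic position.
#' @export
extract_gaps <- function(region) {
  stopifnot(inherits(region, "telomere_region"))
  arrange(region$gaps, .data$genomic_start)
}

# Classify all gaps of one region into SV events in supplied-motif
# coordinates (phase conversion included). Returns list(events, n_complex).
classify_region_gaps <- function(region) {
  L <- nchar(region$motif)
  r <- region$phase_shift
  if (nrow(region$gaps) == 0L) {
    return(list(events = empty_events(), n_complex = 0L))
  }
  rows <- purrr::map(seq_len(nrow(region$gaps)), function(i) {
    g <- region$gaps[i, ]
    cl <- classify_sv(g$seq, region$phase)
    if (cl$type == "COMPLEX") return(mutate(cl, gap_i = i))
    # convert from phase coordinates to supplied-motif coordinates
    site <- cl$motif_site
    if (cl$type == "SI") {
      s0 <- (site - 1L + r) %% L + 1L
      site <- if (s0 == 1L) L + 1L else s0
    } else {
      site <- (site - 1L + r) %% L + 1L
    }
    mutate(cl, motif_site = site, gap_i = i)
  })
  rows <- bind_rows(rows)
  n_complex <- sum(rows$type == "COMPLEX")
  ev <- filter(rows, .data$type != "COMPLEX")
  if (nrow(ev) == 0L) return(list(events = empty_events(), n_complex = n_complex))
  gsub_ <- region$gaps[ev$gap_i, ]
  ev <- tibble(
    chrom_id = region$chrom_id, end = region$end, type = ev$type,
    motif_site = ev$motif_site, ref = ev$ref, alt = ev$alt,
    genomic_pos = gsub_$genomic_start
  )
  list(events = ev, n_complex = n_complex)
}

empty_events <- function() {
  tibble(chrom_id = character(), end = character(), type = character(),
         motif_site = integer(), ref = character(), alt = character(),
         genomic_pos = integer())
}

#' Per-end single-base-variation statistics
#'
#' The SV frequency of one chromosome end is the SV count divided by the
#' total motif count, where the total counts typical (exact) motifs plus
#' motifs carrying one SV. The per-type proportions divide each of the SC,
#' SD and SI counts by the SV count. Ends without an analysable telomere get
#' an `NA` frequency (reported as `NAN` on file).
#'
#' @param events Tibble of SV events (columns `chrom_id`, `end`, `type`).
#' @param regions Tibble with one row per analysed end: `chrom_id`, `end`,
#'   `typical_count`, `complex_count`, `assembled_length` (absent telomeres
#'   as `NA` counts).
#' @return Tibble with one row per (chromosome, end): counts, `sv_frequency`,
#'   `sc_pct`, `sd_pct`, `si_pct`.
#' @examples
#' ev <- tibble::tibble(chrom_id = "c1", end = "right",
#'                      type = c("SC", "SC", "SD", "SI"))
#' rg <- tibble::tibble(chrom_id = "c1", end = "right", typical_count = 16L,
#'                      complex_count = 0L, assembled_length = 120L)
#' compute_sv_stats(ev, rg)
#' @export
compute_sv_stats <- function(events, regions) {
  evc <- events |>
    group_by(.data$chrom_id, .data$end) |>
    summarise(
      sv_count = dplyr::n(),
      sc_count = sum(.data$type == "SC"),
      sd_count = sum(.data$type == "SD"),
      si_count = sum(.data$type == "SI"),
      .groups = "drop"
    )
  out <- regions |>
    left_join(evc, by = c("chrom_id", "end")) |>
    mutate(
      sv_count = ifelse(is.na(.data$typical_count), NA_integer_,
                        dplyr::coalesce(.data$sv_count, 0L)),
      sc_count = dplyr::coalesce(.data$sc_count, 0L),
      sd_count = dplyr::coalesce(.data$sd_count, 0L),
      si_count = dplyr::coalesce(.data$si_count, 0L),
      total_motif_count = .data$typical_count + .data$sv_count,
      sv_frequency = ifelse(!is.na(.data$total_motif_count) &
                              .data$total_motif_count > 0,
                            .data$sv_count / .data$total_motif_count, NA_real_),
      sc_pct = ifelse(.data$sv_count > 0, .data$sc_count / .data$sv_count, NA_real_),
      sd_pct = ifelse(.data$sv_count > 0, .data$sd_count / .data$sv_count, NA_real_),
      si_pct = ifelse(.data$sv_count > 0, .data$si_count / .data$sv_count, NA_real_)
    ) |>
    arrange(.data$chrom_id, match(.data$end, c("left", "right")))
  out
}

#' Positional SV profile along the motif
#'
#' Tallies deletions (`d`), insertions (`i`) and base changes (`c`) at each
#' 1-based motif site, separately per end but always in the right-end
#' (G-rich) motif coordinate frame, so the two ends are directly comparable.
#' Site `L + 1` collects insertions after the final motif base.
#'
#' @param events SV event tibble (columns `end`, `type`, `motif_site`).
#' @param motif The motif (G-rich orientation) the sites refer to.
#' @return Tibble: `end`, `motif_site`, `ref_base`, `d_count`, `i_count`,
#'   `c_count`.
#' @export
positional_profile <- function(events, motif) {
  L <- nchar(motif)
  ends <- sort(unique(events$end))
  if (!length(ends)) ends <- c("left", "right")
  grid <- tidyr::expand_grid(end = ends, motif_site = seq_len(L + 1L))
  tallies <- events |>
    group_by(.data$end, .data$motif_site) |>
    summarise(
      d_count = sum(.data$type == "SD"),
      i_count = sum(.data$type == "SI"),
      c_count = sum(.data$type == "SC"),
      .groups = "drop"
    )
  grid |>
    left_join(tallies, by = c("end", "motif_site")) |>
    mutate(
      dplyr::across(dplyr::ends_with("_count"), ~ dplyr::coalesce(.x, 0L)),
      ref_base = ifelse(.data$motif_site <= L,
                        substring(motif, .data$motif_site, .data$motif_site), "-")
    ) |>
    select("end", "motif_site", "ref_base", "d_count", "i_count", "c_count")
}

#' Analyse single-base variation in telomere sequences
#'
#' Genome mode locates the telomeric array at both ends of every chromosome,
#' extracts the gap sequences between exact motif copies, aligns each gap to
#' the motif and classifies single-base changes, deletions and insertions,
#' reporting per-end frequencies, type proportions and a positional profile.
#' Read mode does the same per read (in its better orientation) and pools
#' everything into one genome-wide average row.
#'
#' @param x Genome tibble, read tibble or FASTA path (as in [detect_motif()]).
#' @param motif Telomeric motif, G-rich orientation (typically the top
#'   candidate from [detect_motif()]).
#' @param window_n Terminal search window in nt. The default (8000) is
#'   deliberately larger than the detection default so the whole assembled
#'   array is covered.
#' @param ends Which ends to analyse (genome mode).
#' @param mode `"auto"`, `"genome"` or `"reads"`.
#' @return An `sv_analysis` object: list with `stats`, `events`, `regions`,
#'   `profile`, `motif`, `mode`. Use [tidy()] for the per-end stats and
#'   [glance()] for a pooled summary.
#' @examples
#' sim <- simulate_genome("TTAGGG", n_chromosomes = 2, copies_per_end = 50,
#'                        sc = 0.1, seed = 1)
#' va <- analyze_variation(sim$genome, "TTAGGG")
#' tidy(va)
#' @export
analyze_variation <- function(x, motif, window_n = 8000L,
                              ends = c("left", "right"), mode = "auto") {
  check_motif(motif)
  motif <- reduce_to_minimal_unit(motif)
  if (is.character(x) && length(x) == 1L) x <- read_genome_fasta(x)
  if (mode == "auto") {
    mode <- if ("read_id" %in% names(x)) "reads" else "genome"
  }

  if (mode == "genome") {
    wins <- terminal_windows(x, window_n = window_n, ends = ends)
    pieces <- purrr::map(seq_len(nrow(wins)), function(i) {
      region <- locate_telomere_region(wins[i, ], motif)
      if (is.null(region)) {
        return(list(
          region_row = tibble(chrom_id = wins$chrom_id[i], end = wins$end[i],
                              phase = NA_character_, typical_count = NA_integer_,
                              complex_count = NA_integer_,
                              assembled_length = NA_integer_,
                              start = NA_integer_, stop = NA_integer_),
          events = empty_events()
        ))
      }
      cl <- classify_region_gaps(region)
      list(
        region_row = tibble(chrom_id = region$chrom_id, end = region$end,
                            phase = region$phase,
                            typical_count = nrow(region$occurrences),
                            complex_count = cl$n_complex,
                            assembled_length = region$assembled_length,
                            start = region$start, stop = region$stop),
        events = cl$events
      )
    })
    regions <- bind_rows(purrr::map(pieces, "region_row"))
    events <- bind_rows(purrr::map(pieces, "events"))
    stats <- compute_sv_stats(events, regions)
    profile <- positional_profile(events, motif)
  } else {
    per_read <- purrr::map(seq_len(nrow(x)), function(i) {
      best <- NULL
      for (s in c(x$seq[i], revcomp(x$seq[i]))) {
        region <- locate_telomere_region(
          tibble(chrom_id = x$read_id[i], end = "right", seq = s,
                 genomic_start = 0L, genomic_stop = nchar(s)), motif)
        if (!is.null(region) &&
            (is.null(best) || nrow(region$occurrences) > nrow(best$occurrences))) {
          best <- region
        }
      }
      if (is.null(best)) return(NULL)
      cl <- classify_region_gaps(best)
      list(typical = nrow(best$occurrences), complex = cl$n_complex,
           assembled = best$assembled_length, events = cl$events)
    })
    per_read <- purrr::compact(per_read)
    events <- bind_rows(purrr::map(per_read, "events"))
    if (nrow(events)) events$end <- "pooled"
    events$chrom_id <- if (nrow(events)) "genome" else character(0)
    typical <- sum(purrr::map_int(per_read, "typical"))
    regions <- tibble(
      chrom_id = "genome", end = "pooled", phase = motif,
      typical_count = if (length(per_read)) typical else NA_integer_,
      complex_count = sum(purrr::map_int(per_read, "complex")),
      assembled_length = sum(purrr::map_int(per_read, "assembled")),
      start = NA_integer_, stop = NA_integer_
    )
    stats <- compute_sv_stats(events, regions)
    profile <- positional_profile(events, motif)
  }

  structure(
    list(stats = stats, events = events, regions = regions, profile = profile,
         motif = motif, mode = mode, window_n = as.integer(window_n)),
    class = "sv_analysis"
  )
}

#' @export
print.sv_analysis <- function(x, ...) {
  cat("<sv_analysis>  motif:", x$motif, " mode:", x$mode, "\n")
  cat(sprintf("  %d end(s) analysed, %d SV event(s), mean SV frequency %.4g\n",
              nrow(x$stats), nrow(x$events),
              mean(x$stats$sv_frequency, na.rm = TRUE)))
  invisible(x)
}

#' Tidy an SV analysis into its per-end statistics table
#' @param x An `sv_analysis`.
#' @param ... Unused.
#' @return The per-end stats tibble (Eq.-style frequency and proportions).
#' @export
tidy.sv_analysis <- function(x, ...) x$stats

#' One-row pooled summary of an SV analysis
#' @param x An `sv_analysis`.
#' @param ... Unused.
#' @return A one-row tibble pooling all analysed ends.
#' @export
glance.sv_analysis <- function(x, ...) {
  st <- filter(x$stats, !is.na(.data$typical_count))
  sv <- sum(st$sv_count)
  tot <- sum(st$total_motif_count)
  tibble(
    motif = x$motif, mode = x$mode, n_ends = nrow(x$stats),
    n_ends_analysed = nrow(st), sv_count = sv, total_motif_count = tot,
    sv_frequency = ifelse(tot > 0, sv / tot, NA_real_),
    sc_pct = ifelse(sv > 0, sum(st$sc_count) / sv, NA_real_),
    sd_pct = ifelse(sv > 0, sum(st$sd_count) / sv, NA_real_),
    si_pct = ifelse(sv > 0, sum(st$si_count) / sv, NA_real_),
    max_assembled_length = if (nrow(st)) max(st$assembled_length) else NA_integer_
  )
}
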