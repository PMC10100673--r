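pkg_version <- function() as.character(utils::packageVersion("telomotif"))

#' Write a motif report to TSV or JSON
#'
#' TSV output is the ranked candidate table with a header row; JSON output
#' wraps version, parameters and results in one object and round-trips
#' losslessly through [read_motif_report_json()]. Row and column order are
#' deterministic, so identical reports produce byte-identical files.
#'
#' @param report A `motif_report` from [detect_motif()].
#' @param path Output path.
#' @param format `"tsv"` or `"json"` (guessed from the extension by default).
#' @return `path`, invisibly.
#' @export
write_motif_report <- function(report, path, format = c("auto", "tsv", "json")) {
  stopifnot(inherits(report, "motif_report"))
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "tsv"
  }
  cand <- mutate(report$candidates, status = report$status)
  if (format == "tsv") {
    readr::write_tsv(cand, path, na = "NAN")
  } else {
    jsonlite::write_json(
      list(version = pkg_version(),
           parameters = unclass(report$params),
           results = list(status = report$status, mode = report$mode,
                          candidates = cand)),
      path, auto_unbox = TRUE, digits = NA, null = "null"
    )
  }
  invisible(path)
}

#' Read back a JSON motif report
#' @param path Path written by [write_motif_report()] with `format = "json"`.
#' @return List with `version`, `parameters` and `results` (candidates as a
#'   tibble).
#' @export
read_motif_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$results$candidates <- as_tibble(x$results$candidates)
  x
}

#' Write SV analysis tables to TSV
#'
#' Writes the per-end statistics (`<prefix>.stats.tsv`), the event list
#' (`<prefix>.events.tsv`) and the positional profile
#' (`<prefix>.profile.tsv`). Missing values (ends whose telomere is too
#' short to analyse) are written as `NAN`.
#'
#' @param va An `sv_analysis` from [analyze_variation()].
#' @param prefix Output path prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_sv_reports <- function(va, prefix) {
  stopifnot(inherits(va, "sv_analysis"))
  paths <- c(stats = paste0(prefix, ".stats.tsv"),
             events = paste0(prefix, ".events.tsv"),
             profile = paste0(prefix, ".profile.tsv"))
  stats <- select(va$stats, "chrom_id", "end", "assembled_length",
                  "typical_count", "sv_count", "complex_count",
                  "sv_frequency", "sc_pct", "sd_pct", "si_pct")
  readr::write_tsv(stats, paths["stats"], na = "NAN")
  events <- select(va$events, "chrom_id", "end", "genomic_pos", "type",
                   "motif_site", "ref", "alt")
  readr::write_tsv(events, paths["events"], na = "NAN")
  readr::write_tsv(va$profile, paths["profile"], na = "NAN")
  invisible(paths)
}
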