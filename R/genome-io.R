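#' Read an assembled genome from FASTA
#'
#' Reads a (possibly gzip-compressed) multi-record FASTA into a tibble with
#' one row per chromosome/contig. Sequences are uppercased and any character
#' outside `A`/`C`/`G`/`T`/`N` (for example IUPAC ambiguity codes) is coerced
#' to `N` with a warning, since the motif search only ever counts unambiguous
#' kmers.
#'
#' @param path Path to a FASTA file (plain or `.gz`).
#' @return A tibble with columns `id` (first whitespace-delimited token of the
#'   header), `seq` and `length`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c1", "ACGTacgt"), fa)
#' read_genome_fasta(fa)
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("FASTA file not found: ", path), class = "telomotif_io_error")
  }
  dss <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    error = function(e) abort(paste0("Failed to parse FASTA '", path, "': ",
                                     conditionMessage(e)),
                              class = "telomotif_format_error")
  )
  if (length(dss) == 0L) {
    abort(paste0("FASTA file '", path, "' contains no records."),
          class = "telomotif_format_error")
  }
  ids <- sub("\\s.*$", "", names(dss))
  seqs <- toupper(as.character(dss))
  names(seqs) <- NULL
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    abort(paste0("FASTA record with empty sequence: ",
                 paste(ids[empty], collapse = ", ")),
          class = "telomotif_format_error")
  }
  n_bad <- sum(nchar(gsub("[ACGTN]", "", seqs)))
  if (n_bad > 0L) {
    warn(paste0(n_bad, " non-ACGTN character(s) coerced to N."))
    seqs <- gsub("[^ACGTN]", "N", seqs)
  }
  if (anyDuplicated(ids)) {
    abort("Duplicated sequence ids in FASTA.", class = "telomotif_format_error")
  }
  tibble(id = ids, seq = seqs, length = nchar(seqs))
}

#' Extract one terminal search window from a chromosome
#'
#' Takes the `window_n` terminal bases of one chromosome end, skipping any
#' run of `N`s at the terminus first (terminal `N` padding does not count
#' towards the window length; `N`s in the interior of the window are kept).
#' If the chromosome is shorter than `window_n` after stripping, the whole
#' remaining sequence is returned. Coordinates are 0-based half-open on the
#' original chromosome.
#'
#' @param seq Chromosome sequence (single string) or a one-row genome tibble.
#' @param end `"left"` or `"right"`: the beginning or the end of the sequence
#'   as stored.
#' @param window_n Window length in nt (default 1000).
#' @param chrom_id Chromosome id used in the output (default `"chr"`).
#' @return One-row tibble: `chrom_id`, `end`, `seq`, `genomic_start`,
#'   `genomic_stop`, `n_stripped`, `window_n`.
#' @examples
#' extract_terminal_window("NNNNNACGTACGT", "left", window_n = 4)
#' @export
extract_terminal_window <- function(seq, end = c("left", "right"),
                                    window_n = 1000L, chrom_id = "chr") {
  end <- match.arg(end)
  if (is.data.frame(seq)) {
    chrom_id <- seq$id[1]
    seq <- seq$seq[1]
  }
  stopifnot(window_n >= 1L)
  L <- nchar(seq)
  if (end == "left") {
    n_strip <- attr(regexpr("^N*", seq), "match.length")
  } else {
    n_strip <- attr(regexpr("N*$", seq), "match.length")
  }
  if (n_strip >= L) {
    abort(paste0("Chromosome '", chrom_id, "' is entirely N at the ", end,
                 " end; no window can be extracted."),
          class = "telomotif_empty_window")
  }
  if (end == "left") {
    start <- n_strip                              # 0-based
    stop_ <- min(L, start + window_n)
  } else {
    stop_ <- L - n_strip
    start <- max(0L, stop_ - window_n)
  }
  tibble(
    chrom_id = chrom_id, end = end,
    seq = substr(seq, start + 1L, stop_),
    genomic_start = as.integer(start), genomic_stop = as.integer(stop_),
    n_stripped = as.integer(n_strip), window_n = as.integer(window_n)
  )
}

#' Terminal windows for every chromosome end of a genome
#'
#' @param genome Genome tibble as returned by [read_genome_fasta()] or
#'   [simulate_genome()] (columns `id`, `seq`).
#' @param window_n Window length in nt.
#' @param ends Which ends to extract (`"left"`, `"right"` or both).
#' @return Tibble of windows, one row per (chromosome, end), ordered by
#'   chromosome then left before right. All-N ends are skipped with a warning.
#' @export
terminal_windows <- function(genome, window_n = 1000L, ends = c("left", "right")) {
  ends <- match.arg(ends, c("left", "right"), several.ok = TRUE)
  rows <- purrr::map(seq_len(nrow(genome)), function(i) {
    purrr::map(ends, function(e) {
      tryCatch(
        extract_terminal_window(genome$seq[i], e, window_n, genome$id[i]),
        telomotif_empty_window = function(cnd) {
          warn(conditionMessage(cnd))
          NULL
        }
      )
    })
  })
  out <- bind_rows(purrr::flatten(rows))
  if (nrow(out)) {
    out <- arrange(out, .data$chrom_id, match(.data$end, c("left", "right")))
  }
  out
}

#' Load reads for read-mode detection
#'
#' FASTQ input passes every read through; SAM/BAM input keeps only records
#' whose FLAG has the unmapped bit (0x4) set, which is where telomeric reads
#' end up when the reference assembly lacks telomeres. Sequences are
#' uppercased; quality strings are ignored.
#'
#' @param path Path to a FASTQ (possibly gzipped), SAM or BAM file.
#' @param format `"fastq"`, `"sam"` or `"bam"`; guessed from the extension by
#'   default.
#' @return Tibble with columns `read_id` and `seq`, plus a `source` attribute.
#' @export
load_unmapped_reads <- function(path, format = c("auto", "fastq", "sam", "bam")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    abort(paste0("Read file not found: ", path), class = "telomotif_io_error")
  }
  if (format == "auto") {
    format <- if (grepl("\\.(fq|fastq)(\\.gz)?$", path, ignore.case = TRUE)) "fastq"
      else if (grepl("\\.bam$", path, ignore.case = TRUE)) "bam"
      else if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam"
      else abort("Cannot guess read format; pass `format` explicitly.",
                 class = "telomotif_format_error")
  }
  if (format == "fastq") {
    dss <- tryCatch(
      Biostrings::readDNAStringSet(path, format = "fastq"),
      error = function(e) abort(paste0("Malformed FASTQ '", path, "': ",
                                       conditionMessage(e)),
                                class = "telomotif_format_error")
    )
    if (length(dss) == 0L) {
      abort("FASTQ contains no reads.", class = "telomotif_format_error")
    }
    seqs <- toupper(as.character(dss))
    names(seqs) <- NULL
    out <- tibble(read_id = sub("\\s.*$", "", names(dss)), seq = seqs)
    attr(out, "source") <- "fastq"
    return(out)
  }
  bam <- path
  if (format == "sam") {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE, indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = TRUE),
    what = c("qname", "seq")
  )
  rec <- Rsamtools::scanBam(bam, param = param)[[1]]
  if (length(rec$qname) == 0L) {
    abort("No unmapped reads in SAM/BAM input.", class = "telomotif_no_reads")
  }
  seqs <- toupper(as.character(rec$seq))
  names(seqs) <- NULL
  out <- tibble(read_id = rec$qname, seq = seqs)
  attr(out, "source") <- "sam_unmapped"
  out
}

#' Write a FASTA file from a genome tibble
#' @param genome Tibble with `id` and `seq`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  dss <- Biostrings::DNAStringSet(genome$seq)
  names(dss) <- genome$id
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}
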