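# Build one G-rich telomeric array of `copies` motif copies with at most one
# injected single-base variation per copy. Returns the array string plus a
# truth tibble of injected events (sites in supplied-motif coordinates).
build_array <- function(motif, copies, sc, sd, si, phase_shift, seed) {
  L <- nchar(motif)
  unit <- rotations(motif)[phase_shift %% L + 1L]
  set.seed(seed)
  u <- stats::runif(copies)
  bases <- c("A", "C", "G", "T")
  seqs <- character(copies)
  events <- vector("list", copies)
  for (i in seq_len(copies)) {
    if (u[i] < sc) {
      site <- sample.int(L, 1L)
      ref <- substring(unit, site, site)
      alt <- sample(setdiff(bases, ref), 1L)
      seqs[i] <- paste0(substr(unit, 1L, site - 1L), alt,
                        substr(unit, site + 1L, L))
      events[[i]] <- tibble(copy = i, type = "SC", site = site, ref = ref, alt = alt)
    } else if (u[i] < sc + sd) {
      site <- sample.int(L, 1L)
      ref <- substring(unit, site, site)
      seqs[i] <- paste0(substr(unit, 1L, site - 1L), substr(unit, site + 1L, L))
      events[[i]] <- tibble(copy = i, type = "SD", site = site, ref = ref,
                            alt = NA_character_)
    } else if (u[i] < sc + sd + si) {
      site <- sample.int(L + 1L, 1L)        # insert before site; L+1 = after end
      alt <- sample(bases, 1L)
      seqs[i] <- paste0(substr(unit, 1L, site - 1L), alt,
                        substr(unit, site, L))
      events[[i]] <- tibble(copy = i, type = "SI", site = site,
                            ref = NA_character_, alt = alt)
    } else {
      seqs[i] <- unit
    }
  }
  ev <- bind_rows(events)
  if (nrow(ev)) {
    # report truth sites in supplied-motif coordinates, matching the analyser
    ev$site <- ifelse(ev$type == "SI" &
                        ((ev$site - 1L + phase_shift) %% L + 1L) == 1L,
                      L + 1L,
                      (ev$site - 1L + phase_shift) %% L + 1L)
  } else {
    ev <- tibble(copy = integer(), type = character(), site = integer(),
                 ref = character(), alt = character())
  }
  list(seq = paste(seqs, collapse = ""), events = ev)
}

#' Simulate a genome with known telomeric structure
#'
#' Each chromosome is built as `N`-padding + a C-rich left telomeric array
#' (the reverse complement of a G-rich array) + a random subtelomere + a
#' random core + a random subtelomere + a G-rich right array + `N`-padding.
#' Every motif copy carries at most one injected single-base change,
#' deletion or insertion, drawn independently per copy with the given
#' per-copy rates, and every injected event is recorded in the returned
#' truth tables, so detection and variation analysis can be scored against
#' ground truth.
#'
#' @param motif Telomeric repeat unit, G-rich orientation, primitive.
#' @param n_chromosomes Number of chromosomes.
#' @param copies_per_end Motif copies per telomeric array.
#' @param sc,sd,si Per-copy probabilities of a single-base change, deletion
#'   and insertion (their sum must be at most 1).
#' @param subtelomere_len,core_len Lengths (nt) of the uniform-random
#'   subtelomeric and core segments.
#' @param n_pad Number of terminal `N`s added to each end.
#' @param phase_shift Rotation offset applied to the first base of every
#'   array copy.
#' @param seed Seed; every chromosome end derives its own deterministic
#'   sub-seed, so the same seed reproduces the genome byte for byte.
#' @return A list of class `telosim`: `genome` (tibble `id`, `seq`,
#'   `length`), `truth` (per-end tibble with motif, copy count and array
#'   coordinates) and `events` (per-end injected SV events, sites in G-rich
#'   motif coordinates).
#' @examples
#' sim <- simulate_genome("TTAGGG", n_chromosomes = 2, copies_per_end = 20,
#'                        seed = 42)
#' sim$truth
#' @export
simulate_genome <- function(motif, n_chromosomes = 8L, copies_per_end = 100L,
                            sc = 0.012, sd = 0.004, si = 0.004,
                            subtelomere_len = 500L, core_len = 2000L,
                            n_pad = 0L, phase_shift = 0L, seed = 1L) {
  check_motif(motif)
  if (reduce_to_minimal_unit(motif) != motif) {
    abort("`motif` must be primitive.", class = "telomotif_bad_motif")
  }
  stopifnot(sc >= 0, sd >= 0, si >= 0, sc + sd + si <= 1,
            n_chromosomes >= 1L, copies_per_end >= 0L,
            subtelomere_len >= 0L, core_len >= 0L, n_pad >= 0L)

  chroms <- vector("list", n_chromosomes)
  truth <- vector("list", n_chromosomes)
  events <- vector("list", n_chromosomes)
  for (ci in seq_len(n_chromosomes)) {
    id <- sprintf("chr%02d", ci)
    arr <- purrr::map(c(left = 1L, right = 2L), function(ei) {
      build_array(motif, copies_per_end, sc, sd, si, phase_shift,
                  seed = derive_seed(seed, ci, ei))
    })
    set.seed(derive_seed(seed, ci, 99L))
    left_seq <- revcomp(arr$left$seq)
    right_seq <- arr$right$seq
    mid <- paste0(random_dna(subtelomere_len), random_dna(core_len),
                  random_dna(subtelomere_len))
    pad <- strrep("N", n_pad)
    seq <- paste0(pad, left_seq, mid, right_seq, pad)

    left_start <- n_pad
    left_stop <- n_pad + nchar(left_seq)
    right_stop <- nchar(seq) - n_pad
    right_start <- right_stop - nchar(right_seq)
    truth[[ci]] <- tibble(
      chrom_id = id, end = c("left", "right"), motif = motif,
      copies = copies_per_end,
      n_events = c(nrow(arr$left$events), nrow(arr$right$events)),
      array_start = c(left_start, right_start),
      array_stop = c(left_stop, right_stop)
    )
    ev <- bind_rows(
      mutate(arr$left$events, chrom_id = id, end = "left"),
      mutate(arr$right$events, chrom_id = id, end = "right")
    )
    events[[ci]] <- select(ev, "chrom_id", "end", "copy", "type", "site",
                           "ref", "alt")
    chroms[[ci]] <- tibble(id = id, seq = seq, length = nchar(seq))
  }

  structure(
    list(genome = bind_rows(chroms), truth = bind_rows(truth),
         events = bind_rows(events),
         spec = list(motif = motif, n_chromosomes = n_chromosomes,
                     copies_per_end = copies_per_end, sc = sc, sd = sd,
                     si = si, subtelomere_len = subtelomere_len,
                     core_len = core_len, n_pad = n_pad,
                     phase_shift = phase_shift, seed = seed)),
    class = "telosim"
  )
}

#' @export
print.telosim <- function(x, ...) {
  cat("<telosim>", x$spec$n_chromosomes, "chromosome(s), motif", x$spec$motif,
      "x", x$spec$copies_per_end, "copies/end,",
      nrow(x$events), "injected SV event(s)\n")
  invisible(x)
}

#' Write a simulated genome and its truth tables to disk
#'
#' @param sim A `telosim` object.
#' @param prefix Output path prefix; writes `<prefix>.fa` and
#'   `<prefix>.truth.json`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_telosim <- function(sim, prefix) {
  stopifnot(inherits(sim, "telosim"))
  fa <- paste0(prefix, ".fa")
  tj <- paste0(prefix, ".truth.json")
  write_genome_fasta(sim$genome, fa)
  jsonlite::write_json(
    list(spec = sim$spec, truth = sim$truth, events = sim$events),
    tj, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(c(fasta = fa, truth = tj))
}

#' Simulate a read set from a simulated genome
#'
#' Reads are sampled uniformly along the genome with a random strand
#' (reverse-complemented reads included) and a constant quality string. The
#' truth table records how many bases of each read overlap a telomeric
#' array; reads overlapping by at least three motif lengths are flagged
#' telomeric.
#'
#' @param sim A `telosim` object.
#' @param n_reads Number of reads.
#' @param read_len Read length (nt); must not exceed the chromosome length.
#' @param seed Seed for read sampling.
#' @return List with `reads` (tibble `read_id`, `seq`) and `truth` (tibble
#'   with source coordinates, strand, `telomere_overlap` and `telomeric`).
#' @export
simulate_reads <- function(sim, n_reads = 200L, read_len = 150L, seed = 1L) {
  stopifnot(inherits(sim, "telosim"), n_reads >= 1L)
  if (read_len > min(sim$genome$length)) {
    abort("`read_len` exceeds the shortest chromosome.",
          class = "telomotif_bad_spec")
  }
  set.seed(derive_seed(seed, 7L))
  ci <- sample.int(nrow(sim$genome), n_reads, replace = TRUE,
                   prob = sim$genome$length)
  start <- vapply(ci, function(i) {
    sample.int(sim$genome$length[i] - read_len + 1L, 1L)
  }, integer(1))
  strand <- sample(c("+", "-"), n_reads, replace = TRUE)
  seqs <- substring(sim$genome$seq[ci], start, start + read_len - 1L)
  seqs[strand == "-"] <- revcomp(seqs[strand == "-"])
  L <- nchar(sim$spec$motif)

  overlap <- vapply(seq_len(n_reads), function(j) {
    tr <- filter(sim$truth, .data$chrom_id == sim$genome$id[ci[j]])
    a <- start[j] - 1L
    b <- a + read_len
    sum(pmax(0L, pmin(b, tr$array_stop) - pmax(a, tr$array_start)))
  }, numeric(1))

  list(
    reads = tibble(read_id = sprintf("read%05d", seq_len(n_reads)), seq = seqs),
    truth = tibble(read_id = sprintf("read%05d", seq_len(n_reads)),
                   chrom_id = sim$genome$id[ci], start = start - 1L,
                   strand = strand, telomere_overlap = as.integer(overlap),
                   telomeric = overlap >= 3L * L)
  )
}

#' Write simulated reads as FASTQ
#' @param reads Read tibble (`read_id`, `seq`).
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  qual <- strrep("I", nchar(reads$seq))
  lines <- as.vector(rbind(paste0("@", reads$read_id), reads$seq, "+", qual))
  writeLines(lines, path)
  invisible(path)
}
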