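write_fasta_lines <- function(...) {
  fa <- tempfile(fileext = ".fa")
  writeLines(c(...), fa)
  fa
}

test_that("FASTA ingest uppercases, orders records and coerces odd characters", {
  fa <- write_fasta_lines(">c1 description here", "acgtn", ">c2", "AA", "CC")
  g <- read_genome_fasta(fa)
  expect_equal(g$id, c("c1", "c2"))
  expect_equal(g$seq, c("ACGTN", "AACC"))
  expect_equal(g$length, c(5L, 4L))

  fa2 <- write_fasta_lines(">c1", "ACGRY")
  expect_warning(g2 <- read_genome_fasta(fa2), "coerced to N")
  expect_equal(g2$seq, "ACGNN")

  expect_error(read_genome_fasta(tempfile()), class = "telomotif_io_error")
  expect_error(read_genome_fasta(write_fasta_lines(">only-header")),
               class = "telomotif_format_error")
})

test_that("terminal windows strip terminal N runs and map back to the genome", {
  set.seed(11)
  body <- paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = "")
  chrom <- paste0(strrep("N", 5), body)

  w <- extract_terminal_window(chrom, "left", window_n = 1000)
  expect_equal(w$n_stripped, 5L)
  expect_equal(w$genomic_start, 5L)
  expect_equal(w$genomic_stop, 1005L)
  expect_equal(nchar(w$seq), 1000L)
  # coordinates map back exactly
  expect_equal(substr(chrom, w$genomic_start + 1, w$genomic_stop), w$seq)

  # plain slice and short-chromosome behaviour
  w2 <- extract_terminal_window(body, "left", window_n = 1000)
  expect_equal(w2$seq, substr(body, 1, 1000))
  short <- substr(body, 1, 600)
  w3 <- extract_terminal_window(short, "right", window_n = 1000)
  expect_equal(w3$seq, short)

  # internal Ns are retained, only the terminal run is skipped
  chromN <- paste0("NN", "ACGT", "N", "ACGTACGT")
  wN <- extract_terminal_window(chromN, "left", window_n = 50)
  expect_equal(wN$seq, "ACGTNACGTACGT")

  expect_error(extract_terminal_window("NNNN", "left"),
               class = "telomotif_empty_window")
})

test_that("window extraction is idempotent and respects strand symmetry", {
  set.seed(21)
  g <- tibble::tibble(
    id = c("a", "b"),
    seq = c(paste0(strrep("N", 3),
                   paste(sample(c("A", "C", "G", "T"), 400, TRUE), collapse = "")),
            paste(sample(c("A", "C", "G", "T"), 150, TRUE), collapse = ""))
  )
  wins <- terminal_windows(g, window_n = 100)
  expect_equal(nrow(wins), 4L)
  expect_equal(wins$end, rep(c("left", "right"), 2))

  # idempotence: extracting from a window changes nothing
  for (i in seq_len(nrow(wins))) {
    again <- extract_terminal_window(wins$seq[i], wins$end[i], wins$window_n[i])
    expect_equal(again$seq, wins$seq[i])
    expect_equal(again$n_stripped, 0L)
  }

  # reverse-complementing a chromosome swaps left/right windows (as rc)
  g_rc <- dplyr::mutate(g, seq = revcomp(seq))
  wins_rc <- terminal_windows(g_rc, window_n = 100)
  for (id in g$id) {
    l <- wins$seq[wins$chrom_id == id & wins$end == "left"]
    r_rc <- wins_rc$seq[wins_rc$chrom_id == id & wins_rc$end == "right"]
    expect_equal(revcomp(l), r_rc)
  }
})

test_that("read loading filters SAM by the unmapped flag and passes FASTQ through", {
  sam <- tempfile(fileext = ".sam")
  writeLines(c(
    "@HD\tVN:1.6", "@SQ\tSN:ref\tLN:100",
    "r1\t0\tref\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII",
    "r2\t4\t*\t0\t0\t*\t*\t0\t0\tttagggttag\tIIIIIIIIII",
    "r3\t4\t*\t0\t0\t*\t*\t0\t0\tGGGTTAGGGT\tIIIIIIIIII"
  ), sam)
  rs <- load_unmapped_reads(sam)
  expect_equal(rs$read_id, c("r2", "r3"))
  expect_equal(rs$seq[1], "TTAGGGTTAG")
  expect_identical(attr(rs, "source"), "sam_unmapped")

  sam2 <- tempfile(fileext = ".sam")
  writeLines(c("@SQ\tSN:ref\tLN:100",
               "r1\t0\tref\t1\t60\t10M\t*\t0\t0\tACGTACGTAC\tIIIIIIIIII"), sam2)
  expect_error(load_unmapped_reads(sam2), class = "telomotif_no_reads")

  fq <- tempfile(fileext = ".fastq")
  writeLines(as.vector(vapply(1:5, function(i) {
    c(paste0("@read", i), "ACGTTTAGGG", "+", "IIIIIIIIII")
  }, character(4))), fq)
  rs2 <- load_unmapped_reads(fq)
  expect_equal(nrow(rs2), 5L)
})

test_that("reports are written deterministically and JSON round-trips", {
  sim <- simulate_genome("TTAGGG", n_chromosomes = 2, copies_per_end = 40,
                         sc = 0, sd = 0, si = 0, seed = 5)
  rep <- detect_motif(sim$genome)

  t1 <- tempfile(fileext = ".tsv"); t2 <- tempfile(fileext = ".tsv")
  write_motif_report(rep, t1)
  write_motif_report(rep, t2)
  expect_identical(readLines(t1), readLines(t2))

  j <- tempfile(fileext = ".json")
  write_motif_report(rep, j)
  back <- read_motif_report_json(j)
  expect_equal(back$results$status, rep$status)
  expect_equal(back$results$candidates$canonical_motif,
               rep$candidates$canonical_motif)
  expect_equal(back$results$candidates$suppchr_ends, rep$candidates$suppchr_ends)
  expect_equal(back$parameters$window_n, rep$params$window_n)

  # header-only TSV for an empty candidate list
  empty <- suppressMessages(
    aggregate_candidates(run_tournament("ACGT", kmin = 5, kmax = 8)))
  t3 <- tempfile(fileext = ".tsv")
  suppressMessages(write_motif_report(empty, t3))
  expect_equal(length(readLines(t3)), 1L)
})
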