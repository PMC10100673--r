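test_that("noise-free arrays are exact tandem repeats at both termini", {
  sim <- simulate_genome("TTAGGG", n_chromosomes = 2, copies_per_end = 100,
                         sc = 0, sd = 0, si = 0, seed = 7)
  for (i in 1:2) {
    seq <- sim$genome$seq[i]
    L <- nchar(seq)
    expect_equal(substr(seq, L - 599, L), strrep("TTAGGG", 100))
    expect_equal(substr(seq, 1, 600), revcomp(strrep("TTAGGG", 100)))
  }
  expect_equal(nrow(sim$events), 0L)
  # truth coordinates slice out the arrays exactly
  for (j in seq_len(nrow(sim$truth))) {
    tr <- sim$truth[j, ]
    arr <- substr(sim$genome$seq[sim$genome$id == tr$chrom_id],
                  tr$array_start + 1, tr$array_stop)
    if (tr$end == "left") arr <- revcomp(arr)
    expect_equal(arr, strrep("TTAGGG", 100))
  }
})

test_that("simulation is deterministic in the seed and sensitive to it", {
  a <- simulate_genome("TTAGGG", n_chromosomes = 2, copies_per_end = 50,
                       seed = 99)
  b <- simulate_genome("TTAGGG", n_chromosomes = 2, copies_per_end = 50,
                       seed = 99)
  expect_identical(a$genome, b$genome)
  expect_identical(a$events, b$events)
  c <- simulate_genome("TTAGGG", n_chromosomes = 2, copies_per_end = 50,
                       seed = 100)
  expect_false(identical(a$genome$seq, c$genome$seq))

  # N padding appears at both termini and is skipped by window extraction
  p <- simulate_genome("TTAGGG", n_chromosomes = 1, copies_per_end = 20,
                       n_pad = 25, seed = 1)
  expect_match(p$genome$seq, "^N{25}")
  w <- extract_terminal_window(p$genome$seq, "left", 100)
  expect_equal(w$n_stripped, 25L)
})

test_that("injected event counts follow the per-copy binomial model", {
  rate <- 0.1
  copies <- 1000L
  counts <- vapply(1:20, function(s) {
    sim <- simulate_genome("TTAGGG", n_chromosomes = 1, copies_per_end = copies,
                           sc = rate, sd = 0, si = 0, seed = s)
    sum(sim$events$end == "right")
  }, numeric(1))
  mu <- copies * rate
  sdev <- sqrt(copies * rate * (1 - rate))
  within3 <- sum(abs(counts - mu) <= 3 * sdev)
  expect_gte(within3, 19L)
})

test_that("the left array is the reverse complement of its same-seed right array", {
  sim <- simulate_genome("TTAGTCAGGG", n_chromosomes = 1, copies_per_end = 30,
                         sc = 0.1, sd = 0.05, si = 0.05, seed = 55)
  tr <- sim$truth
  left <- substr(sim$genome$seq, tr$array_start[tr$end == "left"] + 1,
                 tr$array_stop[tr$end == "left"])
  right_equiv <- telomotif:::build_array(
    "TTAGTCAGGG", 30L, 0.1, 0.05, 0.05, 0L,
    seed = telomotif:::derive_seed(55, 1L, 1L))
  expect_equal(left, revcomp(right_equiv$seq))
})

test_that("simulated reads respect coordinates, strand and telomere truth", {
  sim <- simulate_genome("TTAGGG", n_chromosomes = 2, copies_per_end = 80,
                         seed = 12, core_len = 1000)
  rd <- simulate_reads(sim, n_reads = 80, read_len = 100, seed = 4)
  expect_equal(nrow(rd$reads), 80L)
  expect_true(all(nchar(rd$reads$seq) == 100L))
  # each read slices out of its source chromosome (up to strand)
  for (j in sample(80, 10)) {
    tr <- rd$truth[j, ]
    src <- substr(sim$genome$seq[sim$genome$id == tr$chrom_id],
                  tr$start + 1, tr$start + 100)
    expected <- if (tr$strand == "-") revcomp(src) else src
    expect_equal(rd$reads$seq[j], expected)
  }
  expect_identical(
    simulate_reads(sim, n_reads = 80, read_len = 100, seed = 4)$reads,
    rd$reads)

  # fastq writing round-trips through the reader
  fq <- tempfile(fileext = ".fastq")
  write_reads_fastq(rd$reads, fq)
  back <- load_unmapped_reads(fq)
  expect_equal(back$seq, rd$reads$seq)
})

test_that("fasta/truth files reproduce byte for byte under one seed", {
  sim <- simulate_genome("TTAGGG", n_chromosomes = 2, copies_per_end = 30,
                         seed = 5)
  p1 <- tempfile(); p2 <- tempfile()
  write_telosim(sim, p1)
  write_telosim(simulate_genome("TTAGGG", n_chromosomes = 2,
                                copies_per_end = 30, seed = 5), p2)
  expect_identical(readLines(paste0(p1, ".fa")), readLines(paste0(p2, ".fa")))
  expect_identical(readLines(paste0(p1, ".truth.json")),
                   readLines(paste0(p2, ".truth.json")))
})
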