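test_that("telomeric arrays are located with the gap-capped inward walk", {
  r <- locate_telomere_region(strrep("TTAGGG", 10), "TTAGGG")
  expect_equal(r$assembled_length, 60L)
  expect_equal(nrow(r$occurrences), 10L)
  expect_equal(nrow(r$gaps), 0L)

  w <- paste0(strrep("TTTAGGG", 3), "TTAAGGG", strrep("TTTAGGG", 3))
  r2 <- locate_telomere_region(w, "TTTAGGG")
  expect_equal(nrow(r2$occurrences), 6L)
  expect_equal(extract_gaps(r2)$seq, "TTAAGGG")
  expect_equal(r2$assembled_length, 49L)

  # a long spacer terminates the region at the terminus-proximal side
  w3 <- paste0(strrep("TTAGGG", 5), random_seq(40), strrep("TTAGGG", 5))
  r3 <- locate_telomere_region(w3, "TTAGGG")
  expect_equal(nrow(r3$occurrences), 5L)

  # fewer than two exact occurrences: no analysable region
  expect_null(locate_telomere_region("TTAGGGACGTACGTACGT", "TTAGGG"))
  expect_null(locate_telomere_region(random_seq(100), "TTAGGG"))
})

test_that("region coordinates map back to the genome on both ends", {
  sim <- simulate_genome("TTAGGG", n_chromosomes = 2, copies_per_end = 30,
                         sc = 0.05, sd = 0.02, si = 0.02, seed = 17)
  wins <- terminal_windows(sim$genome, window_n = 2000)
  for (i in seq_len(nrow(wins))) {
    r <- locate_telomere_region(wins[i, ], "TTAGGG")
    chrom <- sim$genome$seq[sim$genome$id == wins$chrom_id[i]]
    region_seq <- substr(chrom, r$start + 1, r$stop)
    # the outermost occurrence in genomic coordinates must be an exact motif
    # phase in the window orientation
    for (j in seq_len(nrow(r$occurrences))) {
      occ <- substr(chrom, r$occurrences$genomic_start[j] + 1,
                    r$occurrences$genomic_stop[j])
      if (r$end == "left") occ <- revcomp(occ)
      expect_equal(occ, r$phase)
    }
    expect_equal(nchar(region_seq), r$assembled_length)
  }
})

test_that("SV statistics implement the frequency and proportion formulas exactly", {
  ev <- tibble::tibble(chrom_id = "c1", end = "right",
                       type = c("SC", "SC", "SD", "SI"))
  rg <- tibble::tibble(chrom_id = "c1", end = "right", typical_count = 16L,
                       complex_count = 0L, assembled_length = 120L)
  st <- compute_sv_stats(ev, rg)
  expect_equal(st$total_motif_count, 20L)
  expect_equal(st$sv_frequency, 0.2)
  expect_equal(st$sc_pct, 0.5)
  expect_equal(st$sd_pct, 0.25)
  expect_equal(st$si_pct, 0.25)

  # zero events: frequency 0, undefined proportions
  st0 <- compute_sv_stats(ev[0, ], rg)
  expect_equal(st0$sv_frequency, 0)
  expect_true(is.na(st0$sc_pct))

  # absent telomere: NA frequency
  rgNA <- dplyr::mutate(rg, typical_count = NA_integer_)
  expect_true(is.na(compute_sv_stats(ev[0, ], rgNA)$sv_frequency))

  # proportions always sum to one when SVs exist
  set.seed(3)
  for (i in 1:10) {
    n <- sample(1:30, 1)
    evr <- tibble::tibble(chrom_id = "c", end = "left",
                          type = sample(c("SC", "SD", "SI"), n, TRUE))
    s <- compute_sv_stats(evr, dplyr::mutate(rg, chrom_id = "c", end = "left"))
    expect_equal(s$sc_pct + s$sd_pct + s$si_pct, 1)
  }
})

test_that("positional profiles tally per site in the right-end frame", {
  ev <- tibble::tibble(chrom_id = "c", end = "right", type = "SC",
                       motif_site = 8L, ref = "A", alt = "G",
                       genomic_pos = 0L)
  pr <- positional_profile(ev, "CAGGGTTAGT")
  expect_equal(pr$c_count[pr$motif_site == 8], 1L)
  expect_equal(sum(pr$c_count), 1L)
  expect_equal(sum(pr$d_count) + sum(pr$i_count), 0L)
  expect_equal(pr$ref_base[pr$motif_site == 8][1], "A")
  expect_equal(nrow(pr), 11L) # sites 1..L+1 for one end

  pr0 <- positional_profile(ev[0, ], "TTAGGG")
  expect_true(all(pr0$d_count + pr0$i_count + pr0$c_count == 0))
})

test_that("gap accounting conserves every occurrence and gap", {
  sim <- simulate_genome("TTAGGG", n_chromosomes = 3, copies_per_end = 200,
                         sc = 0.08, sd = 0.04, si = 0.04, seed = 23)
  va <- analyze_variation(sim$genome, "TTAGGG", window_n = 4000)
  wins <- terminal_windows(sim$genome, window_n = 4000)
  for (i in seq_len(nrow(wins))) {
    r <- locate_telomere_region(wins[i, ], "TTAGGG")
    if (is.null(r)) next
    st <- dplyr::filter(va$stats, chrom_id == wins$chrom_id[i],
                        end == wins$end[i])
    n_ev <- sum(va$events$chrom_id == wins$chrom_id[i] &
                  va$events$end == wins$end[i])
    # every gap is either one SV event or tallied COMPLEX
    expect_equal(n_ev + st$complex_count, nrow(r$gaps))
    expect_equal(st$typical_count, nrow(r$occurrences))
  }
})

test_that("injected variation is recovered at the correct end and type", {
  sim <- simulate_genome("TTAGGG", n_chromosomes = 1, copies_per_end = 400,
                         sc = 0.03, sd = 0.01, si = 0.01, seed = 29)
  va <- analyze_variation(sim$genome, "TTAGGG", window_n = 4000)
  # sensitivity per end and type against the truth table, allowing losses
  # from region truncation at multi-variant junction gaps
  truth_n <- nrow(sim$events)
  rec_n <- nrow(va$events)
  expect_gt(rec_n, 0.6 * truth_n)
  # recovered type mix resembles the injected 60/20/20 split
  tt <- table(factor(va$events$type, levels = c("SC", "SD", "SI"))) / rec_n
  expect_lt(abs(tt[["SC"]] - 0.6), 0.2)
  # events recovered on both ends
  expect_setequal(unique(va$events$end), c("left", "right"))
})

test_that("reverse-complementing the genome swaps left and right results exactly", {
  sim <- simulate_genome("TTAGGG", n_chromosomes = 2, copies_per_end = 150,
                         sc = 0.06, sd = 0.02, si = 0.02, seed = 41)
  va1 <- analyze_variation(sim$genome, "TTAGGG", window_n = 3000)
  g_rc <- dplyr::mutate(sim$genome, seq = revcomp(seq))
  va2 <- analyze_variation(g_rc, "TTAGGG", window_n = 3000)

  flip <- function(x) ifelse(x == "left", "right", "left")
  s1 <- dplyr::arrange(dplyr::select(va1$stats, chrom_id, end, typical_count,
                                     sv_count, sc_count, sd_count, si_count,
                                     sv_frequency),
                       chrom_id, end)
  s2 <- dplyr::arrange(
    dplyr::mutate(dplyr::select(va2$stats, chrom_id, end, typical_count,
                                sv_count, sc_count, sd_count, si_count,
                                sv_frequency),
                  end = flip(end)),
    chrom_id, end)
  expect_equal(s1, s2)

  # positional profiles swap end labels but keep identical site tallies
  p1 <- dplyr::arrange(va1$profile, end, motif_site)
  p2 <- dplyr::arrange(dplyr::mutate(va2$profile, end = flip(end)),
                       end, motif_site)
  expect_equal(p1, p2)
})

test_that("read-mode variation pools to one genome-wide row", {
  sim <- simulate_genome("TTAGGG", n_chromosomes = 2, copies_per_end = 150,
                         sc = 0.05, sd = 0.02, si = 0.02, seed = 37,
                         core_len = 800)
  rd <- simulate_reads(sim, n_reads = 150, read_len = 150, seed = 2)
  va <- analyze_variation(rd$reads, "TTAGGG")
  expect_equal(nrow(va$stats), 1L)
  expect_equal(va$stats$end, "pooled")
  expect_gt(va$stats$typical_count, 0L)
  expect_true(va$stats$sv_frequency >= 0 && va$stats$sv_frequency <= 1)

  # a genome without telomeres yields only NA rows
  bare <- simulate_genome("TTAGGG", n_chromosomes = 2, copies_per_end = 0,
                          seed = 3, core_len = 1500)
  va0 <- analyze_variation(bare$genome, "TTAGGG", window_n = 1000)
  expect_true(all(is.na(va0$stats$sv_frequency)))
})
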