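# Independent literal implementations used as oracles. These deliberately
# re-derive everything from the definitions (greedy non-overlapping repeat
# counting, S = length x repeats, pairwise difference with the substring
# penalty, all-pairs wins) without touching the package's code paths.

oracle_starts <- function(seq, kmer) {
  # greedy left-to-right non-overlapping occurrence starts, 1-based
  out <- integer(0)
  pos <- 1L
  k <- nchar(kmer)
  repeat {
    hit <- regexpr(kmer, substring(seq, pos), fixed = TRUE)
    if (hit == -1L) break
    s <- pos + as.integer(hit) - 1L
    out <- c(out, s)
    pos <- s + k
  }
  out
}

oracle_kmers <- function(seq, kmin, kmax) {
  L <- nchar(seq)
  rows <- list()
  for (k in kmin:min(kmax, L)) {
    subs <- substring(seq, 1:(L - k + 1L), k:L)
    subs <- unique(subs[!grepl("N", subs, fixed = TRUE)])
    for (x in subs) {
      rows[[length(rows) + 1L]] <-
        data.frame(kmer = x, k = k,
                   repeat_times = length(oracle_starts(seq, x)))
    }
  }
  df <- do.call(rbind, rows)
  df$S <- df$k * df$repeat_times
  df
}

oracle_value <- function(seq, km1, km2, occ1, occ2) {
  inside <- function(short_occ, ks, long_occ, kl) {
    sum(vapply(short_occ, function(t) {
      any(long_occ <= t & t + ks <= long_occ + kl)
    }, logical(1)))
  }
  v <- nchar(km1) * length(occ1) - nchar(km2) * length(occ2)
  if (nchar(km1) < nchar(km2) && grepl(km1, km2, fixed = TRUE)) {
    v <- v - inside(occ1, nchar(km1), occ2, nchar(km2)) * nchar(km1)
  } else if (nchar(km2) < nchar(km1) && grepl(km2, km1, fixed = TRUE)) {
    v <- v + inside(occ2, nchar(km2), occ1, nchar(km1)) * nchar(km2)
  }
  v
}

oracle_minimal_unit <- function(x) {
  n <- nchar(x)
  for (p in 1:n) {
    if (n %% p == 0L && paste(rep(substr(x, 1L, p), n / p), collapse = "") == x)
      return(substr(x, 1L, p))
  }
  x
}

# literal all-pairs tournament; returns the winning kmer (or NA if no kmer
# repeats) using the same published tie-break order
oracle_tournament <- function(seq, kmin, kmax) {
  km <- oracle_kmers(seq, kmin, kmax)
  if (is.null(km) || max(km$repeat_times) < 2L) return(NA_character_)
  M <- nrow(km)
  occ <- lapply(km$kmer, function(x) oracle_starts(seq, x))
  wins <- integer(M)
  for (i in seq_len(M - 1L)) {
    for (j in (i + 1L):M) {
      v <- oracle_value(seq, km$kmer[i], km$kmer[j], occ[[i]], occ[[j]])
      if (v > 0) wins[i] <- wins[i] + 1L
      else if (v < 0) wins[j] <- wins[j] + 1L
    }
  }
  best <- which(wins == max(wins))
  if (length(best) > 1L) {
    ul <- nchar(vapply(km$kmer[best], oracle_minimal_unit, character(1)))
    best <- best[order(-km$S[best], ul, km$kmer[best])][1L]
  }
  km$kmer[best]
}

# exhaustive minimum-edit check: the set of all single-edit variants of a motif
oracle_single_edit_variants <- function(motif) {
  L <- nchar(motif)
  bases <- c("A", "C", "G", "T")
  out <- character(0)
  for (s in 1:L) {
    for (b in setdiff(bases, substring(motif, s, s))) {
      out <- c(out, paste0(substr(motif, 1, s - 1), b, substr(motif, s + 1, L)))
    }
    out <- c(out, paste0(substr(motif, 1, s - 1), substr(motif, s + 1, L)))
  }
  for (s in 1:(L + 1)) {
    for (b in bases) {
      out <- c(out, paste0(substr(motif, 1, s - 1), b, substr(motif, s, L)))
    }
  }
  unique(out)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
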