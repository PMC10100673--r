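#' Globally align a gap sequence to the telomeric motif
#'
#' Needleman-Wunsch global alignment with match +1, mismatch -2 and a linear
#' gap cost of -2 per gapped base. The mismatch penalty follows the custom
#' scoring used for telomere gap classification; the gap cost is chosen so a
#' single-base indel and a single mismatch are directly comparable. Among
#' score-optimal alignments the one with leftmost indel placement is
#' returned (the true indel position inside a homopolymer run is inherently
#' ambiguous; leftmost is the stated convention).
#'
#' @param gap Gap sequence (the span between two exact motif copies).
#' @param motif Reference motif, in the orientation of the gap.
#' @param match,mismatch,gap_cost Scoring scheme (defaults +1/-2/-2).
#' @return A list of class `gap_alignment`: `gap_aligned` and `motif_aligned`
#'   (equal-length strings over `ACGT-`), `score`, and `edits`, a tibble with
#'   columns `kind` (`MISMATCH`, `INS_IN_GAP`, `DEL_FROM_MOTIF`),
#'   `motif_site` (1-based; an insertion is recorded at the site it
#'   precedes, `L + 1` after the final base), `ref` and `alt`.
#' @examples
#' align_gap_to_motif("TTAAGGG", "TTTAGGG")$edits
#' @export
align_gap_to_motif <- function(gap, motif, match = 1L, mismatch = -2L,
                               gap_cost = -2L) {
  stopifnot(nchar(gap) >= 1L, nchar(motif) >= 1L)
  g <- strsplit(gap, "")[[1]]
  m <- strsplit(motif, "")[[1]]
  n <- length(g)
  p <- length(m)

  dp <- matrix(0L, n + 1L, p + 1L)
  dp[1L, ] <- gap_cost * 0:p
  dp[, 1L] <- gap_cost * 0:n
  for (i in seq_len(n)) {
    sub <- ifelse(m == g[i], match, mismatch)
    for (j in seq_len(p)) {
      dp[i + 1L, j + 1L] <- max(dp[i, j] + sub[j],
                                dp[i, j + 1L] + gap_cost,
                                dp[i + 1L, j] + gap_cost)
    }
  }

  # backward traceback; preferring the diagonal (then the gap-row insertion)
  # defers indels while walking backwards, i.e. places them leftmost
  i <- n; j <- p
  ga <- character(0); ma <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L &&
        dp[i + 1L, j + 1L] == dp[i, j] + (if (g[i] == m[j]) match else mismatch)) {
      ga <- c(g[i], ga); ma <- c(m[j], ma); i <- i - 1L; j <- j - 1L
    } else if (i > 0L && dp[i + 1L, j + 1L] == dp[i, j + 1L] + gap_cost) {
      ga <- c(g[i], ga); ma <- c("-", ma); i <- i - 1L
    } else {
      ga <- c("-", ga); ma <- c(m[j], ma); j <- j - 1L
    }
  }

  kind <- character(0); site <- integer(0); ref <- character(0); alt <- character(0)
  mp <- 0L
  for (col in seq_along(ga)) {
    if (ma[col] == "-") {
      kind <- c(kind, "INS_IN_GAP"); site <- c(site, mp + 1L)
      ref <- c(ref, NA_character_); alt <- c(alt, ga[col])
    } else if (ga[col] == "-") {
      mp <- mp + 1L
      kind <- c(kind, "DEL_FROM_MOTIF"); site <- c(site, mp)
      ref <- c(ref, ma[col]); alt <- c(alt, NA_character_)
    } else {
      mp <- mp + 1L
      if (ga[col] != ma[col]) {
        kind <- c(kind, "MISMATCH"); site <- c(site, mp)
        ref <- c(ref, ma[col]); alt <- c(alt, ga[col])
      }
    }
  }

  structure(
    list(
      gap_aligned = paste(ga, collapse = ""),
      motif_aligned = paste(ma, collapse = ""),
      score = dp[n + 1L, p + 1L],
      edits = tibble(kind = kind, motif_site = site, ref = ref, alt = alt)
    ),
    class = "gap_alignment"
  )
}

#' @export
print.gap_alignment <- function(x, ...) {
  cat(x$gap_aligned, "\n", x$motif_aligned, "\n", sep = "")
  cat("score:", x$score, " edits:", nrow(x$edits), "\n")
  invisible(x)
}

#' Classify one gap sequence as a single-base variation
#'
#' A gap of length 1 is a single-base insertion between two copies (recorded
#' after the last motif site). A gap whose length is within one base of the
#' motif length and whose optimal alignment carries exactly one edit is the
#' matching single-base variation: a mismatch is a single-base change (SC),
#' a motif base absent from the gap a single-base deletion (SD), an extra
#' gap base a single-base insertion (SI). Everything else is `COMPLEX` and
#' excluded from SV statistics.
#'
#' @param gap Gap sequence.
#' @param motif Reference motif in the gap's orientation.
#' @return One-row tibble `type` (`SC`/`SD`/`SI`/`COMPLEX`), `motif_site`,
#'   `ref`, `alt`.
#' @examples
#' classify_sv("TTAGG", "TTAGGG")   # SD of a G
#' classify_sv("TTTAGGG", "TTAGGG") # SI of a T
#' @export
classify_sv <- function(gap, motif) {
  L <- nchar(motif)
  gl <- nchar(gap)
  if (gl == 1L) {
    return(tibble(type = "SI", motif_site = L + 1L, ref = NA_character_,
                  alt = gap))
  }
  if (!(gl %in% c(L - 1L, L, L + 1L))) {
    return(tibble(type = "COMPLEX", motif_site = NA_integer_,
                  ref = NA_character_, alt = NA_character_))
  }
  al <- align_gap_to_motif(gap, motif)
  if (nrow(al$edits) != 1L) {
    return(tibble(type = "COMPLEX", motif_site = NA_integer_,
                  ref = NA_character_, alt = NA_character_))
  }
  e <- al$edits
  type <- c(MISMATCH = "SC", DEL_FROM_MOTIF = "SD", INS_IN_GAP = "SI")[[e$kind]]
  tibble(type = type, motif_site = e$motif_site, ref = e$ref, alt = e$alt)
}
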