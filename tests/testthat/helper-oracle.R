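# Independent brute-force oracle for the read-to-hairpin aligner,
# exhaustive under the default penalty configuration.
#
# With mismatch 30, gap 40 + 6L and cap 60, any reportable alignment has
# either (a) no gap and at most two mismatches, or (b) exactly one gap of
# at most three bases and no mismatch (one gap plus one mismatch already
# costs 76).  The oracle therefore enumerates, over every clip pair
# (core >= min_core) and every hairpin offset, the gapless mismatch count
# and every single-gap placement, by direct string comparison — no
# dynamic programming shared with the implementation.

oracle_min_penalty <- function(read, hairpin, cap = 60, min_core = 15,
                               mismatch = 30, gap_open = 40,
                               gap_ext = 6) {
  rc <- strsplit(read, "")[[1]]
  hc <- strsplit(hairpin, "")[[1]]
  n <- length(rc)
  m <- length(hc)
  if (n < min_core || m < 1) return(NA_integer_)
  EQ <- outer(rc, hc, function(a, b) a == b & a != "N" & b != "N")
  best <- Inf
  max_gap <- 0
  while (gap_open + gap_ext * (max_gap + 1) <= cap) max_gap <- max_gap + 1
  max_mm <- cap %/% mismatch

  for (c5 in 0:(n - min_core)) {
    for (c3 in 0:(n - min_core - c5)) {
      idx <- (c5 + 1):(n - c3)
      L <- length(idx)
      # leading run of matches of the core at hairpin offset o (0-based;
      # out-of-bounds counts as mismatch)
      pfun <- function(o) {
        k <- 0L
        while (k < L) {
          j <- o + k + 1L
          if (j < 1L || j > m || !EQ[idx[k + 1L], j]) break
          k <- k + 1L
        }
        k
      }
      # trailing run of matches of the core placed at offset o2
      tfun <- function(o2) {
        k <- 0L
        while (k < L) {
          i <- L - k
          j <- o2 + i
          if (j < 1L || j > m || !EQ[idx[i], j]) break
          k <- k + 1L
        }
        k
      }
      if (m >= L) {
        for (o in 0:(m - L)) {
          mmc <- sum(!EQ[cbind(idx, o + seq_len(L))])
          if (mmc <= max_mm) best <- min(best, mismatch * mmc)
        }
      }
      for (g in seq_len(max_gap)) {
        pen <- gap_open + gap_ext * g
        if (pen > cap || pen >= best) next
        # deletion (hairpin-only bases): consumes L + g hairpin bases;
        # break point p in 1..L-1, prefix exact at o, suffix exact
        # shifted right by g
        if (m - L - g >= 0) {
          for (o in 0:(m - L - g)) {
            lo <- max(1L, L - tfun(o + g))
            if (lo > L - 1L) next
            if (lo <= min(L - 1L, pfun(o))) {
              best <- min(best, pen)
              break
            }
          }
        }
        # insertion (read-only bases): consumes L - g hairpin bases;
        # break point p in 1..L-g-1, suffix exact shifted left by g
        if (L >= g + 2 && m - L + g >= 0) {
          for (o in 0:(m - L + g)) {
            lo <- max(1L, L - g - tfun(o - g))
            if (lo > L - g - 1L) next
            if (lo <= min(L - g - 1L, pfun(o))) {
              best <- min(best, pen)
              break
            }
          }
        }
      }
    }
  }
  if (!is.finite(best) || best > cap) NA_integer_ else as.integer(best)
}
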