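#' Parse a CIGAR string into runs
#'
#' @param cigar a CIGAR string (e.g. `"3S19M"`).
#' @return data.frame with columns `len`, `op`.
#' @export
cigar_runs <- function(cigar) {
  if (is.na(cigar) || cigar == "*") {
    return(data.frame(len = integer(0), op = character(0),
                      stringsAsFactors = FALSE))
  }
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigar)[[1]]
  if (m[1] == -1 ||
      sum(attr(m, "match.length")) != nchar(cigar)) {
    stop("malformed CIGAR: ", cigar)
  }
  parts <- regmatches(cigar, gregexpr("\\d+|[MIDNSHP=X]", cigar))[[1]]
  data.frame(len = as.integer(parts[c(TRUE, FALSE)]),
             op = parts[c(FALSE, TRUE)], stringsAsFactors = FALSE)
}

#' @noRd
cigar_read_len <- function(runs) {
  sum(runs$len[runs$op %in% c("M", "I", "S", "=", "X")])
}

#' @noRd
cigar_ref_len <- function(runs) {
  sum(runs$len[runs$op %in% c("M", "D", "N", "=", "X")])
}

#' Read genome alignments from a SAM file
#'
#' Parses the mandatory SAM columns; header lines are skipped.  The
#' 1-based POS is converted to the internal 0-based convention.  Unmapped
#' records (flag 0x4) are yielded with `mapped = FALSE` and no
#' coordinates.  When a sequence is present, the CIGAR must consume
#' exactly the read length.
#'
#' @param path path to a SAM file.
#' @return data.frame with columns `uid`, `flag`, `chrom`, `start`,
#'   `cigar`, `strand`, `mapq`, `mapped`, `secondary`, `seq`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  empty <- data.frame(uid = character(0), flag = integer(0),
                      chrom = character(0), start = integer(0),
                      cigar = character(0), strand = character(0),
                      mapq = integer(0), mapped = logical(0),
                      secondary = logical(0), seq = character(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  fields <- strsplit(lines, "\t")
  short <- which(lengths(fields) < 11)
  if (length(short)) {
    stop("malformed SAM record (fewer than 11 fields) at alignment line ",
         short[1])
  }
  f <- function(i) vapply(fields, `[[`, character(1), i)
  flag <- as.integer(f(2))
  mapped <- bitwAnd(flag, 4L) == 0L
  out <- data.frame(
    uid = f(1), flag = flag,
    chrom = ifelse(mapped, f(3), NA_character_),
    start = ifelse(mapped, as.integer(f(4)) - 1L, NA_integer_),
    cigar = ifelse(mapped, f(6), NA_character_),
    strand = ifelse(mapped, ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
                    NA_character_),
    mapq = as.integer(f(5)),
    mapped = mapped,
    secondary = bitwAnd(flag, 256L) > 0L,
    seq = f(10),
    stringsAsFactors = FALSE)
  chk <- which(out$mapped & out$seq != "*" & out$cigar != "*")
  for (i in chk) {
    runs <- cigar_runs(out$cigar[i])
    if (cigar_read_len(runs) != nchar(out$seq[i])) {
      stop("CIGAR does not consume the read length for ", out$uid[i])
    }
  }
  out
}

#' Write genome alignments to a SAM file
#'
#' @param aln data.frame in the layout of [read_sam()].
#' @param refs named integer vector of reference lengths for the header.
#' @param path output path.
#' @export
write_sam <- function(aln, refs, path) {
  hdr <- c("@HD\tVN:1.6\tSO:unsorted",
           sprintf("@SQ\tSN:%s\tLN:%d", names(refs), as.integer(refs)))
  body <- character(nrow(aln))
  for (i in seq_len(nrow(aln))) {
    if (isTRUE(aln$mapped[i])) {
      body[i] <- paste(aln$uid[i], aln$flag[i], aln$chrom[i],
                       aln$start[i] + 1L, aln$mapq[i], aln$cigar[i],
                       "*", 0, 0, aln$seq[i], "*", sep = "\t")
    } else {
      body[i] <- paste(aln$uid[i], 4L, "*", 0, 0, "*", "*", 0, 0,
                       aln$seq[i], "*", sep = "\t")
    }
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
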