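#' Read a FASTQ file
#'
#' Parses a four-line-per-record FASTQ file (Sanger quality encoding,
#' offset 33).  Sequences are uppercased; read identifiers are the first
#' whitespace-delimited token of the header.  Malformed records (missing
#' `@`, sequence/quality length mismatch, truncated record) raise an error
#' naming the offending line.
#'
#' @param path path to a FASTQ file (transparently decompressed).
#' @return a data.frame with columns `read_id`, `sequence`, `quality`
#'   (quality kept as the raw Phred+33 string).
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  empty <- data.frame(read_id = character(0), sequence = character(0),
                      quality = character(0), stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  if (length(lines) %% 4 != 0) {
    stop("malformed FASTQ: truncated record starting at line ",
         4 * (length(lines) %/% 4) + 1)
  }
  hdr <- lines[seq(1, length(lines), by = 4)]
  seqs <- toupper(lines[seq(2, length(lines), by = 4)])
  sep <- lines[seq(3, length(lines), by = 4)]
  qual <- lines[seq(4, length(lines), by = 4)]

  bad <- which(!startsWith(hdr, "@"))
  if (length(bad)) {
    stop("malformed FASTQ: missing '@' at line ", (bad[1] - 1) * 4 + 1)
  }
  bad <- which(!startsWith(sep, "+"))
  if (length(bad)) {
    stop("malformed FASTQ: missing '+' at line ", (bad[1] - 1) * 4 + 3)
  }
  bad <- which(nchar(seqs) != nchar(qual))
  if (length(bad)) {
    stop("malformed FASTQ: sequence/quality length mismatch at line ",
         (bad[1] - 1) * 4 + 2)
  }
  ids <- sub("^@", "", sub("\\s.*$", "", hdr))
  data.frame(read_id = ids, sequence = seqs, quality = qual,
             stringsAsFactors = FALSE)
}

#' Write reads to a FASTQ file
#'
#' @param reads data.frame as returned by [read_fastq()].
#' @param path output path.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  out <- rbind(paste0("@", reads$read_id), reads$sequence, "+", reads$quality)
  writeLines(as.vector(out), path)
  invisible(path)
}

#' Decode a Phred+33 quality string to integer scores
#'
#' @param quality a quality string.
#' @return integer vector of per-base Phred scores.
#' @export
phred_scores <- function(quality) {
  if (!nzchar(quality)) return(integer(0))
  utf8ToInt(quality) - 33L
}

#' Quality-filter reads
#'
#' A read is kept iff the fraction of its bases with Phred score at least
#' `min_quality` is at least `min_fraction` (boundary inclusive), the
#' whole-read filtering rule of fastq_quality_filter.
#'
#' @param reads data.frame with `quality` strings (see [read_fastq()]).
#' @param min_quality minimum per-base Phred score (default 20).
#' @param min_fraction minimum fraction of bases meeting it (default 0.95).
#' @return list with `reads` (kept rows) and `n_dropped`.
#' @export
quality_filter <- function(reads, min_quality = 20, min_fraction = 0.95) {
  if (nrow(reads) == 0) return(list(reads = reads, n_dropped = 0L))
  thr <- min_quality + 33L
  frac <- vapply(reads$quality, function(q) {
    if (!nzchar(q)) return(0)
    mean(utf8ToInt(q) >= thr)
  }, numeric(1), USE.NAMES = FALSE)
  keep <- frac >= min_fraction
  list(reads = reads[keep, , drop = FALSE],
       n_dropped = sum(!keep))
}
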