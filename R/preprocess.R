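#' Adapter trimming settings
#'
#' Defaults follow common small RNA-seq practice: at most one error base
#' (mismatch or indel) in the detected adapter, a minimum detectable
#' adapter length of 10 nt, and a minimum final clean-read length of
#' 15 nt (the shortest annotated mature miRNA).
#'
#' @param adapter adapter sequence, or `NULL` when unknown.
#' @param max_errors maximum unit-cost edits tolerated in the adapter
#'   occurrence (default 1).
#' @param min_adapter_len minimum adapter bases that must be present
#'   (default 10).
#' @param min_read_len minimum insert length kept after trimming
#'   (default 15).
#' @param skip_trimming pass reads through untouched (for libraries
#'   already clean of adapters).
#' @return a `trim_settings` list.
#' @export
trim_settings <- function(adapter = NULL, max_errors = 1L,
                          min_adapter_len = 10L, min_read_len = 15L,
                          skip_trimming = FALSE) {
  if (!is.null(adapter)) {
    adapter <- toupper(chartr("U", "T", adapter))
    if (min_adapter_len > nchar(adapter)) {
      stop("min_adapter_len exceeds the adapter length")
    }
  }
  structure(list(adapter = adapter, max_errors = as.integer(max_errors),
                 min_adapter_len = as.integer(min_adapter_len),
                 min_read_len = as.integer(min_read_len),
                 skip_trimming = isTRUE(skip_trimming)),
            class = "trim_settings")
}

#' Detect the 3' adapter of a library empirically
#'
#' Tallies all k-mers occurring in the 3' half of (a sample of) the reads,
#' takes the most frequent one as the adapter anchor, and greedily extends
#' it rightward while at least `consensus` of the reads containing it
#' agree on the next base.  Reads shorter than `k` are excluded from
#' tallying.
#'
#' @param sequences character vector of read sequences.
#' @param k anchor k-mer size (default 10).
#' @param sample_size maximum number of reads examined (default 1e5).
#' @param floor_frac minimum fraction of sampled reads that must contain
#'   the anchor for a detection to be reported (default 0.2).
#' @param consensus extension consensus fraction (default 0.8).
#' @return list with `adapter` (or `NULL` when nothing reaches the floor)
#'   and `support` (fraction of sampled reads containing the candidate).
#' @export
detect_adapter <- function(sequences, k = 10L, sample_size = 100000L,
                           floor_frac = 0.2, consensus = 0.8) {
  seqs <- head(sequences, sample_size)
  seqs <- seqs[nchar(seqs) >= k]
  if (length(seqs) == 0) return(list(adapter = NULL, support = 0))
  kmers <- unlist(lapply(seqs, function(s) {
    L <- nchar(s)
    from <- max(1L, L %/% 2L)
    starts <- from:(L - k + 1L)
    if (length(starts) == 0 || starts[1] > L - k + 1L) return(character(0))
    substring(s, starts, starts + k - 1L)
  }))
  kmers <- kmers[!grepl("N", kmers, fixed = TRUE)]
  if (length(kmers) == 0) return(list(adapter = NULL, support = 0))
  tab <- sort(table(kmers), decreasing = TRUE)
  anchor <- names(tab)[1]
  support <- mean(grepl(anchor, seqs, fixed = TRUE))
  if (support < floor_frac) return(list(adapter = NULL, support = support))

  cand <- anchor
  repeat {
    pos <- regexpr(cand, seqs, fixed = TRUE)
    nxt <- pos + nchar(cand)
    ok <- pos > 0 & nxt <= nchar(seqs)
    if (sum(ok) < 2) break
    bases <- substring(seqs[ok], nxt[ok], nxt[ok])
    bt <- sort(table(bases[bases %in% c("A", "C", "G", "T")]),
               decreasing = TRUE)
    if (length(bt) == 0 || bt[1] / sum(ok) < consensus) break
    cand <- paste0(cand, names(bt)[1])
  }
  list(adapter = cand, support = support)
}

#' Trim the 3' adapter off one read
#'
#' An occurrence is either the full adapter internal to the read or an
#' adapter prefix of at least `min_adapter_len` bases running to the
#' read's 3' end, matched with at most `max_errors` unit-cost edits.
#' The occurrence with the fewest errors wins, ties going to the
#' leftmost (so an exact occurrence can never be shadowed by a spurious
#' error-tolerant one starting a base earlier); the read is truncated at
#' the occurrence start.
#'
#' @param sequence read sequence.
#' @param settings a [trim_settings()] object with a non-NULL adapter.
#' @return list with `sequence` (the insert, or the unchanged read),
#'   `status` one of `"trimmed"`, `"no_adapter"`, `"too_short"`,
#'   `insert_len`, `n_errors`, `adapter_len`.
#' @export
trim_adapter <- function(sequence, settings) {
  stopifnot(inherits(settings, "trim_settings"), !is.null(settings$adapter))
  hit <- trim_scan_cpp(sequence, settings$adapter, settings$max_errors,
                       settings$min_adapter_len)
  insert_len <- hit[1, 1]
  if (insert_len < 0) {
    return(list(sequence = sequence, status = "no_adapter",
                insert_len = nchar(sequence), n_errors = NA_integer_,
                adapter_len = NA_integer_))
  }
  if (insert_len < settings$min_read_len) {
    return(list(sequence = substr(sequence, 1, insert_len),
                status = "too_short", insert_len = insert_len,
                n_errors = hit[1, 2], adapter_len = hit[1, 3]))
  }
  list(sequence = substr(sequence, 1, insert_len), status = "trimmed",
       insert_len = insert_len, n_errors = hit[1, 2],
       adapter_len = hit[1, 3])
}

#' Trim a whole library
#'
#' Applies [trim_adapter()] to every read, drops the inserts shorter than
#' the minimum clean-read length, and reports trimming statistics.
#' With `skip_trimming` (or no adapter configured) reads pass through,
#' except that reads shorter than the minimum length are still dropped.
#'
#' @param reads data.frame as from [read_fastq()] (quality column
#'   optional).
#' @param settings a [trim_settings()] object.
#' @return list with `reads` (kept, truncated to the insert), `status`
#'   (per input read), and `stats`.
#' @export
trim_library <- function(reads, settings) {
  n <- nrow(reads)
  has_qual <- "quality" %in% names(reads)
  if (settings$skip_trimming || is.null(settings$adapter)) {
    keep <- nchar(reads$sequence) >= settings$min_read_len
    status <- ifelse(keep, "passthrough", "too_short")
    return(list(reads = reads[keep, , drop = FALSE], status = status,
                stats = list(n_input = n, n_with_adapter = 0L,
                             n_kept = sum(keep), n_too_short = sum(!keep),
                             n_no_adapter = 0L)))
  }
  if (n == 0) {
    return(list(reads = reads, status = character(0),
                stats = list(n_input = 0L, n_with_adapter = 0L,
                             n_kept = 0L, n_too_short = 0L,
                             n_no_adapter = 0L)))
  }
  hits <- trim_scan_cpp(reads$sequence, settings$adapter,
                        settings$max_errors, settings$min_adapter_len)
  insert_len <- hits[, 1]
  found <- insert_len >= 0
  final_len <- ifelse(found, insert_len, nchar(reads$sequence))
  status <- ifelse(!found, "no_adapter",
                   ifelse(insert_len < settings$min_read_len,
                          "too_short", "trimmed"))
  keep <- final_len >= settings$min_read_len
  out <- reads[keep, , drop = FALSE]
  out$sequence <- substr(out$sequence, 1, final_len[keep])
  if (has_qual) out$quality <- substr(out$quality, 1, final_len[keep])
  list(reads = out, status = status,
       stats = list(n_input = n, n_with_adapter = sum(found),
                    n_kept = sum(keep), n_too_short = sum(!keep),
                    n_no_adapter = sum(!found)))
}

#' Collapse clean reads by sequence content
#'
#' One record per distinct sequence with its multiplicity.  Identifiers
#' follow the `XXX-YYY` convention where `XXX` is a unique number and
#' `YYY` the read count; numbering is deterministic (descending count,
#' ties broken by sequence lexicographic order).
#'
#' @param sequences character vector of clean-read sequences.
#' @return data.frame with columns `uid`, `sequence`, `count`.
#' @export
collapse_reads <- function(sequences) {
  if (length(sequences) == 0) {
    return(data.frame(uid = character(0), sequence = character(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  tab <- table(sequences)
  seqs <- names(tab)
  counts <- as.integer(tab)
  ord <- order(-counts, seqs, method = "radix")
  seqs <- seqs[ord]
  counts <- counts[ord]
  data.frame(uid = sprintf("%d-%d", seq_along(seqs), counts),
             sequence = seqs, count = counts, stringsAsFactors = FALSE)
}
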