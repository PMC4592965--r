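#' Alignment parameters for read-to-hairpin mapping
#'
#' The default penalty configuration: mismatch 30, gap opening 40, gap
#' extension 6 per gapped base (a gap of length L costs 40 + 6L), total
#' penalty capped at 60, soft clips free.  Under the cap an alignment may
#' carry at most 2 mismatches, or one gap of at most 3 bases.  The aligned
#' core must keep at least `min_core` read bases (the minimum clean-read
#' length), which prevents degenerate all-clip alignments.
#'
#' @param mismatch mismatch penalty.
#' @param gap_open gap opening penalty.
#' @param gap_extend per-base gap extension penalty.
#' @param cap maximum total penalty for a reportable alignment.
#' @param min_core minimum number of aligned (unclipped) read bases.
#' @param max_ties maximum number of tied optimal alignments enumerated
#'   per read before truncation (pathological repeats).
#' @return an `align_params` list.
#' @export
align_params <- function(mismatch = 30L, gap_open = 40L, gap_extend = 6L,
                         cap = 60L, min_core = 15L, max_ties = 200L) {
  structure(list(mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend),
                 cap = as.integer(cap), min_core = as.integer(min_core),
                 max_ties = as.integer(max_ties)),
            class = "align_params")
}

#' Align one read against one hairpin
#'
#' Penalty-capped semi-global alignment with free terminal soft clips on
#' the read and free overhangs on the hairpin, sense strand only.
#' Optimality is lexicographic — minimum penalty, then minimum clipped
#' bases — and all distinct optimal alignments are returned (deduplicated
#' by start and operation string).  Reads shorter than the core minimum
#' are unalignable.
#'
#' @param sequence read sequence (DNA, uppercase).
#' @param hairpin hairpin sequence.
#' @param params an [align_params()] object.
#' @return data.frame with one row per optimal alignment: `start`, `end`
#'   (0-based half-open hairpin coordinates of the aligned core), `ops`
#'   (per-column operation string over `S= X I D`), `penalty`,
#'   `n_mismatch`, `n_ins`, `n_del`, `clip5`, `clip3`, `n_n`; the
#'   `truncated` attribute flags a tie overflow.  Zero rows = unalignable
#'   within the cap.
#' @export
align_read <- function(sequence, hairpin, params = align_params()) {
  res <- align_read_cpp(sequence, hairpin, params$mismatch,
                        params$gap_open, params$gap_extend, params$cap,
                        params$min_core, params$max_ties)
  out <- data.frame(start = res$start, end = res$end, ops = res$ops,
                    penalty = rep(if (is.null(res$penalty)) NA_integer_ else
                      res$penalty, length(res$start)),
                    n_mismatch = res$n_mismatch, n_ins = res$n_ins,
                    n_del = res$n_del, clip5 = res$clip5,
                    clip3 = res$clip3, n_n = res$n_n,
                    stringsAsFactors = FALSE)
  attr(out, "truncated") <- isTRUE(res$truncated)
  out
}

#' Map collapsed reads against a hairpin reference set
#'
#' For each read the minimum penalty is taken over all hairpins and every
#' alignment achieving it — across hairpins and across loci within one
#' hairpin — is retained, mirroring all-best-score reporting.  Unmapped
#' reads (nothing within the cap) are listed separately.
#'
#' @param collapsed data.frame from [collapse_reads()].
#' @param hairpins named character vector of hairpin sequences.
#' @param params an [align_params()] object.
#' @return list with `mappings` (data.frame: `uid`, `count`, `sequence`,
#'   `hairpin_id` + alignment columns), `unmapped` (data.frame `uid`,
#'   `count`), and `stats` (read-count-weighted tallies of mapping
#'   features; the feature categories overlap except `perfect`).
#' @export
map_all <- function(collapsed, hairpins, params = align_params()) {
  stopifnot(length(names(hairpins)) == length(hairpins))
  rows <- vector("list", nrow(collapsed))
  unmapped <- logical(nrow(collapsed))
  stats <- c(mapped = 0, unmapped = 0, unique = 0, non_unique = 0,
             perfect = 0, mismatch = 0, insertion = 0, deletion = 0,
             clip5 = 0, clip3 = 0, both_clips = 0)
  for (r in seq_len(nrow(collapsed))) {
    seqr <- collapsed$sequence[r]
    cnt <- collapsed$count[r]
    per <- lapply(names(hairpins), function(h) {
      a <- align_read(seqr, hairpins[[h]], params)
      if (nrow(a)) a$hairpin_id <- h
      a
    })
    pens <- vapply(per, function(a) {
      if (nrow(a)) a$penalty[1] else NA_integer_
    }, integer(1))
    if (all(is.na(pens))) {
      unmapped[r] <- TRUE
      stats["unmapped"] <- stats["unmapped"] + cnt
      next
    }
    best <- min(pens, na.rm = TRUE)
    hit <- do.call(rbind, per[!is.na(pens) & pens == best])
    hit$uid <- collapsed$uid[r]
    hit$count <- cnt
    hit$sequence <- seqr
    rows[[r]] <- hit
    stats["mapped"] <- stats["mapped"] + cnt
    if (nrow(hit) == 1) stats["unique"] <- stats["unique"] + cnt else
      stats["non_unique"] <- stats["non_unique"] + cnt
    w <- cnt / nrow(hit)
    for (i in seq_len(nrow(hit))) {
      if (hit$penalty[i] == 0 && hit$clip5[i] == 0 && hit$clip3[i] == 0) {
        stats["perfect"] <- stats["perfect"] + w
      }
      if (hit$n_mismatch[i] > 0) stats["mismatch"] <- stats["mismatch"] + w
      if (hit$n_ins[i] > 0) stats["insertion"] <- stats["insertion"] + w
      if (hit$n_del[i] > 0) stats["deletion"] <- stats["deletion"] + w
      if (hit$clip5[i] > 0 && hit$clip3[i] > 0) {
        stats["both_clips"] <- stats["both_clips"] + w
      } else if (hit$clip5[i] > 0) {
        stats["clip5"] <- stats["clip5"] + w
      } else if (hit$clip3[i] > 0) {
        stats["clip3"] <- stats["clip3"] + w
      }
    }
  }
  mappings <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(mappings)) {
    mappings <- data.frame(start = integer(0), end = integer(0),
                           ops = character(0), penalty = integer(0),
                           n_mismatch = integer(0), n_ins = integer(0),
                           n_del = integer(0), clip5 = integer(0),
                           clip3 = integer(0), n_n = integer(0),
                           hairpin_id = character(0), uid = character(0),
                           count = integer(0), sequence = character(0),
                           stringsAsFactors = FALSE)
  }
  rownames(mappings) <- NULL
  list(mappings = mappings,
       unmapped = collapsed[unmapped, c("uid", "count"), drop = FALSE],
       stats = as.list(stats))
}

#' Locate canonical mature miRNAs on their paired hairpins
#'
#' Mature and hairpin records are paired by their shared id stem: the
#' mature id with any `-5p`/`-3p` suffix removed must equal the hairpin
#' id, case-insensitively (so `xxx-miR-9-5p` pairs with `xxx-mir-9`).
#' Each mature is located by exact substring search in its paired
#' hairpin.  Multiple occurrences are disambiguated by the arm suffix
#' when present; otherwise the first occurrence is taken with a warning.
#' The arm label comes from the id suffix when present, else from the
#' locus midpoint (5' half of the hairpin = 5p).
#'
#' @param matures named character vector of mature sequences.
#' @param hairpins named character vector of hairpin sequences.
#' @return data.frame with columns `mature_id`, `hairpin_id`, `start`,
#'   `end` (0-based half-open on the hairpin), `arm`.
#' @export
locate_matures <- function(matures, hairpins) {
  hp_norm <- tolower(names(hairpins))
  rows <- list()
  for (mid in names(matures)) {
    norm <- tolower(mid)
    suffix <- if (grepl("-5p$", norm)) "5p" else
      if (grepl("-3p$", norm)) "3p" else NA_character_
    stem <- sub("-[35]p$", "", norm)
    hi <- which(hp_norm == stem)
    if (length(hi) == 0) {
      warning("no paired hairpin for mature ", mid, "; excluded")
      next
    }
    hid <- names(hairpins)[hi[1]]
    hseq <- hairpins[[hi[1]]]
    mseq <- matures[[mid]]
    if (nchar(mseq) < 15) {
      warning("mature ", mid, " is shorter than 15 nt")
    }
    occ <- gregexpr(mseq, hseq, fixed = TRUE)[[1]]
    if (occ[1] == -1) {
      warning("mature ", mid, " not found in hairpin ", hid, "; excluded")
      next
    }
    starts <- as.integer(occ) - 1L
    pick <- starts[1]
    if (length(starts) > 1) {
      mids <- starts + nchar(mseq) / 2
      in5 <- mids < nchar(hseq) / 2
      if (!is.na(suffix)) {
        want <- if (suffix == "5p") in5 else !in5
        if (any(want)) pick <- starts[want][1] else {
          warning("ambiguous occurrences for ", mid,
                  "; using the first")
        }
      } else {
        warning("ambiguous occurrences for ", mid, "; using the first")
      }
    }
    arm <- if (!is.na(suffix)) suffix else {
      if (pick + nchar(mseq) / 2 < nchar(hseq) / 2) "5p" else "3p"
    }
    rows[[length(rows) + 1]] <- data.frame(
      mature_id = mid, hairpin_id = hid, start = pick,
      end = pick + nchar(mseq), arm = arm, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0) {
    return(data.frame(mature_id = character(0), hairpin_id = character(0),
                      start = integer(0), end = integer(0),
                      arm = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
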