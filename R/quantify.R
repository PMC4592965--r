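#' Quantification settings
#'
#' @param max_shift maximum tolerated end shift (nt) between a read and
#'   its canonical mature at either end (default 3).
#' @param seed_check require an error-free seed region (read positions
#'   2-8, 1-based) identical in placement to the canonical mature
#'   (default TRUE).
#' @return a `quant_settings` list.
#' @export
quant_settings <- function(max_shift = 3L, seed_check = TRUE) {
  structure(list(max_shift = as.integer(max_shift),
                 seed_check = isTRUE(seed_check),
                 seed_from = 2L, seed_to = 8L),
            class = "quant_settings")
}

#' Position check: match an alignment to a mature locus
#'
#' For every canonical mature locus on the aligned hairpin, the 5' and 3'
#' end shifts of the aligned core are computed; a locus passes when both
#' absolute shifts are within `max_shift`.  Among passing loci the one
#' with the smallest total absolute shift wins, ties going to the 5p arm.
#'
#' @param alignment one mapping (list or single data.frame row with
#'   `hairpin_id`, `start`, `end`).
#' @param loci data.frame from [locate_matures()].
#' @param max_shift maximum absolute end shift.
#' @return list with `mature_id`, `arm`, `shift5`, `shift3`, `locus_start`,
#'   `locus_end`, or `NULL` when no locus passes.
#' @export
position_check <- function(alignment, loci, max_shift = 3L) {
  cand <- loci[loci$hairpin_id == alignment$hairpin_id, , drop = FALSE]
  if (nrow(cand) == 0) return(NULL)
  s5 <- alignment$start - cand$start
  s3 <- alignment$end - cand$end
  pass <- abs(s5) <= max_shift & abs(s3) <= max_shift
  if (!any(pass)) return(NULL)
  tot <- abs(s5) + abs(s3)
  tot[!pass] <- NA
  armord <- ifelse(cand$arm == "5p", 0L, 1L)
  pick <- order(tot, armord, na.last = TRUE)[1]
  list(mature_id = cand$mature_id[pick], arm = cand$arm[pick],
       shift5 = s5[pick], shift3 = s3[pick],
       locus_start = cand$start[pick], locus_end = cand$end[pick])
}

#' Seed-region check
#'
#' Passes iff the read has no 5' soft clip, starts exactly at the locus
#' start, and read positions 2-8 (1-based) align to the seven hairpin
#' bases following the locus start as matches only — no mismatch,
#' insertion or deletion touches the seed window.
#'
#' @param alignment one mapping with `ops`, `clip5`, `start`.
#' @param locus_start 0-based start of the canonical mature locus.
#' @param seed_from,seed_to 1-based read positions delimiting the seed.
#' @return logical.
#' @export
seed_check <- function(alignment, locus_start, seed_from = 2L,
                       seed_to = 8L) {
  if (alignment$clip5 != 0) return(FALSE)
  if (alignment$start != locus_start) return(FALSE)
  ops <- strsplit(alignment$ops, "")[[1]]
  read_pos <- 0L
  for (op in ops) {
    if (op %in% c("=", "X", "I", "S")) {
      read_pos <- read_pos + 1L
      if (read_pos >= seed_from && read_pos <= seed_to && op != "=") {
        return(FALSE)
      }
      # an insertion upstream of the seed shifts its hairpin placement
      if (op == "I" && read_pos < seed_from) return(FALSE)
      if (read_pos > seed_to) return(TRUE)
    } else if (op == "D") {
      # a deletion between read positions p and p+1 breaks the seed
      # window when it falls before position seed_to
      if (read_pos >= seed_from - 1L && read_pos < seed_to) return(FALSE)
    }
  }
  TRUE
}

#' Filter mappings by the position (and optional seed) checks
#'
#' @param mappings data.frame from [map_all()]`$mappings`.
#' @param loci data.frame from [locate_matures()].
#' @param settings a [quant_settings()] object.
#' @return list with `qualified` (mappings annotated with `mature_id`,
#'   `arm`, `shift5`, `shift3`, `clips`) and `stats` (read-count-weighted
#'   tallies: reads failing the position check, reads failing the seed
#'   check, reads qualified).
#' @export
qualify_mappings <- function(mappings, loci, settings = quant_settings()) {
  keep <- logical(nrow(mappings))
  mat <- arm <- character(nrow(mappings))
  s5 <- s3 <- integer(nrow(mappings))
  pos_pass <- logical(nrow(mappings))
  for (i in seq_len(nrow(mappings))) {
    aln <- mappings[i, ]
    pc <- position_check(aln, loci, settings$max_shift)
    if (is.null(pc)) next
    pos_pass[i] <- TRUE
    if (settings$seed_check &&
        !seed_check(aln, pc$locus_start, settings$seed_from,
                    settings$seed_to)) {
      next
    }
    keep[i] <- TRUE
    mat[i] <- pc$mature_id
    arm[i] <- pc$arm
    s5[i] <- pc$shift5
    s3[i] <- pc$shift3
  }
  qual <- mappings[keep, , drop = FALSE]
  qual$mature_id <- mat[keep]
  qual$arm <- arm[keep]
  qual$shift5 <- s5[keep]
  qual$shift3 <- s3[keep]
  qual$clips <- qual$clip5 + qual$clip3

  per_read <- function(flag) {
    tapply(flag, mappings$uid, any)
  }
  counts <- mappings$count[!duplicated(mappings$uid)]
  names(counts) <- mappings$uid[!duplicated(mappings$uid)]
  if (nrow(mappings)) {
    anypos <- per_read(pos_pass)
    anyqual <- per_read(keep)
    stats <- list(
      n_fail_position = sum(counts[names(anypos)[!anypos]]),
      n_fail_seed = sum(counts[names(anypos)[anypos & !anyqual]]),
      n_qualified = sum(counts[names(anyqual)[anyqual]]))
  } else {
    stats <- list(n_fail_position = 0, n_fail_seed = 0, n_qualified = 0)
  }
  list(qualified = qual, stats = stats)
}

#' Assign read counts to mature miRNAs
#'
#' Per collapsed read: no qualified mapping discards the read; a unique
#' qualified mapping contributes its whole count; with several, the
#' best-priority subset — qualified mappings minimising total
#' soft-clipped bases — shares the count evenly, so no read is ever
#' counted more than once.  Fractional counts are accumulated as exact
#' rationals over a common denominator.
#'
#' @param mappings data.frame from [map_all()]`$mappings`.
#' @param loci data.frame from [locate_matures()].
#' @param settings a [quant_settings()] object.
#' @return list with `fractional` (named numeric, exact), `numer`/`denom`
#'   (the exact rational representation), `reads` (the counted
#'   best-priority mappings with their `share`), and `stats`.
#' @export
assign_counts <- function(mappings, loci, settings = quant_settings()) {
  q <- qualify_mappings(mappings, loci, settings)
  qual <- q$qualified
  matures <- sort(unique(loci$mature_id))

  picked <- vector("list", 0)
  ks <- integer(0)
  if (nrow(qual)) {
    for (uid in unique(qual$uid)) {
      rows <- qual[qual$uid == uid, , drop = FALSE]
      rows <- rows[rows$clips == min(rows$clips), , drop = FALSE]
      rows$share <- rows$count / nrow(rows)
      rows$n_share <- nrow(rows)
      picked[[length(picked) + 1]] <- rows
      ks <- c(ks, nrow(rows))
    }
  }
  reads <- if (length(picked)) do.call(rbind, picked) else {
    cbind(qual, share = numeric(0), n_share = integer(0))
  }
  rownames(reads) <- NULL

  denom <- if (length(ks)) Reduce(lcm2, unique(ks)) else 1
  numer <- setNames(numeric(length(matures)), matures)
  if (nrow(reads)) {
    contrib <- reads$count * (denom / reads$n_share)
    agg <- tapply(contrib, reads$mature_id, sum)
    numer[names(agg)] <- agg
  }
  list(fractional = numer / denom, numer = numer, denom = denom,
       reads = reads,
       stats = c(q$stats, list(n_counted = q$stats$n_qualified)))
}

#' Round exact fractional counts to integers
#'
#' Round half away from zero, applied to the exact rational
#' representation so no floating drift can flip a boundary.
#'
#' @param counts result of [assign_counts()], or a plain numeric vector.
#' @return named numeric vector of integers.
#' @export
round_counts <- function(counts) {
  if (is.list(counts) && !is.null(counts$numer)) {
    return(round_rational(counts$numer, counts$denom))
  }
  sign(counts) * floor(abs(counts) + 0.5)
}

#' Aggregate mature counts by miRNA family
#'
#' A family's count is the sum of the counts of all matures whose hairpin
#' belongs to the family.  Matures whose hairpin is in no known family
#' form singleton families named by the mature id.
#'
#' @param counts named numeric vector of per-mature counts.
#' @param mifam data.frame from [parse_mifam()] (may have zero rows).
#' @param loci data.frame from [locate_matures()] linking matures to
#'   hairpins.
#' @return named numeric vector of per-family counts.
#' @export
family_counts <- function(counts, mifam, loci) {
  fam <- vapply(names(counts), function(mid) {
    hid <- loci$hairpin_id[loci$mature_id == mid][1]
    if (is.na(hid)) return(mid)
    f <- family_of(mifam, hid)
    if (is.na(f)) mid else f
  }, character(1))
  out <- tapply(counts, fam, sum)
  setNames(as.numeric(out), names(out))
}
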