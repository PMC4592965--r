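#' Perfect-mapping of collapsed reads to a genome
#'
#' Exact substring search of every collapsed read on both strands of each
#' chromosome.  Minus-strand hits are reported on genomic (plus)
#' coordinates with `strand = "-"`.
#'
#' @param collapsed data.frame from [collapse_reads()].
#' @param genome named character vector of chromosome sequences.
#' @return data.frame with `uid`, `count`, `sequence`, `chrom`, `start`,
#'   `end`, `strand`, `n_loci` (total perfect loci of the read).
#' @export
map_genome_perfect <- function(collapsed, genome) {
  rows <- list()
  for (r in seq_len(nrow(collapsed))) {
    seqr <- collapsed$sequence[r]
    rc <- revcomp(seqr)
    hits <- list()
    for (chrom in names(genome)) {
      for (str in c("+", "-")) {
        pat <- if (str == "+") seqr else rc
        occ <- gregexpr(pat, genome[[chrom]], fixed = TRUE)[[1]]
        if (occ[1] == -1) next
        hits[[length(hits) + 1]] <- data.frame(
          chrom = chrom, start = as.integer(occ) - 1L,
          end = as.integer(occ) - 1L + nchar(seqr), strand = str,
          stringsAsFactors = FALSE)
      }
    }
    if (length(hits) == 0) next
    h <- do.call(rbind, hits)
    h$uid <- collapsed$uid[r]
    h$count <- collapsed$count[r]
    h$sequence <- seqr
    h$n_loci <- nrow(h)
    rows[[length(rows) + 1]] <- h
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               strand = character(0), uid = character(0),
               count = integer(0), sequence = character(0),
               n_loci = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Build genome read stacks from perfect mappings
#'
#' Mappings are filtered to perfect hits of reads 18-25 nt long with at
#' most `max_loci` genomic loci, then merged into stacks by overlapping
#' coordinates on the same strand.
#'
#' @param mappings data.frame from [map_genome_perfect()] (or SAM-derived
#'   perfect mappings in the same layout).
#' @param min_len,max_len read length bounds, inclusive (defaults 18, 25).
#' @param max_loci maximum perfect loci per read (default 5).
#' @return data.frame with `chrom`, `strand`, `start`, `end`, `count`
#'   (summed read counts), `n_reads` (distinct collapsed reads).
#' @export
build_stacks <- function(mappings, min_len = 18L, max_len = 25L,
                         max_loci = 5L) {
  len <- mappings$end - mappings$start
  keep <- len >= min_len & len <= max_len & mappings$n_loci <= max_loci
  maps <- mappings[keep, , drop = FALSE]
  rows <- list()
  for (chrom in unique(maps$chrom)) {
    for (str in c("+", "-")) {
      sub <- maps[maps$chrom == chrom & maps$strand == str, , drop = FALSE]
      if (nrow(sub) == 0) next
      ir <- IRanges::IRanges(sub$start + 1L, sub$end)
      red <- IRanges::reduce(ir, with.revmap = TRUE)
      revmap <- S4Vectors::mcols(red)$revmap
      for (k in seq_along(red)) {
        members <- sub[revmap[[k]], , drop = FALSE]
        rows[[length(rows) + 1]] <- data.frame(
          chrom = chrom, strand = str,
          start = IRanges::start(red)[k] - 1L,
          end = IRanges::end(red)[k],
          count = sum(members$count),
          n_reads = length(unique(members$uid)),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(chrom = character(0), strand = character(0),
               start = integer(0), end = integer(0), count = numeric(0),
               n_reads = integer(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Excise candidate precursors around a read stack
#'
#' Two windows per stack, one per possible mature/loop orientation: a
#' short flank on the mature side and a long flank on the loop side
#' (`[start - 10, end + 70)` and `[start - 70, end + 10)` by default),
#' clipped at chromosome bounds.  Minus-strand stacks yield
#' reverse-complemented candidate sequences.
#'
#' @param genome named character vector of chromosome sequences.
#' @param stack one stack row from [build_stacks()].
#' @param flank_mature,flank_loop flank widths in nt (defaults 10, 70).
#' @return data.frame of at most 2 candidates: `chrom`, `start`, `end`,
#'   `strand`, `sequence`.
#' @export
excise_candidates <- function(genome, stack, flank_mature = 10L,
                              flank_loop = 70L) {
  clen <- nchar(genome[[stack$chrom]])
  win <- unique(list(
    c(max(0L, stack$start - flank_mature), min(clen, stack$end + flank_loop)),
    c(max(0L, stack$start - flank_loop), min(clen, stack$end + flank_mature))))
  rows <- lapply(win, function(wz) {
    s <- substr(genome[[stack$chrom]], wz[1] + 1L, wz[2])
    if (stack$strand == "-") s <- revcomp(s)
    data.frame(chrom = stack$chrom, start = wz[1], end = wz[2],
               strand = stack$strand, sequence = s,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[!duplicated(out[c("start", "end")]), , drop = FALSE]
}

#' Build the read signature of a candidate precursor
#'
#' Perfect mappings of collapsed reads 18-25 nt long, plus known mature
#' miRNAs (flagged), onto the candidate sequence.
#'
#' @param collapsed data.frame from [collapse_reads()].
#' @param known_matures named character vector of known mature sequences.
#' @param candidate_seq candidate precursor sequence.
#' @param min_len,max_len signature read length bounds (defaults 18, 25).
#' @return data.frame with `id`, `sequence`, `start`, `end` (0-based on
#'   the candidate), `count`, `is_known`.
#' @export
build_signature <- function(collapsed, known_matures, candidate_seq,
                            min_len = 18L, max_len = 25L) {
  probe <- function(ids, seqs, counts, known) {
    rows <- list()
    for (i in seq_along(seqs)) {
      L <- nchar(seqs[i])
      if (!known && (L < min_len || L > max_len)) next
      occ <- gregexpr(seqs[i], candidate_seq, fixed = TRUE)[[1]]
      if (occ[1] == -1) next
      rows[[length(rows) + 1]] <- data.frame(
        id = ids[i], sequence = seqs[i], start = as.integer(occ) - 1L,
        end = as.integer(occ) - 1L + L, count = counts[i],
        is_known = known, stringsAsFactors = FALSE)
    }
    rows
  }
  rows <- c(probe(collapsed$uid, collapsed$sequence, collapsed$count,
                  FALSE),
            probe(names(known_matures), unname(known_matures),
                  rep(0L, length(known_matures)), TRUE))
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(id = character(0), sequence = character(0),
               start = integer(0), end = integer(0), count = integer(0),
               is_known = logical(0), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Select the mature sequence of a candidate from its signature
#'
#' Signature reads are grouped into stacks by identical start and end on
#' the candidate; the top stack's read sequence becomes the mature iff
#' its summed count strictly exceeds `fold` times the second-highest
#' stack (with no second stack it suffices that the top count is
#' positive).  Otherwise the candidate is discarded.
#'
#' @param signature data.frame from [build_signature()].
#' @param fold fold-change threshold (default 2).
#' @return list with `sequence`, `start`, `end`, `count`, or `NULL`.
#' @export
select_mature <- function(signature, fold = 2) {
  sig <- signature[!signature$is_known, , drop = FALSE]
  if (nrow(sig) == 0) return(NULL)
  key <- paste(sig$start, sig$end)
  agg <- tapply(sig$count, key, sum)
  ord <- order(-agg, names(agg), method = "radix")
  top <- agg[ord[1]]
  second <- if (length(agg) > 1) agg[ord[2]] else 0
  if (!(top > fold * second) || top <= 0) return(NULL)
  row <- sig[key == names(agg)[ord[1]], , drop = FALSE][1, ]
  list(sequence = row$sequence, start = row$start, end = row$end,
       count = as.numeric(top))
}

#' Score candidate precursors with a pluggable backend
#'
#' The probabilistic precursor score and the folding machinery are
#' third-party; any backend returning a secondary structure and a score
#' for a sequence can be plugged in.  With a backend, candidates with
#' score <= 0 are dropped.  Without one, candidates pass through marked
#' unscored; when a structure is available anyway, a structural sanity
#' filter drops candidates whose mature base-pairs with itself (a mature
#' must lie on one arm of the stem).
#'
#' @param candidates data.frame with `sequence`, `mature_start`,
#'   `mature_end` columns.
#' @param backend `NULL`, or `function(sequence)` returning
#'   `list(structure =, score =)` (either may be `NULL`).
#' @return the candidates with `structure`, `score`, `status`
#'   (`"scored"`/`"unscored"`) columns, filtered.
#' @export
score_candidates <- function(candidates, backend = NULL) {
  if (nrow(candidates) == 0) {
    candidates$structure <- character(0)
    candidates$score <- numeric(0)
    candidates$status <- character(0)
    return(candidates)
  }
  structure_ <- rep(NA_character_, nrow(candidates))
  score <- rep(NA_real_, nrow(candidates))
  status <- rep("unscored", nrow(candidates))
  if (!is.null(backend)) {
    for (i in seq_len(nrow(candidates))) {
      res <- backend(candidates$sequence[i])
      if (!is.null(res$structure)) structure_[i] <- res$structure
      if (!is.null(res$score)) {
        score[i] <- res$score
        status[i] <- "scored"
      }
    }
  }
  candidates$structure <- structure_
  candidates$score <- score
  candidates$status <- status
  keep <- rep(TRUE, nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    if (status[i] == "scored" && score[i] <= 0) keep[i] <- FALSE
    if (keep[i] && !is.na(structure_[i])) {
      keep[i] <- mature_on_one_arm(structure_[i],
                                   candidates$mature_start[i],
                                   candidates$mature_end[i])
    }
  }
  candidates[keep, , drop = FALSE]
}

#' Does the mature avoid base-pairing with itself under a structure?
#' @noRd
mature_on_one_arm <- function(structure, mature_start, mature_end) {
  ch <- strsplit(structure, "")[[1]]
  stack <- integer(0)
  partner <- rep(NA_integer_, length(ch))
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    if (ch[i] == ")") {
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j
      partner[j] <- i
    }
  }
  idx <- (mature_start + 1L):mature_end
  p <- partner[idx]
  !any(!is.na(p) & p %in% idx)
}

#' Backend wrapper around the RNAfold binary
#'
#' Returns the minimum-free-energy structure for a candidate; no
#' precursor score is produced, so candidates remain unscored but gain a
#' structure for the DBN output and the structural sanity filter.
#' Requires `RNAfold` on the PATH.
#'
#' @return a backend function for [score_candidates()].
#' @export
rnafold_backend <- function() {
  if (Sys.which("RNAfold") == "") {
    stop("RNAfold binary not found on the PATH")
  }
  function(sequence) {
    out <- system2("RNAfold", c("--noPS"),
                   input = chartr("T", "U", sequence), stdout = TRUE)
    if (length(out) < 2) return(list(structure = NULL, score = NULL))
    list(structure = sub("\\s.*$", "", out[2]), score = NULL)
  }
}

#' Nominate novel precursor candidates in one library
#'
#' Runs the stack, excision, signature and mature-selection steps over
#' perfect genome mappings.  Candidates whose selected mature is itself a
#' known mature are the known loci and are dropped; overlapping
#' candidates then compete, the strongest signature winning (ties to the
#' leftmost, then the plus strand).
#'
#' @param collapsed data.frame from [collapse_reads()].
#' @param genome named character vector of chromosome sequences.
#' @param known_matures named character vector of known mature sequences.
#' @param backend optional scoring backend (see [score_candidates()]).
#' @param fold mature-selection fold threshold (default 2).
#' @param flank_mature,flank_loop excision flanks (defaults 10, 70).
#' @return data.frame of candidate precursors with their selected mature.
#' @export
predict_novel_library <- function(collapsed, genome, known_matures,
                                  backend = NULL, fold = 2,
                                  flank_mature = 10L, flank_loop = 70L) {
  maps <- map_genome_perfect(collapsed, genome)
  stacks <- build_stacks(maps)
  rows <- list()
  for (s in seq_len(nrow(stacks))) {
    cands <- excise_candidates(genome, stacks[s, ], flank_mature,
                               flank_loop)
    for (ci in seq_len(nrow(cands))) {
      cand <- cands[ci, ]
      sig <- build_signature(collapsed, known_matures, cand$sequence)
      mat <- select_mature(sig, fold)
      if (is.null(mat)) next
      # a candidate whose selected mature is a known mature is the known
      # locus, not a novel one
      if (mat$sequence %in% known_matures) next
      cand$mature_seq <- mat$sequence
      cand$mature_start <- mat$start
      cand$mature_end <- mat$end
      cand$mature_count <- mat$count
      cand$signature_count <- sum(sig$count[!sig$is_known])
      rows[[length(rows) + 1]] <- cand
    }
  }
  if (length(rows) == 0) {
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      sequence = character(0), mature_seq = character(0),
                      mature_start = integer(0), mature_end = integer(0),
                      mature_count = numeric(0),
                      signature_count = numeric(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  # overlapping candidates compete for one precursor locus: keep the one
  # with the strongest signature (ties: leftmost, then plus strand) —
  # excision is per read region, and both excision windows of a stack as
  # well as both strands of a perfect stem describe the same locus
  ord <- order(-out$signature_count, out$start,
               ifelse(out$strand == "+", 0L, 1L), method = "radix")
  out <- out[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(out))
  for (i in seq_len(nrow(out))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(out))) {
      if (j <= i || !keep[j]) next
      if (out$chrom[i] == out$chrom[j] &&
          out$start[j] < out$end[i] && out$start[i] < out$end[j]) {
        keep[j] <- FALSE
      }
    }
  }
  out <- out[keep, , drop = FALSE]
  score_candidates(out, backend)
}

#' Unify novel candidates across libraries and quantify them
#'
#' Candidates with the same genomic coordinates in different libraries
#' are one precursor; numbering follows genomic sort order (chrom, start,
#' strand).  Matures with the same precursor and identical sequences are
#' one mature; several distinct matures on one precursor get letter
#' suffixes.  Each novel mature's seed (positions 2-8) is searched
#' against the known matures for an identical seed, recorded as the
#' description.  Novel matures are then quantified per library with
#' perfect mapping only and the usual position/seed checks.
#'
#' @param per_library named list: per library, the data.frame from
#'   [predict_novel_library()].
#' @param collapsed_per_library named list of collapsed-read data.frames
#'   (same names), used for quantification.
#' @param known_matures named character vector of known mature sequences.
#' @param species species prefix for the `XXX-novel-mir-YYY` names.
#' @param settings a [quant_settings()] object.
#' @return list with `precursors` (data.frame incl. `name`), `matures`
#'   (data.frame incl. `name`, `seed_match`), `counts` (id x library
#'   data.frame of rounded counts).
#' @export
unify_novel <- function(per_library, collapsed_per_library, known_matures,
                        species = "syn", settings = quant_settings()) {
  all_c <- do.call(rbind, c(lapply(names(per_library), function(lib) {
    x <- per_library[[lib]]
    if (nrow(x)) x$library <- lib else x$library <- character(0)
    x
  }), list(stringsAsFactors = FALSE)))
  if (is.null(all_c) || nrow(all_c) == 0) {
    return(list(precursors = data.frame(), matures = data.frame(),
                counts = data.frame(id = character(0))))
  }
  key <- paste(all_c$chrom, all_c$start, all_c$end, all_c$strand)
  uniq <- all_c[!duplicated(key), , drop = FALSE]
  ord <- order(uniq$chrom, uniq$start, uniq$strand, method = "radix")
  uniq <- uniq[ord, , drop = FALSE]
  uniq$name <- sprintf("%s-novel-mir-%d", species, seq_len(nrow(uniq)))

  seeds_known <- substr(unname(known_matures), 2, 8)
  mat_rows <- list()
  for (i in seq_len(nrow(uniq))) {
    k <- paste(uniq$chrom[i], uniq$start[i], uniq$end[i], uniq$strand[i])
    seqs <- sort(unique(all_c$mature_seq[key == k]))
    for (j in seq_along(seqs)) {
      nm <- sprintf("%s-novel-miR-%d", species, i)
      if (length(seqs) > 1) nm <- paste0(nm, "-", letters[j])
      seed <- substr(seqs[j], 2, 8)
      hit <- which(seeds_known == seed)
      mat_rows[[length(mat_rows) + 1]] <- data.frame(
        name = nm, precursor = uniq$name[i], sequence = seqs[j],
        seed_match = if (length(hit)) {
          sort(names(known_matures)[hit])[1]
        } else NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  matures <- do.call(rbind, mat_rows)

  # quantify: perfect mapping of collapsed reads onto each precursor
  prec_seqs <- setNames(uniq$sequence, uniq$name)
  loci <- do.call(rbind, lapply(seq_len(nrow(matures)), function(i) {
    p <- prec_seqs[[matures$precursor[i]]]
    occ <- regexpr(matures$sequence[i], p, fixed = TRUE)
    start <- as.integer(occ) - 1L
    mid <- start + nchar(matures$sequence[i]) / 2
    data.frame(mature_id = matures$name[i],
               hairpin_id = matures$precursor[i], start = start,
               end = start + nchar(matures$sequence[i]),
               arm = if (mid < nchar(p) / 2) "5p" else "3p",
               stringsAsFactors = FALSE)
  }))
  per_lib_counts <- lapply(collapsed_per_library, function(coll) {
    maps <- perfect_hairpin_mappings(coll, prec_seqs)
    round_counts(assign_counts(maps, loci, settings))
  })
  list(precursors = uniq, matures = matures,
       counts = build_count_table(per_lib_counts))
}

#' Perfect (exact substring) mappings of collapsed reads onto reference
#' sequences, in the layout of [map_all()]`$mappings`
#' @noRd
perfect_hairpin_mappings <- function(collapsed, refs) {
  rows <- list()
  for (r in seq_len(nrow(collapsed))) {
    seqr <- collapsed$sequence[r]
    for (h in names(refs)) {
      occ <- gregexpr(seqr, refs[[h]], fixed = TRUE)[[1]]
      if (occ[1] == -1) next
      for (p in as.integer(occ)) {
        rows[[length(rows) + 1]] <- data.frame(
          start = p - 1L, end = p - 1L + nchar(seqr),
          ops = strrep("=", nchar(seqr)), penalty = 0L,
          n_mismatch = 0L, n_ins = 0L, n_del = 0L, clip5 = 0L,
          clip3 = 0L, n_n = 0L, hairpin_id = h,
          uid = collapsed$uid[r], count = collapsed$count[r],
          sequence = seqr, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      ops = character(0), penalty = integer(0),
                      n_mismatch = integer(0), n_ins = integer(0),
                      n_del = integer(0), clip5 = integer(0),
                      clip3 = integer(0), n_n = integer(0),
                      hairpin_id = character(0), uid = character(0),
                      count = integer(0), sequence = character(0),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
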