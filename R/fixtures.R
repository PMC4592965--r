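#' Generate synthetic hairpins with planted 5p/3p matures
#'
#' Each hairpin is a stem-loop in sequence space: a random 5' arm, a loop,
#' and a 3' arm that is the exact reverse complement of the 5' arm, with
#' short single-stranded flanks on both sides so that templated 5'/3'
#' extensions of either mature exist.  Matures are the two arms; ids
#' follow the paired-naming convention (`syn-mir-N` / `syn-miR-N-5p`).
#'
#' A few bases are pinned so every planted variant is recoverable
#' unambiguously: the loop and flanks start with `C` (so planted
#' non-templated tails beginning with A/T/G can never be templated), and
#' two arm positions carry fixed bases giving both matures an internal
#' `A` in the clip-protected centre (so A-to-G editing reads exist).
#'
#' @param n number of hairpins.
#' @param seed RNG seed.
#' @param arm_len,loop_len,flank_len segment lengths (defaults 22, 12, 4).
#' @return list with `hairpins` (named character), `matures` (named
#'   character), `loci` (the planted coordinates, same layout as
#'   [locate_matures()]).
#' @export
make_hairpins <- function(n = 3L, seed = 1L, arm_len = 22L, loop_len = 12L,
                          flank_len = 4L) {
  stopifnot(arm_len >= 16, loop_len >= 5, flank_len >= 1)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  hairpins <- character(0)
  matures <- character(0)
  loci <- list()
  for (i in seq_len(n)) {
    # arms carry no two adjacent equal bases: planted indels then have a
    # unique gap placement and cannot be beaten by a mismatch-plus-clip
    # alignment (every shifted comparison mismatches)
    arm5 <- character(arm_len)
    for (p in seq_len(arm_len)) {
      if (p == 8) {        # gives the 3p mature an internal A (revcomp)
        arm5[p] <- "T"
      } else if (p == 12) {  # gives the 5p mature an internal A
        arm5[p] <- "A"
      } else {
        banned <- c(if (p > 1) arm5[p - 1], if (p == 7) "T",
                    if (p == 11) "A")
        arm5[p] <- sample(setdiff(bases, banned), 1)
      }
    }
    arm5 <- paste(arm5, collapse = "")
    loop <- paste0("CCG",
                   paste(sample(bases, loop_len - 4, replace = TRUE),
                         collapse = ""), "C")
    flank5 <- strrep("C", flank_len)
    flank3 <- paste0("CCG", strrep("C", max(0, flank_len - 3)))
    flank3 <- substr(flank3, 1, flank_len)
    arm3 <- revcomp(arm5)
    hp <- paste0(flank5, arm5, loop, arm3, flank3)
    hid <- sprintf("syn-mir-%d", i)
    hairpins[hid] <- hp
    m5 <- sprintf("syn-miR-%d-5p", i)
    m3 <- sprintf("syn-miR-%d-3p", i)
    matures[m5] <- arm5
    matures[m3] <- arm3
    loci[[length(loci) + 1]] <- data.frame(
      mature_id = c(m5, m3), hairpin_id = hid,
      start = c(flank_len, flank_len + arm_len + loop_len),
      end = c(flank_len + arm_len, flank_len + 2L * arm_len + loop_len),
      arm = c("5p", "3p"), stringsAsFactors = FALSE)
  }
  list(hairpins = hairpins, matures = matures,
       loci = do.call(rbind, loci))
}

#' Planted isomiR composition of a synthetic library
#'
#' Fractions of the counted reads planted in each variant category; they
#' must sum to 1.  `edit` reads are pure A-to-G mismatch reads (a subset
#' of the mismatch dimension); `mismatch` reads carry one non-A-to-G
#' substitution.  The defaults emulate a deeply 3'-variable composition
#' typical of animal small RNA-seq libraries.
#'
#' @param canonical,super3,sub3,super5,sub5,mismatch,edit,insertion,deletion,nta_polyA,nta_polyU,nta_other,nta5,mixture
#'   category fractions.
#' @return a named numeric `variant_profile` vector.
#' @export
variant_profile <- function(canonical = 0.40, super3 = 0.22, sub3 = 0.08,
                            super5 = 0, sub5 = 0, mismatch = 0.04,
                            edit = 0.01, insertion = 0.02,
                            deletion = 0.02, nta_polyA = 0.07,
                            nta_polyU = 0.06, nta_other = 0.03,
                            nta5 = 0, mixture = 0.05) {
  p <- c(canonical = canonical, super3 = super3, sub3 = sub3,
         super5 = super5, sub5 = sub5, mismatch = mismatch, edit = edit,
         insertion = insertion, deletion = deletion,
         nta_polyA = nta_polyA, nta_polyU = nta_polyU,
         nta_other = nta_other, nta5 = nta5, mixture = mixture)
  if (abs(sum(p) - 1) > 1e-9) stop("variant profile must sum to 1")
  structure(p, class = "variant_profile")
}

#' @noRd
largest_remainder <- function(fracs, total) {
  raw <- fracs * total
  base <- floor(raw)
  rem <- total - sum(base)
  if (rem > 0) {
    ord <- order(-(raw - base), seq_along(raw))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

#' Build one planted variant read
#' @noRd
make_variant_read <- function(category, mature, hairpin, locus_start,
                              locus_end) {
  L <- nchar(mature)
  bases <- c("A", "C", "G", "T")
  sub_at <- function(s, p, b) {
    paste0(substr(s, 1, p - 1), b, substr(s, p + 1, nchar(s)))
  }
  switch(category,
    canonical = mature,
    super3 = paste0(mature, substr(hairpin, locus_end + 1, locus_end + 2)),
    sub3 = substr(mature, 1, L - 2),
    super5 = paste0(substr(hairpin, locus_start, locus_start), mature),
    sub5 = substr(mature, 2, L),
    mismatch = {
      p <- 10L
      orig <- substr(mature, p, p)
      repl <- if (orig == "C") "G" else "C"
      sub_at(mature, p, repl)
    },
    edit = {
      cand <- 9:15
      ok <- cand[substring(mature, cand, cand) == "A"]
      if (length(ok) == 0) stop("no central A available for an edit read")
      sub_at(mature, ok[1], "G")
    },
    insertion = {
      p <- 12L
      nb <- setdiff(bases, c(substr(mature, p, p),
                             substr(mature, p + 1, p + 1)))
      paste0(substr(mature, 1, p), nb[1], substr(mature, p + 1, L))
    },
    deletion = {
      # prefer a clip-protected site whose neighbours differ (unique gap
      # placement); a homopolymer-interior deletion still yields the same
      # aligned span, so fall back to the centre if need be
      cand <- 9:15
      ok <- cand[substring(mature, cand - 1, cand - 1) !=
                   substring(mature, cand, cand) &
                 substring(mature, cand, cand) !=
                   substring(mature, cand + 1, cand + 1)]
      p <- if (length(ok)) ok[1] else 12L
      paste0(substr(mature, 1, p - 1), substr(mature, p + 1, L))
    },
    nta_polyA = paste0(mature, "AAA"),
    nta_polyU = paste0(mature, "TTT"),
    nta_other = paste0(mature, "GC"),
    nta5 = paste0("G", mature),
    mixture = paste0(mature, substr(hairpin, locus_end + 1, locus_end + 1),
                     "TT"),
    stop("unknown category: ", category))
}

#' Generate a synthetic FASTQ library with a planted truth manifest
#'
#' Reads are drawn deterministically from the planted composition: per
#' hairpin and arm, category counts follow the profile by largest
#' remainder; the adapter is appended to every read (a configurable
#' fraction carrying one planted error base in the adapter); a planted
#' fraction of extra reads fails the quality rule; a further fraction has
#' inserts too short to survive trimming.
#'
#' @param ref result of [make_hairpins()].
#' @param profile a [variant_profile()].
#' @param n_reads number of countable reads planted (before the extra
#'   quality-fail / too-short reads).
#' @param adapter adapter sequence appended to every read.
#' @param arm_counts optional named list `hairpin_id -> c(p5 =, p3 =)`
#'   overriding the per-arm read allocation (used to plant arm
#'   dominance); when given, `n_reads` is ignored.
#' @param arm_weights default 5p/3p split of each hairpin's reads.
#' @param quality_fail_frac fraction of extra reads planted to fail the
#'   Q20/95\% rule.
#' @param too_short_frac fraction of extra reads with inserts shorter
#'   than the clean-read minimum.
#' @param adapter_error_frac fraction of reads whose appended adapter
#'   carries one planted error base.
#' @param seed RNG seed (read shuffling and error placement).
#' @return list with `reads` (FASTQ-layout data.frame) and `manifest`
#'   (planted truth: per-read-class table and totals).
#' @export
make_library <- function(ref, profile = variant_profile(),
                         n_reads = 1000L, adapter = default_adapter(),
                         arm_counts = NULL,
                         arm_weights = c(p5 = 0.7, p3 = 0.3),
                         quality_fail_frac = 0.05, too_short_frac = 0.02,
                         adapter_error_frac = 0.1, seed = 1L) {
  set.seed(seed)
  hp_ids <- names(ref$hairpins)
  plan <- list()
  for (hi in seq_along(hp_ids)) {
    hid <- hp_ids[hi]
    if (!is.null(arm_counts)) {
      if (!hid %in% names(arm_counts)) next
      per_arm <- arm_counts[[hid]]
    } else {
      n_h <- largest_remainder(rep(1 / length(hp_ids), length(hp_ids)),
                               n_reads)[hi]
      per_arm <- setNames(largest_remainder(unname(arm_weights), n_h),
                          c("p5", "p3"))
    }
    for (arm in c("5p", "3p")) {
      n_arm <- per_arm[[if (arm == "5p") "p5" else "p3"]]
      if (n_arm == 0) next
      loci <- ref$loci[ref$loci$hairpin_id == hid &
                         ref$loci$arm == arm, ]
      mid <- loci$mature_id[1]
      mat <- ref$matures[[mid]]
      cat_counts <- largest_remainder(unclass(profile), n_arm)
      names(cat_counts) <- names(profile)
      for (k in names(cat_counts)) {
        if (cat_counts[[k]] == 0) next
        seqk <- make_variant_read(k, mat, ref$hairpins[[hid]],
                                  loci$start[1], loci$end[1])
        plan[[length(plan) + 1]] <- data.frame(
          hairpin_id = hid, arm = arm, mature_id = mid, category = k,
          count = cat_counts[[k]], sequence = seqk,
          stringsAsFactors = FALSE)
      }
    }
  }
  plan <- do.call(rbind, plan)
  rownames(plan) <- NULL
  n_planted <- sum(plan$count)

  n_fail <- round(quality_fail_frac * n_planted)
  n_short <- round(too_short_frac * n_planted)
  first_mat <- ref$matures[[plan$mature_id[1]]]

  inserts <- c(rep(plan$sequence, plan$count),
               rep(first_mat, n_fail),
               rep(substr(first_mat, 1, 12), n_short))
  bad_quality <- c(rep(FALSE, n_planted), rep(TRUE, n_fail),
                   rep(FALSE, n_short))

  full <- paste0(inserts, adapter)
  n_tot <- length(full)
  err_adapter <- rep(FALSE, n_tot)
  if (adapter_error_frac > 0 && n_tot > 0) {
    idx <- which(!bad_quality)
    pick <- idx[seq_along(idx) %% max(1L, round(1 / adapter_error_frac)) == 0]
    for (i in pick) {
      # plant one mismatch inside the adapter, beyond its first 10 bases
      p <- nchar(inserts[i]) + 12L
      orig <- substr(full[i], p, p)
      repl <- setdiff(c("A", "C", "G", "T"), orig)[1]
      full[i] <- paste0(substr(full[i], 1, p - 1), repl,
                        substring(full[i], p + 1))
      err_adapter[i] <- TRUE
    }
  }
  qual <- strrep("I", nchar(full))
  if (any(bad_quality)) {
    nb <- nchar(full[bad_quality])
    qual[bad_quality] <- paste0(strrep("+", 6L), strrep("I", nb - 6L))
  }
  ord <- sample(n_tot)
  reads <- data.frame(read_id = sprintf("r%d", seq_len(n_tot)),
                      sequence = full[ord], quality = qual[ord],
                      stringsAsFactors = FALSE)
  list(reads = reads,
       manifest = list(plan = plan, n_planted = n_planted,
                       n_quality_fail = n_fail, n_too_short = n_short,
                       n_adapter_error = sum(err_adapter),
                       n_raw = n_tot, adapter = adapter))
}

#' Default adapter used by the synthetic generator
#' @export
default_adapter <- function() "ATCTCGTATGCCGTCTTCTGCTTG"

#' miFam-style family text for synthetic hairpins
#'
#' The first two hairpins are grouped into one family; all others are
#' left unassigned (downstream they become singleton families).
#'
#' @param ref result of [make_hairpins()].
#' @return character vector of miFam.dat-style lines.
#' @export
make_mifam_text <- function(ref) {
  ids <- names(ref$hairpins)
  if (length(ids) < 2) return(character(0))
  c("AC   SYNF0000001",
    "ID   syn-fam-1",
    sprintf("MI   SYNMI%07d  %s", 1:2, ids[1:2]),
    "//")
}

#' Embed hairpins in a synthetic genome with annotation and alignments
#'
#' Chromosome `chr1` carries each known hairpin, one extra novel hairpin
#' absent from the known references, and decoy genes (protein coding,
#' rRNA, and an overlapping gene pair), all separated by random spacers.
#' Returns the genome, the feature table (known hairpins annotated as
#' miRNA genes), planted genome alignments for the cataloguing module,
#' and the truth coordinates.
#'
#' @param ref result of [make_hairpins()] (the known references).
#' @param seed RNG seed.
#' @param spacer_len spacer length between planted elements.
#' @return list with `genome`, `features`, `alignments`, `truth`.
#' @export
make_genome <- function(ref, seed = 1L, spacer_len = 300L) {
  set.seed(seed + 7L)
  bases <- c("A", "C", "G", "T")
  rnd <- function(n) paste(sample(bases, n, replace = TRUE), collapse = "")

  novel <- make_hairpins(1, seed = seed + 31L)
  names(novel$hairpins) <- "syn-novel-hairpin"

  parts <- character(0)
  feats <- list()
  truth <- list()
  pos <- 0L
  push <- function(s) {
    parts[[length(parts) + 1]] <<- s
    at <- pos
    pos <<- pos + nchar(s)
    at
  }
  push(rnd(spacer_len))
  for (hid in names(ref$hairpins)) {
    at <- push(ref$hairpins[[hid]])
    feats[[length(feats) + 1]] <- data.frame(
      chrom = "chr1", start = at, end = at + nchar(ref$hairpins[[hid]]),
      strand = "+", gene_id = hid, biotype = "miRNA",
      stringsAsFactors = FALSE)
    truth[[hid]] <- c(start = at, end = at + nchar(ref$hairpins[[hid]]))
    push(rnd(spacer_len))
  }
  nov_at <- push(novel$hairpins[[1]])
  truth$novel <- list(
    start = nov_at, end = nov_at + nchar(novel$hairpins[[1]]),
    hairpin = novel$hairpins[[1]],
    mature5p = novel$matures[["syn-miR-1-5p"]],
    mature3p = novel$matures[["syn-miR-1-3p"]],
    mature5p_start = nov_at + novel$loci$start[1],
    mature5p_end = nov_at + novel$loci$end[1])
  push(rnd(spacer_len))
  pc_at <- push(rnd(200L))
  feats[[length(feats) + 1]] <- data.frame(
    chrom = "chr1", start = pc_at, end = pc_at + 200L, strand = "+",
    gene_id = "gene_pc1", biotype = "protein_coding",
    stringsAsFactors = FALSE)
  push(rnd(spacer_len))
  rr_at <- push(rnd(150L))
  feats[[length(feats) + 1]] <- data.frame(
    chrom = "chr1", start = rr_at, end = rr_at + 150L, strand = "+",
    gene_id = "gene_rrna1", biotype = "rRNA", stringsAsFactors = FALSE)
  push(rnd(spacer_len))
  ov_at <- push(rnd(240L))
  feats[[length(feats) + 1]] <- data.frame(
    chrom = "chr1", start = ov_at, end = ov_at + 160L, strand = "+",
    gene_id = "gene_ovlA", biotype = "protein_coding",
    stringsAsFactors = FALSE)
  feats[[length(feats) + 1]] <- data.frame(
    chrom = "chr1", start = ov_at + 80L, end = ov_at + 240L, strand = "+",
    gene_id = "gene_ovlB", biotype = "protein_coding",
    stringsAsFactors = FALSE)
  spacer_at <- push(rnd(spacer_len))
  genome <- c(chr1 = paste(parts, collapse = ""))

  truth$pc <- c(start = pc_at, end = pc_at + 200L)
  truth$rrna <- c(start = rr_at, end = rr_at + 150L)
  truth$overlap <- c(start = ov_at + 80L, end = ov_at + 160L)
  truth$spacer <- c(start = spacer_at, end = spacer_at + spacer_len)

  mk_aln <- function(uid, at, len) {
    data.frame(uid = uid, flag = 0L, chrom = "chr1", start = at,
               cigar = sprintf("%dM", len), strand = "+", mapq = 30L,
               mapped = TRUE, secondary = FALSE,
               seq = substr(genome[["chr1"]], at + 1L, at + len),
               stringsAsFactors = FALSE)
  }
  first_hp <- names(ref$hairpins)[1]
  aln <- rbind(
    mk_aln("1-10", truth[[first_hp]][["start"]] + 4L, 22L),  # miRNA
    mk_aln("2-7", pc_at + 20L, 22L),                         # protein_coding
    mk_aln("3-5", rr_at + 30L, 22L),                         # rRNA
    mk_aln("4-2", spacer_at + 50L, 22L),                     # no_feature
    mk_aln("5-3", ov_at + 100L, 22L))                        # ambiguous
  unm <- data.frame(uid = "6-4", flag = 4L, chrom = NA_character_,
                    start = NA_integer_, cigar = NA_character_,
                    strand = NA_character_, mapq = 0L, mapped = FALSE,
                    secondary = FALSE, seq = strrep("A", 22L),
                    stringsAsFactors = FALSE)
  alignments <- rbind(aln, unm)
  truth$catalog <- list(miRNA = 10, protein_coding = 7, rRNA = 5,
                        no_feature = 2, ambiguous = 3, unmapped = 4,
                        total = 31)

  list(genome = genome, features = do.call(rbind, feats),
       alignments = alignments, truth = truth)
}

#' Write a feature table as a GTF file
#'
#' Converts the internal 0-based half-open coordinates back to 1-based
#' inclusive GTF lines of the configured feature kind.
#'
#' @param features data.frame in the [parse_gtf()] layout.
#' @param path output path.
#' @param feature feature column value (default `"exon"`).
#' @export
write_gtf <- function(features, path, feature = "exon") {
  lines <- sprintf(
    '%s\tmirvar\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; gene_biotype "%s";',
    features$chrom, feature, features$start + 1L, features$end,
    features$strand, features$gene_id, features$biotype)
  writeLines(lines, path)
  invisible(path)
}

#' Write a complete fixture set to a directory
#'
#' Emits hairpin/mature FASTA, a family file, per-library FASTQ, the
#' genome FASTA with GTF annotation and planted SAM alignments, and the
#' truth manifest as JSON.
#'
#' @param dir output directory (created if needed).
#' @param seed RNG seed.
#' @param n_libraries number of FASTQ libraries.
#' @param n_reads planted reads per library.
#' @return invisibly, the truth manifest list.
#' @export
write_fixtures <- function(dir, seed = 1L, n_libraries = 2L,
                           n_reads = 1000L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_hairpins(3, seed = seed)
  write_fasta(ref$hairpins, file.path(dir, "hairpin.fa"), rna = TRUE)
  write_fasta(ref$matures, file.path(dir, "mature.fa"), rna = TRUE)
  writeLines(make_mifam_text(ref), file.path(dir, "miFam.dat"))
  manifests <- list()
  for (i in seq_len(n_libraries)) {
    lib <- make_library(ref, n_reads = n_reads, seed = seed + i)
    write_fastq(lib$reads, file.path(dir, sprintf("lib%d.fastq", i)))
    lib$manifest$plan <- as.list(lib$manifest$plan)
    manifests[[sprintf("lib%d", i)]] <- lib$manifest
  }
  gen <- make_genome(ref, seed = seed)
  write_fasta(gen$genome, file.path(dir, "genome.fa"))
  write_gtf(gen$features, file.path(dir, "annotation.gtf"))
  write_sam(gen$alignments,
            setNames(nchar(gen$genome), names(gen$genome)),
            file.path(dir, "genome.sam"))
  manifest <- list(seed = seed, libraries = manifests,
                   genome_truth = gen$truth)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
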