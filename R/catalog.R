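#' Count genome-aligned reads per gene, union mode
#'
#' Union-mode feature resolution: the set of gene ids overlapped by any
#' aligned base of the read decides its fate — empty set `no_feature`,
#' one gene counts to that gene, several genes `ambiguous`.  Unmapped
#' records land in `unmapped`; mapped records under the quality floor in
#' `below_quality`.  Multi-mapped reads are resolved by their primary
#' alignment only (secondary records are ignored).  Collapsed reads are
#' expanded by their support counts (parsed from `XXX-YYY` uids) so the
#' tallies are in clean reads.
#'
#' @param alignments data.frame from [read_sam()].
#' @param features data.frame from [parse_gtf()].
#' @param min_quality minimum alignment quality (default 0).
#' @param stranded require the read and feature strands to agree
#'   (default FALSE).
#' @return list with `gene_counts` (named numeric), `buckets` (named
#'   numeric: `no_feature`, `ambiguous`, `unmapped`, `below_quality`),
#'   and `n_total` (clean reads represented).
#' @export
count_features <- function(alignments, features, min_quality = 0,
                           stranded = FALSE) {
  aln <- alignments[!alignments$secondary, , drop = FALSE]
  w <- read_weights(aln$uid)
  buckets <- c(no_feature = 0, ambiguous = 0, unmapped = 0,
               below_quality = 0)
  gene_counts <- setNames(numeric(0), character(0))
  n_total <- sum(w)

  is_un <- !aln$mapped
  buckets["unmapped"] <- sum(w[is_un])
  low <- aln$mapped & aln$mapq < min_quality
  buckets["below_quality"] <- sum(w[low])
  use <- which(aln$mapped & !low)
  if (length(use) && nrow(features)) {
    spans <- vapply(aln$cigar[use], function(cg) {
      cigar_ref_len(cigar_runs(cg))
    }, numeric(1))
    rg <- GenomicRanges::GRanges(
      aln$chrom[use],
      IRanges::IRanges(aln$start[use] + 1L, aln$start[use] + spans),
      strand = aln$strand[use])
    fg <- GenomicRanges::GRanges(
      features$chrom, IRanges::IRanges(features$start + 1L, features$end),
      strand = features$strand)
    ov <- GenomicRanges::findOverlaps(rg, fg,
                                      ignore.strand = !stranded)
    qh <- S4Vectors::queryHits(ov)
    genes <- features$gene_id[S4Vectors::subjectHits(ov)]
    per_read <- split(genes, qh)
    hit_sets <- lapply(per_read, unique)
    n_genes <- integer(length(use))
    n_genes[as.integer(names(hit_sets))] <- lengths(hit_sets)

    buckets["no_feature"] <- sum(w[use][n_genes == 0])
    buckets["ambiguous"] <- sum(w[use][n_genes > 1])
    one <- which(n_genes == 1)
    if (length(one)) {
      g <- vapply(hit_sets[as.character(one)], `[[`, character(1), 1)
      agg <- tapply(w[use][one], g, sum)
      gene_counts <- setNames(as.numeric(agg), names(agg))
    }
  } else if (length(use)) {
    buckets["no_feature"] <- sum(w[use])
  }
  list(gene_counts = gene_counts, buckets = buckets, n_total = n_total)
}

#' @noRd
read_weights <- function(uids) {
  m <- regmatches(uids, regexec("^\\d+-(\\d+)$", uids))
  vapply(m, function(x) {
    if (length(x) == 2) as.numeric(x[2]) else 1
  }, numeric(1))
}

#' Aggregate per-gene counts into a biotype catalogue
#'
#' Gene counts are summed by annotated biotype; the special buckets are
#' appended.  Percentages are over the total clean reads represented
#' (mapped and unmapped), not over mapped reads only.
#'
#' @param counted result of [count_features()].
#' @param features data.frame from [parse_gtf()].
#' @return data.frame with `category`, `count`, `pct`; the biotype rows
#'   and the special buckets partition the total.
#' @export
aggregate_biotypes <- function(counted, features) {
  bmap <- features$biotype[match(names(counted$gene_counts),
                                 features$gene_id)]
  rows <- if (length(counted$gene_counts)) {
    agg <- tapply(counted$gene_counts, bmap, sum)
    data.frame(category = names(agg), count = as.numeric(agg),
               stringsAsFactors = FALSE)
  } else {
    data.frame(category = character(0), count = numeric(0),
               stringsAsFactors = FALSE)
  }
  rows <- rbind(rows, data.frame(category = names(counted$buckets),
                                 count = as.numeric(counted$buckets),
                                 stringsAsFactors = FALSE))
  rows$pct <- if (counted$n_total > 0) {
    100 * rows$count / counted$n_total
  } else 0
  rownames(rows) <- NULL
  rows
}

#' Catalogue a library's genome alignments by biotype
#'
#' Convenience wrapper: SAM + GTF in, biotype table out.
#'
#' @param sam_path path to a SAM file of genome alignments.
#' @param gtf_path path to a GTF annotation.
#' @param feature GTF feature kind to count against (default `"exon"`).
#' @param min_quality minimum alignment quality (default 0).
#' @param stranded strand-aware counting (default FALSE).
#' @return data.frame as from [aggregate_biotypes()].
#' @export
catalog_reads <- function(sam_path, gtf_path, feature = "exon",
                          min_quality = 0, stranded = FALSE) {
  aln <- read_sam(sam_path)
  feats <- parse_gtf(gtf_path, feature = feature)
  aggregate_biotypes(count_features(aln, feats, min_quality, stranded),
                     feats)
}
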