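#' Parse a GTF annotation into genome features
#'
#' Reads an Ensembl-dialect GTF via rtracklayer and converts the 1-based
#' inclusive coordinates to the internal 0-based half-open convention.
#' Only rows of the configured feature kind are retained.  The biotype is
#' taken from the `gene_biotype` attribute, falling back to `biotype`,
#' then to the GTF source column.  Rows without a `gene_id` are skipped
#' with a warning.
#'
#' @param path path to a GTF file.
#' @param feature feature kind to retain (default `"exon"`).
#' @return data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `gene_id`, `biotype`.
#' @export
parse_gtf <- function(path, feature = "exon") {
  g <- rtracklayer::import(path, format = "gtf")
  g <- g[as.character(g$type) == feature]
  mc <- S4Vectors::mcols(g)
  gene_id <- if ("gene_id" %in% names(mc)) as.character(mc$gene_id) else
    rep(NA_character_, length(g))
  biotype <- rep(NA_character_, length(g))
  if ("gene_biotype" %in% names(mc)) {
    biotype <- as.character(mc$gene_biotype)
  }
  if ("biotype" %in% names(mc)) {
    biotype <- ifelse(is.na(biotype), as.character(mc$biotype), biotype)
  }
  biotype <- ifelse(is.na(biotype), as.character(mc$source), biotype)

  drop <- is.na(gene_id)
  if (any(drop)) {
    warning("skipping ", sum(drop), " GTF record(s) without gene_id")
  }
  keep <- !drop
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(g))[keep],
    start = GenomicRanges::start(g)[keep] - 1L,
    end = GenomicRanges::end(g)[keep],
    strand = as.character(GenomicRanges::strand(g))[keep],
    gene_id = gene_id[keep],
    biotype = biotype[keep],
    stringsAsFactors = FALSE)
}
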