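#' Validate a pipeline run configuration
#'
#' @param libraries named character vector of FASTQ paths (names are the
#'   library/column names).
#' @param mature_fa,hairpin_fa reference FASTA paths (required).
#' @param mifam optional family-classification file path.
#' @param gtf,genome_fa,genome_sam optional annotation / genome /
#'   genome-alignment paths for the cataloguing and novel modules.
#' @param out_dir output directory.
#' @param trim a [trim_settings()] object.
#' @param align an [align_params()] object.
#' @param quant a [quant_settings()] object.
#' @param min_quality,min_fraction quality-filter settings.
#' @param species species prefix for novel names.
#' @return a validated `run_config` list.
#' @export
run_config <- function(libraries, mature_fa, hairpin_fa, mifam = NULL,
                       gtf = NULL, genome_fa = NULL, genome_sam = NULL,
                       out_dir = tempfile("mirvar_run_"),
                       trim = trim_settings(),
                       align = align_params(),
                       quant = quant_settings(),
                       min_quality = 20, min_fraction = 0.95,
                       species = "syn") {
  if (is.null(names(libraries)) || any(!nzchar(names(libraries)))) {
    stop("libraries must be a named vector (library name -> FASTQ path)")
  }
  for (p in c(libraries, mature_fa, hairpin_fa, mifam, gtf, genome_fa,
              genome_sam)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("configuration error: missing input file ", p)
    }
  }
  structure(list(libraries = libraries, mature_fa = mature_fa,
                 hairpin_fa = hairpin_fa, mifam = mifam, gtf = gtf,
                 genome_fa = genome_fa, genome_sam = genome_sam,
                 out_dir = out_dir, trim = trim, align = align,
                 quant = quant, min_quality = min_quality,
                 min_fraction = min_fraction, species = species),
            class = "run_config")
}

#' Run the full known-miRNA pipeline
#'
#' Stages, in order, per library: quality filter, adapter trim, collapse,
#' hairpin mapping, quantification (with family aggregation and isomiR
#' tables), then optionally read cataloguing (SAM + GTF given) and novel
#' precursor prediction (genome given).  Per-stage read tallies are
#' logged to `run.log`; count tables are written as CSV.  Arm-switch
#' detection runs as a separate call ([detect_arm_switches()]) once
#' results for several treatments exist.
#'
#' @param config a [run_config()] object.
#' @return invisibly, a list with the per-library stage results and the
#'   assembled count tables.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(config$out_dir, "run.log")
  logcon <- file(logf, open = "wt")
  on.exit(close(logcon), add = TRUE)
  note <- function(...) {
    msg <- sprintf(...)
    writeLines(msg, logcon)
    message(msg)
  }

  matures <- read_fasta(config$mature_fa)
  hairpins <- read_fasta(config$hairpin_fa)
  loci <- locate_matures(matures, hairpins)
  mifam <- if (!is.null(config$mifam)) parse_mifam(config$mifam) else {
    data.frame(family_ac = character(0), family_id = character(0),
               mi_ac = character(0), precursor = character(0),
               stringsAsFactors = FALSE)
  }

  mature_counts <- list()
  family_tabs <- list()
  per_lib <- list()
  collapsed_all <- list()
  for (lib in names(config$libraries)) {
    note("[%s] reading %s", lib, config$libraries[[lib]])
    raw <- read_fastq(config$libraries[[lib]])
    qf <- quality_filter(raw, config$min_quality, config$min_fraction)
    note("[%s] quality filter: %d/%d kept (%.2f%%)", lib, nrow(qf$reads),
         nrow(raw), if (nrow(raw)) 100 * nrow(qf$reads) / nrow(raw) else 0)
    tr <- trim_library(qf$reads, config$trim)
    note("[%s] adapter trim: %d with adapter, %d kept", lib,
         tr$stats$n_with_adapter, tr$stats$n_kept)
    collapsed <- collapse_reads(tr$reads$sequence)
    note("[%s] collapsed: %d distinct reads / %d clean reads", lib,
         nrow(collapsed), sum(collapsed$count))
    mapped <- map_all(collapsed, hairpins, config$align)
    note("[%s] mapped: %d reads (%d unique, %d non-unique), %d unmapped",
         lib, mapped$stats$mapped, mapped$stats$unique,
         mapped$stats$non_unique, mapped$stats$unmapped)
    assigned <- assign_counts(mapped$mappings, loci, config$quant)
    note("[%s] quantified: %d reads counted (%d failed position, %d failed seed)",
         lib, assigned$stats$n_counted, assigned$stats$n_fail_position,
         assigned$stats$n_fail_seed)
    rounded <- round_counts(assigned)
    mature_counts[[lib]] <- rounded
    family_tabs[[lib]] <- family_counts(rounded, mifam, loci)
    iso <- isomir_records(assigned, hairpins, config$trim$adapter)
    tab <- tabulate_isomirs(iso)
    utils::write.csv(iso, file.path(config$out_dir,
                                    sprintf("isomir_%s.csv", lib)),
                     row.names = FALSE)
    utils::write.csv(tab$categories,
                     file.path(config$out_dir,
                               sprintf("isomir_summary_%s.csv", lib)),
                     row.names = FALSE)
    per_lib[[lib]] <- list(filter = qf, trim = tr$stats,
                           map = mapped$stats, assign = assigned$stats,
                           isomir = tab)
    collapsed_all[[lib]] <- collapsed
  }
  counts_tab <- build_count_table(mature_counts)
  write_counts_csv(counts_tab, file.path(config$out_dir,
                                         "mature_counts.csv"))
  fam_tab <- build_count_table(family_tabs)
  write_counts_csv(fam_tab, file.path(config$out_dir,
                                      "family_counts.csv"))

  catalog <- NULL
  if (!is.null(config$genome_sam) && !is.null(config$gtf)) {
    catalog <- catalog_reads(config$genome_sam, config$gtf)
    utils::write.csv(catalog, file.path(config$out_dir, "catalog.csv"),
                     row.names = FALSE)
    note("read catalogue written (%d categories)", nrow(catalog))
  }

  novel <- NULL
  if (!is.null(config$genome_fa)) {
    genome <- read_fasta(config$genome_fa)
    per_lib_novel <- lapply(collapsed_all, function(coll) {
      predict_novel_library(coll, genome, matures)
    })
    novel <- unify_novel(per_lib_novel, collapsed_all, matures,
                         species = config$species,
                         settings = config$quant)
    if (nrow(novel$counts)) {
      write_counts_csv(novel$counts,
                       file.path(config$out_dir, "novel_counts.csv"))
      write_fasta(setNames(novel$precursors$sequence,
                           novel$precursors$name),
                  file.path(config$out_dir, "novel_precursor.fa"),
                  desc = sprintf("%s:%d-%d(%s)", novel$precursors$chrom,
                                 novel$precursors$start,
                                 novel$precursors$end,
                                 novel$precursors$strand),
                  rna = TRUE)
      write_fasta(setNames(novel$matures$sequence, novel$matures$name),
                  file.path(config$out_dir, "novel_mature.fa"),
                  desc = ifelse(is.na(novel$matures$seed_match), "",
                                novel$matures$seed_match),
                  rna = TRUE)
      note("novel prediction: %d precursors, %d matures",
           nrow(novel$precursors), nrow(novel$matures))
    }
  }

  invisible(list(libraries = per_lib, mature_counts = counts_tab,
                 family_counts = fam_tab, loci = loci,
                 catalog = catalog, novel = novel))
}
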