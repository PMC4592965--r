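#' Classify one counted mapping as an isomiR variant
#'
#' Variation dimensions: internal mismatches, indels, end shifts relative
#' to the canonical mature, and non-templated tails (soft-clipped
#' terminal bases, which by construction of the optimal alignment either
#' disagree with the adjacent hairpin bases or run past the hairpin end).
#' A read varying in no dimension is canonical; exactly one active
#' dimension with a single expression gives that category (`mismatch`,
#' `insertion`, `deletion`, `super5`/`sub5`/`super3`/`sub3`, `nta3`,
#' `nta5`); anything else is a `mixture`.
#'
#' @param mapping one counted mapping row (with `sequence`, `ops`,
#'   alignment fields, `shift5`, `shift3`, `mature_id`).
#' @param hairpin hairpin sequence the mapping is on.
#' @param adapter adapter sequence used for the remnant test, or `NULL`.
#' @return list: `mature_id`, `shift5`, `shift3`, `n_mismatch`, `n_ins`,
#'   `n_del`, `mismatches` (data.frame hairpin_base/read_base/read_pos),
#'   `nta3`, `nta5`, `nta_class` (`polyA`/`polyU`/`other`/`none`),
#'   `adapter_remnant`, `a_to_g_only`, `category`.
#' @export
classify_read <- function(mapping, hairpin, adapter = NULL) {
  seqr <- mapping$sequence
  L <- nchar(seqr)
  nta3 <- if (mapping$clip3 > 0) substr(seqr, L - mapping$clip3 + 1, L)
    else ""
  nta5 <- if (mapping$clip5 > 0) substr(seqr, 1, mapping$clip5) else ""

  # mismatch detail: walk the per-column operation string
  ops <- strsplit(mapping$ops, "")[[1]]
  read_pos <- 0L
  hp_pos <- mapping$start  # 0-based; next hairpin base to consume
  mm <- list()
  for (op in ops) {
    if (op == "S" || op == "I") {
      read_pos <- read_pos + 1L
    } else if (op == "=") {
      read_pos <- read_pos + 1L
      hp_pos <- hp_pos + 1L
    } else if (op == "X") {
      read_pos <- read_pos + 1L
      hp_pos <- hp_pos + 1L
      mm[[length(mm) + 1]] <- data.frame(
        hairpin_base = substr(hairpin, hp_pos, hp_pos),
        read_base = substr(seqr, read_pos, read_pos),
        read_pos = read_pos, stringsAsFactors = FALSE)
    } else if (op == "D") {
      hp_pos <- hp_pos + 1L
    }
  }
  mismatches <- if (length(mm)) do.call(rbind, mm) else {
    data.frame(hairpin_base = character(0), read_base = character(0),
               read_pos = integer(0), stringsAsFactors = FALSE)
  }

  nta_class <- "none"
  if (nzchar(nta3)) {
    ch <- strsplit(nta3, "")[[1]]
    nta_class <- if (all(ch == "A")) "polyA" else
      if (all(ch == "T")) "polyU" else "other"
  }
  adapter_remnant <- FALSE
  if (nzchar(nta3) && nchar(nta3) >= 5 && !is.null(adapter)) {
    lens <- nchar(nta3) + (-1:1)
    lens <- lens[lens >= 1 & lens <= nchar(adapter)]
    if (length(lens)) {
      d <- min(adist(nta3, substring(adapter, 1, lens)))
      adapter_remnant <- d <= 1
    }
  }
  a_to_g_only <- mapping$n_mismatch >= 1 && mapping$n_ins == 0 &&
    mapping$n_del == 0 && nrow(mismatches) > 0 &&
    all(mismatches$hairpin_base == "A" & mismatches$read_base == "G")

  dim_mism <- mapping$n_mismatch > 0
  dim_indel <- mapping$n_ins > 0 || mapping$n_del > 0
  dim_shift <- mapping$shift5 != 0 || mapping$shift3 != 0
  dim_tail <- nzchar(nta3) || nzchar(nta5)
  active <- sum(dim_mism, dim_indel, dim_shift, dim_tail)
  category <- if (active == 0) {
    "canonical"
  } else if (active > 1) {
    "mixture"
  } else if (dim_mism) {
    "mismatch"
  } else if (dim_indel) {
    if (mapping$n_ins > 0 && mapping$n_del > 0) "mixture" else
      if (mapping$n_ins > 0) "insertion" else "deletion"
  } else if (dim_shift) {
    if (mapping$shift5 != 0 && mapping$shift3 != 0) "mixture" else
      if (mapping$shift5 < 0) "super5" else if (mapping$shift5 > 0) "sub5"
      else if (mapping$shift3 > 0) "super3" else "sub3"
  } else {
    if (nzchar(nta3) && nzchar(nta5)) "mixture" else
      if (nzchar(nta3)) "nta3" else "nta5"
  }

  list(mature_id = mapping$mature_id, shift5 = mapping$shift5,
       shift3 = mapping$shift3, n_mismatch = mapping$n_mismatch,
       n_ins = mapping$n_ins, n_del = mapping$n_del,
       mismatches = mismatches, nta3 = nta3, nta5 = nta5,
       nta_class = nta_class, adapter_remnant = adapter_remnant,
       a_to_g_only = a_to_g_only, category = category)
}

#' Build per-read isomiR records for a counted library
#'
#' @param assigned result of [assign_counts()].
#' @param hairpins named character vector of hairpin sequences.
#' @param adapter adapter sequence for the remnant test, or `NULL`.
#' @return data.frame with one row per counted best-priority mapping:
#'   identifiers, variation fields and the count `weight` (the read-count
#'   share carried by the mapping).
#' @export
isomir_records <- function(assigned, hairpins, adapter = NULL) {
  reads <- assigned$reads
  rows <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    cl <- classify_read(reads[i, ], hairpins[[reads$hairpin_id[i]]],
                        adapter)
    rows[[i]] <- data.frame(
      uid = reads$uid[i], mature_id = cl$mature_id,
      weight = reads$share[i], shift5 = cl$shift5, shift3 = cl$shift3,
      n_mismatch = cl$n_mismatch, n_ins = cl$n_ins, n_del = cl$n_del,
      nta3 = cl$nta3, nta5 = cl$nta5, nta_class = cl$nta_class,
      adapter_remnant = cl$adapter_remnant, a_to_g_only = cl$a_to_g_only,
      category = cl$category, stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(uid = character(0), mature_id = character(0),
               weight = numeric(0), shift5 = integer(0),
               shift3 = integer(0), n_mismatch = integer(0),
               n_ins = integer(0), n_del = integer(0),
               nta3 = character(0), nta5 = character(0),
               nta_class = character(0), adapter_remnant = logical(0),
               a_to_g_only = logical(0), category = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Category levels of the isomiR taxonomy
#' @export
isomir_categories <- function() {
  c("canonical", "mismatch", "insertion", "deletion", "super5", "sub5",
    "super3", "sub3", "nta3", "nta5", "mixture")
}

#' Tabulate isomiR categories for one library
#'
#' Fractions are computed over the counted mature-read total, weighted by
#' collapsed-read counts.  The non-templated-addition sub-table
#' classifies 3' tails into poly(A), poly(U) and other patterns among
#' tail-bearing reads, excluding adapter remnants.  The editing fraction
#' is the weight of pure hairpin-A/read-G mismatch reads among
#' mismatch-only reads (mismatches but no indel).
#'
#' @param records data.frame from [isomir_records()].
#' @return list with `categories` (data.frame `category`, `count`,
#'   `fraction`), `nta` (data.frame `class`, `count`, `fraction`),
#'   `a_to_g_fraction`, `total`.
#' @export
tabulate_isomirs <- function(records) {
  total <- sum(records$weight)
  cats <- isomir_categories()
  cnt <- vapply(cats, function(k) {
    sum(records$weight[records$category == k])
  }, numeric(1))
  categories <- data.frame(category = cats, count = unname(cnt),
                           fraction = if (total > 0) unname(cnt) / total
                           else rep(0, length(cats)),
                           stringsAsFactors = FALSE)

  tails <- records[nzchar(records$nta3) & !records$adapter_remnant, ,
                   drop = FALSE]
  tail_total <- sum(tails$weight)
  classes <- c("polyA", "polyU", "other")
  tcnt <- vapply(classes, function(k) {
    sum(tails$weight[tails$nta_class == k])
  }, numeric(1))
  nta <- data.frame(class = classes, count = unname(tcnt),
                    fraction = if (tail_total > 0) unname(tcnt) / tail_total
                    else rep(0, 3),
                    stringsAsFactors = FALSE)

  mm_only <- records$n_mismatch >= 1 & records$n_ins == 0 &
    records$n_del == 0
  mm_total <- sum(records$weight[mm_only])
  a2g <- sum(records$weight[mm_only & records$a_to_g_only])
  list(categories = categories, nta = nta,
       a_to_g_fraction = if (mm_total > 0) a2g / mm_total else NA_real_,
       total = total)
}
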