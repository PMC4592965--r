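#' Dominant arm of a 5p/3p mature pair in one library
#'
#' The 5p form is dominant iff its count exceeds `fold` times the 3p
#' count AND the count difference exceeds `diff` (mirrored for 3p);
#' otherwise no form is dominant.  With a zero denominator the fold
#' criterion is satisfied iff the numerator is positive.
#'
#' @param c5,c3 read counts of the 5p and 3p forms.
#' @param fold fold-change threshold (strict, default 2).
#' @param diff count-difference threshold (strict, default 10).
#' @return `"5p"`, `"3p"` or `"none"`.
#' @export
dominant_form <- function(c5, c3, fold = 2, diff = 10) {
  if (c5 > fold * c3 && c5 - c3 > diff) return("5p")
  if (c3 > fold * c5 && c3 - c5 > diff) return("3p")
  "none"
}

#' Hairpins carrying both a 5p and a 3p mature
#'
#' Hairpins with only one annotated arm are skipped.
#'
#' @param loci data.frame from [locate_matures()].
#' @return data.frame with `hairpin_id`, `mature5p`, `mature3p`.
#' @export
arm_pairs <- function(loci) {
  rows <- list()
  for (h in unique(loci$hairpin_id)) {
    sub <- loci[loci$hairpin_id == h, , drop = FALSE]
    m5 <- sub$mature_id[sub$arm == "5p"]
    m3 <- sub$mature_id[sub$arm == "3p"]
    if (length(m5) >= 1 && length(m3) >= 1) {
      rows[[length(rows) + 1]] <- data.frame(
        hairpin_id = h, mature5p = m5[1], mature3p = m3[1],
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(hairpin_id = character(0), mature5p = character(0),
                      mature3p = character(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Detect arm switching between treatments
#'
#' A hairpin's treatment-level dominant form is defined only when every
#' replicate library of that treatment yields the same non-none dominant
#' form.  A switch is called when at least two treatments have defined
#' forms that differ.
#'
#' @param counts data.frame with `id` plus one column per library
#'   (rounded mature counts, as written by [write_counts_csv()]).
#' @param loci data.frame from [locate_matures()].
#' @param design data.frame with columns `library`, `treatment`; every
#'   library must be a column of `counts`.
#' @param fold,diff dominance thresholds (see [dominant_form()]).
#' @return list with `calls` (data.frame `hairpin_id`, `mature5p`,
#'   `mature3p`, `forms` — `treatment=form` pairs, defined treatments
#'   only) and `detail` (per-library counts and dominance).
#' @export
detect_arm_switches <- function(counts, loci, design, fold = 2,
                                diff = 10) {
  missing_lib <- setdiff(design$library, names(counts))
  if (length(missing_lib)) {
    stop("design names libraries absent from the count table: ",
         paste(missing_lib, collapse = ", "))
  }
  if (length(unique(design$treatment)) < 2) {
    stop("arm-switch detection needs at least two treatments")
  }
  pairs <- arm_pairs(loci)
  getc <- function(id, lib) {
    v <- counts[[lib]][match(id, counts$id)]
    if (is.na(v)) 0 else v
  }
  calls <- list()
  detail <- list()
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    forms <- character(0)
    for (tr in sort(unique(design$treatment))) {
      libs <- design$library[design$treatment == tr]
      dom <- vapply(libs, function(lib) {
        c5 <- getc(p$mature5p, lib)
        c3 <- getc(p$mature3p, lib)
        detail[[length(detail) + 1]] <<- data.frame(
          hairpin_id = p$hairpin_id, library = lib, treatment = tr,
          c5 = c5, c3 = c3, dominant = dominant_form(c5, c3, fold, diff),
          stringsAsFactors = FALSE)
        dominant_form(c5, c3, fold, diff)
      }, character(1))
      if (all(dom == dom[1]) && dom[1] != "none") forms[tr] <- dom[1]
    }
    if (length(forms) >= 2 && length(unique(forms)) > 1) {
      calls[[length(calls) + 1]] <- data.frame(
        hairpin_id = p$hairpin_id, mature5p = p$mature5p,
        mature3p = p$mature3p,
        forms = paste(sprintf("%s=%s", names(forms), forms),
                      collapse = ";"),
        stringsAsFactors = FALSE)
    }
  }
  list(calls = if (length(calls)) do.call(rbind, calls) else {
    data.frame(hairpin_id = character(0), mature5p = character(0),
               mature3p = character(0), forms = character(0),
               stringsAsFactors = FALSE)
  },
  detail = if (length(detail)) do.call(rbind, detail) else {
    data.frame(hairpin_id = character(0), library = character(0),
               treatment = character(0), c5 = numeric(0), c3 = numeric(0),
               dominant = character(0), stringsAsFactors = FALSE)
  })
}
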