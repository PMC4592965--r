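# Shared synthetic references and small utilities for the test suite.

fix_ref <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_hairpins(3, seed = 42)
    cache
  }
})

fix_loci <- function(ref = fix_ref()) {
  locate_matures(ref$matures, ref$hairpins)
}

# substitute position p of a string with a different base (never A->G)
sub_base <- function(s, p) {
  b <- substr(s, p, p)
  r <- if (b == "C") "G" else "C"
  paste0(substr(s, 1, p - 1), r, substring(s, p + 1))
}

# run the preprocessing + mapping + quantification chain on a generated
# library and return the pieces
quantify_library <- function(ref, lib, settings = quant_settings(),
                             params = align_params()) {
  qf <- quality_filter(lib$reads)
  tr <- trim_library(qf$reads,
                     trim_settings(adapter = lib$manifest$adapter))
  coll <- collapse_reads(tr$reads$sequence)
  mapped <- map_all(coll, ref$hairpins, params)
  loci <- locate_matures(ref$matures, ref$hairpins)
  assigned <- assign_counts(mapped$mappings, loci, settings)
  list(filtered = qf, trimmed = tr, collapsed = coll, mapped = mapped,
       loci = loci, assigned = assigned)
}

# expected per-category counted weights from a library manifest, on the
# reporting categories (edit reads are mismatch-category reads; the three
# planted tail classes report as nta3)
manifest_category_expect <- function(plan) {
  pl <- tapply(plan$count, plan$category, sum)
  get <- function(k) if (k %in% names(pl)) pl[[k]] else 0
  c(canonical = get("canonical"),
    mismatch = get("mismatch") + get("edit"),
    insertion = get("insertion"), deletion = get("deletion"),
    super5 = get("super5"), sub5 = get("sub5"),
    super3 = get("super3"), sub3 = get("sub3"),
    nta3 = get("nta_polyA") + get("nta_polyU") + get("nta_other"),
    nta5 = get("nta5"), mixture = get("mixture"))
}
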