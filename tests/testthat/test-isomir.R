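test_that("single-dimension variants classify into their category", {
  ref <- fix_ref()
  loci <- fix_loci()
  l5 <- loci[loci$mature_id == "syn-miR-1-5p", ]
  hp <- ref$hairpins[["syn-mir-1"]]
  mat <- ref$matures[["syn-miR-1-5p"]]

  classify_one <- function(seqr, settings = quant_settings(seed_check = FALSE)) {
    res <- map_all(collapse_reads(seqr), ref$hairpins)
    a <- assign_counts(res$mappings, loci, settings)
    recs <- isomir_records(a, ref$hairpins, default_adapter())
    expect_equal(nrow(recs), 1)
    recs
  }

  expect_equal(classify_one(mat)$category, "canonical")
  sup3 <- paste0(mat, substr(hp, l5$end + 1, l5$end + 2))
  r <- classify_one(sup3)
  expect_equal(r$category, "super3")
  expect_equal(r$shift3, 2L)
  polyA <- classify_one(paste0(mat, "AAA"))
  expect_equal(polyA$category, "nta3")
  expect_equal(polyA$nta_class, "polyA")
  polyU <- classify_one(paste0(mat, "TTT"))
  expect_equal(polyU$nta_class, "polyU")
  other <- classify_one(paste0(mat, "GC"))
  expect_equal(other$nta_class, "other")

  edit <- classify_one(mirvar:::make_variant_read("edit", mat, hp,
                                                  l5$start, l5$end))
  expect_equal(edit$category, "mismatch")
  expect_true(edit$a_to_g_only)
  mm <- classify_one(mirvar:::make_variant_read("mismatch", mat, hp,
                                                l5$start, l5$end))
  expect_false(mm$a_to_g_only)

  mix <- classify_one(paste0(mat, substr(hp, l5$end + 1, l5$end + 1), "TG"))
  expect_equal(mix$category, "mixture")
})

test_that("long adapter-remnant tails are flagged and excluded from the NTA table", {
  ref <- fix_ref()
  loci <- fix_loci()
  mat <- ref$matures[["syn-miR-1-5p"]]
  remnant <- substr(default_adapter(), 1, 6)  # >= 5 nt of adapter
  res <- map_all(collapse_reads(paste0(mat, remnant)), ref$hairpins)
  a <- assign_counts(res$mappings, loci)
  recs <- isomir_records(a, ref$hairpins, default_adapter())
  expect_true(recs$adapter_remnant[1])
  tab <- tabulate_isomirs(recs)
  expect_equal(sum(tab$nta$count), 0)
  # without the adapter the same tail is an ordinary 'other' NTA
  recs2 <- isomir_records(a, ref$hairpins, NULL)
  expect_false(recs2$adapter_remnant[1])
})

test_that("planted composition is recovered exactly from a library", {
  ref <- fix_ref()
  lib <- make_library(ref, n_reads = 2000, seed = 23)
  run <- quantify_library(ref, lib)
  recs <- isomir_records(run$assigned, ref$hairpins, lib$manifest$adapter)
  tab <- tabulate_isomirs(recs)
  got <- setNames(tab$categories$count, tab$categories$category)
  exp <- manifest_category_expect(lib$manifest$plan)
  expect_equal(got[names(exp)], exp)
  expect_equal(tab$total, sum(exp))
  expect_equal(sum(tab$categories$fraction), 1)

  # NTA sub-table: planted tails plus the mixture reads' tails
  pl <- tapply(lib$manifest$plan$count, lib$manifest$plan$category, sum)
  expect_equal(unname(got["nta3"] + 0),
               unname(pl[["nta_polyA"]] + pl[["nta_polyU"]] +
                        pl[["nta_other"]]))
  nta <- setNames(tab$nta$count, tab$nta$class)
  expect_equal(unname(nta["polyA"]), unname(pl[["nta_polyA"]]))
  expect_equal(unname(nta["polyU"]),
               unname(pl[["nta_polyU"]] + pl[["mixture"]]))
  expect_equal(unname(nta["other"]), unname(pl[["nta_other"]]))

  # editing fraction among mismatch-only reads
  expect_equal(tab$a_to_g_fraction,
               pl[["edit"]] / (pl[["edit"]] + pl[["mismatch"]]))
})

test_that("with the seed check on, no 5' variants or 5' tails are reported", {
  ref <- fix_ref()
  prof <- variant_profile(canonical = 0.55, super3 = 0.1, sub3 = 0.05,
                          super5 = 0.08, sub5 = 0.08, mismatch = 0.03,
                          edit = 0.01, insertion = 0.01, deletion = 0.01,
                          nta_polyA = 0.02, nta_polyU = 0.02,
                          nta_other = 0.01, nta5 = 0.03, mixture = 0)
  lib <- make_library(ref, profile = prof, n_reads = 1200, seed = 29)
  pl <- tapply(lib$manifest$plan$count, lib$manifest$plan$category, sum)

  run_on <- quantify_library(ref, lib, quant_settings(seed_check = TRUE))
  tab_on <- tabulate_isomirs(isomir_records(run_on$assigned, ref$hairpins,
                                            lib$manifest$adapter))
  on <- setNames(tab_on$categories$count, tab_on$categories$category)
  expect_equal(unname(on["super5"]), 0)
  expect_equal(unname(on["sub5"]), 0)
  expect_equal(unname(on["nta5"]), 0)
  expect_equal(tab_on$total,
               sum(pl) - pl[["super5"]] - pl[["sub5"]] - pl[["nta5"]])

  # the same planted variants are visible with the check off
  run_off <- quantify_library(ref, lib, quant_settings(seed_check = FALSE))
  tab_off <- tabulate_isomirs(isomir_records(run_off$assigned,
                                             ref$hairpins,
                                             lib$manifest$adapter))
  off <- setNames(tab_off$categories$count, tab_off$categories$category)
  expect_equal(unname(off["super5"]), unname(pl[["super5"]]))
  expect_equal(unname(off["sub5"]), unname(pl[["sub5"]]))
  expect_equal(unname(off["nta5"]), unname(pl[["nta5"]]))
})

test_that("categories partition the counted reads", {
  ref <- fix_ref()
  lib <- make_library(ref, n_reads = 700, seed = 31)
  run <- quantify_library(ref, lib)
  recs <- isomir_records(run$assigned, ref$hairpins, lib$manifest$adapter)
  expect_true(all(recs$category %in% isomir_categories()))
  tab <- tabulate_isomirs(recs)
  expect_equal(sum(tab$categories$count), run$assigned$stats$n_counted)
  # NTA classes partition tail-bearing reads
  tails <- recs[nzchar(recs$nta3) & !recs$adapter_remnant, ]
  expect_equal(sum(tab$nta$count), sum(tails$weight))
})
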