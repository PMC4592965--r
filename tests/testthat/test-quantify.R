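test_that("position check enforces the 3-nt end-shift bound inclusively", {
  loci <- data.frame(mature_id = "m1", hairpin_id = "h1", start = 10L,
                     end = 32L, arm = "5p", stringsAsFactors = FALSE)
  aln <- list(hairpin_id = "h1", start = 10L, end = 32L)
  pc <- position_check(aln, loci, 3)
  expect_equal(pc$shift5, 0L)
  expect_equal(pc$shift3, 0L)
  expect_equal(position_check(list(hairpin_id = "h1", start = 7L,
                                   end = 32L), loci, 3)$shift5, -3L)
  expect_null(position_check(list(hairpin_id = "h1", start = 6L,
                                  end = 32L), loci, 3))
  expect_null(position_check(list(hairpin_id = "h2", start = 10L,
                                  end = 32L), loci, 3))
})

test_that("position check prefers the smaller total shift, ties to 5p", {
  loci <- data.frame(mature_id = c("m5", "m3"),
                     hairpin_id = "h1", start = c(10L, 13L),
                     end = c(32L, 35L), arm = c("5p", "3p"),
                     stringsAsFactors = FALSE)
  hit <- position_check(list(hairpin_id = "h1", start = 12L, end = 34L),
                        loci, 3)
  expect_equal(hit$mature_id, "m3")  # shifts (2,2) beat (-? ) for m5: (2,2)=4 vs m5 (2,2)=4 tie -> 5p
})

test_that("seed check requires exact error-free placement of read positions 2-8", {
  mk <- function(ops, clip5 = 0L, start = 10L) {
    list(ops = ops, clip5 = clip5, start = start)
  }
  ok22 <- strrep("=", 22)
  expect_true(seed_check(mk(ok22), 10L))
  expect_false(seed_check(mk(ok22, start = 9L), 10L))       # shifted start
  expect_false(seed_check(mk(paste0("S", strrep("=", 21)), clip5 = 1L),
                          10L))                              # 5' clip
  x5 <- paste0(strrep("=", 4), "X", strrep("=", 17))
  expect_false(seed_check(mk(x5), 10L))                      # error at pos 5
  x12 <- paste0(strrep("=", 11), "X", strrep("=", 10))
  expect_true(seed_check(mk(x12), 10L))                      # outside window
  d5 <- paste0(strrep("=", 5), "D", strrep("=", 17))
  expect_false(seed_check(mk(d5), 10L))                      # deletion in window
  d12 <- paste0(strrep("=", 12), "D", strrep("=", 10))
  expect_true(seed_check(mk(d12), 10L))
})

test_that("tie in position check goes to the 5p arm", {
  loci <- data.frame(mature_id = c("a3", "a5"), hairpin_id = "h1",
                     start = c(12L, 8L), end = c(34L, 30L),
                     arm = c("3p", "5p"), stringsAsFactors = FALSE)
  hit <- position_check(list(hairpin_id = "h1", start = 10L, end = 32L),
                        loci, 3)
  expect_equal(hit$mature_id, "a5")  # totals tie at 4
})

test_that("multi-mapping counts divide evenly over best-priority mappings", {
  ref <- fix_ref()
  loci <- fix_loci()
  hp1 <- ref$hairpins[["syn-mir-1"]]
  m5 <- ref$matures[["syn-miR-1-5p"]]

  # duplicated hairpin: counts split exactly in half
  dup_h <- c(`syn-mir-1` = hp1, `syn-mir-9` = hp1)
  dup_l <- rbind(loci[loci$hairpin_id == "syn-mir-1", ],
                 within(loci[loci$hairpin_id == "syn-mir-1", ], {
                   hairpin_id <- "syn-mir-9"
                   mature_id <- sub("miR-1", "miR-9", mature_id)
                 }))
  coll <- collapse_reads(rep(m5, 10))
  res <- map_all(coll, dup_h)
  q <- assign_counts(res$mappings, dup_l)
  expect_equal(unname(q$fractional[c("syn-miR-1-5p", "syn-miR-9-5p")]),
               c(5, 5))
  expect_equal(sum(q$fractional), 10)

  # count 9 over three clip-free mappings: exact thirds until rounding
  tri_h <- c(a = hp1, b = hp1, c = hp1)
  tri_l <- do.call(rbind, lapply(c("a", "b", "c"), function(h) {
    within(loci[loci$hairpin_id == "syn-mir-1", ], {
      mature_id <- paste0(mature_id, "-", h)
      hairpin_id <- h
    })
  }))
  q3 <- assign_counts(map_all(collapse_reads(rep(m5, 9)),
                              tri_h)$mappings, tri_l)
  expect_equal(q3$denom %% 3, 0)
  expect_equal(sum(q3$fractional), 9)
  expect_equal(unname(round_counts(q3)[q3$fractional > 0]), c(3, 3, 3))
})

test_that("the clip-free mapping takes the whole count over clipped ties", {
  ref <- fix_ref()
  loci <- fix_loci()
  hp1 <- ref$hairpins[["syn-mir-1"]]
  m5 <- ref$matures[["syn-miR-1-5p"]]
  # second hairpin equals the first with the mature's last 2 bases changed:
  # the read maps there at equal penalty only by clipping 2 bases
  l1 <- loci[loci$mature_id == "syn-miR-1-5p", ]
  hp2 <- hp1
  substr(hp2, l1$end - 1, l1$end) <- chartr("ACGT", "CATG",
                                            substr(hp2, l1$end - 1, l1$end))
  hps <- c(`syn-mir-1` = hp1, `syn-mir-9` = hp2)
  loci2 <- rbind(loci[loci$hairpin_id == "syn-mir-1", ],
                 within(l1, {
                   hairpin_id <- "syn-mir-9"
                   mature_id <- "syn-miR-9-5p"
                 }))
  res <- map_all(collapse_reads(rep(m5, 10)), hps)
  expect_equal(sort(unique(res$mappings$clip3)), c(0L, 2L))
  q <- assign_counts(res$mappings, loci2)
  expect_equal(unname(q$fractional["syn-miR-1-5p"]), 10)
  expect_equal(unname(q$fractional["syn-miR-9-5p"]), 0)
})

test_that("rounding is half away from zero on exact rationals", {
  expect_equal(unname(round_counts(c(2.5, 10 / 3, 0, 1.49))),
               c(3, 3, 0, 1))
  fake <- list(numer = c(a = 5, b = 20, c = 0), denom = 2)
  expect_equal(round_counts(fake), c(a = 3, b = 10, c = 0))
})

test_that("enabling the seed check never increases any mature's count", {
  ref <- fix_ref()
  prof <- variant_profile(canonical = 0.5, super3 = 0.1, sub3 = 0.05,
                          super5 = 0.05, sub5 = 0.05, mismatch = 0.05,
                          edit = 0.02, insertion = 0.02, deletion = 0.02,
                          nta_polyA = 0.05, nta_polyU = 0.04,
                          nta_other = 0.03, nta5 = 0.02, mixture = 0)
  lib <- make_library(ref, profile = prof, n_reads = 600, seed = 17)
  run_on <- quantify_library(ref, lib, quant_settings(seed_check = TRUE))
  run_off <- quantify_library(ref, lib, quant_settings(seed_check = FALSE))
  on <- run_on$assigned$fractional
  off <- run_off$assigned$fractional
  expect_true(all(on <= off + 1e-9))
})

test_that("fractional counts conserve the number of counted reads", {
  ref <- fix_ref()
  lib <- make_library(ref, n_reads = 800, seed = 19)
  run <- quantify_library(ref, lib)
  a <- run$assigned
  expect_equal(sum(a$fractional), a$stats$n_counted)
  expect_true(all(abs(round_counts(a) - a$fractional) < 1))
})

test_that("family counts aggregate by family with orphan singletons", {
  ref <- fix_ref()
  loci <- fix_loci()
  p <- withr::local_tempfile()
  writeLines(make_mifam_text(ref), p)
  fam <- parse_mifam(p)
  counts <- c(`syn-miR-1-5p` = 7, `syn-miR-1-3p` = 2, `syn-miR-2-5p` = 5,
              `syn-miR-2-3p` = 0, `syn-miR-3-5p` = 4, `syn-miR-3-3p` = 1)
  fc <- family_counts(counts, fam, loci)
  expect_equal(unname(fc["syn-fam-1"]), 14)  # hairpins 1 and 2
  expect_equal(unname(fc["syn-miR-3-5p"]), 4)
  expect_equal(unname(fc["syn-miR-3-3p"]), 1)
  expect_equal(sum(fc), sum(counts))
})
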