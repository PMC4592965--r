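test_that("stack building filters by length, locus count, and merges overlaps", {
  maps <- data.frame(
    chrom = "chr1",
    start = c(100L, 103L, 300L, 400L, 500L),
    end = c(122L, 125L, 326L, 422L, 522L),
    strand = "+",
    uid = c("1-5", "2-3", "3-9", "4-2", "5-8"),
    count = c(5L, 3L, 9L, 2L, 8L),
    sequence = "x",
    n_loci = c(1L, 1L, 1L, 6L, 1L),
    stringsAsFactors = FALSE)
  st <- build_stacks(maps)
  # 26-nt read excluded, 6-locus read excluded, two overlaps merged
  expect_equal(nrow(st), 2)
  merged <- st[st$start == 100, ]
  expect_equal(merged$count, 8)
  expect_equal(merged$end, 125L)
  expect_equal(merged$n_reads, 2L)
})

test_that("excision takes mirrored flank windows clipped at chromosome bounds", {
  genome <- c(chr1 = strrep("ACGT", 100))
  stack <- data.frame(chrom = "chr1", strand = "+", start = 100L,
                      end = 122L, stringsAsFactors = FALSE)
  cands <- excise_candidates(genome, stack)
  expect_equal(sort(cands$start), c(30L, 90L))
  expect_equal(sort(cands$end), c(132L, 192L))
  near0 <- excise_candidates(genome, within(stack, {
    start <- 5L
    end <- 27L
  }))
  expect_true(all(near0$start >= 0))
  minus <- excise_candidates(genome, within(stack, strand <- "-"))
  fwd <- substr(genome[["chr1"]], 91, 192)
  expect_true(mirvar:::revcomp(fwd) %in% minus$sequence)
})

test_that("signatures keep only perfect 18-25 nt matches plus known matures", {
  cand <- paste0(strrep("C", 10), "ACGTTGCAACGTTGCAACGTTG", strrep("A", 10))
  coll <- data.frame(
    uid = c("1-4", "2-2", "3-1"),
    sequence = c("ACGTTGCAACGTTGCAACGTTG",   # perfect 22-mer
                 "ACGTTGCAACGTTGCAA",        # 17 nt: too short
                 "ACGTTGCAACGTTGCAACGTTT"),  # 1 mismatch: excluded
    count = c(4L, 2L, 1L), stringsAsFactors = FALSE)
  known <- c(`syn-miR-x` = "ACGTTGCAACGTTGCAACGTTG")
  sig <- build_signature(coll, known, cand)
  expect_equal(sum(!sig$is_known), 1)
  expect_equal(sig$id[!sig$is_known], "1-4")
  expect_equal(sig$start[!sig$is_known], 10L)
  expect_true(any(sig$is_known))
})

test_that("mature selection needs a strict 2-fold margin over the runner-up", {
  sig <- function(counts, starts) {
    data.frame(id = paste0(seq_along(counts), "-x"),
               sequence = strrep("A", 22), start = starts,
               end = starts + 22L, count = counts, is_known = FALSE,
               stringsAsFactors = FALSE)
  }
  expect_equal(select_mature(sig(c(30, 10), c(0, 30)))$count, 30)
  expect_null(select_mature(sig(c(20, 10), c(0, 30))))   # 20 !> 20
  expect_equal(select_mature(sig(7, 0))$count, 7)        # no runner-up
  expect_null(select_mature(sig(c(5, 5), c(0, 30))))     # exact tie
})

test_that("scoring backend filters on score and structure arm sanity", {
  cands <- data.frame(sequence = c("ACGT", "ACGT", "ACGT"),
                      mature_start = 0L, mature_end = 2L,
                      stringsAsFactors = FALSE)
  backend <- local({
    i <- 0
    function(s) {
      i <<- i + 1
      list(structure = NULL, score = c(-1, 3, 1)[i])
    }
  })
  out <- score_candidates(cands, backend)
  expect_equal(nrow(out), 2)  # score -1 dropped
  expect_true(all(out$status == "scored"))

  unscored <- score_candidates(cands, NULL)
  expect_equal(nrow(unscored), 3)
  expect_true(all(unscored$status == "unscored"))

  # a mature pairing with itself fails the structural filter
  hair <- data.frame(sequence = strrep("A", 8),
                     mature_start = 0L, mature_end = 8L,
                     stringsAsFactors = FALSE)
  self_pair <- function(s) list(structure = "((.)).(.", score = NULL)
  expect_equal(nrow(score_candidates(hair,
                                     function(s) {
                                       list(structure = "(((..)))",
                                            score = NULL)
                                     })), 0)
  one_arm <- function(s) list(structure = "........", score = NULL)
  expect_equal(nrow(score_candidates(hair, one_arm)), 1)
})

test_that("a planted novel hairpin is recovered as exactly one candidate", {
  ref <- fix_ref()
  gen <- make_genome(ref, seed = 42)
  tn <- gen$truth$novel
  coll <- data.frame(uid = c("1-30", "2-5"),
                     sequence = c(tn$mature5p, tn$mature3p),
                     count = c(30L, 5L), stringsAsFactors = FALSE)
  nv <- predict_novel_library(coll, gen$genome, ref$matures)
  expect_equal(nrow(nv), 1)
  expect_equal(nv$mature_seq, tn$mature5p)
  expect_true(nv$start < tn$end && tn$start < nv$end)  # overlaps the plant
  expect_equal(nv$status, "unscored")
})

test_that("novel names unify across libraries and counts are quantified", {
  ref <- fix_ref()
  gen <- make_genome(ref, seed = 42)
  tn <- gen$truth$novel
  coll1 <- data.frame(uid = c("1-30", "2-5"),
                      sequence = c(tn$mature5p, tn$mature3p),
                      count = c(30L, 5L), stringsAsFactors = FALSE)
  coll2 <- coll1
  coll2$count <- c(12L, 2L)
  nv1 <- predict_novel_library(coll1, gen$genome, ref$matures)
  nv2 <- predict_novel_library(coll2, gen$genome, ref$matures)
  un <- unify_novel(list(libA = nv1, libB = nv2),
                    list(libA = coll1, libB = coll2), ref$matures,
                    species = "syn")
  expect_equal(nrow(un$precursors), 1)  # same coordinates = same precursor
  expect_equal(un$precursors$name, "syn-novel-mir-1")
  expect_equal(un$matures$name, "syn-novel-miR-1")
  expect_equal(un$counts$libA, 30)
  expect_equal(un$counts$libB, 12)
  # library input order does not change the naming
  un2 <- unify_novel(list(libB = nv2, libA = nv1),
                     list(libB = coll2, libA = coll1), ref$matures,
                     species = "syn")
  expect_equal(un2$precursors$name, un$precursors$name)
})

test_that("a novel mature seed identical to a known mature is described", {
  ref <- fix_ref()
  gen <- make_genome(ref, seed = 42)
  tn <- gen$truth$novel
  coll <- data.frame(uid = "1-30", sequence = tn$mature5p, count = 30L,
                     stringsAsFactors = FALSE)
  nv <- predict_novel_library(coll, gen$genome, ref$matures)
  known <- c(ref$matures,
             `syn-miR-77-5p` = paste0("G", substr(tn$mature5p, 2, 8),
                                      strrep("A", 14)))
  un <- unify_novel(list(lib = nv), list(lib = coll), known)
  expect_equal(un$matures$seed_match, "syn-miR-77-5p")
})
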