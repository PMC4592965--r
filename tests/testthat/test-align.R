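test_that("exact substring reads align with penalty 0 and no clips", {
  set.seed(21)
  hp <- paste(sample(c("A", "C", "G", "T"), 70, TRUE), collapse = "")
  read <- substr(hp, 11, 32)
  a <- align_read(read, hp)
  expect_equal(nrow(a), 1)
  expect_equal(a$penalty, 0L)
  expect_equal(a$start, 10L)
  expect_equal(a$end, 32L)
  expect_equal(a$clip5 + a$clip3, 0L)
})

test_that("the penalty cap admits exactly two mismatches and a three-base gap", {
  set.seed(22)
  hp <- paste(sample(c("A", "C", "G", "T"), 70, TRUE), collapse = "")
  read <- substr(hp, 21, 42)
  # substitutions in the clip-protected centre of the read
  two <- sub_base(sub_base(read, 10), 13)
  a2 <- align_read(two, hp)
  expect_equal(a2$penalty[1], 60L)
  expect_equal(a2$n_mismatch[1], 2L)
  three <- sub_base(two, 11)
  expect_equal(nrow(align_read(three, hp)), 0)

  # one contiguous deletion: 40 + 6L
  del3 <- paste0(substr(read, 1, 9), substring(read, 13))
  a3 <- align_read(del3, hp)
  expect_equal(a3$penalty[1], 58L)  # 40 + 18
  expect_equal(a3$n_del[1], 3L)
  del4 <- paste0(substr(read, 1, 9), substring(read, 14))
  expect_equal(nrow(align_read(del4, hp)), 0)  # 64 > 60
})

test_that("clipping beats terminal mismatches and is otherwise avoided", {
  set.seed(23)
  hp <- paste(sample(c("A", "C", "G", "T"), 70, TRUE), collapse = "")
  read <- substr(hp, 11, 32)
  tail4 <- chartr("ACGT", "CATG", substr(hp, 33, 36))  # mismatches template
  a <- align_read(paste0(read, tail4), hp)
  expect_equal(a$penalty[1], 0L)
  expect_equal(a$clip3[1], 4L)
  # no reported alignment could convert a terminal mismatch into a clip
  reads <- c(read, paste0(read, tail4), sub_base(read, 11))
  for (r in reads) {
    al <- align_read(r, hp)
    for (i in seq_len(nrow(al))) {
      ops <- strsplit(al$ops[i], "")[[1]]
      core <- ops[ops != "S"]
      expect_false(core[1] == "X" || core[length(core)] == "X")
    }
  }
})

test_that("reads shorter than the core minimum are unalignable", {
  hp <- strrep("ACGT", 20)
  expect_equal(nrow(align_read("ACGTACGTACGTAC", hp)), 0)  # 14 nt
})

test_that("DP minimum penalty equals exhaustive enumeration on random pairs", {
  set.seed(101)
  bases <- c("A", "C", "G", "T")
  rnd <- function(k) paste(sample(bases, k, TRUE), collapse = "")
  mutate <- function(s, k) {
    for (z in seq_len(k)) {
      op <- sample(c("sub", "ins", "del"), 1)
      p <- sample(nchar(s), 1)
      if (op == "sub") {
        substr(s, p, p) <- sample(setdiff(bases, substr(s, p, p)), 1)
      } else if (op == "ins") {
        s <- paste0(substr(s, 1, p), sample(bases, 1), substring(s, p + 1))
      } else if (nchar(s) > 15) {
        s <- paste0(substr(s, 1, p - 1), substring(s, p + 1))
      }
    }
    s
  }
  for (it in 1:500) {
    m <- sample(30:60, 1)
    hp <- rnd(m)
    if (it %% 2 == 0) {
      read <- rnd(sample(15:25, 1))
    } else {
      L <- sample(15:min(25, m - 2), 1)
      o <- sample(m - L, 1)
      read <- mutate(substr(hp, o, o + L - 1), sample(0:3, 1))
      if (nchar(read) < 15) read <- rnd(18)
    }
    if (it %% 37 == 0) substr(read, 3, 3) <- "N"
    a <- align_read(read, hp)
    dp <- if (nrow(a)) a$penalty[1] else NA_integer_
    expect_identical(as.integer(dp), oracle_min_penalty(read, hp),
                     label = sprintf("pair %d (read %s / hairpin %s)",
                                     it, read, hp))
  }
})

test_that("alignment is symmetric under joint reversal of read and hairpin", {
  rev_str <- function(s) {
    paste(rev(strsplit(s, "")[[1]]), collapse = "")
  }
  set.seed(55)
  bases <- c("A", "C", "G", "T")
  for (it in 1:25) {
    hp <- paste(sample(bases, 50, TRUE), collapse = "")
    read <- substr(hp, 6, 27)
    if (it %% 2 == 0) read <- sub_base(read, sample(8:15, 1))
    a <- align_read(read, hp)
    b <- align_read(rev_str(read), rev_str(hp))
    expect_equal(nrow(a), nrow(b))
    if (nrow(a)) {
      expect_equal(sort(a$penalty), sort(b$penalty))
      expect_setequal(nchar(hp) - a$end, b$start)
      expect_setequal(a$clip5, b$clip3)
    }
  }
})

test_that("N bases always count as mismatches and are tallied", {
  hp <- strrep("ACGTT", 14)
  read <- substr(hp, 11, 32)
  rn <- read
  substr(rn, 11, 11) <- "N"
  a <- align_read(rn, hp)
  expect_equal(a$penalty[1], 30L)
  expect_equal(a$n_mismatch[1], 1L)
  expect_equal(a$n_n[1], 1L)
})

test_that("all best mappings across hairpins are kept, better penalties win", {
  ref <- fix_ref()
  hp1 <- ref$hairpins[[1]]
  m5 <- ref$matures[["syn-miR-1-5p"]]
  # duplicated hairpin: a perfect read maps to both
  hps <- c(a = hp1, b = hp1)
  coll <- collapse_reads(rep(m5, 4))
  res <- map_all(coll, hps)
  expect_equal(nrow(res$mappings), 2)
  expect_setequal(res$mappings$hairpin_id, c("a", "b"))
  expect_equal(res$stats$non_unique, 4)

  # a 1-mismatch hit on a second hairpin loses to the perfect one
  hp2 <- sub_base(hp1, 15)
  res2 <- map_all(coll, c(a = hp1, b = hp2))
  expect_equal(res2$mappings$hairpin_id, "a")

  # unmappable read
  res3 <- map_all(collapse_reads(strrep("AG", 11)), ref$hairpins)
  expect_equal(nrow(res3$mappings), 0)
  expect_equal(res3$unmapped$count, 1L)
})

test_that("matures locate on their paired hairpins with arm labels", {
  ref <- fix_ref()
  loci <- locate_matures(ref$matures, ref$hairpins)
  expect_equal(nrow(loci), 6)
  r1 <- loci[loci$mature_id == "syn-miR-1-5p", ]
  expect_equal(r1$hairpin_id, "syn-mir-1")
  expect_equal(substr(ref$hairpins[[r1$hairpin_id]], r1$start + 1, r1$end),
               ref$matures[["syn-miR-1-5p"]])
  expect_equal(loci$arm[loci$mature_id == "syn-miR-1-3p"], "3p")

  # mature not present in its hairpin is excluded with a warning
  bad <- c(ref$matures, `syn-miR-1-5x` = strrep("ACGT", 5))
  expect_warning(l2 <- locate_matures(bad, ref$hairpins), "no paired")
  expect_equal(nrow(l2), 6)
})

test_that("planted truth loci match located loci", {
  ref <- fix_ref()
  loci <- locate_matures(ref$matures, ref$hairpins)
  key <- function(d) d[order(d$mature_id), c("mature_id", "start", "end",
                                             "arm")]
  expect_equal(key(loci), key(ref$loci), ignore_attr = TRUE)
})
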