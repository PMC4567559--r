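# Quality filtering rules: 3' trimming, mean/length discards, pair logic.

test_that("3' trimming drops exactly the maximal low-quality suffix", {
  t1 <- trimReads3p("ACGTT", phred(c(30, 30, 30, 20, 20)))
  expect_equal(t1$len, 3L)
  expect_equal(t1$seq, "ACG")
  expect_equal(nchar(t1$qual), 3L)

  # an internal low base is not a 3' suffix
  t2 <- trimReads3p("ACG", phred(c(30, 20, 30)))
  expect_equal(t2$len, 3L)
  expect_equal(t2$seq, "ACG")

  # everything below threshold trims to an empty read
  t3 <- trimReads3p("ACGT", phred(c(26, 26, 26, 26)))
  expect_equal(t3$len, 0L)
  expect_equal(t3$seq, "")
})

test_that("mean-quality and length rules use strict '<' (ties kept)", {
  mk <- function(quals) {
    n <- length(quals)
    PairedReads("p1", strrep("A", n), phred(quals),
                strrep("A", 100), q_string(100))
  }
  # mean exactly 26.9 < 27: dropped (low bases internal, so nothing trims)
  q269 <- c(rep(27L, 45), rep(26L, 10), rep(27L, 45))
  expect_equal(mean(q269), 26.9)
  out <- filterPairs(mk(q269))
  expect_equal(length(out$pairs), 0L)
  expect_equal(unname(out$report["reads_dropped_by_mean"]), 1L)

  # mean exactly 27 and length exactly 80: kept
  q27 <- rep(27L, 80)
  out2 <- filterPairs(mk(q27))
  expect_equal(length(out2$pairs), 1L)

  # length 79 after trimming: dropped by length, mate discarded as unpaired
  q79 <- c(rep(35L, 79), rep(20L, 21))
  out3 <- filterPairs(mk(q79))
  expect_equal(length(out3$pairs), 0L)
  expect_equal(unname(out3$report["reads_dropped_by_length"]), 1L)
  expect_equal(unname(out3$report["reads_dropped_unpaired"]), 1L)
})

test_that("a pair survives only when both mates pass", {
  pairs <- PairedReads(
    c("a", "b", "c"),
    c(strrep("A", 100), strrep("C", 100), strrep("G", 50)),
    c(q_string(100, 35), q_string(100, 35), q_string(50, 35)),
    c(strrep("T", 100), strrep("T", 60), strrep("T", 100)),
    c(q_string(100, 35), q_string(60, 35), q_string(100, 35)))
  out <- filterPairs(pairs)
  expect_equal(pairIds(out$pairs), "a")
  expect_equal(unname(out$report["pairs_out"]), 1L)
  expect_equal(unname(out$report["reads_dropped_by_length"]), 2L)
  expect_equal(unname(out$report["reads_dropped_unpaired"]), 2L)
})

test_that("filtering is idempotent and survivors satisfy the rules", {
  sc <- small_scenario(seed = 12, targetDepth = 4)
  gs <- makeGenomeSet(sc)
  lib <- simulateLibrary(gs, sc)
  out1 <- filterPairs(lib)
  expect_lte(length(out1$pairs), length(lib))
  lens <- nchar(c(out1$pairs@seq1, out1$pairs@seq2))
  expect_true(all(lens >= 80))
  meanq <- function(q) vapply(q, function(x)
    mean(utf8ToInt(x) - 33), numeric(1))
  expect_true(all(meanq(out1$pairs@qual1) >= 27))
  expect_true(all(meanq(out1$pairs@qual2) >= 27))

  out2 <- filterPairs(out1$pairs)
  expect_equal(length(out2$pairs), length(out1$pairs))
  expect_identical(out2$pairs@seq1, out1$pairs@seq1)
  expect_equal(unname(out2$report["reads_trimmed"]), 0L)
})
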