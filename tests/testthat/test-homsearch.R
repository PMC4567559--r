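# Translated / nucleotide homology search.

test_that("six-frame translation handles frames, stops and boundaries", {
  fr <- sixFrameTranslate("ATGGCC")
  expect_equal(as.character(fr[["+1"]]), "MA")
  expect_equal(as.character(fr[["-1"]]), "GH") # revcomp GGCCAT -> GGC CAT
  expect_equal(as.character(fr[["+2"]]), "W")

  # length-4 input: frame +2 one residue, frame +3 empty
  fr4 <- sixFrameTranslate("ATGA")
  expect_equal(nchar(as.character(fr4[["+1"]])), 1L)
  expect_equal(nchar(as.character(fr4[["+2"]])), 1L)
  expect_equal(as.character(fr4[["+3"]]), "")

  # stop codons appear as '*'
  expect_equal(as.character(sixFrameTranslate("ATGTAA")[["+1"]]), "M*")
})

test_that("a self-hit spans the full sequence at identity 1", {
  s <- rand_dna(3000, seed = 11)
  h <- searchHits(setNames(s, "q"), setNames(s, "s"),
                  SearchParams("nucleotide"))
  expect_equal(nrow(h), 1L)
  expect_equal(h$identity, 1)
  expect_equal(h$q_start, 0)
  expect_equal(h$q_end, 3000)
  expect_equal(h$s_start, 0)
  expect_equal(h$s_end, 3000)
  expect_lt(h$evalue, 1e-200)
})

test_that("reported scores equal the optimal local DP score of the span", {
  # windowed re-scoring must agree with an independent full Smith-Waterman
  # on the reported span subsequences (nucleotide mode, planted homology)
  mat <- Biostrings::nucleotideSubstitutionMatrix(2, -3, baseOnly = TRUE)
  for (seed in 1:6) {
    core <- rand_dna(300, seed = 100 + seed)
    q <- paste0(rand_dna(200, seed = 200 + seed), core,
                rand_dna(150, seed = 300 + seed))
    s <- paste0(rand_dna(100, seed = 400 + seed),
                endosift:::mutate_dna(core, 0.05),
                rand_dna(250, seed = 500 + seed))
    h <- searchHits(setNames(q, "q"), setNames(s, "s"),
                    SearchParams("nucleotide", keepBestOnly = FALSE))
    expect_gte(nrow(h), 1)
    for (i in seq_len(nrow(h))) {
      qs <- substr(q, h$q_start[i] + 1, h$q_end[i])
      ss <- substr(s, h$s_start[i] + 1, h$s_end[i])
      if (h$q_frame[i] < 0) qs <- rc(qs)
      sw <- Biostrings::pairwiseAlignment(qs, ss, type = "local",
                                          substitutionMatrix = mat,
                                          gapOpening = 5, gapExtension = 2)
      expect_equal(h$raw_score[i], Biostrings::score(sw))
    }
  }
})

test_that("unrelated random sequences yield no hits at the selection threshold", {
  for (seed in 1:5) {
    q <- rand_dna(1000, seed = 600 + seed)
    s <- rand_dna(20000, seed = 700 + seed)
    h <- searchHits(setNames(q, "q"), setNames(s, "s"),
                    SearchParams("nucleotide", evalueMax = 1e-12))
    expect_equal(nrow(h), 0L)
  }
})

test_that("an ORF finds its diverged homologue in translated mode", {
  sc <- small_scenario(seed = 1, refDivergences = 0.25)
  gs <- makeGenomeSet(sc)
  ref <- setNames(as.character(gs@refs[["0.25"]]), "ref")
  long <- which(gs@genes$end - gs@genes$start >= 300)
  for (i in long[1:5]) {
    g <- gs@genes[i, ]
    orf <- substr(as.character(gs@target), g$start + 1, g$end)
    h <- searchHits(setNames(orf, "orf"), ref, SearchParams("translated"))
    expect_gte(nrow(h), 1)
    expect_lt(h$evalue[1], 1e-12)
  }
})

test_that("detection is symmetric and E-value thresholds are monotone", {
  core <- rand_dna(400, seed = 31)
  a <- paste0(rand_dna(300, seed = 32), core)
  b <- paste0(core, rand_dna(500, seed = 33))
  p <- SearchParams("nucleotide")
  hab <- searchHits(setNames(a, "a"), setNames(b, "b"), p)
  hba <- searchHits(setNames(b, "b"), setNames(a, "a"), p)
  expect_equal(nrow(hab), 1L)
  expect_equal(nrow(hba), 1L)
  expect_equal(hab$raw_score, hba$raw_score)
  expect_equal(hab$q_start, hba$s_start)
  expect_equal(hab$s_start, hba$q_start)

  # lowering evalueMax never adds hits
  loose <- searchHits(setNames(a, "a"), setNames(b, "b"),
                      SearchParams("nucleotide", evalueMax = 1e-3,
                                   keepBestOnly = FALSE))
  strict <- searchHits(setNames(a, "a"), setNames(b, "b"),
                       SearchParams("nucleotide", evalueMax = 1e-30,
                                    keepBestOnly = FALSE))
  expect_lte(nrow(strict), nrow(loose))
  expect_true(all(strict$evalue < 1e-30))
})

test_that("best-hit reduction applies the documented tie-breaks", {
  hits <- data.frame(
    query_id = c("q1", "q1", "q2", "q2"),
    subject_id = c("s_b", "s_a", "s_b", "s_a"),
    mode = "nucleotide",
    bit_score = c(60, 50, 40, 40),
    evalue = c(1e-20, 1e-15, 1e-10, 1e-10),
    stringsAsFactors = FALSE)
  best <- bestHitTable(hits)
  expect_equal(best$subject_id[best$query_id == "q1"], "s_b") # higher bits
  expect_equal(best$subject_id[best$query_id == "q2"], "s_a") # lexicographic
  expect_equal(nrow(bestHitTable(hits[0, ])), 0L)
})
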