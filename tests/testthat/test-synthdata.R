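# Synthetic genome set and library generator.

test_that("genome set is deterministic, AT-rich and gene-dense", {
  sc <- small_scenario(seed = 4)
  gs1 <- makeGenomeSet(sc)
  gs2 <- makeGenomeSet(sc)
  expect_identical(as.character(gs1@target), as.character(gs2@target))
  expect_identical(as.character(gs1@refs), as.character(gs2@refs))
  expect_identical(as.character(gs1@host), as.character(gs2@host))

  gc <- endosift:::gc_frac(as.character(gs1@target))
  expect_lt(abs(gc - sc@targetGC), 0.02)

  coding <- sum(gs1@genes$end - gs1@genes$start) / sc@targetLen
  expect_gte(coding, 0.80)
  expect_gte(nrow(gs1@genes), 5)
})

test_that("gene table ORFs translate without internal stops", {
  gs <- makeGenomeSet(small_scenario(seed = 5))
  tg <- as.character(gs@target)
  for (i in seq_len(nrow(gs@genes))) {
    g <- gs@genes[i, ]
    dna <- substr(tg, g$start + 1, g$end)
    if (g$strand == "-") dna <- rc(dna)
    pep <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(dna, 1, nchar(dna) - 3)),
      no.init.codon = TRUE))
    expect_identical(pep, g$peptide)
    expect_false(grepl("*", pep, fixed = TRUE))
  }
})

test_that("zero-divergence reference re-encodes identical peptides in new codons", {
  sc <- small_scenario(seed = 6, refDivergences = 0)
  gs <- makeGenomeSet(sc)
  ref0 <- as.character(gs@refs[["0.00"]])
  expect_false(identical(ref0, as.character(gs@target)))
  for (i in seq_len(nrow(gs@genes))) {
    g <- gs@genes[i, ]
    dna <- substr(ref0, g$start + 1, g$end)
    if (g$strand == "-") dna <- rc(dna)
    pep <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(dna, 1, nchar(dna) - 3)),
      no.init.codon = TRUE))
    expect_identical(pep, g$peptide)
  }
})

test_that("divergence-0.25 reference has mean ORF amino-acid identity near 0.75", {
  # oracle: global alignment of each peptide pair, averaged over ORFs
  sc <- small_scenario(seed = 1, refDivergences = 0.25)
  gs <- makeGenomeSet(sc)
  ref <- as.character(gs@refs[["0.25"]])
  ids <- vapply(seq_len(nrow(gs@genes)), function(i) {
    g <- gs@genes[i, ]
    dna <- substr(ref, g$start + 1, g$end)
    if (g$strand == "-") dna <- rc(dna)
    pep2 <- as.character(Biostrings::translate(
      Biostrings::DNAString(substr(dna, 1, nchar(dna) - 3)),
      no.init.codon = TRUE))
    al <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(g$peptide), Biostrings::AAString(pep2),
      type = "global", substitutionMatrix = "BLOSUM62",
      gapOpening = 10, gapExtension = 0.5)
    Biostrings::pid(al) / 100
  }, numeric(1))
  expect_gte(mean(ids), 0.72)
  expect_lte(mean(ids), 0.78)
})

test_that("decoy genomes share no >=60-nt window at >=95% identity with the target", {
  gs <- makeGenomeSet(small_scenario(seed = 7))
  rrn <- substr(as.character(gs@target), gs@rrnRegion[1] + 1, gs@rrnRegion[2])
  expect_lt(endosift:::max_window_identity(as.character(gs@hostRrna), rrn), 0.95)
  core <- substr(as.character(gs@contaminant), 1, nchar(rrn))
  expect_lt(endosift:::max_window_identity(core, substr(rrn, 1, nchar(core))),
            0.95)
})

test_that("library counts follow the closed form and purity is realized", {
  sc <- small_scenario(seed = 2)
  # closed form at the published BPAA purity on the full-size target
  sc50 <- SimScenario(seed = 2, purity = 0.285, targetDepth = 20)
  expect_equal(round(20 * 50000 / 200), 5000)
  expect_equal(round(5000 / 0.285), 17544)

  gs <- makeGenomeSet(sc)
  lib <- simulateLibrary(gs, sc)
  n_target <- round(sc@targetDepth * sc@targetLen / (2 * sc@readLen))
  expect_equal(length(lib), round(n_target / sc@purity))
  realized <- mean(pairTruth(lib) == "target")
  expect_lt(abs(realized - sc@purity), 0.005)
  depth <- 2 * sc@readLen * sum(pairTruth(lib) == "target") / sc@targetLen
  expect_lt(abs(depth / sc@targetDepth - 1), 0.05)
})

test_that("degenerate mixtures and error-free reads behave exactly", {
  sc <- small_scenario(seed = 3, purity = 1, targetDepth = 3,
                       perBaseError = 0, qcFailFrac = 0)
  gs <- makeGenomeSet(sc)
  lib <- simulateLibrary(gs, sc)
  expect_true(all(pairTruth(lib) == "target"))
  # every read is an exact substring of the (circular) target
  big <- paste0(as.character(gs@target), as.character(gs@target))
  idx <- sample(length(lib), 50)
  for (i in idx) {
    expect_true(grepl(lib@seq1[i], big, fixed = TRUE))
    expect_true(grepl(rc(lib@seq2[i]), big, fixed = TRUE))
  }
})

test_that("same seed gives byte-identical FASTQ output", {
  sc <- small_scenario(seed = 8, targetLen = 12000L, hostLen = 20000L,
                       targetDepth = 5)
  gs <- makeGenomeSet(sc)
  d1 <- tempfile(); d2 <- tempfile()
  writeLibrary(simulateLibrary(gs, sc), paste0(d1, "_1.fq"), paste0(d1, "_2.fq"))
  writeLibrary(simulateLibrary(gs, sc), paste0(d2, "_1.fq"), paste0(d2, "_2.fq"))
  expect_identical(readLines(paste0(d1, "_1.fq")), readLines(paste0(d2, "_1.fq")))
  expect_identical(readLines(paste0(d1, "_2.fq")), readLines(paste0(d2, "_2.fq")))
})

test_that("invalid scenarios are rejected", {
  expect_error(SimScenario(purity = 0), "purity")
  expect_error(SimScenario(refDivergences = c(0.1, 1)), "divergence")
  expect_error(SimScenario(insertMean = 50, readLen = 100L), "insertMean")
  expect_error(makeGenomeSet(SimScenario(targetLen = 2000L)), "ORF")
})
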