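# Contig selection and decoy filtering.

make_tcsf_fixture <- function(seed = 14) {
  gs <- makeGenomeSet(small_scenario(seed = seed, refDivergences = 0.17))
  tg <- as.character(gs@target)
  # pick a gene-rich slice of the target, a mito slice covering the shared
  # degenerate gene, and a random contig
  g <- gs@genes[which.max(gs@genes$end - gs@genes$start), ]
  mito <- as.character(gs@mito)
  contigs <- c(
    target_slice = substr(tg, g$start + 1, g$end),
    mito_slice = substr(mito, nchar(mito) %/% 2 - 800,
                        nchar(mito) %/% 2 + 800),
    random = rand_dna(800, seed = 1000 + seed))
  list(gs = gs, contigs = contigs)
}

test_that("selection keeps reference homologs and partitions the input", {
  fx <- make_tcsf_fixture()
  sel <- selectContigs(fx$contigs, fx$gs@refs[[1]], mito = fx$gs@mito,
                       rrna = fx$gs@hostRrna)
  sets <- selectionSets(sel)
  expect_setequal(unlist(sets), names(fx$contigs))
  expect_true("target_slice" %in% sel@kept)
  expect_true("random" %in% sel@removedNoHit)
  # the mito slice carries the shared degenerate gene: it hits the
  # reference weakly but its self-hit against the mitochondrion dominates
  expect_true("mito_slice" %in% sel@removedMito)
})

test_that("a verbatim reference slice is kept in nucleotide mode", {
  fx <- make_tcsf_fixture(seed = 15)
  ref <- as.character(fx$gs@refs[[1]])
  ctg <- c(ref_slice = substr(ref, 5001, 7000))
  sel <- selectContigs(ctg, ref, mito = fx$gs@mito, rrna = fx$gs@hostRrna,
                       mode = "nucleotide")
  expect_equal(sel@kept, "ref_slice")
})

test_that("host rRNA contigs are evicted by the rRNA decoy", {
  # a near-identical reference keeps the conserved rRNA family detectable,
  # so the host rRNA contig retrieves a reference hit - and a far better
  # decoy hit
  gs <- makeGenomeSet(small_scenario(seed = 16, refDivergences = 0.02))
  rrna_contig <- c(rrna_like = as.character(gs@hostRrna))
  sel <- selectContigs(rrna_contig, gs@refs[[1]], mito = gs@mito,
                       rrna = gs@hostRrna, mode = "nucleotide")
  expect_true("rrna_like" %in% sel@removedRrna)
})

test_that("missing decoys skip filtering with a warning", {
  fx <- make_tcsf_fixture(seed = 17)
  expect_warning(
    expect_warning(
      sel <- selectContigs(fx$contigs["target_slice"], fx$gs@refs[[1]]),
      "mito"),
    "rRNA")
  expect_true("target_slice" %in% sel@kept)
  expect_error(selectContigs(fx$contigs, Biostrings::DNAStringSet()),
               "empty reference")
})

test_that("translated mode is more sensitive than nucleotide at high divergence", {
  sc <- small_scenario(seed = 18, refDivergences = 0.26)
  gs <- makeGenomeSet(sc)
  tg <- as.character(gs@target)
  # gene-bearing slices of the target as pseudo-contigs
  slices <- lapply(seq_len(6), function(i)
    substr(tg, (i - 1) * 3000 + 1, i * 3000))
  names(slices) <- sprintf("slice%02d", 1:6)
  contigs <- unlist(slices)
  cmp <- compareSelectionModes(
    contigs, list(d26 = as.character(gs@refs[["0.26"]])),
    assignments = data.frame(contig = names(contigs), label = "target",
                             stringsAsFactors = FALSE),
    mito = gs@mito, rrna = gs@hostRrna)
  tab <- cmp$table
  fn_tr <- tab$fn_nt[tab$mode == "translated"]
  fn_nt <- tab$fn_nt[tab$mode == "nucleotide"]
  expect_lte(fn_tr, fn_nt)
  expect_gt(tab$tp_nt[tab$mode == "translated"], 0)
})
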