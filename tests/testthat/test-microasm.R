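# Greedy OLC assembly and read mapping.

test_that("error-free tiling pairs reconstruct the source exactly", {
  src <- rand_dna(2000, seed = 21)
  pr <- tiling_pairs(src, 300) # 30x
  asm <- assembleReads(pr, AsmParams(minContigLen = 100L))
  expect_equal(nContigs(asm), 1L)
  s <- as.character(contigs(asm)[[1]])
  expect_true(s == src || rc(s) == src)
})

test_that("degenerate inputs behave per contract", {
  # single read in, minContigLen = 100, read 100 nt: one contig = the read
  r <- setNames(rand_dna(100, seed = 22), "r1")
  asm <- assembleReads(r, AsmParams(minContigLen = 100L, usePairs = FALSE))
  expect_equal(nContigs(asm), 1L)
  s <- as.character(contigs(asm)[[1]])
  expect_true(s == unname(r) || rc(s) == unname(r))

  # empty input: empty assembly
  empty <- assembleReads(character(0), AsmParams())
  expect_equal(nContigs(empty), 0L)
  expect_equal(totalLength(empty), 0)
})

test_that("an exact 300-nt repeat splits the assembly without pair evidence", {
  base <- rand_dna(4300, seed = 23)
  repseq <- substr(base, 4001, 4300)
  src <- paste0(substr(base, 1, 1500), repseq,
                substr(base, 1501, 3000), repseq, substr(base, 3001, 4000))
  pr <- tiling_pairs(src, 900, seed = 3)
  asm <- assembleReads(pr, AsmParams(minContigLen = 100L, usePairs = FALSE))
  expect_gte(nContigs(asm), 2L)
})

test_that("qualifying overlaps match the exhaustive all-pairs oracle", {
  # brute force: every suffix/prefix placement of every oriented read pair
  brute_overlaps <- function(reads, min_id, min_ovl) {
    n <- length(reads)
    out <- list()
    orient <- function(s, st) if (st > 0) s else rc(s)
    for (a in seq_len(n)) for (sa in c(1, -1)) {
      A <- orient(reads[a], sa)
      for (b in seq_len(n)) for (sb in c(1, -1)) {
        if (a == b) next
        B <- orient(reads[b], sb)
        La <- nchar(A); Lb <- nchar(B)
        for (p in 1:(La - min_ovl)) {
          ov <- La - p
          if (Lb <= ov) next
          av <- substr(A, p + 1, La); bv <- substr(B, 1, ov)
          mm <- sum(strsplit(av, "")[[1]] != strsplit(bv, "")[[1]])
          if (mm <= floor((1 - min_id) * ov))
            out[[length(out) + 1]] <- data.frame(a = a, a_strand = sa, b = b,
                                                 b_strand = sb, offset = p,
                                                 overlap = ov, mismatches = mm)
        }
      }
    }
    do.call(rbind, out)
  }
  src <- rand_dna(900, seed = 24)
  reads <- endosift:::with_seed(4, {
    start <- sample.int(800, 40, replace = TRUE)
    r <- substring(src, start, start + 99)
    st <- sample(c(1, -1), 40, replace = TRUE)
    ifelse(st > 0, r, vapply(r, rc, character(1)))
  })
  got <- endosift:::cpp_enumerate_overlaps(reads, 0.9, 40L, 21L)
  want <- brute_overlaps(reads, 0.9, 40L)
  key <- function(d) sort(paste(d$a, d$a_strand, d$b, d$b_strand, d$offset,
                                d$overlap, d$mismatches))
  expect_identical(key(got), key(want))
})

test_that("overlap stringency is monotone", {
  src <- rand_dna(1200, seed = 25)
  pr <- tiling_pairs(src, 120, seed = 5)
  reads <- endosift:::.flatten_pairs(pr)
  n_base <- nrow(endosift:::cpp_enumerate_overlaps(unname(reads), 0.90, 40L, 21L))
  n_len <- nrow(endosift:::cpp_enumerate_overlaps(unname(reads), 0.90, 60L, 21L))
  n_id <- nrow(endosift:::cpp_enumerate_overlaps(unname(reads), 0.99, 40L, 21L))
  expect_lte(n_len, n_base)
  expect_lte(n_id, n_base)
})

test_that("every output contig is supported by its recorded members", {
  src <- rand_dna(3000, seed = 26)
  pr <- tiling_pairs(src, 450, seed = 6)
  asm <- assembleReads(pr, AsmParams(minContigLen = 100L))
  m <- contigMembers(asm)
  reads <- endosift:::.flatten_pairs(pr)
  mp <- mapReads(reads, asm, AsmParams())
  mp <- mp[match(m$read_id, mp$read_id), ]
  expect_true(all(mp$class %in% c("Full", "Partial")))
  expect_true(all(mp$contig == m$contig))
  expect_true(all(abs(mp$start - m$offset) <= 0))
})

test_that("mapping classifies Full, Partial and Unmapped per contract", {
  ctg <- setNames(rand_dna(1000, seed = 27), "c1")
  p <- AsmParams()
  # exact interior substring: Full
  r_full <- setNames(substr(ctg, 301, 400), "rF")
  # overlapping the contig end by 60 of 100 nt: Partial
  r_part <- setNames(paste0(substr(ctg, 941, 1000), rand_dna(40, seed = 28)),
                     "rP")
  # random read: Unmapped
  r_none <- setNames(rand_dna(100, seed = 29), "rU")
  mp <- mapReads(c(r_full, r_part, r_none), ctg, p)
  expect_equal(mp$class, c("Full", "Partial", "Unmapped"))
  expect_equal(mp$start[1], 300)
  expect_equal(mp$end[2] - mp$start[2], 60)
  # reverse-complement reads map on the minus strand
  mp2 <- mapReads(setNames(rc(unname(r_full)), "rRC"), ctg, p)
  expect_equal(mp2$class, "Full")
  expect_equal(mp2$strand, -1)
})

test_that("assembly output is deterministic under fixed input", {
  sc <- small_scenario(seed = 13, targetLen = 12000L, hostLen = 15000L,
                       targetDepth = 12)
  gs <- makeGenomeSet(sc)
  lib <- simulateLibrary(gs, sc)
  qc <- filterPairs(lib)
  a1 <- assembleReads(qc$pairs, AsmParams(minContigLen = 100L))
  a2 <- assembleReads(qc$pairs, AsmParams(minContigLen = 100L))
  expect_identical(as.character(contigs(a1)), as.character(contigs(a2)))
  expect_identical(contigMembers(a1), contigMembers(a2))
})
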