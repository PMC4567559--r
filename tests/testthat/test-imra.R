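# Iterative mapping and reassembly.

test_that("pair recruitment follows the one-mapped-mate rule", {
  ctg <- setNames(rand_dna(2000, seed = 41), "c1")
  # p1: both mates from the contig (both map Full)
  # p2: fwd overhangs the contig end (Partial), rev random (Unmapped)
  # p3: both random (excluded)
  pairs <- PairedReads(
    c("p1", "p2", "p3"),
    c(substr(ctg, 101, 200),
      paste0(substr(ctg, 1941, 2000), rand_dna(40, seed = 42)),
      rand_dna(100, seed = 43)),
    rep(q_string(100), 3),
    c(rc(substr(ctg, 301, 400)), rand_dna(100, seed = 44),
      rand_dna(100, seed = 45)),
    rep(q_string(100), 3))
  mp <- mapReads(pairs, ctg, AsmParams())
  rec <- recruitPairs(mp, pairs)
  expect_equal(pairIds(rec), c("p1", "p2"))

  # all reads map: recruit everything
  pr_all <- tiling_pairs(unname(ctg), 50, seed = 46)
  mp_all <- mapReads(pr_all, ctg, AsmParams())
  expect_equal(length(recruitPairs(mp_all, pr_all)), 50L)
})

test_that("a complete seed is a fixed point and maxIter=1 flags non-convergence", {
  src <- rand_dna(6000, seed = 47)
  pr <- tiling_pairs(src, 600, seed = 48)
  seed_ctg <- setNames(src, "ctg1")
  res <- imraIterate(seed_ctg, pr, ImraParams(minContigLen = 500L))
  st <- iterationStats(res)
  expect_true(res@converged)
  expect_equal(st$n_contigs[nrow(st)], 1L)
  expect_lte(max(st$iter), 3)
  fin <- as.character(contigs(finalAssembly(res))[[1]])
  expect_true(fin == src || rc(fin) == src)

  # an unconverged problem capped at one iteration is flagged
  part <- setNames(substr(src, 1500, 3500), "part")
  res1 <- imraIterate(part, pr,
                      ImraParams(minContigLen = 500L, maxIter = 1L))
  expect_false(res1@converged)
  expect_equal(max(iterationStats(res1)$iter), 1L)
})

test_that("IMRA elongates a partial seed to the full source", {
  src <- rand_dna(12000, seed = 49)
  pr <- tiling_pairs(src, 1500, seed = 50) # 25x
  seed_ctg <- setNames(substr(src, 2001, 8000), "seed1") # 50% of the source
  res <- imraIterate(seed_ctg, pr, ImraParams(minContigLen = 500L))
  st <- iterationStats(res)
  expect_true(all(diff(st$total_len[st$iter >= 1]) >= 0))
  fin <- finalAssembly(res)
  expect_lte(nContigs(fin), 3)
  expect_gte(genomeFraction(fin, src, circular = FALSE), 99)
})

test_that("recruitment grows with elongation on error-free data", {
  src <- rand_dna(10000, seed = 51)
  pr <- tiling_pairs(src, 1200, seed = 52)
  seed_ctg <- setNames(substr(src, 3001, 7000), "seed1")
  params <- ImraParams(minContigLen = 500L)
  mp1 <- mapReads(pr, seed_ctg, params@asm)
  rec1 <- recruitPairs(mp1, pr)
  res <- imraIterate(seed_ctg, pr, params)
  mp2 <- mapReads(pr, finalAssembly(res), params@asm)
  rec2 <- recruitPairs(mp2, pr)
  expect_true(all(pairIds(rec1) %in% pairIds(rec2)))
  expect_gt(length(rec2), length(rec1))
})

test_that("empty seeds are an error and short-insert warnings fire", {
  src <- rand_dna(2000, seed = 53)
  pr <- tiling_pairs(src, 100, seed = 54)
  expect_error(imraIterate(Biostrings::DNAStringSet(), pr),
               "no contigs")
  expect_warning(imraIterate(setNames(substr(src, 1, 1200), "c"), pr,
                             ImraParams(minContigLen = 300L)),
                 "insert")
})
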