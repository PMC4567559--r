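# Scenario-grid benchmarking.

test_that("a selection grid yields one row per mode x reference and is deterministic", {
  sc <- small_scenario(seed = 81, targetLen = 12000L, hostLen = 15000L,
                       targetDepth = 8, refDivergences = c(0.02, 0.21))
  g1 <- benchmarkGrid(list(sc))
  expect_equal(nrow(g1$selection), 4L) # 2 modes x 2 references
  expect_setequal(unique(g1$selection$mode), c("translated", "nucleotide"))
  expect_setequal(unique(g1$selection$reference), c("0.02", "0.21"))
  expect_true(all(g1$selection$tp_nt >= 0))

  g2 <- benchmarkGrid(list(sc))
  expect_identical(g1$selection, g2$selection)

  # single-mode grid: one row per reference
  g3 <- benchmarkGrid(list(sc), modes = "translated")
  expect_equal(nrow(g3$selection), 2L)
})
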