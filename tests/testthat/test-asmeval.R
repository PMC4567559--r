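# Truth-based evaluation metrics.

test_that("origin assignment applies the >99% similarity criterion", {
  gs <- makeGenomeSet(small_scenario(seed = 61))
  tg <- as.character(gs@target)
  host <- as.character(gs@host)
  contigs <- c(
    t_exact = substr(tg, 1001, 3000),
    h_exact = substr(host, 5001, 7000),
    t_mut2 = endosift:::with_seed(62, endosift:::mutate_dna(
      substr(tg, 8001, 10000), 0.02)),
    junk = rand_dna(1500, seed = 63))
  asg <- assignOrigin(contigs, gs)
  lab <- setNames(asg$label, asg$contig)
  expect_equal(unname(lab["t_exact"]), "target")
  expect_equal(unname(lab["h_exact"]), "other")
  # 2% substitutions push identity below the 99.0% threshold
  expect_false(lab[["t_mut2"]] == "target")
  expect_equal(unname(lab["junk"]), "unassigned")

  # circular rotation: a contig spanning the origin is still target
  wrap <- paste0(substr(tg, nchar(tg) - 799, nchar(tg)), substr(tg, 1, 800))
  asg2 <- assignOrigin(c(wrap = wrap), gs)
  expect_equal(asg2$label, "target")
})

test_that("confusion lengths follow the selection partition", {
  lens <- c(a = 1000, b = 700, c = 1500, d = 400)
  asg <- data.frame(contig = names(lens),
                    label = c("target", "other", "target", "target"),
                    stringsAsFactors = FALSE)
  sel <- new("SelectionOutcome", kept = c("a", "b"), removedNoHit = c("c"),
             removedMito = "d", removedRrna = character(0),
             bestHits = data.frame())
  conf <- confusionLengths(sel, asg, lens)
  expect_equal(unname(conf["tp_nt"]), 1000)
  expect_equal(unname(conf["fn_nt"]), 1900)
  expect_equal(unname(conf["fp_nt"]), 700)
  # tp + fn is selection-independent: it is the truth-target total
  sel2 <- new("SelectionOutcome", kept = c("c", "d"),
              removedNoHit = c("a", "b"), removedMito = character(0),
              removedRrna = character(0), bestHits = data.frame())
  conf2 <- confusionLengths(sel2, asg, lens)
  expect_equal(conf["tp_nt"] + conf["fn_nt"], conf2["tp_nt"] + conf2["fn_nt"],
               ignore_attr = TRUE)
  expect_error(confusionLengths(sel, asg[1:2, ], lens), "missing")
})

test_that("genome fraction and NGA50 match their definitions on constructed blocks", {
  tg <- rand_dna(50000, seed = 64)
  # disjoint tiling: [0, 30k) and [30k, 50k)
  ctgs <- c(c1 = substr(tg, 1, 30000), c2 = substr(tg, 30001, 50000))
  expect_equal(genomeFraction(ctgs, tg, circular = FALSE), 100)
  ng <- nga50(ctgs, tg, circular = FALSE)
  expect_equal(as.numeric(ng), 30000)
  expect_true(attr(ng, "defined"))

  # one whole-genome contig
  expect_equal(as.numeric(nga50(c(all = tg), tg, circular = FALSE)), 50000)

  # 40% coverage: NGA50 undefined
  ng2 <- nga50(c(c1 = substr(tg, 1, 20000)), tg, circular = FALSE)
  expect_equal(as.numeric(ng2), 0)
  expect_false(attr(ng2, "defined"))

  # monotone under adding contigs
  gf1 <- genomeFraction(ctgs[1], tg, circular = FALSE)
  expect_lte(gf1, genomeFraction(ctgs, tg, circular = FALSE))

  # empty input
  expect_equal(genomeFraction(character(0), tg, circular = FALSE), 0)
})

test_that("genome fraction and NGA50 agree with brute force on random block sets", {
  tg <- rand_dna(30000, seed = 65)
  brute <- function(starts, lens, L) {
    cov <- rep(FALSE, L)
    for (i in seq_along(starts)) cov[seq(starts[i], starts[i] + lens[i] - 1)] <- TRUE
    half <- L / 2
    cand <- sort(unique(lens), decreasing = FALSE)
    ng <- 0
    for (Lc in cand) if (sum(lens[lens >= Lc]) >= half) ng <- Lc
    list(gf = 100 * mean(cov), nga50 = ng,
         defined = 100 * mean(cov) >= 50)
  }
  for (trial in 1:20) {
    set.seed(700 + trial)
    k <- sample(2:8, 1)
    lens <- sample(500:6000, k)
    starts <- integer(k) # non-overlapping placement
    pos <- 1
    ok <- TRUE
    for (i in seq_len(k)) {
      gap <- sample(0:2000, 1)
      starts[i] <- pos + gap
      pos <- starts[i] + lens[i]
      if (pos > 30000) { ok <- FALSE; break }
    }
    if (!ok) next
    ctgs <- substring(tg, starts, starts + lens - 1)
    names(ctgs) <- sprintf("b%02d", seq_len(k))
    want <- brute(starts, lens, 30000)
    expect_equal(genomeFraction(ctgs, tg, circular = FALSE), want$gf,
                 tolerance = 1e-9)
    ng <- nga50(ctgs, tg, circular = FALSE)
    if (want$defined) {
      expect_equal(as.numeric(ng), want$nga50)
    } else {
      expect_false(attr(ng, "defined"))
    }
  }
})

test_that("purity estimation recovers the truth composition", {
  sc <- small_scenario(seed = 66, purity = 1, targetDepth = 4,
                       perBaseError = 0, qcFailFrac = 0)
  gs <- makeGenomeSet(sc)
  lib <- simulateLibrary(gs, sc)
  pur <- estimatePurity(lib, gs@target)
  expect_equal(pur$estimate, 100)
  expect_equal(pur$truth, 100)
  expect_error(estimatePurity(lib[0], gs@target), "empty")
})
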