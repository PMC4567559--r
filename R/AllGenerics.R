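# Generics, constructors, accessors and show methods.

#' @rdname SimScenario-class
#' @param seed integer RNG seed.
#' @param targetLen,targetGC,hostLen,mitoLen,rrnaLen,contaminantLen see slots.
#' @param refDivergences,purity,targetDepth,readLen see slots.
#' @param insertMean,insertSD,perBaseError,nonTargetMix,qcFailFrac see slots.
#' @return A validated `SimScenario`.
#' @examples
#' sc <- SimScenario(seed = 1, purity = 0.285, targetDepth = 20)
#' @export
SimScenario <- function(seed = 1L, targetLen = 50000L, targetGC = 0.26,
                        hostLen = 250000L, mitoLen = 15000L, rrnaLen = 1800L,
                        contaminantLen = 1550L,
                        refDivergences = c(0.02, 0.17, 0.21, 0.26),
                        purity = 0.285, targetDepth = 20, readLen = 100L,
                        insertMean = 230, insertSD = 25,
                        perBaseError = 0.002,
                        nonTargetMix = c(host = 0.90, mito = 0.07,
                                         rrna = 0.02, contaminant = 0.01),
                        qcFailFrac = 0.04) {
  new("SimScenario", seed = as.integer(seed), targetLen = as.integer(targetLen),
      targetGC = targetGC, hostLen = as.integer(hostLen),
      mitoLen = as.integer(mitoLen), rrnaLen = as.integer(rrnaLen),
      contaminantLen = as.integer(contaminantLen),
      refDivergences = refDivergences, purity = purity,
      targetDepth = targetDepth, readLen = as.integer(readLen),
      insertMean = insertMean, insertSD = insertSD,
      perBaseError = perBaseError, nonTargetMix = nonTargetMix,
      qcFailFrac = qcFailFrac)
}

#' @rdname QCParams-class
#' @param trimQ,minMeanQ,minLen thresholds.
#' @export
QCParams <- function(trimQ = 27L, minMeanQ = 27, minLen = 80L) {
  new("QCParams", trimQ = as.integer(trimQ), minMeanQ = minMeanQ,
      minLen = as.integer(minLen))
}

#' @rdname SearchParams-class
#' @param mode "translated" or "nucleotide".
#' @param wordSize,gapOpen,gapExt,evalueMax,keepBestOnly see slots.
#' @param bandHalfwidth,windowMargin gapped extension geometry.
#' @export
SearchParams <- function(mode = c("translated", "nucleotide"),
                         wordSize = NULL, gapOpen = NULL, gapExt = NULL,
                         evalueMax = 1e-12, keepBestOnly = TRUE,
                         bandHalfwidth = 16L, windowMargin = 32L) {
  mode <- match.arg(mode)
  if (is.null(wordSize)) wordSize <- if (mode == "translated") 4L else 16L
  if (is.null(gapOpen)) gapOpen <- if (mode == "translated") 11L else 5L
  if (is.null(gapExt)) gapExt <- if (mode == "translated") 1L else 2L
  stopifnot(wordSize >= 2, evalueMax > 0)
  new("SearchParams", mode = mode, wordSize = as.integer(wordSize),
      gapOpen = as.integer(gapOpen), gapExt = as.integer(gapExt),
      evalueMax = evalueMax, keepBestOnly = keepBestOnly,
      bandHalfwidth = as.integer(bandHalfwidth),
      windowMargin = as.integer(windowMargin))
}

#' @rdname AsmParams-class
#' @param minOverlapIdentity,minOverlapLen,minContigLen,usePairs see slots.
#' @param kmer,insertMean,insertSD,minJoinPairs,minJoinOverlap see slots.
#' @export
AsmParams <- function(minOverlapIdentity = 90, minOverlapLen = 40L,
                      minContigLen = 100L, usePairs = TRUE, kmer = 21L,
                      insertMean = 230, insertSD = 25, minJoinPairs = 3L,
                      minJoinOverlap = 10L) {
  new("AsmParams", minOverlapIdentity = minOverlapIdentity,
      minOverlapLen = as.integer(minOverlapLen),
      minContigLen = as.integer(minContigLen), usePairs = usePairs,
      kmer = as.integer(kmer), insertMean = insertMean, insertSD = insertSD,
      minJoinPairs = as.integer(minJoinPairs),
      minJoinOverlap = as.integer(minJoinOverlap))
}

#' @rdname ImraParams-class
#' @param minContigLen,saturationLenTol,saturationWindow,maxIter see slots.
#' @param asm assembler parameters for the reassembly step.
#' @export
ImraParams <- function(minContigLen = 500L, saturationLenTol = 0,
                       saturationWindow = 2L, maxIter = 30L,
                       asm = AsmParams(minContigLen = minContigLen)) {
  asm@minContigLen <- as.integer(minContigLen)
  new("ImraParams", minContigLen = as.integer(minContigLen),
      saturationLenTol = saturationLenTol,
      saturationWindow = as.integer(saturationWindow),
      maxIter = as.integer(maxIter), asm = asm)
}

#' Construct a PairedReads object
#'
#' @param pairId pair identifiers (unique).
#' @param seq1,qual1,seq2,qual2 mate sequences and Phred+33 quality strings.
#' @param truth optional per-pair truth labels.
#' @return A `PairedReads` object.
#' @export
PairedReads <- function(pairId, seq1, qual1, seq2, qual2,
                        truth = rep(NA_character_, length(pairId))) {
  new("PairedReads", pairId = as.character(pairId), seq1 = as.character(seq1),
      qual1 = as.character(qual1), seq2 = as.character(seq2),
      qual2 = as.character(qual2), truth = as.character(truth))
}

#' @describeIn PairedReads number of pairs.
#' @param x a `PairedReads` object.
#' @export
setMethod("length", "PairedReads", function(x) length(x@pairId))

#' @describeIn PairedReads subset pairs.
#' @param i index vector.
#' @param j,...,drop ignored.
#' @export
setMethod("[", "PairedReads", function(x, i, j, ..., drop = FALSE) {
  new("PairedReads", pairId = x@pairId[i], seq1 = x@seq1[i],
      qual1 = x@qual1[i], seq2 = x@seq2[i], qual2 = x@qual2[i],
      truth = x@truth[i])
})

setMethod("show", "PairedReads", function(object) {
  n <- length(object)
  cat("PairedReads with", n, "pairs\n")
  if (n) {
    cat("  read lengths:", paste(range(nchar(c(object@seq1, object@seq2))),
                                 collapse = "-"), "nt\n")
    if (!all(is.na(object@truth))) {
      tb <- table(object@truth)
      cat("  truth:", paste(names(tb), tb, sep = "=", collapse = " "), "\n")
    }
  }
})

#' Truth labels of simulated pairs
#' @param x a `PairedReads` object.
#' @return Character vector of per-pair source labels.
#' @export
pairTruth <- function(x) setNames(x@truth, x@pairId)

#' Pair identifiers
#' @param x a `PairedReads` object.
#' @export
pairIds <- function(x) x@pairId

#' Contig sequences of an assembly
#' @param x an `Assembly`.
#' @return A named `DNAStringSet`.
#' @export
contigs <- function(x) x@contigs

#' Per-contig mean read depth
#' @param x an `Assembly`.
#' @export
contigDepth <- function(x) x@depth

#' Read-placement table of an assembly
#' @param x an `Assembly`.
#' @export
contigMembers <- function(x) x@members

#' Number of contigs
#' @param x an `Assembly`.
#' @export
nContigs <- function(x) length(x@contigs)

#' Total assembled length (nt)
#' @param x an `Assembly`.
#' @export
totalLength <- function(x) sum(Biostrings::width(x@contigs))

setMethod("show", "Assembly", function(object) {
  w <- Biostrings::width(object@contigs)
  cat("Assembly:", length(w), "contig(s),", sum(w), "nt total")
  if (length(w)) cat(", longest", max(w), "nt")
  cat("\n")
})

setMethod("show", "SimScenario", function(object) {
  cat(sprintf(paste0("SimScenario: target %d nt (GC %.2f), purity %.3f, ",
                     "depth %.0fx, reads %d nt, insert %.0f+/-%.0f\n"),
              object@targetLen, object@targetGC, object@purity,
              object@targetDepth, object@readLen, object@insertMean,
              object@insertSD))
})

setMethod("show", "GenomeSet", function(object) {
  cat("GenomeSet: target", length(object@target), "nt,",
      nrow(object@genes), "genes;",
      length(object@refs), "reference genome(s); host",
      length(object@host), "nt; mito", length(object@mito), "nt",
      if (length(object@contaminant)) "; contaminant present" else "", "\n")
})

setMethod("show", "SelectionOutcome", function(object) {
  cat("SelectionOutcome: kept", length(object@kept),
      "| no-hit", length(object@removedNoHit),
      "| mito-better", length(object@removedMito),
      "| rrna-better", length(object@removedRrna), "\n")
})

setMethod("show", "ImraResult", function(object) {
  it <- object@stats[nrow(object@stats), ]
  cat(sprintf("ImraResult: %d iteration(s), %sconverged; best iteration %d: %d contig(s), %d nt\n",
              max(object@stats$iter), if (object@converged) "" else "NOT ",
              object@bestIter, nContigs(object@assembly),
              totalLength(object@assembly)))
  invisible(it)
})

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport: TP %d nt | FN %d nt | FP %d nt | genome fraction %.2f%% | NGA50 %s%s\n",
              as.integer(object@tpNt), as.integer(object@fnNt),
              as.integer(object@fpNt), object@genomeFraction,
              if (object@nga50Defined) as.integer(object@nga50) else "undefined",
              if (is.na(object@purity)) "" else
                sprintf(" | purity %.2f%%", object@purity)))
})

#' @describeIn SelectionOutcome kept contig ids.
#' @param x a `SelectionOutcome`.
#' @export
keptContigs <- function(x) x@kept

#' @describeIn SelectionOutcome the four-way partition as a named list.
#' @param object a `SelectionOutcome`.
#' @export
selectionSets <- function(object) {
  list(kept = object@kept, no_hit = object@removedNoHit,
       mito = object@removedMito, rrna = object@removedRrna)
}

#' Per-iteration IMRA statistics
#' @param x an `ImraResult`.
#' @export
iterationStats <- function(x) x@stats

#' Final assembly of an IMRA run
#' @param x an `ImraResult`.
#' @export
finalAssembly <- function(x) x@assembly
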