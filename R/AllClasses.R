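# S4 class definitions. Parameter classes carry the tunables of each stage;
# data classes wrap Biostrings containers with stage-specific metadata.

#' Simulation scenario for a mixed endosymbiont sequencing library
#'
#' Describes the genomes and the library to simulate: an AT-rich circular
#' endosymbiont target, a panel of reference genomes at graded amino-acid
#' divergences, host nuclear DNA with an embedded rRNA gene, an AT-rich
#' mitochondrion carrying one degenerate gene shared with the target, and an
#' optional trace contaminant with partial 16S-like similarity. `purity` is
#' the fraction of read pairs drawn from the target; `targetDepth` the
#' fold-coverage of the target genome.
#'
#' @slot seed integer RNG seed; the whole genome set and library are
#'   byte-reproducible given the scenario.
#' @slot targetLen,targetGC target genome length (nt) and GC fraction.
#' @slot hostLen,mitoLen,rrnaLen,contaminantLen lengths (nt) of the host
#'   chromosome sample, mitochondrion, host rRNA gene and contaminant
#'   (0 disables the contaminant).
#' @slot refDivergences amino-acid divergences of the reference panel.
#' @slot purity,targetDepth library composition and target coverage.
#' @slot readLen,insertMean,insertSD,perBaseError read geometry and
#'   substitution error rate.
#' @slot nonTargetMix proportions of host/mito/rrna/contaminant among
#'   non-target pairs.
#' @slot qcFailFrac fraction of reads given qualities that fail the
#'   Q27/80-nt quality rule, to exercise read QC.
#' @exportClass SimScenario
setClass("SimScenario", representation(
  seed = "integer", targetLen = "integer", targetGC = "numeric",
  hostLen = "integer", mitoLen = "integer", rrnaLen = "integer",
  contaminantLen = "integer", refDivergences = "numeric",
  purity = "numeric", targetDepth = "numeric", readLen = "integer",
  insertMean = "numeric", insertSD = "numeric", perBaseError = "numeric",
  nonTargetMix = "numeric", qcFailFrac = "numeric"))

setValidity("SimScenario", function(object) {
  msg <- character()
  if (object@purity <= 0 || object@purity > 1)
    msg <- c(msg, "purity must be in (0, 1]")
  if (any(object@refDivergences < 0) || any(object@refDivergences >= 1))
    msg <- c(msg, "reference divergences must be in [0, 1)")
  if (object@insertMean < object@readLen)
    msg <- c(msg, "insertMean must be at least readLen")
  lens <- c(object@targetLen, object@hostLen, object@mitoLen, object@rrnaLen,
            object@readLen)
  if (any(lens <= 0)) msg <- c(msg, "all lengths must be positive")
  if (object@targetGC <= 0 || object@targetGC >= 1)
    msg <- c(msg, "targetGC must be in (0, 1)")
  if (object@targetDepth <= 0) msg <- c(msg, "targetDepth must be positive")
  if (length(object@nonTargetMix) != 4 || any(object@nonTargetMix < 0))
    msg <- c(msg, "nonTargetMix must be four non-negative proportions")
  if (length(msg)) msg else TRUE
})

#' A truth-labelled genome set for simulation
#'
#' The genomes a mixed fat-body library is drawn from. Only the target is
#' circular. `genes` is a 0-based half-open table of the target's ORFs
#' (minus-strand genes stored with start < end plus a strand flag);
#' `rrnRegion` is the target's conserved rRNA-family region, the anchor for
#' host-rRNA and contaminant homology.
#'
#' @slot target circular endosymbiont genome (`DNAString`).
#' @slot refs reference panel, one genome per amino-acid divergence
#'   (`DNAStringSet` named by divergence).
#' @slot host,mito,hostRrna,contaminant the non-target genomes; the
#'   contaminant has length zero when disabled.
#' @slot genes data.frame with columns start, end, strand, peptide.
#' @slot rrnRegion integer start/end of the target rRNA-family region.
#' @exportClass GenomeSet
setClass("GenomeSet", representation(
  target = "DNAString", refs = "DNAStringSet", host = "DNAString",
  mito = "DNAString", hostRrna = "DNAString", contaminant = "DNAString",
  genes = "data.frame", rrnRegion = "integer"))

#' Paired-end reads with optional truth labels
#'
#' A flat container for read pairs: mate sequences and Phred+33 quality
#' strings, plus a truth label per pair (target/host/mito/rrna/contaminant)
#' carried only in simulation - truth is never written to FASTQ.
#'
#' @slot pairId character pair identifiers.
#' @slot seq1,qual1,seq2,qual2 mate sequences and quality strings.
#' @slot truth per-pair source label, `NA` for real data.
#' @exportClass PairedReads
setClass("PairedReads", representation(
  pairId = "character", seq1 = "character", qual1 = "character",
  seq2 = "character", qual2 = "character", truth = "character"))

setValidity("PairedReads", function(object) {
  n <- length(object@pairId)
  ok <- all(lengths(list(object@seq1, object@qual1, object@seq2,
                         object@qual2, object@truth)) == n)
  if (!ok) return("all slots must have one entry per pair")
  if (any(nchar(object@seq1) != nchar(object@qual1)) ||
      any(nchar(object@seq2) != nchar(object@qual2)))
    return("sequence and quality lengths differ")
  TRUE
})

#' An assembly: contigs with read membership and depth
#'
#' @slot contigs named `DNAStringSet` of consensus sequences.
#' @slot depth mean read depth per contig.
#' @slot circular per-contig flag: terminal self-overlap detected (ends are
#'   not auto-joined).
#' @slot members data.frame (read_id, contig, offset, strand, len) recording
#'   each read's placement in the layout.
#' @exportClass Assembly
setClass("Assembly", representation(
  contigs = "DNAStringSet", depth = "numeric", circular = "logical",
  members = "data.frame"))

#' Outcome of reference-based contig selection
#'
#' The partition produced by TCSF (or its nucleotide-mode counterpart):
#' contigs kept on a reference hit, removed for lack of any hit, or evicted
#' for scoring better against the mitochondrial / host-rRNA decoys.
#'
#' @slot kept,removedNoHit,removedMito,removedRrna contig ids; the four
#'   sets partition the input.
#' @slot bestHits data.frame of per-contig best bit scores against the
#'   reference and each decoy.
#' @exportClass SelectionOutcome
setClass("SelectionOutcome", representation(
  kept = "character", removedNoHit = "character", removedMito = "character",
  removedRrna = "character", bestHits = "data.frame"))

setValidity("SelectionOutcome", function(object) {
  sets <- list(object@kept, object@removedNoHit, object@removedMito,
               object@removedRrna)
  all_ids <- unlist(sets)
  if (anyDuplicated(all_ids)) return("selection sets must be disjoint")
  TRUE
})

#' Result of iterative mapping and reassembly
#'
#' @slot assembly the assembly at the best iteration (fewest contigs,
#'   then largest total length).
#' @slot stats per-iteration statistics: iter, n_contigs, total_len,
#'   n_pairs_recruited, delta_len, delta_count (iteration 0 is the seed).
#' @slot converged FALSE when the loop hit its iteration cap before
#'   saturation.
#' @slot bestIter the iteration the returned assembly comes from.
#' @exportClass ImraResult
setClass("ImraResult", representation(
  assembly = "Assembly", stats = "data.frame", converged = "logical",
  bestIter = "integer"))

#' Truth-based evaluation of a selection or assembly
#'
#' @slot tpNt,fnNt,fpNt total nucleotides of target contigs kept, target
#'   contigs removed, and non-target contigs kept.
#' @slot genomeFraction percent of target positions covered by aligned
#'   contig blocks.
#' @slot nga50 largest block length L such that aligned blocks of length at
#'   least L cover half the target; 0 when undefined.
#' @slot nga50Defined FALSE when coverage is below 50 percent.
#' @slot purity percent of reads mapping to the target (NA when reads were
#'   not supplied).
#' @slot assignments per-contig origin labels (target/other/unassigned).
#' @exportClass EvalReport
setClass("EvalReport", representation(
  tpNt = "numeric", fnNt = "numeric", fpNt = "numeric",
  genomeFraction = "numeric", nga50 = "numeric", nga50Defined = "logical",
  purity = "numeric", assignments = "data.frame"))

# ---- parameter classes ------------------------------------------------------

#' Read quality-filtering parameters
#'
#' Defaults follow the standard stringent Illumina recipe: trim 3' bases
#' below Q27, then discard reads with mean quality below 27 or fewer than
#' 80 nt, and drop pairs that lost a mate.
#'
#' @slot trimQ,minMeanQ,minLen thresholds (Phred, Phred, nt).
#' @exportClass QCParams
setClass("QCParams", representation(
  trimQ = "integer", minMeanQ = "numeric", minLen = "integer"))

#' Local homology search parameters
#'
#' @slot mode "translated" (six-frame x six-frame, BLOSUM62) or
#'   "nucleotide" (strand x strand, match +2 / mismatch -3).
#' @slot wordSize exact-word seed length (residues): 4 for translated,
#'   16 for nucleotide.
#' @slot gapOpen,gapExt affine gap penalties (a gap of length L costs
#'   gapOpen + L * gapExt).
#' @slot evalueMax report hits with E strictly below this value.
#' @slot keepBestOnly retain one best hit per query.
#' @slot bandHalfwidth,windowMargin gapped-extension band half-width and
#'   re-scoring window margin (residues).
#' @exportClass SearchParams
setClass("SearchParams", representation(
  mode = "character", wordSize = "integer", gapOpen = "integer",
  gapExt = "integer", evalueMax = "numeric", keepBestOnly = "logical",
  bandHalfwidth = "integer", windowMargin = "integer"))

#' Assembler / mapper parameters
#'
#' `minOverlapIdentity` (percent) and `minOverlapLen` (nt) are the two
#' stringency knobs shared by overlap detection and read mapping -
#' parameter set A is 90/40, set B is 85/35. `minContigLen` is 100 for the
#' initial de novo assembly and 500 inside IMRA.
#'
#' @slot minOverlapIdentity,minOverlapLen overlap stringency.
#' @slot minContigLen contigs shorter than this are discarded.
#' @slot usePairs join contig ends linked by at least `minJoinPairs`
#'   read pairs with a consistent implied gap, when the ends share an
#'   exact-overlap join (no N-gaps are ever emitted).
#' @slot kmer overlap prefilter k-mer length.
#' @slot insertMean,insertSD library insert geometry used for pair joining.
#' @slot minJoinPairs,minJoinOverlap pair-join evidence thresholds.
#' @exportClass AsmParams
setClass("AsmParams", representation(
  minOverlapIdentity = "numeric", minOverlapLen = "integer",
  minContigLen = "integer", usePairs = "logical", kmer = "integer",
  insertMean = "numeric", insertSD = "numeric", minJoinPairs = "integer",
  minJoinOverlap = "integer"))

setValidity("AsmParams", function(object) {
  msg <- character()
  if (object@minOverlapIdentity <= 0 || object@minOverlapIdentity > 100)
    msg <- c(msg, "minOverlapIdentity is a percentage in (0, 100]")
  if (object@minOverlapLen <= 0 || object@minContigLen <= 0)
    msg <- c(msg, "lengths must be positive")
  if (length(msg)) msg else TRUE
})

#' IMRA iteration parameters
#'
#' @slot minContigLen contig length cutoff applied after every reassembly
#'   (default 500 nt; 1000 nt is the strict anti-contaminant setting).
#' @slot saturationLenTol,saturationWindow saturation is declared when the
#'   contig count is unchanged and the total length changes by at most
#'   `saturationLenTol` nt for `saturationWindow` consecutive iterations.
#' @slot maxIter iteration cap; hitting it flags non-convergence.
#' @slot asm assembler parameters passed through to every reassembly.
#' @exportClass ImraParams
setClass("ImraParams", representation(
  minContigLen = "integer", saturationLenTol = "numeric",
  saturationWindow = "integer", maxIter = "integer", asm = "AsmParams"))

setValidity("ImraParams", function(object) {
  msg <- character()
  if (object@maxIter < 1) msg <- c(msg, "maxIter must be at least 1")
  if (object@saturationWindow < 1) msg <- c(msg, "saturationWindow >= 1")
  if (length(msg)) msg else TRUE
})
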