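# Iterative mapping and reassembly: map all reads to the current contigs,
# rescue whole pairs with at least one mapped mate, reassemble from scratch,
# drop short contigs, repeat until contig count and total length saturate.

#' Recruit read pairs with at least one mapped mate
#'
#' A pair is recruited iff its forward or reverse mate has mapping class
#' `Full` or `Partial`. This is the rescue that lets unmapped mate ends
#' extend contigs and close gaps. Output order is deterministic (by pair
#' id).
#'
#' @param mapping a mapping table from [mapReads()] over all reads
#'   (single-end).
#' @param pairs the full [PairedReads-class] dataset.
#' @return The recruited [PairedReads-class] subset.
#' @export
recruitPairs <- function(mapping, pairs) {
  stopifnot(is(pairs, "PairedReads"))
  mapped <- mapping$read_id[mapping$class %in% c("Full", "Partial")]
  base <- unique(sub("/[12]$", "", mapped))
  sel <- sort(intersect(pairs@pairId, base))
  pairs[match(sel, pairs@pairId)]
}

#' Iterative mapping and reassembly to saturation
#'
#' Starting from seed contigs (normally the kept set of a
#' [selectContigs()] run), loops: map all reads single-end onto the current
#' contigs, recruit every pair with a mapped mate, reassemble the recruited
#' pairs in paired-end mode from scratch, drop contigs shorter than
#' `minContigLen`, and record statistics. The loop stops when for
#' `saturationWindow` consecutive iterations the contig count is unchanged
#' and the total length moves by at most `saturationLenTol` nt; a
#' single-contig fixed point stops immediately; hitting `maxIter` flags
#' non-convergence. Returns the assembly at the best iteration (fewest
#' contigs, then largest total length, then earliest).
#'
#' @param seedContigs an [Assembly-class], `DNAStringSet` or named
#'   character of seed contigs.
#' @param pairs the full quality-filtered [PairedReads-class] dataset (not
#'   only reads used so far).
#' @param params an [ImraParams()].
#' @return An [ImraResult-class].
#' @export
imraIterate <- function(seedContigs, pairs, params = ImraParams()) {
  stopifnot(is(params, "ImraParams"), is(pairs, "PairedReads"))
  seeds <- as_contig_set(seedContigs)
  if (!length(seeds)) stop("TCSF produced no contigs")
  if (params@minContigLen < 2 * params@asm@insertMean)
    warning(sprintf(paste0("minContigLen (%d) is below twice the mean ",
                           "insert size (%.0f); short contaminant contigs ",
                           "may be elongated"),
                    params@minContigLen, params@asm@insertMean))
  asmp <- params@asm
  asmp@minContigLen <- params@minContigLen

  stats <- data.frame(iter = 0L, n_contigs = length(seeds),
                      total_len = sum(Biostrings::width(seeds)),
                      n_pairs_recruited = NA_integer_,
                      delta_len = NA_integer_, delta_count = NA_integer_)
  current <- seeds
  assemblies <- list()
  sat_run <- 0L
  converged <- FALSE
  for (it in seq_len(params@maxIter)) {
    mp <- mapReads(pairs, current, asmp)
    rec <- recruitPairs(mp, pairs)
    if (length(rec) == 0) {
      warning("no pairs recruited at iteration ", it, "; stopping")
      break
    }
    asm <- assembleReads(rec, asmp)
    n <- nContigs(asm)
    tl <- totalLength(asm)
    prev <- stats[nrow(stats), ]
    stats <- rbind(stats, data.frame(
      iter = it, n_contigs = n, total_len = tl,
      n_pairs_recruited = length(rec),
      delta_len = tl - prev$total_len,
      delta_count = n - prev$n_contigs))
    assemblies[[it]] <- asm
    if (n == 0) break
    d_len <- tl - prev$total_len
    d_cnt <- n - prev$n_contigs
    sat <- (d_cnt == 0 && abs(d_len) <= params@saturationLenTol)
    sat_run <- if (sat) sat_run + 1L else 0L
    if (n == 1 && d_len == 0) { converged <- TRUE; break }
    if (sat_run >= params@saturationWindow) { converged <- TRUE; break }
    current <- contigs(asm)
  }
  if (!length(assemblies)) stop("IMRA performed no successful iteration")
  st <- stats[stats$iter > 0, , drop = FALSE]
  best_n <- min(st$n_contigs[st$n_contigs > 0], Inf)
  cand <- st$iter[st$n_contigs == best_n]
  if (!length(cand)) cand <- st$iter
  best_iter <- cand[which.max(st$total_len[match(cand, st$iter)])]
  rownames(stats) <- NULL
  new("ImraResult", assembly = assemblies[[best_iter]], stats = stats,
      converged = converged, bestIter = as.integer(best_iter))
}

#' Run the full endosymbiont recovery pipeline
#'
#' Quality filtering, initial de novo assembly (100-nt contig cutoff),
#' reference-based contig selection with decoy filtering, and iterative
#' mapping/reassembly; when a truth [GenomeSet-class] is supplied each
#' stage is also evaluated against it.
#'
#' @param pairs raw [PairedReads-class] (or paths via [readLibrary()]).
#' @param reference related reference genome for selection.
#' @param mito,rrna decoy sequences (optional but recommended).
#' @param qcParams,asmParams,imraParams stage parameters.
#' @param mode selection mode ("translated" = TCSF).
#' @param evalueMax selection threshold.
#' @param truth optional [GenomeSet-class] for evaluation.
#' @return list with `qcReport`, `reads`, `denovo`, `selection`, `imra`,
#'   and (with truth) `evalSelection`, `evalFinal`.
#' @export
runPipeline <- function(pairs, reference, mito = NULL, rrna = NULL,
                        qcParams = QCParams(), asmParams = AsmParams(),
                        imraParams = ImraParams(asm = asmParams),
                        mode = c("translated", "nucleotide"),
                        evalueMax = 1e-12, truth = NULL) {
  mode <- match.arg(mode)
  qc <- filterPairs(pairs, qcParams)
  denovo_params <- asmParams
  denovo_params@minContigLen <- min(asmParams@minContigLen, 100L)
  denovo <- assembleReads(qc$pairs, denovo_params)
  if (nContigs(denovo) == 0) stop("de novo assembly produced no contigs")
  sel <- selectContigs(denovo, reference, mito = mito, rrna = rrna,
                       evalueMax = evalueMax, mode = mode)
  if (!length(sel@kept)) stop("TCSF produced no contigs")
  seed <- contigs(denovo)[sel@kept]
  imra <- imraIterate(seed, qc$pairs, imraParams)
  out <- list(qcReport = qc$report, reads = qc$pairs, denovo = denovo,
              selection = sel, imra = imra)
  if (!is.null(truth)) {
    stopifnot(is(truth, "GenomeSet"))
    assign_dn <- assignOrigin(denovo, truth)
    out$evalSelection <- evaluateSelection(sel, assign_dn, denovo, truth)
    out$evalFinal <- evaluateAssembly(finalAssembly(imra), truth,
                                      pairs = qc$pairs)
  }
  out
}
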