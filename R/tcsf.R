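# Contig selection and filtering: keep contigs with translated-homology
# hits to a related reference genome, then evict contigs that hit the
# mitochondrial genome or host rRNA better than the reference.

#' Select endosymbiont contigs against a reference with decoy filtering
#'
#' Step one drops every contig without a hit to the reference at
#' `E < evalueMax` (translated mode is TCSF proper; nucleotide mode is the
#' BLASTN-style comparison method). Step two computes each survivor's best
#' translated hit against the mitochondrial genome and best nucleotide hit
#' against the host rRNA; a contig whose best bit score against a decoy
#' strictly exceeds its best bit score against the reference is evicted
#' (ties retain the contig, favouring sensitivity). Missing decoys skip
#' that filter with a warning.
#'
#' @param contigs an [Assembly-class], `DNAStringSet` or named character
#'   (contigs are expected to be at least 100 nt; shorter input is allowed
#'   but was normally removed upstream).
#' @param reference reference genome(s); multi-FASTA allowed, the best hit
#'   is taken across records.
#' @param mito,rrna decoy sequences, or `NULL` to skip.
#' @param evalueMax selection threshold (default 1e-12).
#' @param mode `"translated"` or `"nucleotide"` for the reference search.
#' @return A [SelectionOutcome-class].
#' @export
selectContigs <- function(contigs, reference, mito = NULL, rrna = NULL,
                          evalueMax = 1e-12,
                          mode = c("translated", "nucleotide")) {
  mode <- match.arg(mode)
  cs <- as_contig_set(contigs)
  ref <- as_contig_set(reference)
  if (!length(ref) || sum(Biostrings::width(ref)) == 0)
    stop("empty reference")
  ids <- names(cs)

  ref_hits <- searchHits(cs, ref, SearchParams(mode, evalueMax = evalueMax))
  ref_best <- setNames(rep(NA_real_, length(ids)), ids)
  ref_best[ref_hits$query_id] <- ref_hits$bit_score
  no_hit <- ids[is.na(ref_best)]
  survivors <- setdiff(ids, no_hit)

  mito_best <- setNames(rep(NA_real_, length(ids)), ids)
  rrna_best <- setNames(rep(NA_real_, length(ids)), ids)
  removed_mito <- removed_rrna <- character(0)
  if (length(survivors)) {
    surv <- cs[survivors]
    if (is.null(mito) || !length(as_contig_set(mito))) {
      warning("no mitochondrial decoy supplied; mito filter skipped")
    } else {
      mh <- searchHits(surv, as_contig_set(mito),
                       SearchParams("translated", evalueMax = evalueMax))
      mito_best[mh$query_id] <- mh$bit_score
    }
    if (is.null(rrna) || !length(as_contig_set(rrna))) {
      warning("no host rRNA decoy supplied; rRNA filter skipped")
    } else {
      rh <- searchHits(surv, as_contig_set(rrna),
                       SearchParams("nucleotide", evalueMax = evalueMax))
      rrna_best[rh$query_id] <- rh$bit_score
    }
    is_mito <- !is.na(mito_best[survivors]) &
      mito_best[survivors] > ref_best[survivors]
    removed_mito <- survivors[is_mito]
    rest <- survivors[!is_mito]
    is_rrna <- !is.na(rrna_best[rest]) & rrna_best[rest] > ref_best[rest]
    removed_rrna <- rest[is_rrna]
  }
  kept <- setdiff(survivors, c(removed_mito, removed_rrna))

  new("SelectionOutcome", kept = kept, removedNoHit = no_hit,
      removedMito = removed_mito, removedRrna = removed_rrna,
      bestHits = data.frame(contig = ids,
                            ref_bits = unname(ref_best),
                            mito_bits = unname(mito_best),
                            rrna_bits = unname(rrna_best),
                            stringsAsFactors = FALSE))
}

#' Compare selection modes across a reference panel
#'
#' Runs [selectContigs()] for every (mode, reference) combination and
#' scores each outcome against truth assignments, yielding the
#' length-weighted TP/FN/FP confusion table.
#'
#' @param contigs contigs to select from.
#' @param referencePanel named list or `DNAStringSet` of reference genomes
#'   (typically one per divergence).
#' @param assignments per-contig truth labels from [assignOrigin()].
#' @param mito,rrna decoys passed through.
#' @param evalueMax threshold.
#' @param modes modes to compare.
#' @return list with `table` (one row per mode x reference: tp_nt, fn_nt,
#'   fp_nt) and `outcomes` (the named [SelectionOutcome-class] objects).
#' @export
compareSelectionModes <- function(contigs, referencePanel, assignments,
                                  mito = NULL, rrna = NULL,
                                  evalueMax = 1e-12,
                                  modes = c("translated", "nucleotide")) {
  cs <- as_contig_set(contigs)
  if (is(referencePanel, "DNAStringSet"))
    referencePanel <- as.list(as.character(referencePanel))
  rows <- list()
  outcomes <- list()
  for (mode in modes) {
    for (rn in names(referencePanel)) {
      sel <- selectContigs(cs, referencePanel[[rn]], mito = mito, rrna = rrna,
                           evalueMax = evalueMax, mode = mode)
      conf <- confusionLengths(sel, assignments,
                               setNames(Biostrings::width(cs), names(cs)))
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, reference = rn, tp_nt = conf[["tp_nt"]],
        fn_nt = conf[["fn_nt"]], fp_nt = conf[["fp_nt"]],
        stringsAsFactors = FALSE)
      outcomes[[paste(mode, rn, sep = ".")]] <- sel
    }
  }
  list(table = do.call(rbind, rows), outcomes = outcomes)
}
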