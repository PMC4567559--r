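# Read quality filtering: 3' quality trimming, mean-quality and length
# discard rules, and exclusion of unpaired survivors.

#' Trim low-quality 3' ends
#'
#' Repeatedly drops the final base of each read while its Phred score is
#' below `trimQ`. May return empty reads; sequence and quality stay aligned.
#'
#' @param seqs,quals character vectors (sequences, Phred+33 qualities).
#' @param trimQ Phred threshold (default 27).
#' @return list with `seq`, `qual`, `len`, `mean_q`, `trimmed`.
#' @examples
#' trimReads3p("ACGTT", paste(intToUtf8(c(63, 63, 63, 53, 53), TRUE),
#'                            collapse = ""))
#' @export
trimReads3p <- function(seqs, quals, trimQ = 27L) {
  stopifnot(length(seqs) == length(quals))
  cpp_trim3(as.character(seqs), as.character(quals), as.integer(trimQ))
}

#' Quality-filter a paired library
#'
#' Both mates are 3'-trimmed at `trimQ`; a read then passes iff its
#' post-trim mean quality is at least `minMeanQ` and its length at least
#' `minLen` (strict "< threshold" discards, so exact ties are kept). A pair
#' survives only if both mates pass; passing reads whose mate failed are
#' discarded and counted as `reads_dropped_unpaired`.
#'
#' @param pairs a [PairedReads-class] object.
#' @param params a [QCParams()].
#' @return list with `pairs` (surviving, trimmed, truth preserved) and
#'   `report` (named integer counts).
#' @export
filterPairs <- function(pairs, params = QCParams()) {
  stopifnot(is(pairs, "PairedReads"), is(params, "QCParams"))
  t1 <- cpp_trim3(pairs@seq1, pairs@qual1, params@trimQ)
  t2 <- cpp_trim3(pairs@seq2, pairs@qual2, params@trimQ)
  pass <- function(t) t$mean_q >= params@minMeanQ & t$len >= params@minLen
  p1 <- pass(t1); p2 <- pass(t2)
  keep <- p1 & p2
  by_len <- sum(t1$len < params@minLen) + sum(t2$len < params@minLen)
  by_mean <- sum(t1$mean_q < params@minMeanQ & t1$len >= params@minLen) +
    sum(t2$mean_q < params@minMeanQ & t2$len >= params@minLen)
  unpaired <- sum(p1 & !p2) + sum(p2 & !p1)
  out <- PairedReads(pairId = pairs@pairId[keep],
                     seq1 = t1$seq[keep], qual1 = t1$qual[keep],
                     seq2 = t2$seq[keep], qual2 = t2$qual[keep],
                     truth = pairs@truth[keep])
  report <- c(pairs_in = length(pairs),
              reads_in = 2L * length(pairs),
              reads_trimmed = sum(t1$trimmed) + sum(t2$trimmed),
              reads_dropped_by_length = by_len,
              reads_dropped_by_mean = by_mean,
              reads_dropped_unpaired = unpaired,
              pairs_out = sum(keep))
  list(pairs = out, report = report)
}
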