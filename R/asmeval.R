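# Truth-based evaluation: contig origin assignment, length-weighted
# TP/FN/FP, genome fraction, NGA50 and library purity.

# near-identity alignment blocks of queries against one subject, both
# strands; q coordinates on the forward strand of each query, `query` is the
# index into `q` (the subject is k-mer indexed once for all queries)
.blocks <- function(q, s, k = 21L, min_len = 65L, xdrop = 12L) {
  q <- as.character(q); s <- as.character(s)
  b1 <- cpp_anchor_blocks(q, s, k, min_len, xdrop)
  if (nrow(b1)) b1$strand <- 1L
  b2 <- cpp_anchor_blocks(revcomp(q), s, k, min_len, xdrop)
  if (nrow(b2)) {
    L <- nchar(q)[b2$query]
    qs <- L - b2$qend
    b2$qend <- L - b2$qstart
    b2$qstart <- qs
    b2$strand <- -1L
  }
  out <- rbind(b1, b2)
  if (nrow(out)) {
    out$len <- out$qend - out$qstart
    out$identity <- out$matches / pmax(out$len, 1)
  }
  out
}

# union length of 0-based half-open intervals
.union_len <- function(starts, ends) {
  if (!length(starts)) return(0L)
  o <- order(starts)
  s <- starts[o]; e <- ends[o]
  tot <- 0L; cs <- s[1]; ce <- e[1]
  for (i in seq_along(s)[-1]) {
    if (s[i] > ce) { tot <- tot + (ce - cs); cs <- s[i]; ce <- e[i] }
    else ce <- max(ce, e[i])
  }
  tot + (ce - cs)
}

.truth_genomes <- function(gs) {
  g <- list(host = gs@host, mito = gs@mito, rrna = gs@hostRrna)
  if (length(gs@contaminant)) g$contaminant <- gs@contaminant
  g
}

#' Assign contig origin against truth genomes
#'
#' A contig is labelled `target` when an alignment (both strands, circular
#' rotations of the target considered) covers at least 95 percent of the
#' contig at identity above 99.0 percent; failing that, `other` if it meets
#' the same test against any non-target truth genome; otherwise
#' `unassigned`.
#'
#' @param contigs an [Assembly-class], `DNAStringSet` or named character.
#' @param gs the truth [GenomeSet-class].
#' @param minCover,minIdentity the coverage and identity clauses.
#' @return data.frame with columns `contig` and `label`.
#' @export
assignOrigin <- function(contigs, gs, minCover = 0.95, minIdentity = 0.99) {
  cs <- as_contig_set(contigs)
  target2 <- paste0(as.character(gs@target), as.character(gs@target))
  others <- Filter(length, .truth_genomes(gs))
  qv <- as.character(cs)
  score_all <- function(genome) {
    b <- .blocks(qv, genome, min_len = 30L)
    ok <- rep(FALSE, length(qv))
    matches <- rep(0, length(qv))
    if (!nrow(b)) return(list(ok = ok, matches = matches))
    for (i in unique(b$query)) {
      bi <- b[b$query == i, ]
      cover <- .union_len(bi$qstart, bi$qend) / nchar(qv[i])
      ident <- sum(bi$matches) / sum(bi$len)
      ok[i] <- cover >= minCover && ident > minIdentity
      matches[i] <- sum(bi$matches)
    }
    list(ok = ok, matches = matches)
  }
  genomes <- c(list(target = target2), lapply(others, as.character))
  scored <- lapply(genomes, score_all)
  labels <- ifelse(scored$target$ok, "target", NA_character_)
  source <- ifelse(!is.na(labels), "target", NA_character_)
  for (gn in names(others)) {
    todo <- is.na(labels)
    if (!any(todo)) break
    hit <- scored[[gn]]$ok
    source[todo & hit] <- gn
    labels[todo & hit] <- "other"
  }
  labels[is.na(labels)] <- "unassigned"
  # weak evidence for unassigned contigs: the genome with the most aligned
  # matching bases, if any aligned at all
  mat <- vapply(scored, `[[`, numeric(length(qv)), "matches")
  if (is.null(dim(mat)))
    mat <- matrix(mat, nrow = 1, dimnames = list(NULL, names(scored)))
  best <- apply(mat, 1, which.max)
  evidence <- ifelse(rowSums(mat) > 0, colnames(mat)[best], NA_character_)
  data.frame(contig = names(cs), label = labels, source = source,
             evidence = evidence, stringsAsFactors = FALSE)
}

#' Length-weighted selection confusion
#'
#' TP: total length of target-origin contigs kept; FN: target-origin
#' contigs removed; FP: kept contigs assigned to another genome, plus kept
#' unassigned contigs whose strongest (sub-threshold) alignment evidence
#' does not point at the target - a short low-coverage target contig whose
#' consensus errors push it just under the 99% identity criterion is not
#' charged as a false positive, but anything alien is.
#' `tp_nt + fn_nt` depends only on the truth assignment, not on the
#' selection method.
#'
#' @param selection a [SelectionOutcome-class].
#' @param assignments from [assignOrigin()] covering every selected contig.
#' @param contigLengths named lengths of all contigs in the selection
#'   universe.
#' @return named numeric: tp_nt, fn_nt, fp_nt.
#' @export
confusionLengths <- function(selection, assignments, contigLengths) {
  stopifnot(is(selection, "SelectionOutcome"))
  ids <- unlist(selectionSets(selection), use.names = FALSE)
  missing <- setdiff(ids, assignments$contig)
  if (length(missing))
    stop("contigs missing from assignments: ",
         paste(utils::head(missing), collapse = ", "))
  lab <- setNames(assignments$label, assignments$contig)
  ev <- if ("evidence" %in% names(assignments))
    setNames(assignments$evidence, assignments$contig)
  else setNames(rep(NA_character_, nrow(assignments)), assignments$contig)
  len <- contigLengths
  kept <- selection@kept
  removed <- c(selection@removedNoHit, selection@removedMito,
               selection@removedRrna)
  is_fp <- lab[kept] == "other" |
    (lab[kept] == "unassigned" & (is.na(ev[kept]) | ev[kept] != "target"))
  c(tp_nt = sum(len[kept[lab[kept] == "target"]]),
    fn_nt = sum(len[removed[lab[removed] == "target"]]),
    fp_nt = sum(len[kept[is_fp]]))
}

# alignment blocks of contigs on the (doubled, when circular) target,
# projected to target coordinates
.target_blocks <- function(contigs, target, circular = TRUE,
                           minIdentity = 0.95, minLen = 65L) {
  cs <- as_contig_set(contigs)
  tg <- as.character(target)
  L <- nchar(tg)
  sub <- if (circular) paste0(tg, tg) else tg
  starts <- integer(0); ends <- integer(0); lens <- integer(0)
  b <- .blocks(as.character(cs), sub, min_len = minLen)
  b <- b[b$identity >= minIdentity & b$len >= minLen, , drop = FALSE]
  if (nrow(b)) {
    for (j in seq_len(nrow(b))) {
      s0 <- b$sstart[j]; e0 <- b$send[j]
      blen <- min(e0 - s0, L)
      lens <- c(lens, blen)
      if (e0 - s0 >= L) { starts <- c(starts, 0L); ends <- c(ends, L) }
      else {
        s1 <- s0 %% L; e1 <- s1 + (e0 - s0)
        if (e1 <= L) { starts <- c(starts, s1); ends <- c(ends, e1) }
        else {
          starts <- c(starts, s1, 0L)
          ends <- c(ends, L, e1 - L)
        }
      }
    }
  }
  list(starts = starts, ends = ends, lens = lens, L = L)
}

#' Genome fraction
#'
#' Percent of target positions covered by at least one aligned contig
#' block (each position counted once). Blocks are near-identity diagonal
#' alignments of contigs on the target; a chimeric contig contributes only
#' its aligned blocks.
#'
#' @param contigs assembly or sequences.
#' @param target the true target genome (`DNAString` or character).
#' @param circular treat the target as circular.
#' @return Percent in [0, 100].
#' @export
genomeFraction <- function(contigs, target, circular = TRUE) {
  tb <- .target_blocks(contigs, target, circular)
  100 * .union_len(tb$starts, tb$ends) / tb$L
}

#' NGA50
#'
#' The largest block length L such that reference-aligned contig blocks of
#' length at least L together sum to at least half the target length.
#' Undefined (0, with attribute `defined = FALSE`) when the aligned blocks
#' cover less than half the genome.
#'
#' @inheritParams genomeFraction
#' @return Numeric NGA50 with attribute `defined`.
#' @export
nga50 <- function(contigs, target, circular = TRUE) {
  tb <- .target_blocks(contigs, target, circular)
  half <- tb$L / 2
  covered <- .union_len(tb$starts, tb$ends)
  if (!length(tb$lens) || covered < half) {
    return(structure(0, defined = FALSE))
  }
  lens <- sort(tb$lens, decreasing = TRUE)
  cum <- cumsum(lens)
  i <- which(cum >= half)[1]
  if (is.na(i)) return(structure(0, defined = FALSE))
  structure(as.numeric(lens[i]), defined = TRUE)
}

#' Estimate library purity by mapping reads to the target
#'
#' Percent of reads with a Full or Partial mapping to the target genome at
#' the default stringency; in simulation the truth-label purity is
#' reported alongside for cross-checking.
#'
#' @param pairs a [PairedReads-class] object.
#' @param target the complete target genome.
#' @param params mapping stringency ([AsmParams()]).
#' @param circular treat the target as circular.
#' @return list with `estimate` (percent of reads) and `truth` (percent of
#'   pairs, `NA` without labels).
#' @export
estimatePurity <- function(pairs, target, params = AsmParams(),
                           circular = TRUE) {
  stopifnot(is(pairs, "PairedReads"))
  if (!length(pairs)) stop("empty read set")
  tg <- as.character(target)
  sub <- if (circular) paste0(tg, tg) else tg
  mp <- mapReads(pairs, setNames(sub, "target"), params)
  est <- 100 * mean(mp$class %in% c("Full", "Partial"))
  tr <- if (all(is.na(pairs@truth))) NA_real_
        else 100 * mean(pairs@truth == "target")
  list(estimate = est, truth = tr)
}

#' Evaluate a final assembly against truth
#'
#' @param assembly the assembly to score.
#' @param gs the truth [GenomeSet-class].
#' @param pairs optional reads for purity estimation.
#' @return An [EvalReport-class]; for a final assembly every contig counts
#'   as kept, so FN is 0 and FP is the length of non-target contigs.
#' @export
evaluateAssembly <- function(assembly, gs, pairs = NULL) {
  asg <- assignOrigin(assembly, gs)
  cs <- as_contig_set(assembly)
  len <- setNames(Biostrings::width(cs), names(cs))
  gf <- genomeFraction(cs, gs@target, circular = TRUE)
  ng <- nga50(cs, gs@target, circular = TRUE)
  pur <- if (is.null(pairs)) NA_real_
         else estimatePurity(pairs, gs@target)$estimate
  is_fp <- asg$label == "other" |
    (asg$label == "unassigned" & (is.na(asg$evidence) | asg$evidence != "target"))
  new("EvalReport",
      tpNt = sum(len[asg$contig[asg$label == "target"]]),
      fnNt = 0, fpNt = sum(len[asg$contig[is_fp]]),
      genomeFraction = gf, nga50 = as.numeric(ng),
      nga50Defined = isTRUE(attr(ng, "defined")),
      purity = pur, assignments = asg)
}

#' Evaluate a selection outcome against truth
#'
#' @param selection a [SelectionOutcome-class].
#' @param assignments truth labels covering the selection universe.
#' @param contigs the contig set the selection ran on.
#' @param gs the truth [GenomeSet-class].
#' @return An [EvalReport-class] scoring the kept set.
#' @export
evaluateSelection <- function(selection, assignments, contigs, gs) {
  cs <- as_contig_set(contigs)
  len <- setNames(Biostrings::width(cs), names(cs))
  conf <- confusionLengths(selection, assignments, len)
  kept <- cs[selection@kept]
  gf <- genomeFraction(kept, gs@target, circular = TRUE)
  ng <- nga50(kept, gs@target, circular = TRUE)
  new("EvalReport", tpNt = conf[["tp_nt"]], fnNt = conf[["fn_nt"]],
      fpNt = conf[["fp_nt"]], genomeFraction = gf, nga50 = as.numeric(ng),
      nga50Defined = isTRUE(attr(ng, "defined")), purity = NA_real_,
      assignments = assignments)
}
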