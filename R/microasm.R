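# Greedy overlap-layout-consensus assembly and seeded read mapping.

# flatten a PairedReads object into an id-sorted read vector
.flatten_pairs <- function(pairs) {
  ids <- c(rbind(paste0(pairs@pairId, "/1"), paste0(pairs@pairId, "/2")))
  seqs <- c(rbind(pairs@seq1, pairs@seq2))
  o <- order(ids, method = "radix")
  setNames(seqs[o], ids[o])
}

.mate_id <- function(ids) {
  ifelse(endsWith(ids, "/1"), paste0(substr(ids, 1, nchar(ids) - 2), "/2"),
         ifelse(endsWith(ids, "/2"),
                paste0(substr(ids, 1, nchar(ids) - 2), "/1"), NA_character_))
}

#' Assemble reads into contigs
#'
#' Greedy overlap-layout-consensus: qualifying overlaps (length at least
#' `minOverlapLen`, identity at least `minOverlapIdentity`, found through a
#' 21-mer prefilter) drive a mutual-best unitig walk; a read end with two
#' qualifying extensions whose sequences disagree is a branch point and
#' stops extension. Consensus is per-column majority vote. With `usePairs`,
#' contig ends linked by at least `minJoinPairs` read pairs with a
#' consistent implied gap are joined when the ends share an exact overlap
#' (never with N-gaps). Contigs shorter than `minContigLen` are dropped.
#' Deterministic: reads are processed in lexicographic id order and all tie
#' breaks are fixed.
#'
#' @param x a [PairedReads-class] object or a named character vector of
#'   reads (pair joining requires pairs).
#' @param params an [AsmParams()].
#' @return An [Assembly-class]; empty input yields an empty assembly.
#' @export
assembleReads <- function(x, params = AsmParams()) {
  stopifnot(is(params, "AsmParams"))
  if (is(x, "PairedReads")) {
    reads <- .flatten_pairs(x)
  } else {
    reads <- setNames(as.character(x), names(x))
    if (is.null(names(reads))) names(reads) <- sprintf("r%06d", seq_along(reads))
    reads <- reads[order(names(reads), method = "radix")]
  }
  if (!length(reads)) {
    return(new("Assembly", contigs = Biostrings::DNAStringSet(),
               depth = numeric(0), circular = logical(0),
               members = data.frame(read_id = character(0),
                                    contig = character(0), offset = integer(0),
                                    strand = integer(0), len = integer(0))))
  }
  mi <- params@minOverlapIdentity / 100
  core <- cpp_assemble_core(unname(reads), mi, params@minOverlapLen,
                            params@kmer)
  seqs <- as.character(core$seqs)
  m <- core$members
  m$len <- nchar(reads)[m$read]
  clen <- nchar(seqs)

  # canonical orientation: lexicographically smaller of seq / revcomp
  rcs <- revcomp(seqs)
  flip <- rcs < seqs
  seqs[flip] <- rcs[flip]
  fl <- which(flip[m$contig])
  if (length(fl)) {
    c0 <- m$contig[fl]
    m$offset[fl] <- clen[c0] - m$offset[fl] - m$len[fl]
    m$strand[fl] <- -m$strand[fl]
  }

  repeat { # containment removal to fixpoint (hosts may themselves be shadowed)
    if (length(seqs) <= 1) break
    n_before <- length(seqs)
    rc2 <- .remove_contained(seqs, m, mi)
    seqs <- rc2$seqs
    m <- rc2$members
    if (length(seqs) == n_before) break
  }

  if (params@usePairs && is(x, "PairedReads") && length(seqs) > 1) {
    joined <- .join_by_pairs(seqs, m, names(reads), params)
    seqs <- joined$seqs
    m <- joined$members
    repeat { # joins may have absorbed the span of leftover fragments
      if (length(seqs) <= 1) break
      n_before <- length(seqs)
      rc2 <- .remove_contained(seqs, m, mi)
      seqs <- rc2$seqs
      m <- rc2$members
      if (length(seqs) == n_before) break
    }
  }
  clen <- nchar(seqs)

  keep <- which(clen >= params@minContigLen)
  ord <- keep[order(-clen[keep], seqs[keep])]
  if (!length(ord)) {
    return(new("Assembly", contigs = Biostrings::DNAStringSet(),
               depth = numeric(0), circular = logical(0),
               members = data.frame(read_id = character(0),
                                    contig = character(0), offset = integer(0),
                                    strand = integer(0), len = integer(0))))
  }
  newid <- setNames(sprintf("ctg%05d", seq_along(ord)), ord)
  m <- m[m$contig %in% ord, , drop = FALSE]
  members <- data.frame(read_id = names(reads)[m$read],
                        contig = unname(newid[as.character(m$contig)]),
                        offset = m$offset, strand = m$strand, len = m$len,
                        stringsAsFactors = FALSE)
  members <- members[order(members$contig, members$offset, members$read_id), ]
  rownames(members) <- NULL
  out_seqs <- Biostrings::DNAStringSet(setNames(seqs[ord], unname(newid)))
  tot <- tapply(members$len, factor(members$contig, levels = unname(newid)),
                sum, default = 0)
  depth <- as.numeric(tot) / nchar(seqs[ord])
  # circularity: reported as a terminal self-overlap flag (ends not joined)
  circ <- rep(FALSE, length(ord))
  for (i in seq_along(ord)) {
    s <- seqs[ord[i]]
    if (nchar(s) >= 2 * params@minOverlapLen) {
      ov <- cpp_best_end_overlap(s, s, params@minOverlapLen,
                                 min(nchar(s) %/% 2, 1000L), mi)
      if (ov[1] > 0) circ[i] <- TRUE
    }
  }
  new("Assembly", contigs = out_seqs, depth = depth, circular = circ,
      members = members)
}

# drop contigs whose whole span aligns inside a longer contig at the overlap
# identity threshold (layout paths that shadowed an already-assembled
# region), transplanting their read members onto the host contig
.remove_contained <- function(seqs, m, mi, overhang_tol = 10L) {
  n <- length(seqs)
  lens <- nchar(seqs)
  mp <- cpp_map_reads(seqs, seqs, 15L, mi, 30L, 2L, self = seq_len(n))
  # hosts are strictly longer (or equal length with smaller index), so host
  # pointers cannot cycle; a shadow contig overhanging its host by at most
  # overhang_tol nt counts as contained
  j <- mp$contig
  near_full <- mp$class == "Full" |
    (mp$class == "Partial" & (mp$qend - mp$qstart) >= lens - overhang_tol)
  ok <- j > 0 & near_full &
    (lens[pmax(j, 1)] > lens |
       (lens[pmax(j, 1)] == lens & mp$class == "Full" & j < seq_len(n)))
  host <- ifelse(ok, j, 0L)
  if (!any(host > 0)) return(list(seqs = seqs, members = m))
  hstart <- ifelse(ok, mp$start - mp$qstart, 0L)
  hstrand <- ifelse(ok, mp$strand, 1L)
  # resolve transplant chains (a host may itself be dropped)
  fhost <- host; fstart <- hstart; fstrand <- hstrand
  repeat {
    idx <- which(fhost > 0)
    idx <- idx[host[fhost[idx]] > 0]
    if (!length(idx)) break
    jj <- fhost[idx]
    ns <- ifelse(hstrand[jj] > 0,
                 hstart[jj] + fstart[idx],
                 hstart[jj] + (lens[jj] - fstart[idx] - lens[idx]))
    fstrand[idx] <- fstrand[idx] * hstrand[jj]
    fstart[idx] <- ns
    fhost[idx] <- host[jj]
  }
  # one vectorized member transplant
  ci <- m$contig
  rows <- which(fhost[ci] > 0)
  if (length(rows)) {
    c0 <- ci[rows]
    st <- fstrand[c0]
    s0 <- fstart[c0]
    m$offset[rows] <- ifelse(st > 0, s0 + m$offset[rows],
                             s0 + (lens[c0] - m$offset[rows] - m$len[rows]))
    m$strand[rows] <- m$strand[rows] * st
    m$contig[rows] <- fhost[c0]
  }
  drop <- fhost > 0
  remap <- cumsum(!drop)
  m <- m[!drop[m$contig], , drop = FALSE]
  m$contig <- remap[m$contig]
  seqs <- seqs[!drop]
  list(seqs = seqs, members = m)
}

# pair-evidence contig joining: ends linked by >= minJoinPairs pairs whose
# implied gap is consistent, merged through a verified exact end overlap;
# each round commits every join over untouched contigs, then applies one
# vectorized member update
.join_by_pairs <- function(seqs, m, read_ids, params) {
  sd4 <- 4 * params@insertSD
  mi <- params@minOverlapIdentity / 100
  nreads <- length(read_ids)
  mate_read <- match(.mate_id(read_ids), read_ids) # integer mate lookup, once
  guard <- 0L
  repeat {
    guard <- guard + 1L
    if (guard > 50L) break
    clen <- nchar(seqs)
    alive <- !is.na(seqs)
    # placements: one row per read at most
    rowofread <- rep(NA_integer_, nreads)
    ok_rows <- which(alive[m$contig])
    rowofread[m$read[ok_rows]] <- ok_rows
    a_read <- which(!is.na(rowofread) & !is.na(mate_read) &
                      seq_len(nreads) < mate_read &
                      !is.na(rowofread[pmax(mate_read, 1L)]))
    if (!length(a_read)) break
    ra <- rowofread[a_read]
    rb <- rowofread[mate_read[a_read]]
    A <- m$contig[ra]; B <- m$contig[rb]
    # ignore single-read shreds (shadow fragments) as junction evidence
    thr <- min(params@minContigLen, max(m$len) + 1L)
    cross <- which(A != B & clen[A] >= thr & clen[B] >= thr)
    if (!length(cross)) break
    ra <- ra[cross]; rb <- rb[cross]; A <- A[cross]; B <- B[cross]
    dist_of <- function(rows) ifelse(m$strand[rows] > 0,
                                     clen[m$contig[rows]] - m$offset[rows],
                                     m$offset[rows] + m$len[rows])
    g <- params@insertMean - dist_of(ra) - dist_of(rb)
    eA <- ifelse(m$strand[ra] > 0, "R", "L")
    eB <- ifelse(m$strand[rb] > 0, "R", "L")
    swap <- B < A
    tmp <- A[swap]; A[swap] <- B[swap]; B[swap] <- tmp
    tmp <- eA[swap]; eA[swap] <- eB[swap]; eB[swap] <- tmp
    keep <- g <= params@insertMean + sd4 & g >= -pmin(clen[A], clen[B])
    if (!any(keep)) break
    # numeric group key per (contig, end, contig, end) junction
    modk <- 2 * length(seqs) + 2
    combo <- ((A * 2 + (eA == "R")) * modk + (B * 2 + (eB == "R")))[keep]
    gk <- g[keep]
    o2 <- order(combo)
    combo <- combo[o2]; gk <- gk[o2]
    runs <- rle(combo)
    grp_end <- cumsum(runs$lengths)
    grp_start <- grp_end - runs$lengths + 1L
    ord_g <- order(runs$lengths, decreasing = TRUE)
    # commit joins over untouched contigs; record one transform per contig
    touched <- rep(FALSE, length(seqs))
    flip <- rep(FALSE, length(seqs))
    shift <- rep(0L, length(seqs))
    newid <- seq_along(seqs)
    n_joined <- 0L
    for (gi in ord_g) {
      if (runs$lengths[gi] < params@minJoinPairs) break
      code <- runs$values[gi]
      b2 <- round(code %% modk)
      a2 <- round((code - b2) / modk)
      cA <- as.integer(a2 %/% 2); endA <- if (a2 %% 2) "R" else "L"
      cB <- as.integer(b2 %/% 2); endB <- if (b2 %% 2) "R" else "L"
      if (touched[cA] || touched[cB]) next
      gs <- gk[grp_start[gi]:grp_end[gi]]
      gh <- median(gs)
      if (sum(abs(gs - gh) <= sd4) < params@minJoinPairs) next
      lo <- max(params@minJoinOverlap, as.integer(floor(-gh - sd4)))
      hi <- min(clen[cA], clen[cB], as.integer(ceiling(-gh + sd4)))
      if (hi < lo) next
      A2 <- if (endA == "R") seqs[cA] else revcomp(seqs[cA])
      B2 <- if (endB == "L") seqs[cB] else revcomp(seqs[cB])
      ov <- cpp_best_end_overlap(A2, B2, lo, hi, mi)
      if (ov[1] == 0) next
      flip[cA] <- endA == "L"
      flip[cB] <- endB == "R"
      shift[cB] <- nchar(A2) - ov[1]
      newid[cB] <- cA
      seqs[cA] <- paste0(A2, substr(B2, ov[1] + 1, nchar(B2)))
      seqs[cB] <- NA_character_
      touched[cA] <- TRUE; touched[cB] <- TRUE
      n_joined <- n_joined + 1L
    }
    if (n_joined == 0L) break
    # one vectorized member update for all joins of this round
    ci <- m$contig
    fl <- which(flip[ci])
    if (length(fl)) {
      c0 <- ci[fl]
      m$offset[fl] <- clen[c0] - m$offset[fl] - m$len[fl]
      m$strand[fl] <- -m$strand[fl]
    }
    sh <- which(shift[ci] > 0L)
    if (length(sh)) m$offset[sh] <- m$offset[sh] + shift[ci[sh]]
    m$contig <- newid[ci]
  }
  drop <- is.na(seqs)
  if (any(drop)) {
    remap <- cumsum(!drop)
    m <- m[!drop[m$contig], , drop = FALSE]
    m$contig <- remap[m$contig]
    seqs <- seqs[!drop]
  }
  list(seqs = seqs, members = m)
}

#' Map reads onto contigs
#'
#' Seeded diagonal alignment of each read (both strands) to its best contig
#' position; `Full` when the alignment covers the whole read at the
#' identity threshold, `Partial` when it covers at least `minOverlapLen`
#' read bases (read overhanging a contig end, or a locally diverged read),
#' `Unmapped` otherwise. Best position maximizes aligned length times
#' identity; ties go to the lexicographically smallest contig id, then the
#' leftmost position.
#'
#' @param reads a [PairedReads-class] object (both mates, single-end), a
#'   named character vector, or `DNAStringSet`.
#' @param contigs an [Assembly-class], `DNAStringSet`, or named character.
#' @param params an [AsmParams()]; `minOverlapIdentity` and
#'   `minOverlapLen` are the mapper's thresholds.
#' @param seedStep spacing of mapping seeds along the read.
#' @return data.frame: read_id, contig (NA when unmapped), start, end,
#'   strand, identity, class.
#' @export
mapReads <- function(reads, contigs, params = AsmParams(), seedStep = 2L) {
  if (is(reads, "PairedReads")) {
    rv <- .flatten_pairs(reads)
  } else if (is(reads, "DNAStringSet")) {
    rv <- setNames(as.character(reads), names(reads))
  } else {
    rv <- setNames(as.character(reads), names(reads))
    if (is.null(names(rv))) names(rv) <- sprintf("r%06d", seq_along(rv))
  }
  cs <- as_contig_set(contigs)
  cs <- cs[order(names(cs), method = "radix")]
  if (!length(cs)) stop("no contigs to map against")
  df <- cpp_map_reads(unname(rv), as.character(cs), 15L,
                      params@minOverlapIdentity / 100,
                      params@minOverlapLen, as.integer(seedStep))
  data.frame(read_id = names(rv),
             contig = ifelse(df$contig > 0, names(cs)[pmax(df$contig, 1)],
                             NA_character_),
             start = df$start, end = df$end, strand = df$strand,
             identity = df$identity, class = df$class,
             stringsAsFactors = FALSE)
}
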