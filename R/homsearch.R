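# Local homology search: translated (six-frame x six-frame, BLOSUM62) and
# nucleotide (strand x strand, +2/-3) modes with Karlin-Altschul E-values.

# fixed Karlin-Altschul constants per scoring system (no effective-length
# correction; E-values approximate BLAST's - the contract is threshold
# behaviour, not E-value parity)
KA_CONSTANTS <- list(
  translated = list(lambda = 0.267, K = 0.041),  # BLOSUM62, gap 11/1
  nucleotide = list(lambda = 0.625, K = 0.41))   # +2/-3, gap 5/2

blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

nt_matrix <- function() {
  m <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -3,
                                                baseOnly = TRUE)
  storage.mode(m) <- "integer"
  m
}

#' Six-frame translation
#'
#' Frames +1..+3 read the forward strand, -1..-3 the reverse complement;
#' trailing partial codons are dropped, stop codons are emitted as `*` and
#' fuzzy codons as `X`. Inputs shorter than 3 nt yield six empty frames.
#'
#' @param seq a `DNAString` or character scalar.
#' @return An `AAStringSet` named `+1`, `+2`, `+3`, `-1`, `-2`, `-3`.
#' @examples
#' sixFrameTranslate("ATGGCC") # frame +1 is "MA", frame -1 is "GH"
#' @export
sixFrameTranslate <- function(seq) {
  if (is.character(seq)) seq <- Biostrings::DNAString(seq)
  L <- length(seq)
  rc <- Biostrings::reverseComplement(seq)
  peps <- character(6)
  nm <- c("+1", "+2", "+3", "-1", "-2", "-3")
  for (i in seq_len(6)) {
    f <- ((i - 1) %% 3) + 1
    src <- if (i <= 3) seq else rc
    n <- L - (f - 1)
    n <- n - (n %% 3)
    peps[i] <- if (n >= 3)
      as.character(Biostrings::translate(Biostrings::subseq(src, f, f + n - 1),
                                         if.fuzzy.codon = "X",
                                         no.init.codon = TRUE))
    else ""
  }
  out <- Biostrings::AAStringSet(peps)
  names(out) <- nm
  out
}

# vectorized frame translation across a whole sequence set
.translate_frame <- function(set, frame) {
  w <- pmax(Biostrings::width(set) - (abs(frame) - 1L), 0L)
  w <- w - w %% 3L
  sub <- Biostrings::subseq(set, start = abs(frame), width = w)
  as.character(Biostrings::translate(sub, if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

# variant tables: one row per (sequence, frame) search string; in
# nucleotide mode the query carries both strands and the subject only the
# forward strand (frame +/-1 means query strand)
.variants <- function(seqs, mode, both_strands = TRUE) {
  seqs <- as_contig_set(seqs)
  n <- length(seqs)
  if (mode == "translated") {
    rc <- Biostrings::reverseComplement(seqs)
    frames <- c(1L, 2L, 3L, -1L, -2L, -3L)
    strs <- unlist(lapply(frames, function(f)
      .translate_frame(if (f > 0) seqs else rc, f)))
    meta <- data.frame(seq = rep(names(seqs), 6),
                       frame = rep(frames, each = n),
                       nt_len = rep(Biostrings::width(seqs), 6),
                       stringsAsFactors = FALSE)
  } else {
    frames <- if (both_strands) c(1L, -1L) else 1L
    strs <- unlist(lapply(frames, function(f)
      if (f > 0) as.character(seqs)
      else as.character(Biostrings::reverseComplement(seqs))))
    meta <- data.frame(seq = rep(names(seqs), length(frames)),
                       frame = rep(frames, each = n),
                       nt_len = rep(Biostrings::width(seqs), length(frames)),
                       stringsAsFactors = FALSE)
  }
  meta$str <- unname(strs)
  meta
}

# variant-local 0-based half-open span -> forward-strand nt coordinates
.to_nt <- function(frame, a, b, L, mode) {
  if (mode == "nucleotide") {
    if (frame > 0) c(a, b) else c(L - b, L - a)
  } else {
    f <- abs(frame)
    if (frame > 0) c(f - 1 + 3 * a, f - 1 + 3 * b)
    else c(L - (f - 1 + 3 * b), L - (f - 1 + 3 * a))
  }
}

#' Seed-and-extend local homology search
#'
#' Exact word seeds (4 aa or 16 nt) are extended ungapped with an X-drop,
#' then re-scored by windowed local dynamic programming, so each reported
#' hit's score is the optimal local alignment score of its reported span.
#' Raw scores S are converted to bits S' = (lambda S - ln K) / ln 2 and
#' E = m n 2^-S' with m, n the query/subject nucleotide lengths; hits with
#' E >= `evalueMax` are removed. With `keepBestOnly` one best hit per query
#' is retained (max bit score, tie: lower E, then lexicographically smaller
#' subject id).
#'
#' @param query,subject sequences (`DNAStringSet`, named character, or
#'   [Assembly-class]).
#' @param params a [SearchParams()].
#' @return data.frame with columns query_id, subject_id, mode, bit_score,
#'   evalue, identity, q_start, q_end, s_start, s_end, q_frame, s_frame
#'   (0-based half-open forward-strand spans) plus raw alignment details.
#' @export
searchHits <- function(query, subject, params = SearchParams("translated")) {
  stopifnot(is(params, "SearchParams"))
  mode <- params@mode
  qv <- .variants(query, mode)
  sv <- .variants(subject, mode, both_strands = FALSE)
  if (!nrow(qv) || !nrow(sv)) stop("empty query or subject")

  if (mode == "translated") {
    mat <- blosum62()
    storage.mode(mat) <- "integer"
    xdrop <- 38L
  } else {
    mat <- nt_matrix()
    xdrop <- 22L
  }
  alphabet <- paste(rownames(mat), collapse = "")
  ka <- KA_CONSTANTS[[mode]]

  m_min <- min(qv$nt_len)
  n_tot <- sum(sv$nt_len[!duplicated(sv$seq)])
  bits_min <- log2(pmax(m_min, 1) * pmax(n_tot, 1) / params@evalueMax)
  min_raw <- max(as.integer(ceiling((bits_min * log(2) + log(ka$K)) /
                                      ka$lambda)), 4L * params@wordSize)
  trigger <- max(as.integer(floor(0.6 * min_raw)), 2L * params@wordSize)

  raw <- cpp_search_core(qv$str, sv$str, alphabet, mat,
                         params@wordSize, params@gapOpen, params@gapExt,
                         xdrop, trigger, min_raw,
                         params@windowMargin, params@bandHalfwidth, 4e6)
  cols <- c("query_id", "subject_id", "mode", "bit_score", "evalue",
            "identity", "q_start", "q_end", "s_start", "s_end",
            "q_frame", "s_frame", "raw_score", "matches", "aln_cols", "gaps")
  if (!nrow(raw)) {
    out <- as.data.frame(setNames(rep(list(logical(0)), length(cols)), cols))
    return(out)
  }

  qm <- qv[raw$qvar, ]
  sm <- sv[raw$svar, ]
  bits <- (ka$lambda * raw$score - log(ka$K)) / log(2)
  evalue <- as.numeric(qm$nt_len) * n_tot * 2^(-bits)
  qspan <- t(mapply(.to_nt, qm$frame, raw$qstart, raw$qend, qm$nt_len,
                    MoreArgs = list(mode = mode)))
  sspan <- t(mapply(.to_nt, sm$frame, raw$sstart, raw$send, sm$nt_len,
                    MoreArgs = list(mode = mode)))
  hits <- data.frame(
    query_id = qm$seq, subject_id = sm$seq, mode = mode,
    bit_score = bits, evalue = evalue,
    identity = raw$matches / pmax(raw$cols, 1),
    q_start = qspan[, 1], q_end = qspan[, 2],
    s_start = sspan[, 1], s_end = sspan[, 2],
    q_frame = qm$frame, s_frame = sm$frame,
    raw_score = raw$score, matches = raw$matches, aln_cols = raw$cols,
    gaps = raw$gaps, stringsAsFactors = FALSE)
  hits <- hits[hits$evalue < params@evalueMax, , drop = FALSE]
  if (!nrow(hits)) return(hits)

  # drop duplicate reports of the same region (overlapping spans on both
  # sequences from different seeds/frames keep the best-scoring one)
  hits <- hits[order(-hits$raw_score, hits$evalue, hits$subject_id,
                     hits$query_id, hits$q_start), , drop = FALSE]
  keep <- rep(TRUE, nrow(hits))
  ovl <- function(a1, a2, b1, b2) {
    inter <- pmax(0, pmin(a2, b2) - pmax(a1, b1))
    inter / pmax(1, pmin(a2 - a1, b2 - b1))
  }
  key_all <- paste(hits$query_id, hits$subject_id)
  for (key in unique(key_all)) {
    ix <- which(key_all == key)
    if (length(ix) < 2) next
    for (j in seq_along(ix)[-1]) {
      i2 <- ix[j]
      prev <- ix[seq_len(j - 1)][keep[ix[seq_len(j - 1)]]]
      if (!length(prev)) next
      qo <- ovl(hits$q_start[i2], hits$q_end[i2],
                hits$q_start[prev], hits$q_end[prev])
      so <- ovl(hits$s_start[i2], hits$s_end[i2],
                hits$s_start[prev], hits$s_end[prev])
      if (any(qo > 0.5 & so > 0.5)) keep[i2] <- FALSE
    }
  }
  hits <- hits[keep, , drop = FALSE]

  if (params@keepBestOnly) hits <- bestHitTable(hits)
  rownames(hits) <- NULL
  hits
}

#' Best hit per query
#'
#' Deterministic reduction of a hit table to one row per query: maximum
#' bit score, tie broken by lower E-value, then lexicographically smaller
#' subject id.
#'
#' @param hits a hit table from [searchHits()].
#' @return The reduced hit table.
#' @export
bestHitTable <- function(hits) {
  if (!nrow(hits)) return(hits)
  hits <- hits[order(hits$query_id, -hits$bit_score, hits$evalue,
                     hits$subject_id), , drop = FALSE]
  out <- hits[!duplicated(hits$query_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
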