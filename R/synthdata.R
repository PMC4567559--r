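# Synthetic genome set and mixed-library simulation.
#
# The generator emulates the structure of a fat-body shotgun library from a
# cockroach hosting an obligate endosymbiont: an AT-rich, gene-dense circular
# target genome; a reference panel diverged from the target at the amino-acid
# level, back-translated under each reference's own (GC-richer, free-living)
# codon bias so nucleotide identity decays much faster than protein identity;
# host nuclear DNA with an embedded rRNA gene; an AT-rich mitochondrion
# sharing one degenerate gene family with the target; and an optional trace
# contaminant with partial 16S-like similarity to the conserved rRNA family.

#' Forge a truth-labelled genome set
#'
#' Builds the target endosymbiont genome (gene-dense, AT-rich, circular, with
#' one conserved rRNA-family region), one reference genome per requested
#' amino-acid divergence, host nuclear DNA containing a host rRNA copy, a
#' mitochondrion carrying a degenerate (~60 percent amino-acid identity)
#' copy of one target gene, and an optional contaminant 16S-like fragment at
#' ~85 percent nucleotide identity to the target's rRNA region.
#' Deterministic: the same scenario yields a byte-identical genome set.
#'
#' @param scenario a [SimScenario()].
#' @return A [GenomeSet-class] object.
#' @examples
#' gs <- makeGenomeSet(SimScenario(seed = 1, targetLen = 20000L,
#'                                 hostLen = 40000L))
#' @export
makeGenomeSet <- function(scenario) {
  stopifnot(is(scenario, "SimScenario"))
  validObject(scenario)
  with_seed(scenario@seed, .make_genome_set(scenario))
}

.make_genome_set <- function(sc) {
  L <- sc@targetLen
  gc <- sc@targetGC

  # --- gene layout on the target -------------------------------------------
  rrn_len <- if (L >= 12000L) min(1500L, as.integer(L %/% 10)) else 0L
  genes <- list()
  pieces <- character()
  pos <- 0L
  rrn_at <- if (rrn_len > 0) L %/% 2L else -1L
  rrn_span <- c(NA_integer_, NA_integer_)
  rrn_seq <- ""
  while (TRUE) {
    gap <- sample(20:100, 1)
    if (rrn_at >= 0 && pos >= rrn_at && is.na(rrn_span[1])) {
      rrn_seq <- random_dna(rrn_len, gc)
      pieces <- c(pieces, rrn_seq)
      rrn_span <- c(pos, pos + rrn_len)
      pos <- pos + rrn_len
      next
    }
    aa_len <- max(100L, min(600L, as.integer(round(rnorm(1, 300, 60)))))
    glen <- 3L * aa_len + 3L # start + body + stop (start within the aa_len)
    if (pos + gap + glen > L - 20L) break
    pieces <- c(pieces, random_dna(gap, gc))
    pos <- pos + gap
    body <- paste(sample_codons(aa_len - 1L, gc), collapse = "")
    stopc <- sample(STOPS, 1, prob = c(0.6, 0.2, 0.2))
    gdna <- paste0("ATG", body, stopc)
    pep <- as.character(Biostrings::translate(Biostrings::DNAString(
      substr(gdna, 1, nchar(gdna) - 3))))
    strand <- sample(c("+", "-"), 1)
    genes[[length(genes) + 1L]] <- data.frame(
      start = pos, end = pos + glen, strand = strand, peptide = pep,
      stringsAsFactors = FALSE)
    pieces <- c(pieces, if (strand == "+") gdna else revcomp(gdna))
    pos <- pos + glen
  }
  if (length(genes) < 5L)
    stop("scenario cannot host at least 5 ORFs on the target")
  pieces <- c(pieces, random_dna(L - pos, gc))
  target <- paste(pieces, collapse = "")
  genes <- do.call(rbind, genes)

  # --- reference panel ------------------------------------------------------
  refs <- character(0)
  for (d in sc@refDivergences) {
    gc_ref <- min(0.50, gc + 0.7 * d) # free-living relatives are GC-richer
    rpieces <- character()
    rpos <- 0L
    # rebuild with the same layout: intergenic randomized, genes mutated
    # at the amino-acid level and back-translated under the reference bias
    bounds <- rbind(
      if (!is.na(rrn_span[1])) data.frame(start = rrn_span[1], end = rrn_span[2],
                                          kind = "rrn", idx = 0L),
      data.frame(start = genes$start, end = genes$end, kind = "gene",
                 idx = seq_len(nrow(genes))))
    bounds <- bounds[order(bounds$start), ]
    for (k in seq_len(nrow(bounds))) {
      b <- bounds[k, ]
      if (b$start > rpos) rpieces <- c(rpieces, random_dna(b$start - rpos, gc_ref))
      if (b$kind == "rrn") {
        rpieces <- c(rpieces, mutate_dna(rrn_seq, 0.8 * d))
      } else {
        g <- genes[b$idx, ]
        pep2 <- mutate_peptide(g$peptide, d)
        gdna2 <- paste0(back_translate(pep2, gc_ref),
                        sample(STOPS, 1, prob = c(0.6, 0.2, 0.2)))
        rpieces <- c(rpieces, if (g$strand == "+") gdna2 else revcomp(gdna2))
      }
      rpos <- b$end
    }
    if (rpos < L) rpieces <- c(rpieces, random_dna(L - rpos, gc_ref))
    refs[sprintf("%.2f", d)] <- paste(rpieces, collapse = "")
  }

  # --- host, mitochondrion, rRNA, contaminant -------------------------------
  host_rrna <- if (rrn_len > 0)
    break_similar_windows(mutate_dna(rrn_seq, 0.30), rrn_seq)
  else random_dna(max(sc@rrnaLen, 300L), 0.45)
  if (sc@rrnaLen > nchar(host_rrna))
    host_rrna <- paste0(host_rrna, random_dna(sc@rrnaLen - nchar(host_rrna), 0.45))
  host_core <- random_dna(sc@hostLen - nchar(host_rrna), 0.40)
  at <- max(1L, sc@hostLen %/% 3L)
  host <- paste0(substr(host_core, 1, at), host_rrna,
                 substr(host_core, at + 1, nchar(host_core)))

  # mitochondrion: AT-rich with one degenerate shared gene family
  gi <- which.max(nchar(genes$peptide))
  mito_pep <- mutate_peptide(genes$peptide[gi], 0.40)
  mito_gene <- paste0(back_translate(mito_pep, 0.20), "TAA")
  mito_core <- random_dna(max(0L, sc@mitoLen - nchar(mito_gene)), 0.20)
  mat <- max(1L, nchar(mito_core) %/% 2L)
  mito <- paste0(substr(mito_core, 1, mat), mito_gene,
                 substr(mito_core, mat + 1, nchar(mito_core)))

  # every constructed homolog is kept below a 95%-identity 60-nt window
  # against its target template (the construction invariant that keeps
  # decoys from being mistaken for the target itself)
  contaminant <- ""
  if (sc@contaminantLen > 0 && rrn_len > 0) {
    core_len <- min(rrn_len, sc@contaminantLen)
    core <- break_similar_windows(mutate_dna(substr(rrn_seq, 1, core_len), 0.15),
                                  substr(rrn_seq, 1, core_len))
    pad <- sc@contaminantLen - core_len
    contaminant <- paste0(core, random_dna(pad, 0.45))
  }

  new("GenomeSet",
      target = Biostrings::DNAString(target),
      refs = Biostrings::DNAStringSet(refs),
      host = Biostrings::DNAString(host),
      mito = Biostrings::DNAString(mito),
      hostRrna = Biostrings::DNAString(host_rrna),
      contaminant = Biostrings::DNAString(contaminant),
      genes = genes,
      rrnRegion = as.integer(rrn_span))
}

#' Simulate paired-end reads from one source sequence
#'
#' Low-level fragment sampler: inserts are Normal(insertMean, insertSD)
#' truncated to [readLen, 3 * insertMean]; the forward mate reads the
#' fragment 5' end, the reverse mate is the reverse complement of the 3'
#' end; substitution errors are i.i.d. per base. On a circular source
#' fragments may span the origin.
#'
#' @param seq source sequence (character or `DNAString`).
#' @param nPairs number of pairs.
#' @param readLen,insertMean,insertSD read geometry.
#' @param circular treat `seq` as circular.
#' @param perBaseError substitution rate.
#' @return list with character vectors `fwd` and `rev`.
#' @export
simulateReadPairs <- function(seq, nPairs, readLen = 100L, insertMean = 230,
                              insertSD = 25, circular = FALSE,
                              perBaseError = 0) {
  seq <- as.character(seq)
  L <- nchar(seq)
  if (nPairs <= 0) return(list(fwd = character(0), rev = character(0)))
  max_ins <- if (circular) 3L * as.integer(insertMean) else
    min(3L * as.integer(insertMean), L)
  ins <- pmin(pmax(as.integer(round(rnorm(nPairs, insertMean, insertSD))),
                   as.integer(readLen)), max_ins)
  if (circular) {
    start <- sample.int(L, nPairs, replace = TRUE) # 1-based
    big <- paste0(seq, substr(seq, 1, 3L * as.integer(insertMean)))
  } else {
    start <- vapply(L - ins + 1L, function(m) sample.int(m, 1), integer(1))
    big <- seq
  }
  fwd <- substring(big, start, start + readLen - 1L)
  rev <- revcomp(substring(big, start + ins - readLen, start + ins - 1L))
  if (perBaseError > 0) {
    for (mate in 1:2) {
      v <- if (mate == 1) fwd else rev
      nerr <- rbinom(nPairs, readLen, perBaseError)
      idx <- rep(seq_len(nPairs), nerr)
      if (length(idx)) {
        pos <- vapply(idx, function(i) sample.int(readLen, 1), integer(1))
        base <- sample(NTS, length(idx), replace = TRUE)
        v <- as.character(cpp_substitute(v, idx, pos, base))
      }
      if (mate == 1) fwd <- v else rev <- v
    }
  }
  list(fwd = fwd, rev = rev)
}

#' Simulate a mixed paired-end library at a requested purity
#'
#' The number of target pairs is `round(targetDepth * targetLen /
#' (2 * readLen))`; the library total is `round(targetPairs / purity)`;
#' the non-target remainder is split host : mito : rrna : contaminant
#' according to `scenario@nonTargetMix`. Qualities are drawn so that a
#' small configurable fraction of reads fails the Q27/80-nt rule.
#' Deterministic under the scenario seed; pair order is a fixed permutation.
#'
#' @param gs a [GenomeSet-class] from the same scenario.
#' @param scenario the [SimScenario()].
#' @return A [PairedReads-class] object with truth labels.
#' @export
simulateLibrary <- function(gs, scenario) {
  stopifnot(is(gs, "GenomeSet"), is(scenario, "SimScenario"))
  if (scenario@targetDepth <= 0) stop("targetDepth must be positive")
  with_seed(scenario@seed + 1000L, .simulate_library(gs, scenario))
}

.simulate_library <- function(gs, sc) {
  tlen <- length(gs@target)
  n_target <- as.integer(round(sc@targetDepth * tlen / (2 * sc@readLen)))
  if (n_target < 1) stop("scenario yields no target pairs")
  n_total <- as.integer(round(n_target / sc@purity))
  n_other <- n_total - n_target

  mix <- sc@nonTargetMix
  names(mix) <- c("host", "mito", "rrna", "contaminant")
  if (length(gs@contaminant) == 0) mix["contaminant"] <- 0
  if (sum(mix) == 0) mix["host"] <- 1
  mix <- mix / sum(mix)
  counts <- floor(mix * n_other)
  rem <- n_other - sum(counts)
  if (rem > 0) { # assign remainders by largest fractional part
    fr <- order(mix * n_other - counts, decreasing = TRUE)
    counts[fr[seq_len(rem)]] <- counts[fr[seq_len(rem)]] + 1
  }

  src <- list(
    target = list(seq = as.character(gs@target), n = n_target, circ = TRUE),
    host = list(seq = as.character(gs@host), n = counts[["host"]], circ = FALSE),
    mito = list(seq = as.character(gs@mito), n = counts[["mito"]], circ = FALSE),
    rrna = list(seq = as.character(gs@hostRrna), n = counts[["rrna"]], circ = FALSE),
    contaminant = list(seq = as.character(gs@contaminant),
                       n = counts[["contaminant"]], circ = FALSE))

  fwd <- rev <- truth <- character(0)
  for (nm in names(src)) {
    s <- src[[nm]]
    if (s$n <= 0) next
    rp <- simulateReadPairs(s$seq, s$n, sc@readLen, sc@insertMean, sc@insertSD,
                            circular = s$circ, perBaseError = sc@perBaseError)
    fwd <- c(fwd, rp$fwd); rev <- c(rev, rp$rev)
    truth <- c(truth, rep(nm, s$n))
  }
  n <- length(fwd)

  # qualities: solid reads get a uniform per-read quality; a configurable
  # tail gets either a low-quality 3' run (trims below 80 nt) or borderline
  # per-base qualities whose mean straddles 27
  qual_for <- function(seqs) {
    lens <- nchar(seqs)
    qr <- sample(33:40, n, replace = TRUE)
    quals <- vapply(seq_len(n), function(i)
      strrep(intToUtf8(qr[i] + 33L), lens[i]), character(1))
    n_fail <- as.integer(round(sc@qcFailFrac * n))
    if (n_fail > 0) {
      bad <- sample.int(n, n_fail)
      half <- length(bad) %/% 2L
      for (i in bad[seq_len(half)]) { # low-quality 3' tail
        t <- sample(40:79, 1)
        t <- min(t, lens[i])
        lowq <- sample(10:25, 1)
        quals[i] <- paste0(strrep(intToUtf8(qr[i] + 33L), t),
                           strrep(intToUtf8(lowq + 33L), lens[i] - t))
      }
      for (i in bad[-seq_len(half)]) { # borderline mean quality
        qs <- sample(23:31, lens[i], replace = TRUE)
        qs[lens[i]] <- 31L
        quals[i] <- intToUtf8(qs + 33L, multiple = FALSE)
      }
    }
    quals
  }
  qual1 <- qual_for(fwd)
  qual2 <- qual_for(rev)

  perm <- sample.int(n)
  PairedReads(pairId = sprintf("p%07d", seq_len(n)),
              seq1 = fwd[perm], qual1 = qual1[perm],
              seq2 = rev[perm], qual2 = qual2[perm],
              truth = truth[perm])
}
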