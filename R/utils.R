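# Internal helpers: RNG hygiene, codon machinery, random sequence generation.

NTS <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")

# run expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  force(expr)
}

nt_probs <- function(gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  p / sum(p)
}

random_dna <- function(n, gc) {
  if (n <= 0) return("")
  paste(sample(NTS, n, replace = TRUE, prob = nt_probs(gc)), collapse = "")
}

# all 61 sense codons and their translations
codon_table <- local({
  cods <- as.vector(outer(as.vector(outer(NTS, NTS, paste0)), NTS, paste0))
  cods <- cods[!cods %in% STOPS]
  aas <- vapply(cods, function(cd) {
    as.character(Biostrings::translate(Biostrings::DNAString(cd),
                                       no.init.codon = TRUE))
  }, character(1))
  data.frame(codon = cods, aa = unname(aas), stringsAsFactors = FALSE)
})

# codon sampling weights under a genome-wide GC bias
codon_weights <- function(gc) {
  p <- nt_probs(gc)
  w <- vapply(codon_table$codon, function(cd) {
    prod(p[strsplit(cd, "")[[1]]])
  }, numeric(1))
  unname(w / sum(w))
}

# sample n sense codons under the bias; returns character vector of codons
sample_codons <- function(n, gc) {
  sample(codon_table$codon, n, replace = TRUE, prob = codon_weights(gc))
}

# back-translate a peptide, sampling synonymous codons under the bias
back_translate <- function(peptide, gc) {
  aa <- strsplit(peptide, "")[[1]]
  w <- codon_weights(gc)
  cods <- vapply(aa, function(a) {
    i <- which(codon_table$aa == a)
    if (!length(i)) stop("cannot back-translate residue ", a)
    if (length(i) == 1) codon_table$codon[i]
    else sample(codon_table$codon[i], 1, prob = w[i])
  }, character(1))
  paste(cods, collapse = "")
}

# conservative amino-acid substitution partners (positive BLOSUM62 pairs)
AA_PARTNERS <- list(
  A = c("S", "T", "G"), R = c("K", "Q"), N = c("D", "S", "H"),
  D = c("E", "N"), C = c("S", "A"), Q = c("E", "K", "R"),
  E = c("D", "Q", "K"), G = c("A", "S"), H = c("N", "Y", "Q"),
  I = c("V", "L", "M"), L = c("I", "M", "V", "F"), K = c("R", "Q", "E"),
  M = c("L", "I", "V"), F = c("Y", "L", "W"), P = c("A", "S"),
  S = c("T", "A", "N"), T = c("S", "A", "V"), W = c("Y", "F"),
  Y = c("F", "H", "W"), V = c("I", "L", "M"))
AA20 <- names(AA_PARTNERS)

# mutate a peptide at amino-acid rate d with a similarity-biased scheme:
# 70% of substitutions draw from conservative partners, 30% uniformly.
mutate_peptide <- function(peptide, d) {
  if (d <= 0) return(peptide)
  aa <- strsplit(peptide, "")[[1]]
  hit <- which(runif(length(aa)) < d)
  hit <- hit[hit > 1] # preserve the initiator methionine
  for (i in hit) {
    a <- aa[i]
    partners <- AA_PARTNERS[[a]]
    aa[i] <- if (!is.null(partners) && runif(1) < 0.7) {
      if (length(partners) == 1) partners else sample(partners, 1)
    } else {
      others <- setdiff(AA20, a)
      sample(others, 1)
    }
  }
  paste(aa, collapse = "")
}

# mutate DNA at per-base rate d (substitutions to a uniform different base)
mutate_dna <- function(seq, d) {
  if (d <= 0 || !nzchar(seq)) return(seq)
  s <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(s)) < d)
  for (i in hit) s[i] <- sample(setdiff(NTS, s[i]), 1)
  paste(s, collapse = "")
}

revcomp <- function(x) as.character(cpp_revcomp(x))

gc_frac <- function(seq) {
  s <- strsplit(seq, "")[[1]]
  mean(s %in% c("G", "C"))
}

# max identity of any w-nt window along the construction diagonal of a
# mutated copy vs its template (both same length)
max_window_identity <- function(a, b, w = 60L) {
  sa <- strsplit(a, "")[[1]]; sb <- strsplit(b, "")[[1]]
  n <- min(length(sa), length(sb))
  if (n < w) return(mean(sa[seq_len(n)] == sb[seq_len(n)]))
  eq <- as.integer(sa[seq_len(n)] == sb[seq_len(n)])
  cs <- c(0L, cumsum(eq))
  max((cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]) / w)
}

# force every w-nt window of seq below the identity cap against its template
# by adding substitutions inside the most conserved window until it complies
# (a diverged homolog at, say, 85% identity otherwise often carries chance
# windows above 95%)
break_similar_windows <- function(seq, template, w = 60L, cap = 0.95) {
  sa <- strsplit(seq, "")[[1]]; sb <- strsplit(template, "")[[1]]
  n <- min(length(sa), length(sb))
  if (n < 1) return(seq)
  limit <- ceiling(cap * w) # matches allowed is limit - 1
  for (round in seq_len(500)) {
    eq <- as.integer(sa[seq_len(n)] == sb[seq_len(n)])
    if (n < w) {
      if (sum(eq) / n < cap) break
      win <- c(1L, n)
    } else {
      cs <- c(0L, cumsum(eq))
      sums <- cs[(w + 1):(n + 1)] - cs[1:(n - w + 1)]
      i <- which.max(sums)
      if (sums[i] < limit) break
      win <- c(i, i + w - 1L)
    }
    same <- which(eq[win[1]:win[2]] == 1L) + win[1] - 1L
    hit <- sample(same, min(3L, length(same)))
    for (p in hit) sa[p] <- sample(setdiff(NTS, sa[p]), 1)
  }
  paste(sa, collapse = "")
}
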