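# Shared fixture builders: deterministic reads, libraries and tiny genomes.

NTS4 <- c("A", "C", "G", "T")

rand_dna <- function(n, gc = 0.5, seed = NULL) {
  f <- function() paste(sample(NTS4, n, replace = TRUE,
                               prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                        (1 - gc) / 2)), collapse = "")
  if (is.null(seed)) f() else endosift:::with_seed(seed, f())
}

rc <- function(x) endosift:::revcomp(x)

q_string <- function(len, q = 40L) strrep(intToUtf8(q + 33L), len)

# error-free pairs tiling a linear source, termini guaranteed covered
tiling_pairs <- function(src, n_pairs, read_len = 100L, insert = 230L,
                         seed = 1L) {
  L <- nchar(src)
  stopifnot(L >= insert)
  endosift:::with_seed(seed, {
    start <- c(1L, L - insert + 1L,
               sample.int(L - insert + 1L, n_pairs - 2L, replace = TRUE))
    fwd <- substring(src, start, start + read_len - 1L)
    rev <- rc(substring(src, start + insert - read_len, start + insert - 1L))
    PairedReads(sprintf("p%05d", seq_len(n_pairs)), fwd,
                rep(q_string(read_len), n_pairs), rev,
                rep(q_string(read_len), n_pairs))
  })
}

# small default scenario used across unit tests (fast; not the acceptance
# study conditions)
small_scenario <- function(seed = 1L, ...) {
  args <- list(seed = seed, targetLen = 20000L, hostLen = 50000L,
               mitoLen = 8000L, refDivergences = c(0.02, 0.17, 0.21, 0.26),
               purity = 0.285, targetDepth = 20)
  args <- utils::modifyList(args, list(...))
  do.call(SimScenario, args)
}

# phred string from integer vector
phred <- function(q) intToUtf8(q + 33L, multiple = FALSE)

make_read_pair <- function(id, s1, q1, s2, q2) {
  PairedReads(id, s1, q1, s2, q2)
}
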