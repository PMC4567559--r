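# FASTQ / FASTA / TSV interfaces (Biostrings-backed).

#' Write a paired library as two FASTQ files
#'
#' Standard 4-line FASTQ records, Phred+33; mate ids are `<pairId>/1` and
#' `<pairId>/2`. Truth labels are never written to FASTQ (see
#' [writeTruth()]).
#'
#' @param pairs a [PairedReads-class] object.
#' @param r1,r2 output paths.
#' @return Invisibly, the two paths.
#' @export
writeLibrary <- function(pairs, r1, r2) {
  stopifnot(is(pairs, "PairedReads"))
  if (length(pairs) == 0) stop("refusing to write an empty library")
  s1 <- Biostrings::DNAStringSet(pairs@seq1)
  names(s1) <- paste0(pairs@pairId, "/1")
  s2 <- Biostrings::DNAStringSet(pairs@seq2)
  names(s2) <- paste0(pairs@pairId, "/2")
  Biostrings::writeXStringSet(s1, r1, format = "fastq",
                              qualities = Biostrings::BStringSet(pairs@qual1))
  Biostrings::writeXStringSet(s2, r2, format = "fastq",
                              qualities = Biostrings::BStringSet(pairs@qual2))
  invisible(c(r1, r2))
}

#' Read a paired library from two FASTQ files
#'
#' @param r1,r2 FASTQ paths (mate order must correspond).
#' @return A [PairedReads-class] object (truth labels `NA`).
#' @export
readLibrary <- function(r1, r2) {
  x1 <- Biostrings::readDNAStringSet(r1, format = "fastq", with.qualities = TRUE)
  x2 <- Biostrings::readDNAStringSet(r2, format = "fastq", with.qualities = TRUE)
  if (length(x1) != length(x2)) stop("R1/R2 record counts differ")
  id <- sub("/[12]$", "", names(x1))
  id2 <- sub("/[12]$", "", names(x2))
  if (!identical(id, id2)) stop("R1/R2 pair ids do not correspond")
  PairedReads(pairId = id,
              seq1 = as.character(x1), qual1 = as.character(mcols(x1)$qualities),
              seq2 = as.character(x2), qual2 = as.character(mcols(x2)$qualities))
}

#' Write / read the simulation truth table
#'
#' A headered TSV with columns `pair_id` and `truth`.
#'
#' @param pairs a [PairedReads-class] object with truth labels.
#' @param path output path.
#' @export
writeTruth <- function(pairs, path) {
  stopifnot(is(pairs, "PairedReads"))
  write.table(data.frame(pair_id = pairs@pairId, truth = pairs@truth),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  setNames(df$truth, df$pair_id)
}

#' Write assembly contigs as FASTA
#'
#' @param assembly an [Assembly-class] or named `DNAStringSet`.
#' @param path output path.
#' @export
writeContigs <- function(assembly, path) {
  x <- if (is(assembly, "Assembly")) contigs(assembly) else assembly
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

# coerce a contig argument to a named DNAStringSet
as_contig_set <- function(x) {
  if (is(x, "Assembly")) return(contigs(x))
  if (is(x, "DNAStringSet")) {
    if (is.null(names(x))) names(x) <- sprintf("ctg%05d", seq_along(x))
    return(x)
  }
  if (is.character(x)) {
    nm <- names(x)
    if (is.null(nm)) nm <- sprintf("ctg%05d", seq_along(x))
    y <- Biostrings::DNAStringSet(x)
    names(y) <- nm
    return(y)
  }
  if (is(x, "DNAString")) return(Biostrings::DNAStringSet(setNames(
    as.character(x), "seq1")))
  stop("cannot interpret contigs argument of class ", class(x)[1])
}
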