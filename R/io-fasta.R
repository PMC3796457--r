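# FASTA input/output, backed by Biostrings.

#' Read a FASTA file into a named character vector
#'
#' Sequence names are the header words up to the first whitespace, in
#' order of first appearance. Sequences are uppercased.
#'
#' @param path Path to a (possibly multi-record) FASTA file.
#' @return Named character vector, one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (file.size(path) == 0L) stop("empty FASTA file: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (!startsWith(first, ">")) {
    stop("malformed FASTA header at line 1 of ", path, call. = FALSE)
  }
  x <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs Named character vector of nucleotide sequences.
#' @param path Output path.
#' @param width Line-wrap width (bases per line).
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = width)
  invisible(path)
}
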