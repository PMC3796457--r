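# Strand-aware scanning of sequences for a degenerate motif.

#' Scan a nucleotide sequence for a degenerate motif
#'
#' Reports every offset at which the motif matches on the requested
#' strand(s). A minus-strand hit is an offset where the reverse-complement
#' pattern matches the plus-strand sequence; hits are always reported in
#' plus-strand coordinates. Overlapping matches are all reported. `N`
#' bases never match.
#'
#' @param seq A single nucleotide string over A/C/G/T/N
#'   (case-insensitive).
#' @param motif An [iupac_motif()] or IUPAC pattern string.
#' @param strands `"both"` (default), `"plus"` or `"minus"`.
#' @return A data.frame with columns `offset` (0-based start within
#'   `seq`), `strand` (`"+"`/`"-"`) and `matched` (the literal plus-strand
#'   substring), sorted by offset then strand (`"+"` before `"-"`).
#' @examples
#' scan_sequence("AGAATAT", "VGAATAW")       # one plus-strand hit
#' scan_sequence("ATATTCT", "VGAATAW")       # one minus-strand hit
#' @export
scan_sequence <- function(seq, motif = iupac_motif(),
                          strands = c("both", "plus", "minus")) {
  strands <- match.arg(strands)
  stopifnot(is.character(seq), length(seq) == 1L)
  motif <- as_motif(motif)
  seq <- toupper(seq)
  k <- length(motif$sets)

  hit_offsets <- function(pattern_regex) {
    if (nchar(seq) < k) return(integer(0))
    # lookahead makes gregexpr return overlapping match starts
    m <- gregexpr(paste0("(?=", pattern_regex, ")"), seq, perl = TRUE)[[1L]]
    if (m[1L] == -1L) integer(0) else as.integer(m) - 1L
  }

  out <- list()
  if (strands %in% c("both", "plus")) {
    off <- hit_offsets(motif_regex(motif))
    if (length(off)) {
      out[["+"]] <- data.frame(offset = off, strand = "+",
                               stringsAsFactors = FALSE)
    }
  }
  if (strands %in% c("both", "minus")) {
    off <- hit_offsets(motif_regex(reverse_complement_motif(motif)))
    if (length(off)) {
      out[["-"]] <- data.frame(offset = off, strand = "-",
                               stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(out)) do.call(rbind, out) else
    data.frame(offset = integer(0), strand = character(0),
               stringsAsFactors = FALSE)
  hits <- hits[order(hits$offset, match(hits$strand, c("+", "-"))), ,
               drop = FALSE]
  hits$matched <- if (nrow(hits) > 0L) {
    substring(seq, hits$offset + 1L, hits$offset + k)
  } else {
    character(0)
  }
  rownames(hits) <- NULL
  hits
}

#' Partition binding regions by motif presence
#'
#' Extracts each region's sequence from the genome, scans it on both
#' strands (by default) and splits the region set into motif-containing
#' and motif-free subsets. A region is motif-containing iff it has at
#' least one hit on either scanned strand fully inside `[start, end)`.
#'
#' @param regions A binding-region data.frame (see [read_region_table()]).
#' @param genome Named character vector of chromosome sequences, as
#'   returned by [read_fasta()].
#' @param motif An [iupac_motif()] or IUPAC pattern string.
#' @param strands Strands to scan, as in [scan_sequence()].
#' @return A list with elements `with_motif`, `without_motif` (disjoint
#'   subsets of `regions`, input order preserved) and `hits` (data.frame
#'   `region_id`, `offset` — genomic, 0-based —, `strand`, `matched`).
#' @export
regions_with_motif <- function(regions, genome, motif = iupac_motif(),
                               strands = "both") {
  motif <- as_motif(motif)
  stopifnot(is.data.frame(regions), is.character(genome))
  missing_chr <- setdiff(unique(regions$chrom), names(genome))
  if (length(missing_chr) > 0L) {
    stop("region chromosome(s) absent from genome: ",
         paste(missing_chr, collapse = ", "), call. = FALSE)
  }
  lens <- nchar(genome)[regions$chrom]
  bad <- which(regions$start < 0L | regions$end > lens)
  if (length(bad) > 0L) {
    stop("region(s) outside sequence bounds: ",
         paste(regions$region_id[bad], collapse = ", "), call. = FALSE)
  }
  hit_list <- vector("list", nrow(regions))
  has <- logical(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    sub <- substring(genome[[regions$chrom[i]]],
                     regions$start[i] + 1L, regions$end[i])
    h <- scan_sequence(sub, motif, strands)
    has[i] <- nrow(h) > 0L
    if (nrow(h) > 0L) {
      h <- cbind(region_id = regions$region_id[i], h,
                 stringsAsFactors = FALSE)
      h$offset <- h$offset + regions$start[i]
      hit_list[[i]] <- h
    }
  }
  hits <- do.call(rbind, hit_list[!vapply(hit_list, is.null, TRUE)])
  if (is.null(hits)) {
    hits <- data.frame(region_id = character(0), offset = integer(0),
                       strand = character(0), matched = character(0),
                       stringsAsFactors = FALSE)
  }
  rownames(hits) <- NULL
  list(with_motif = regions[has, , drop = FALSE],
       without_motif = regions[!has, , drop = FALSE],
       hits = hits)
}
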