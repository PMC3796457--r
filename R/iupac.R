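# IUPAC degenerate nucleotide codes and motif objects.

# The 15 standard IUPAC nucleotide codes mapped to their base sets.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"),
  H = c("A", "C", "T"), V = c("A", "C", "G"),
  N = c("A", "C", "G", "T")
)

BASE_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

#' Expand an IUPAC pattern into per-position allowed-base sets
#'
#' @param pattern A string over the 15 IUPAC nucleotide codes
#'   (case-insensitive), e.g. `"VGAATAW"`.
#' @return A list with one character vector of allowed bases (subset of
#'   A, C, G, T) per pattern position.
#' @examples
#' expand_iupac("VGAATAW")
#' @export
expand_iupac <- function(pattern) {
  stopifnot(is.character(pattern), length(pattern) == 1L)
  if (nchar(pattern) < 1L) {
    stop("motif pattern must have length >= 1", call. = FALSE)
  }
  syms <- strsplit(toupper(pattern), "")[[1L]]
  unknown <- setdiff(unique(syms), names(IUPAC_SETS))
  if (length(unknown) > 0L) {
    stop("unknown IUPAC symbol(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  unname(IUPAC_SETS[syms])
}

#' Construct a degenerate motif
#'
#' Bundles an IUPAC pattern with its per-position allowed-base sets.
#'
#' @param pattern IUPAC string; the default is the binding motif used
#'   throughout the pipeline.
#' @return An object of class `iupac_motif` with elements `pattern` and
#'   `sets`.
#' @examples
#' m <- iupac_motif("VGAATAW")
#' reverse_complement_motif(m)$pattern
#' @export
iupac_motif <- function(pattern = "VGAATAW") {
  structure(
    list(pattern = toupper(pattern), sets = expand_iupac(pattern)),
    class = "iupac_motif"
  )
}

#' @export
print.iupac_motif <- function(x, ...) {
  cat("<iupac_motif>", x$pattern, "(length", length(x$sets), ")\n")
  invisible(x)
}

as_motif <- function(motif) {
  if (inherits(motif, "iupac_motif")) motif else iupac_motif(motif)
}

# Re-encode a set of bases as the minimal IUPAC symbol.
encode_iupac_set <- function(bases) {
  key <- paste(sort(unique(bases)), collapse = "")
  keys <- vapply(IUPAC_SETS, function(b) paste(sort(b), collapse = ""), "")
  sym <- names(keys)[match(key, keys)]
  if (is.na(sym)) stop("no IUPAC symbol for base set {", key, "}")
  sym
}

#' Reverse-complement a degenerate motif
#'
#' Each position's allowed-base set is complemented base-by-base, the
#' positions are reversed, and the result re-encoded as IUPAC symbols.
#' Applying the operation twice is the identity.
#'
#' @param motif An [iupac_motif()] or an IUPAC pattern string.
#' @return An `iupac_motif` for the reverse-complement pattern.
#' @examples
#' reverse_complement_motif("VGAATAW")$pattern # "WTATTCB"
#' @export
reverse_complement_motif <- function(motif) {
  motif <- as_motif(motif)
  rc_sets <- rev(lapply(motif$sets, function(b) unname(BASE_COMPLEMENT[b])))
  pattern <- paste(vapply(rc_sets, encode_iupac_set, ""), collapse = "")
  iupac_motif(pattern)
}

# Translate a motif into a PCRE character-class regex, e.g. "[ACG]GAATA[AT]".
motif_regex <- function(motif) {
  motif <- as_motif(motif)
  paste(vapply(motif$sets, function(b) {
    if (length(b) == 1L) b else paste0("[", paste(b, collapse = ""), "]")
  }, ""), collapse = "")
}

# Reverse-complement a concrete nucleotide string (A/C/G/T/N).
revcomp <- function(seq) {
  comp <- c(BASE_COMPLEMENT, N = "N")
  chars <- strsplit(toupper(seq), "")[[1L]]
  paste(rev(unname(comp[chars])), collapse = "")
}
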