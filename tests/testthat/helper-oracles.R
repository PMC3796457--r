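# Independent oracles used across test files. These deliberately avoid
# the code paths they check: brute-force enumeration only.

# Brute-force motif scan: enumerate every offset x strand and test base
# membership against the expanded IUPAC sets.
oracle_scan <- function(seq, pattern, strands = c("+", "-")) {
  seq <- toupper(seq)
  chars <- strsplit(seq, "")[[1L]]
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  sets <- kanseek::expand_iupac(pattern)
  k <- length(sets)
  rows <- list()
  n <- nchar(seq)
  if (n >= k) {
    for (off in 0:(n - k)) {
      win <- chars[(off + 1):(off + k)]
      if ("+" %in% strands &&
          all(mapply(function(b, s) b %in% s, win, sets))) {
        rows[[length(rows) + 1L]] <-
          data.frame(offset = off, strand = "+",
                     matched = paste(win, collapse = ""),
                     stringsAsFactors = FALSE)
      }
      if ("-" %in% strands) {
        # minus-strand match: the reverse complement of the window
        # matches the pattern read forwards
        rcwin <- rev(unname(comp[win]))
        if (all(mapply(function(b, s) b %in% s, rcwin, sets))) {
          rows[[length(rows) + 1L]] <-
            data.frame(offset = off, strand = "-",
                       matched = paste(win, collapse = ""),
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(offset = integer(0), strand = character(0),
               matched = character(0), stringsAsFactors = FALSE)
  out <- out[order(out$offset, match(out$strand, c("+", "-"))), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

# Brute-force minimum pair distance over the cross product of two site
# vectors.
oracle_min_dist <- function(a, b) {
  best <- Inf
  for (x in a) for (y in b) best <- min(best, abs(x - y))
  as.integer(best)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Tiny deterministic region table used by several files.
toy_regions <- function() {
  data.frame(
    region_id = c("r1", "r2", "r3"),
    chrom = "chr1",
    start = c(0L, 100L, 200L),
    end = c(50L, 150L, 260L),
    summit = c(25L, 125L, 230L),
    enrichment_1 = c(4.3, 1.8, 2.9),
    enrichment_2 = c(2.7, 6.5, 2.9),
    fdr_1 = c(8.2e-4, 1.69e-30, 0.5),
    fdr_2 = c(3.93e-4, 3.33e-23, 0.5),
    rank = c(1L, 2L, 3L),
    stringsAsFactors = FALSE
  )
}
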