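# GFF3 gene-model input/output, backed by rtracklayer.
#
# Internal convention is 0-based half-open; GFF3 is 1-based inclusive.
# A gene model is one row: gene body span plus the union extent of the
# gene's CDS features.

#' Read gene models from a GFF3 file
#'
#' Expects `gene` features carrying an `ID` attribute and `CDS` features
#' carrying a `Parent` attribute naming their gene. The CDS span of a
#' gene is the union extent of its CDS features; genes without CDS
#' features use their body span as the CDS span.
#'
#' @param path Path to a GFF3 file.
#' @return A data.frame with columns `gene_id`, `chrom`, `strand`,
#'   `body_start`, `body_end`, `cds_start`, `cds_end` (0-based
#'   half-open).
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  gr <- rtracklayer::import(path, format = "GFF3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", path, call. = FALSE)
  strand <- as.character(GenomicRanges::strand(genes))
  if (any(!strand %in% c("+", "-"))) {
    bad <- genes$ID[!strand %in% c("+", "-")]
    stop("gene(s) with missing strand: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    gene_id = as.character(genes$ID),
    chrom = as.character(GenomicRanges::seqnames(genes)),
    strand = strand,
    body_start = GenomicRanges::start(genes) - 1L,
    body_end = GenomicRanges::end(genes),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$gene_id)) {
    stop("duplicated gene IDs in ", path, call. = FALSE)
  }
  cds <- gr[type == "CDS"]
  parent <- vapply(as.list(cds$Parent), function(p) p[1L], "")
  out$cds_start <- out$body_start
  out$cds_end <- out$body_end
  if (length(cds) > 0L) {
    cs <- tapply(GenomicRanges::start(cds) - 1L, parent, min)
    ce <- tapply(GenomicRanges::end(cds), parent, max)
    idx <- match(names(cs), out$gene_id)
    if (anyNA(idx)) {
      stop("CDS with unknown Parent gene: ",
           paste(names(cs)[is.na(idx)], collapse = ", "), call. = FALSE)
    }
    out$cds_start[idx] <- as.integer(cs)
    out$cds_end[idx] <- as.integer(ce)
  }
  bad <- out$cds_start < out$body_start | out$cds_end > out$body_end |
    out$cds_start >= out$cds_end
  if (any(bad)) {
    stop("CDS outside gene body for: ",
         paste(out$gene_id[bad], collapse = ", "), call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Write gene models to a GFF3 file
#'
#' Emits one `gene` and one `CDS` feature per model, converting the
#' internal 0-based half-open spans back to 1-based inclusive.
#'
#' @param genes Gene-model data.frame as returned by [read_gff3()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(genes, path) {
  stopifnot(is.data.frame(genes), nrow(genes) > 0L)
  gene_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$body_start + 1L, genes$body_end),
    strand = genes$strand,
    type = "gene",
    ID = genes$gene_id
  )
  cds_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(genes$cds_start + 1L, genes$cds_end),
    strand = genes$strand,
    type = "CDS",
    ID = paste0(genes$gene_id, ".cds"),
    Parent = genes$gene_id,
    phase = 0L
  )
  S4Vectors::mcols(gene_gr)$Parent <- NA_character_
  S4Vectors::mcols(gene_gr)$phase <- NA_integer_
  gr <- c(gene_gr, cds_gr)
  rtracklayer::export(gr, path, format = "GFF3")
  invisible(path)
}
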