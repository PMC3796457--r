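# Tab-separated table input/output, tolerant of the printed-table
# dialect: comma decimal separators ("4,3"), comma-mantissa scientific
# notation ("8,20E-04"), "yes"/"-" flag columns, blank continuation
# cells.

#' Parse numeric cells that may use comma decimal separators
#'
#' `"4,3"` parses as 4.3 and `"2,66E-39"` as 2.66e-39; dot-decimal cells
#' parse unchanged. Blank cells give `NA`.
#'
#' @param x Character vector of cells.
#' @param what Label used in error messages.
#' @return Numeric vector; non-numeric non-blank cells raise an error
#'   naming the offending element indices.
#' @export
parse_numeric_cell <- function(x, what = "cell") {
  x <- trimws(as.character(x))
  blank <- is.na(x) | x == ""
  y <- suppressWarnings(as.numeric(gsub(",", ".", x, fixed = TRUE)))
  bad <- which(!blank & is.na(y))
  if (length(bad) > 0L) {
    stop("non-numeric ", what, " at row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  y
}

parse_flag_cell <- function(x, what = "flag") {
  x <- trimws(as.character(x))
  x[is.na(x) | x == ""] <- "-"
  bad <- which(!x %in% c("yes", "-"))
  if (length(bad) > 0L) {
    stop("unrecognized ", what, " token at row(s) ",
         paste(bad, collapse = ", "), ": ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  x == "yes"
}

normalize_location <- function(x) {
  x <- trimws(as.character(x))
  out <- rep(NA_character_, length(x))
  out[x %in% c("UP", "up")] <- "UP"
  out[x %in% c("DOWN", "down")] <- "DOWN"
  out[x %in% c("in CDS", "IN_CDS", "in_CDS", "CDS")] <- "IN_CDS"
  bad <- which(!(is.na(x) | x == "") & is.na(out))
  if (length(bad) > 0L) {
    stop("unrecognized location token: ",
         paste(unique(x[bad]), collapse = ", "), call. = FALSE)
  }
  out
}

enrichment_cols <- function(regions) {
  grep("^enrichment_[0-9]+$", names(regions), value = TRUE)
}

fdr_cols <- function(regions) {
  grep("^fdr_[0-9]+$", names(regions), value = TRUE)
}

#' Per-replicate enrichment values as a matrix
#'
#' @param regions Binding-region data.frame.
#' @return Numeric matrix, one row per region, one column per replicate.
#' @export
enrichment_matrix <- function(regions) {
  cols <- enrichment_cols(regions)
  if (length(cols) == 0L) stop("no enrichment_* columns", call. = FALSE)
  as.matrix(regions[, cols, drop = FALSE])
}

#' Read a binding-region table
#'
#' Expects a TSV with header and columns `chrom`, `start`, `end`, at
#' least one `enrichment_<i>` column, matching `fdr_<i>` columns, and
#' optionally `region_id`, `summit` and `rank`. Numeric cells may use
#' either decimal dialect. A missing summit defaults to the interval
#' midpoint. FDR values greater than 1 are kept but flagged with a
#' warning.
#'
#' @param path Path to the TSV file.
#' @return A validated binding-region data.frame with columns
#'   `region_id`, `chrom`, `start`, `end`, `summit`, `enrichment_*`,
#'   `fdr_*`, `rank` (0-based half-open coordinates).
#' @export
read_region_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- read.delim(path, colClasses = "character", check.names = TRUE)
  need <- c("chrom", "start", "end")
  miss <- setdiff(need, names(raw))
  if (length(miss) > 0L) {
    stop("region table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(
    region_id = if ("region_id" %in% names(raw)) raw$region_id else
      sprintf("region_%05d", seq_len(nrow(raw))),
    chrom = raw$chrom,
    start = as.integer(parse_numeric_cell(raw$start, "start")),
    end = as.integer(parse_numeric_cell(raw$end, "end")),
    stringsAsFactors = FALSE
  )
  if (any(out$start < 0L, na.rm = TRUE)) {
    stop("negative coordinates at row(s) ",
         paste(which(out$start < 0L), collapse = ", "), call. = FALSE)
  }
  if (any(out$start >= out$end)) {
    stop("start >= end at row(s) ",
         paste(which(out$start >= out$end), collapse = ", "), call. = FALSE)
  }
  out$summit <- if ("summit" %in% names(raw)) {
    as.integer(parse_numeric_cell(raw$summit, "summit"))
  } else {
    NA_integer_
  }
  mid <- out$start + (out$end - out$start) %/% 2L
  out$summit <- ifelse(is.na(out$summit), mid, out$summit)
  if (any(out$summit < out$start | out$summit >= out$end)) {
    stop("summit outside [start,end) at row(s) ",
         paste(which(out$summit < out$start | out$summit >= out$end),
               collapse = ", "), call. = FALSE)
  }
  ecols <- grep("^enrichment_[0-9]+$", names(raw), value = TRUE)
  fcols <- grep("^fdr_[0-9]+$", names(raw), value = TRUE)
  if (length(ecols) == 0L) {
    stop("region table lacks enrichment_* columns", call. = FALSE)
  }
  if (length(fcols) != length(ecols)) {
    stop("enrichment_* and fdr_* column counts differ", call. = FALSE)
  }
  for (cc in ecols) {
    v <- parse_numeric_cell(raw[[cc]], paste0("enrichment (", cc, ")"))
    if (anyNA(v)) {
      stop("missing enrichment at row(s) ",
           paste(which(is.na(v)), collapse = ", "), call. = FALSE)
    }
    if (any(v <= 0)) {
      stop("non-positive enrichment at row(s) ",
           paste(which(v <= 0), collapse = ", "), call. = FALSE)
    }
    out[[cc]] <- v
  }
  for (cc in fcols) {
    out[[cc]] <- parse_numeric_cell(raw[[cc]], paste0("fdr (", cc, ")"))
  }
  fm <- as.matrix(out[, fcols, drop = FALSE])
  if (any(fm > 1, na.rm = TRUE)) {
    warning(sum(rowSums(fm > 1, na.rm = TRUE) > 0),
            " region(s) with FDR > 1 kept as printed", call. = FALSE)
  }
  out$rank <- if ("rank" %in% names(raw)) {
    as.integer(parse_numeric_cell(raw$rank, "rank"))
  } else {
    NA_integer_
  }
  rownames(out) <- NULL
  out
}

#' Write a binding-region table
#'
#' Deterministic column order, dot decimals, tab separated.
#'
#' @param regions Binding-region data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_region_table <- function(regions, path) {
  cols <- c("region_id", "chrom", "start", "end", "summit",
            enrichment_cols(regions), fdr_cols(regions),
            intersect("rank", names(regions)))
  write.table(regions[, cols, drop = FALSE], path, sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export binding regions as BED6
#'
#' Score is replicate-1 enrichment times 100, truncated to integer;
#' strand is `"."`.
#'
#' @param regions Binding-region data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  bed <- data.frame(
    chrom = regions$chrom,
    start = regions$start,
    end = regions$end,
    name = regions$region_id,
    score = as.integer(trunc(regions$enrichment_1 * 100)),
    strand = ".",
    stringsAsFactors = FALSE
  )
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-gene regulation-call table
#'
#' Expects a TSV whose first column is the gene ID and which carries two
#' flag columns ("yes" = consistently down-regulated over the full
#' transcript, "-" or blank = no significant down-regulation) for the 80
#' and 160 min post-induction timepoints. Duplicate gene rows are
#' collapsed by logical OR per timepoint.
#'
#' @param path Path to the TSV file.
#' @param gene_col,col_80,col_160 Column names; defaults match both the
#'   packaged fixtures and the pipeline's own writers.
#' @return A data.frame with columns `gene_id`, `down_80`, `down_160`,
#'   one row per unique gene.
#' @export
read_regulation_table <- function(path, gene_col = NULL,
                                  col_80 = NULL, col_160 = NULL) {
  raw <- read.delim(path, colClasses = "character", check.names = FALSE)
  if (is.null(gene_col)) gene_col <- names(raw)[1L]
  if (is.null(col_80)) {
    col_80 <- grep("80", names(raw), value = TRUE)[1L]
  }
  if (is.null(col_160)) {
    col_160 <- grep("160", names(raw), value = TRUE)[1L]
  }
  if (is.na(col_80) || is.na(col_160)) {
    stop("cannot locate 80/160 min flag columns in ", path, call. = FALSE)
  }
  gene_id <- trimws(raw[[gene_col]])
  if (any(gene_id == "")) {
    stop("empty gene ID at row(s) ",
         paste(which(gene_id == ""), collapse = ", "), call. = FALSE)
  }
  d80 <- parse_flag_cell(raw[[col_80]], "80 min flag")
  d160 <- parse_flag_cell(raw[[col_160]], "160 min flag")
  out <- data.frame(
    gene_id = unique(gene_id),
    stringsAsFactors = FALSE
  )
  out$down_80 <- as.logical(tapply(d80, gene_id, any)[out$gene_id])
  out$down_160 <- as.logical(tapply(d160, gene_id, any)[out$gene_id])
  rownames(out) <- NULL
  out
}

#' Read a printed candidate-target table fixture
#'
#' Parses the transcription of a published per-binding-site candidate
#' table: AGI gene codes, ranks, summit-to-CDS distances,
#' UP/DOWN/in-CDS locations, per-replicate enrichment and FDR in the
#' comma-decimal dialect, and "yes"/"-" regulation flags. Blank distance
#' cells on "in CDS" rows become 0.
#'
#' @param path Path to the fixture TSV.
#' @return A data.frame with columns `gene_id`, `symbol`, `rank`,
#'   `distance`, `location`, `enrichment_1`, `enrichment_2`, `fdr_1`,
#'   `fdr_2`, `down_80`, `down_160` (one row per binding site).
#' @export
read_target_table <- function(path) {
  raw <- read.delim(path, colClasses = "character", check.names = FALSE)
  out <- data.frame(
    gene_id = trimws(raw[["AGI"]]),
    symbol = trimws(raw[["Gene Symbol"]]),
    rank = as.integer(parse_numeric_cell(raw[["ORP-rank"]], "ORP-rank")),
    distance = parse_numeric_cell(raw[["Distance"]], "distance"),
    location = normalize_location(raw[["Location"]]),
    enrichment_1 = parse_numeric_cell(raw[["Enrichment replicate 1"]],
                                      "enrichment"),
    enrichment_2 = parse_numeric_cell(raw[["Enrichment replicate 2"]],
                                      "enrichment"),
    fdr_1 = parse_numeric_cell(raw[["FDR replicate 1"]], "fdr"),
    fdr_2 = parse_numeric_cell(raw[["FDR replicate 2"]], "fdr"),
    down_80 = parse_flag_cell(raw[["80 min"]], "80 min flag"),
    down_160 = parse_flag_cell(raw[["160 min"]], "160 min flag"),
    stringsAsFactors = FALSE
  )
  out$distance[is.na(out$distance) & out$location == "IN_CDS"] <- 0
  out$distance <- as.integer(out$distance)
  rownames(out) <- NULL
  out
}

#' Read the dual-factor candidate table fixture
#'
#' Parses the transcription of the published table pairing one factor's
#' and a second factor's binding sites per gene, including the
#' inter-site distance column. Continuation rows (blank first-factor
#' cells for a repeated gene) are kept as their own binding-site rows.
#'
#' @param path Path to the fixture TSV.
#' @return A data.frame with columns `gene_id`, `symbol`,
#'   `rev_distance`, `rev_location`, `fdr_1`, `fdr_2`, `enrichment_1`,
#'   `enrichment_2`, `kan1_distance`, `kan1_location`, `pair_distance`.
#' @export
read_dual_table <- function(path) {
  raw <- read.delim(path, colClasses = "character", check.names = FALSE)
  out <- data.frame(
    gene_id = trimws(raw[["AGI"]]),
    symbol = trimws(raw[["Gene symbol"]]),
    rev_distance = parse_numeric_cell(raw[["Distance REV"]], "distance"),
    rev_location = normalize_location(raw[["Location REV"]]),
    fdr_1 = parse_numeric_cell(raw[["FDR replicate 1"]], "fdr"),
    fdr_2 = parse_numeric_cell(raw[["FDR replicate 2"]], "fdr"),
    enrichment_1 = parse_numeric_cell(raw[["Enrichment replicate 1"]],
                                      "enrichment"),
    enrichment_2 = parse_numeric_cell(raw[["Enrichment replicate 2"]],
                                      "enrichment"),
    kan1_distance = parse_numeric_cell(raw[["Distance KAN1"]], "distance"),
    kan1_location = normalize_location(raw[["Location KAN1"]]),
    pair_distance = as.integer(
      parse_numeric_cell(raw[["Distance REV/KAN1 binding"]],
                         "pair distance")),
    stringsAsFactors = FALSE
  )
  out$rev_distance[is.na(out$rev_distance) &
                     !is.na(out$rev_location) &
                     out$rev_location == "IN_CDS"] <- 0
  out$kan1_distance[is.na(out$kan1_distance) &
                      !is.na(out$kan1_location) &
                      out$kan1_location == "IN_CDS"] <- 0
  rownames(out) <- NULL
  out
}

#' Packaged candidate-table fixtures
#'
#' Returns a parsed copy of one of the three packaged fixture tables:
#' `"development"` (candidate targets with organ/shoot-development
#' roles), `"auxin"` (candidates in auxin response) or `"dual"` (genes
#' bound by both factors with inter-site distances).
#'
#' @param which One of `"development"`, `"auxin"`, `"dual"`.
#' @return Parsed data.frame (see [read_target_table()] /
#'   [read_dual_table()]).
#' @examples
#' nrow(kan_fixture("dual"))
#' @export
kan_fixture <- function(which = c("development", "auxin", "dual")) {
  which <- match.arg(which)
  path <- kan_fixture_path(which)
  if (which == "dual") read_dual_table(path) else read_target_table(path)
}

#' @rdname kan_fixture
#' @export
kan_fixture_path <- function(which = c("development", "auxin", "dual")) {
  which <- match.arg(which)
  file <- switch(which,
    development = "table1_development_targets.tsv",
    auxin = "table2_auxin_targets.tsv",
    dual = "table3_dual_regulation.tsv"
  )
  system.file("extdata", file, package = "kanseek", mustWork = TRUE)
}
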