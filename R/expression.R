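# Per-gene regulation calls from probe-level induction signals.
#
# A gene is called down at a timepoint when at least `min_fraction` of
# its probes (and at least `min_probes` probes exist) show a log2
# induced/control ratio at or below -delta — the "consistent regulation
# along the full transcript" criterion. Up calls are symmetric.

#' Call regulation for one probe track
#'
#' @param log_ratios Per-probe log2(induced/control) values for one gene
#'   at one timepoint, ordered along the transcript.
#' @param delta Positive log2 threshold (default 1, i.e. two-fold).
#' @param min_fraction Fraction of probes that must pass (default 0.9).
#'   Values `<= 0.5` could satisfy both directions at once; such
#'   ambiguous tracks yield no call.
#' @param min_probes Minimum number of probes for a call (default 4);
#'   shorter tracks yield no call rather than an error.
#' @return A list with logical `down` and `up` and a `reason` string
#'   when no call was possible.
#' @export
call_regulation <- function(log_ratios, delta = 1, min_fraction = 0.9,
                            min_probes = 4) {
  stopifnot(delta > 0, min_fraction > 0, min_fraction <= 1,
            min_probes >= 1)
  if (any(!is.finite(log_ratios))) {
    stop("log ratios must be finite", call. = FALSE)
  }
  n <- length(log_ratios)
  if (n < min_probes) {
    return(list(down = FALSE, up = FALSE,
                reason = sprintf("track has %d < %d probes", n,
                                 min_probes)))
  }
  down <- mean(log_ratios <= -delta) >= min_fraction
  up <- mean(log_ratios >= delta) >= min_fraction
  if (down && up) {
    return(list(down = FALSE, up = FALSE,
                reason = "ambiguous: both directions pass"))
  }
  list(down = down, up = up, reason = NA_character_)
}

#' Call per-gene regulation from a probe table
#'
#' Probe-level signals are grouped by gene and timepoint (replicate
#' tracks, if a `replicate` column is present, are averaged probe-wise
#' by position first), sorted by transcript position, and passed to
#' [call_regulation()]. Calls at all timepoints are merged into one row
#' per gene.
#'
#' @param probes A data.frame with columns `gene_id`, `timepoint`,
#'   `position`, `log_ratio` and optionally `replicate`.
#' @param delta,min_fraction,min_probes See [call_regulation()].
#' @param timepoints Timepoints (minutes) expected in the output
#'   (default `c(80, 160)`); genes lacking a timepoint get `FALSE`
#'   flags there.
#' @return A regulation-call data.frame with columns `gene_id`,
#'   `down_<t>` and `up_<t>` for each timepoint, sorted by gene ID.
#' @export
call_expression <- function(probes, delta = 1, min_fraction = 0.9,
                            min_probes = 4, timepoints = c(80, 160)) {
  stopifnot(all(c("gene_id", "timepoint", "position", "log_ratio") %in%
                  names(probes)))
  if ("replicate" %in% names(probes)) {
    agg <- stats::aggregate(
      log_ratio ~ gene_id + timepoint + position, data = probes, FUN = mean)
    probes <- agg
  }
  key <- interaction(probes$gene_id, probes$timepoint, drop = TRUE)
  pieces <- split(probes, key)
  calls <- lapply(pieces, function(p) {
    p <- p[order(p$position), , drop = FALSE]
    if (anyDuplicated(p$position)) {
      stop("duplicate probe positions for gene ", p$gene_id[1L],
           " at timepoint ", p$timepoint[1L], call. = FALSE)
    }
    cl <- call_regulation(p$log_ratio, delta, min_fraction, min_probes)
    data.frame(gene_id = p$gene_id[1L], timepoint = p$timepoint[1L],
               down = cl$down, up = cl$up, stringsAsFactors = FALSE)
  })
  merge_timepoints(do.call(rbind, calls), timepoints = timepoints)
}

#' Merge per-timepoint calls into one row per gene
#'
#' @param calls A data.frame with columns `gene_id`, `timepoint`,
#'   `down`, `up` — at most one row per (gene, timepoint).
#' @param timepoints Timepoints represented in the output columns.
#' @return One row per gene with `down_<t>`/`up_<t>` columns; genes
#'   absent at a timepoint are `FALSE` there.
#' @export
merge_timepoints <- function(calls, timepoints = c(80, 160)) {
  if (is.null(calls) || nrow(calls) == 0L) {
    out <- data.frame(gene_id = character(0), stringsAsFactors = FALSE)
    for (t in timepoints) {
      out[[paste0("down_", t)]] <- logical(0)
      out[[paste0("up_", t)]] <- logical(0)
    }
    return(out)
  }
  if (anyDuplicated(calls[, c("gene_id", "timepoint")])) {
    stop("duplicate (gene, timepoint) call", call. = FALSE)
  }
  genes <- sort(unique(calls$gene_id))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  for (t in timepoints) {
    sub <- calls[calls$timepoint == t, , drop = FALSE]
    idx <- match(genes, sub$gene_id)
    out[[paste0("down_", t)]] <- !is.na(idx) & sub$down[idx] %in% TRUE
    out[[paste0("up_", t)]] <- !is.na(idx) & sub$up[idx] %in% TRUE
  }
  rownames(out) <- NULL
  out
}

#' Regulation calls from a printed yes/- flag table
#'
#' Adapts a pre-computed down-regulation flag table (e.g. a packaged
#' fixture parsed with [read_regulation_table()] or
#' [read_target_table()]) to the call format produced by
#' [call_expression()], collapsing duplicate gene rows by logical OR.
#'
#' @param flags A data.frame with columns `gene_id`, `down_80`,
#'   `down_160`.
#' @return A regulation-call data.frame (`up_*` columns all `FALSE`).
#' @export
calls_from_flags <- function(flags) {
  stopifnot(all(c("gene_id", "down_80", "down_160") %in% names(flags)))
  genes <- sort(unique(flags$gene_id))
  out <- data.frame(gene_id = genes, stringsAsFactors = FALSE)
  out$down_80 <- as.logical(tapply(flags$down_80, flags$gene_id,
                                   any)[genes])
  out$down_160 <- as.logical(tapply(flags$down_160, flags$gene_id,
                                    any)[genes])
  out$up_80 <- FALSE
  out$up_160 <- FALSE
  rownames(out) <- NULL
  out
}
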