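# End-to-end orchestration: filter -> scan -> annotate -> expression
# calls -> integration (-> dual-factor comparison), with a manifest of
# parameter values, input checksums and per-stage record counts.

#' Build a pipeline configuration
#'
#' Inputs may be given either as file paths (FASTA / GFF3 / TSV) or as
#' the in-memory objects the corresponding readers produce.
#'
#' @param regions Region table path or data.frame.
#' @param genome FASTA path or named character vector.
#' @param genes GFF3 path or gene-model data.frame.
#' @param probes Probe table path or data.frame (optional if
#'   `regulation` is given).
#' @param regulation Pre-computed yes/- regulation table path or
#'   call data.frame (used instead of probe-level calling).
#' @param policy A [filter_policy()].
#' @param motif IUPAC pattern.
#' @param window,anchor Annotation parameters (see [assign_regions()]).
#' @param delta,min_fraction,min_probes Expression-call thresholds.
#' @param mode Integration mode (see [intersect_bound_regulated()]).
#' @param sites_b Optional second factor's site table (data.frame with
#'   `gene_id`, `pos`) or path, enabling the co-binding comparison.
#' @param proximity_threshold Strict co-binding cutoff in bp.
#' @param motif_only If `TRUE` (default) only genes annotated to
#'   motif-containing regions count as bound.
#' @param outdir Optional output directory for intermediate tables.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(regions, genome, genes, probes = NULL,
                            regulation = NULL,
                            policy = filter_policy(),
                            motif = "VGAATAW",
                            window = 10500, anchor = "summit",
                            delta = 1, min_fraction = 0.9, min_probes = 4,
                            mode = "down_any",
                            sites_b = NULL, proximity_threshold = 100,
                            motif_only = TRUE, outdir = NULL) {
  if (is.null(probes) && is.null(regulation)) {
    stop("either probes or a regulation table must be given",
         call. = FALSE)
  }
  for (p in list(regions, genome, genes, probes, regulation, sites_b)) {
    if (is.character(p) && length(p) == 1L && !file.exists(p)) {
      stop("input path does not exist: ", p, call. = FALSE)
    }
  }
  structure(list(regions = regions, genome = genome, genes = genes,
                 probes = probes, regulation = regulation,
                 policy = policy, motif = motif, window = window,
                 anchor = anchor, delta = delta,
                 min_fraction = min_fraction, min_probes = min_probes,
                 mode = mode, sites_b = sites_b,
                 proximity_threshold = proximity_threshold,
                 motif_only = motif_only, outdir = outdir),
            class = "pipeline_config")
}

load_input <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) reader(x) else x
}

input_checksum <- function(x) {
  if (is.character(x) && length(x) == 1L && file.exists(x)) {
    unname(tools::md5sum(x))
  } else {
    NA_character_
  }
}

#' Run the full target-identification pipeline
#'
#' Executes filter, motif scan, annotation, regulation calling (from
#' probes, or adoption of a pre-computed flag table) and the
#' bound-regulated intersection; when a second factor's sites are
#' configured, also the proximity comparison. All intermediate tables
#' are written when `outdir` is set.
#'
#' @param config A [pipeline_config()].
#' @return A list with elements `targets` (direct-target data.frame),
#'   `assignments`, `calls`, `scan`, `filtered`, `distribution`,
#'   optional `dual`, and `manifest` — a data.frame of per-stage record
#'   counts plus recorded parameters and input checksums as attributes.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  regions <- load_input(config$regions, read_region_table)
  genome <- load_input(config$genome, read_fasta)
  genes <- load_input(config$genes, read_gff3)

  filtered <- filter_regions(regions, config$policy)
  scan <- regions_with_motif(filtered, genome, config$motif)
  bound_regions <- if (config$motif_only) scan$with_motif else filtered
  assignments <- assign_regions(bound_regions, genes,
                                window = config$window,
                                anchor = config$anchor)
  bound_genes <- sort(unique(assignments$gene_id))
  distribution <- position_distribution(
    assign_regions(filtered, genes, window = config$window,
                   anchor = config$anchor),
    n_regions = nrow(filtered))

  calls <- if (!is.null(config$regulation)) {
    calls_from_flags(load_input(config$regulation,
                                read_regulation_table))
  } else {
    call_expression(load_input(config$probes, read.delim),
                    delta = config$delta,
                    min_fraction = config$min_fraction,
                    min_probes = config$min_probes)
  }
  targets <- intersect_bound_regulated(bound_genes, calls,
                                       mode = config$mode)

  dual <- NULL
  if (!is.null(config$sites_b)) {
    near <- assignments[assignments$is_nearest, , drop = FALSE]
    anchor_pos <- regions$summit[match(near$region_id,
                                       regions$region_id)]
    sites_a <- data.frame(gene_id = near$gene_id, pos = anchor_pos,
                          stringsAsFactors = FALSE)
    sites_b <- load_input(config$sites_b, read.delim)
    dual <- compare_factors(sites_a, sites_b,
                            config$proximity_threshold)
  }

  n_regulated <- sum(calls$down_80 | calls$down_160)
  manifest <- data.frame(
    stage = c("input", "filter", "motif_scan", "bound_genes",
              "regulated_genes", "direct_targets",
              if (!is.null(dual)) "dual_candidates"),
    records = c(nrow(regions), nrow(filtered), nrow(scan$with_motif),
                length(bound_genes), n_regulated, nrow(targets),
                if (!is.null(dual)) nrow(dual)),
    stringsAsFactors = FALSE
  )
  attr(manifest, "parameters") <- list(
    min_fold = config$policy$min_fold,
    fold_rule = config$policy$fold_rule,
    motif = config$motif, window = config$window,
    anchor = config$anchor, mode = config$mode,
    delta = config$delta, min_fraction = config$min_fraction,
    min_probes = config$min_probes,
    proximity_threshold = config$proximity_threshold
  )
  attr(manifest, "checksums") <- vapply(
    list(regions = config$regions, genome = config$genome,
         genes = config$genes), input_checksum, "")

  if (!is.null(config$outdir)) {
    dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
    write_region_table(filtered, file.path(config$outdir,
                                           "filtered_regions.tsv"))
    write_bed(filtered, file.path(config$outdir,
                                  "filtered_regions.bed"))
    write.table(scan$hits, file.path(config$outdir, "motif_hits.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(assignments, file.path(config$outdir,
                                       "assignments.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(calls, file.path(config$outdir, "regulation_calls.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(targets, file.path(config$outdir,
                                   "direct_targets.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(distribution, file.path(config$outdir,
                                        "position_distribution.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(dual)) {
      write.table(dual, file.path(config$outdir,
                                  "dual_candidates.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write.table(manifest, file.path(config$outdir, "manifest.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  list(targets = targets, assignments = assignments, calls = calls,
       scan = scan, filtered = filtered, distribution = distribution,
       dual = dual, manifest = manifest)
}
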