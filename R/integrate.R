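# Intersection of binding and regulation evidence, and dual-factor
# co-binding comparison.

#' Intersect bound genes with regulation calls
#'
#' A gene is a direct-target candidate when it is bound (present in
#' `bound_genes`) and regulated under the chosen mode: `down_any`
#' (default; down at either timepoint), `down_both`, or `any_change`
#' (down or up at either timepoint). Genes without a call are treated
#' as not regulated.
#'
#' @param bound_genes Character vector of bound gene IDs.
#' @param calls Regulation-call data.frame (see [call_expression()] /
#'   [calls_from_flags()]).
#' @param mode Regulation requirement; see above.
#' @return A data.frame sorted by `gene_id` with the call flags and a
#'   logical `regulated` column (all `TRUE`), plus a `counts` attribute
#'   tabulating the regulation patterns among bound genes
#'   (`down_both`, `down_80_only`, `down_160_only`, `down_any`).
#' @export
intersect_bound_regulated <- function(bound_genes, calls,
                                      mode = c("down_any", "down_both",
                                               "any_change")) {
  mode <- match.arg(mode)
  bound_genes <- unique(as.character(bound_genes))
  calls <- calls[calls$gene_id %in% bound_genes, , drop = FALSE]
  up_any <- if (all(c("up_80", "up_160") %in% names(calls))) {
    calls$up_80 | calls$up_160
  } else {
    rep(FALSE, nrow(calls))
  }
  regulated <- switch(mode,
    down_any = calls$down_80 | calls$down_160,
    down_both = calls$down_80 & calls$down_160,
    any_change = calls$down_80 | calls$down_160 | up_any
  )
  out <- calls[regulated, , drop = FALSE]
  out <- out[order(out$gene_id), , drop = FALSE]
  out$regulated <- rep(TRUE, nrow(out))
  attr(out, "counts") <- c(
    bound = length(bound_genes),
    called = nrow(calls),
    down_both = sum(calls$down_80 & calls$down_160),
    down_80_only = sum(calls$down_80 & !calls$down_160),
    down_160_only = sum(!calls$down_80 & calls$down_160),
    down_any = sum(calls$down_80 | calls$down_160)
  )
  rownames(out) <- NULL
  out
}

#' Compare two factors' binding sites per gene
#'
#' For every gene present in both site maps, computes the minimum
#' distance over all cross pairs of single-base site anchors and flags
#' the gene proximal when that distance is strictly below
#' `proximity_threshold`.
#'
#' @param sites_a,sites_b Data.frames with columns `gene_id` and `pos`
#'   (site anchor, base position), one row per site.
#' @param proximity_threshold Strict distance cutoff in bp (default
#'   100).
#' @return A data.frame with one row per shared gene: `gene_id`,
#'   `site_a`, `site_b` (the anchors realizing the minimum),
#'   `pair_distance`, `proximal`; sorted by gene ID. Attribute
#'   `summary` counts genes present in only one map.
#' @export
compare_factors <- function(sites_a, sites_b, proximity_threshold = 100) {
  stopifnot(proximity_threshold > 0)
  for (s in list(sites_a, sites_b)) {
    stopifnot(all(c("gene_id", "pos") %in% names(s)))
    if (anyNA(s$pos)) stop("missing site position", call. = FALSE)
  }
  shared <- sort(intersect(sites_a$gene_id, sites_b$gene_id))
  rows <- lapply(shared, function(g) {
    a <- sites_a$pos[sites_a$gene_id == g]
    b <- sites_b$pos[sites_b$gene_id == g]
    if (length(a) == 0L || length(b) == 0L) {
      stop("empty site list for gene ", g, call. = FALSE)
    }
    d <- abs(outer(a, b, "-"))
    ij <- which(d == min(d), arr.ind = TRUE)[1L, ]
    data.frame(gene_id = g, site_a = a[ij[1L]], site_b = b[ij[2L]],
               pair_distance = as.integer(min(d)),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), site_a = integer(0),
               site_b = integer(0), pair_distance = integer(0),
               stringsAsFactors = FALSE)
  out$proximal <- out$pair_distance < proximity_threshold
  attr(out, "summary") <- c(
    shared = length(shared),
    only_a = length(setdiff(sites_a$gene_id, sites_b$gene_id)),
    only_b = length(setdiff(sites_b$gene_id, sites_a$gene_id))
  )
  rownames(out) <- NULL
  out
}

#' Per-gene minimum inter-factor distance from a printed dual table
#'
#' Collapses a parsed dual-binding fixture (one row per site pair) to
#' one row per gene with the minimum printed inter-site distance and a
#' strict proximal flag.
#'
#' @param dual A data.frame as returned by [read_dual_table()].
#' @param proximity_threshold Strict cutoff in bp (default 100).
#' @return A data.frame `gene_id`, `pair_distance`, `proximal`, sorted
#'   by gene ID.
#' @export
dual_candidates <- function(dual, proximity_threshold = 100) {
  stopifnot(all(c("gene_id", "pair_distance") %in% names(dual)))
  genes <- sort(unique(dual$gene_id))
  pd <- as.integer(tapply(dual$pair_distance, dual$gene_id, min)[genes])
  data.frame(gene_id = genes, pair_distance = pd,
             proximal = pd < proximity_threshold,
             stringsAsFactors = FALSE)
}

#' Tabulate direct-target candidates by category
#'
#' @param records A data.frame with a `gene_id` column and a logical
#'   `regulated` column (e.g. fixture rows with per-gene down flags, or
#'   [intersect_bound_regulated()] output).
#' @param category_map A data.frame mapping `gene_id` to `category`
#'   (possibly partial; genes may carry several categories).
#' @return A data.frame per category with unique-gene counts `n_genes`
#'   (no regulation requirement) and `n_regulated`.
#' @export
tabulate_targets <- function(records, category_map) {
  stopifnot(all(c("gene_id", "category") %in% names(category_map)))
  reg <- if ("regulated" %in% names(records)) records$regulated else
    rep(TRUE, nrow(records))
  reg_by_gene <- tapply(reg, records$gene_id, any)
  cats <- sort(unique(category_map$category))
  rows <- lapply(cats, function(cc) {
    members <- unique(category_map$gene_id[category_map$category == cc])
    present <- members[members %in% records$gene_id]
    data.frame(category = cc,
               n_genes = length(present),
               n_regulated = sum(reg_by_gene[present] %in% TRUE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
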