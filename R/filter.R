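# Fold-enrichment filtering of called regions.

#' Construct a region filtering policy
#'
#' The default policy keeps a region when at least one replicate shows
#' at least three-fold enrichment; printed candidate rows with one
#' replicate below 3 (e.g. enrichment 1.8/6.5) rule out an
#' all-replicates reading of the threshold, so `any_replicate` is the
#' default and the rule is configurable. No FDR cut is applied unless
#' `max_fdr` is given.
#'
#' @param min_fold Positive fold-enrichment threshold (default 3).
#' @param fold_rule How replicates are combined: `"any_replicate"`
#'   (max), `"all_replicates"` (min) or `"mean"`.
#' @param max_fdr Optional FDR ceiling; a region additionally passes
#'   only if its smallest replicate FDR is `<= max_fdr`.
#' @return A `filter_policy` list.
#' @export
filter_policy <- function(min_fold = 3,
                          fold_rule = c("any_replicate", "all_replicates",
                                        "mean"),
                          max_fdr = NULL) {
  fold_rule <- match.arg(fold_rule)
  stopifnot(is.numeric(min_fold), length(min_fold) == 1L, min_fold > 0)
  if (!is.null(max_fdr)) {
    stopifnot(is.numeric(max_fdr), length(max_fdr) == 1L)
  }
  structure(list(min_fold = min_fold, fold_rule = fold_rule,
                 max_fdr = max_fdr),
            class = "filter_policy")
}

#' Filter binding regions by fold enrichment
#'
#' Returns the subset of `regions` passing `policy`, preserving input
#' order. Under `any_replicate` a region passes iff its maximum
#' replicate enrichment meets `min_fold`; `all_replicates` requires the
#' minimum to; `mean` the arithmetic mean.
#'
#' @param regions Binding-region data.frame.
#' @param policy A [filter_policy()].
#' @return Subset of `regions`.
#' @export
filter_regions <- function(regions, policy = filter_policy()) {
  if (!inherits(policy, "filter_policy")) {
    stop("policy must be a filter_policy()", call. = FALSE)
  }
  em <- enrichment_matrix(regions)
  if (ncol(em) < 1L) stop("regions carry no enrichment values", call. = FALSE)
  if (anyNA(em) || any(is.nan(em))) {
    stop("NA/NaN enrichment at row(s) ",
         paste(which(rowSums(is.na(em)) > 0), collapse = ", "),
         call. = FALSE)
  }
  stat <- switch(policy$fold_rule,
    any_replicate = apply(em, 1L, max),
    all_replicates = apply(em, 1L, min),
    mean = rowMeans(em)
  )
  keep <- stat >= policy$min_fold
  if (!is.null(policy$max_fdr)) {
    fm <- as.matrix(regions[, fdr_cols(regions), drop = FALSE])
    keep <- keep & apply(fm, 1L, min) <= policy$max_fdr
  }
  regions[keep, , drop = FALSE]
}
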