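# Synthetic-study generator: genome, gene models, planted motif
# instances, enriched regions with replicate enrichments/FDRs, probe
# tracks, and a recorded ground truth.
#
# The background sequence is rejection-screened to contain zero motif
# occurrences on either strand outside planted instances, so planted
# counts are exact and every downstream recovery test has an exact
# truth.

#' Configuration for a synthetic study
#'
#' Defaults state the emulated world: a five-chromosome genome of
#' non-overlapping gene models, binding-site placement mixture
#' 0.24/0.40/0.11/0.25 over upstream-1kb / gene-body / downstream-1kb /
#' distal (matching the reported ~24% upstream-1kb and ~11%
#' downstream-1kb shares), two-replicate log-normal enrichment with
#' target regions centred near 6-fold and background near 1.5-fold
#' (the printed candidate rows span roughly 1.3-14.2), and probe
#' tracks at 80 and 160 min post-induction with a -2 log2 shift for
#' down-regulated genes against noise SD 0.4.
#'
#' @param seed Integer RNG seed; the whole study is a deterministic
#'   function of the configuration.
#' @param n_chroms,chrom_length Genome shape. `chrom_length = NULL`
#'   (default) sizes each chromosome to fit its genes plus margins; a
#'   given length that cannot hold the genes is an error.
#' @param n_genes Number of gene models.
#' @param body_length Two-element range of gene body lengths (bp).
#' @param min_gap,max_gap Intergenic gap range (bp); the minimum must
#'   leave room for distal placements without crowding neighbours.
#' @param motif IUPAC pattern planted at target summits.
#' @param placement_mixture Named proportions over `upstream_1kb`,
#'   `gene_body`, `downstream_1kb`, `distal`; must sum to 1.
#' @param n_target_genes Number of bound genes (each receives
#'   `regions_per_target` regions with a planted motif at the summit).
#' @param regions_per_target Planted regions per target gene.
#' @param n_background_regions Motif-free decoy regions.
#' @param region_halfwidth Half-width of emitted regions around the
#'   summit (bp).
#' @param n_replicates ChIP replicates.
#' @param enrichment_target,enrichment_background Named `meanlog` /
#'   `sdlog` log-normal parameters per class; the target median must
#'   be at least the standard three-fold filter threshold.
#' @param effect_size Log2 down-shift applied to probes of
#'   down-regulated genes.
#' @param noise_sd Gaussian probe noise SD (log2 units).
#' @param p_down_given_bound,p_down_background Probability that a
#'   bound / unbound gene is down-regulated.
#' @param timepoints Post-induction timepoints (minutes).
#' @param probes_per_gene Probes per transcript track.
#' @param truth_window Window (bp) used to record which genes count as
#'   bound in the truth table: any gene whose CDS span lies within this
#'   distance of a planted-region summit, mirroring the many-to-many
#'   region-to-gene annotation convention. Matches the default
#'   annotation window.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 7L,
                             n_chroms = 5L,
                             chrom_length = NULL,
                             n_genes = 300L,
                             body_length = c(1000L, 3000L),
                             min_gap = 4500L,
                             max_gap = 6000L,
                             motif = "VGAATAW",
                             placement_mixture = c(upstream_1kb = 0.24,
                                                   gene_body = 0.40,
                                                   downstream_1kb = 0.11,
                                                   distal = 0.25),
                             n_target_genes = 60L,
                             regions_per_target = 1L,
                             n_background_regions = 150L,
                             region_halfwidth = 150L,
                             n_replicates = 2L,
                             enrichment_target = c(meanlog = log(6),
                                                   sdlog = 0.3),
                             enrichment_background = c(meanlog = log(1.5),
                                                       sdlog = 0.3),
                             effect_size = 2,
                             noise_sd = 0.4,
                             p_down_given_bound = 0.4,
                             p_down_background = 0.02,
                             timepoints = c(80, 160),
                             probes_per_gene = 12L,
                             truth_window = 10500L) {
  mix <- placement_mixture
  need <- c("upstream_1kb", "gene_body", "downstream_1kb", "distal")
  if (!setequal(names(mix), need)) {
    stop("placement_mixture must be named over: ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  mix <- mix[need]
  if (abs(sum(mix) - 1) > 1e-9) {
    stop("placement_mixture must sum to 1", call. = FALSE)
  }
  if (any(mix < 0)) {
    stop("placement_mixture proportions must be non-negative",
         call. = FALSE)
  }
  if (n_target_genes > n_genes) {
    stop("n_target_genes exceeds n_genes", call. = FALSE)
  }
  if (exp(enrichment_target[["meanlog"]]) < 3) {
    stop("target enrichment median below the three-fold filter threshold",
         call. = FALSE)
  }
  if (min_gap < 4000L) {
    stop("min_gap below 4000 bp would let distal placements crowd ",
         "neighbouring genes", call. = FALSE)
  }
  structure(list(
    seed = as.integer(seed), n_chroms = as.integer(n_chroms),
    chrom_length = chrom_length, n_genes = as.integer(n_genes),
    body_length = as.integer(body_length),
    min_gap = as.integer(min_gap), max_gap = as.integer(max_gap),
    motif = motif, placement_mixture = mix,
    n_target_genes = as.integer(n_target_genes),
    regions_per_target = as.integer(regions_per_target),
    n_background_regions = as.integer(n_background_regions),
    region_halfwidth = as.integer(region_halfwidth),
    n_replicates = as.integer(n_replicates),
    enrichment_target = enrichment_target,
    enrichment_background = enrichment_background,
    effect_size = effect_size, noise_sd = noise_sd,
    p_down_given_bound = p_down_given_bound,
    p_down_background = p_down_background,
    timepoints = timepoints,
    probes_per_gene = as.integer(probes_per_gene),
    truth_window = as.integer(truth_window)
  ), class = "synthetic_config")
}

# Resample the non-protected bases of every unwanted motif hit until the
# sequence (char vector) is motif-free outside protected intervals.
repair_motif_hits <- function(chars, motif, protected_offsets,
                              protected_strands, max_iter = 50L) {
  k <- length(as_motif(motif)$sets)
  prot_mask <- rep(FALSE, length(chars))
  for (o in protected_offsets) prot_mask[(o + 1L):(o + k)] <- TRUE
  prot_key <- paste(protected_offsets,
                    protected_strands %||% character(0))
  for (iter in seq_len(max_iter)) {
    hits <- scan_sequence(paste(chars, collapse = ""), motif, "both")
    key <- paste(hits$offset, hits$strand)
    extra <- hits[!key %in% prot_key, , drop = FALSE]
    if (nrow(extra) == 0L) return(chars)
    for (j in seq_len(nrow(extra))) {
      idx <- (extra$offset[j] + 1L):(extra$offset[j] + k)
      idx <- idx[!prot_mask[idx]]
      chars[idx] <- sample(c("A", "C", "G", "T"), length(idx),
                           replace = TRUE)
    }
  }
  stop("failed to screen background motif-free after ", max_iter,
       " iterations", call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate a synthetic study with recorded ground truth
#'
#' Produces a genome whose background is motif-free on both strands,
#' gene models laid out without overlap, one planted concrete motif
#' instance (random allowed bases, random orientation) at the summit of
#' each target region, enriched regions with per-replicate log-normal
#' enrichment and FDR columns derived as noisy monotone transforms of
#' enrichment, probe tracks with a `-effect_size` log2 shift for
#' down-regulated genes, and a truth table consistent with all emitted
#' objects.
#'
#' @param config A [synthetic_config()].
#' @param outdir Optional directory; when given, FASTA, GFF3 and TSV
#'   files are written there deterministically.
#' @return A list with elements `genome` (named character), `genes`,
#'   `regions`, `probes` (data.frames) and `truth` (list with `genes`,
#'   `regions` data.frames and `n_planted`).
#' @export
generate_synthetic_study <- function(config = synthetic_config(),
                                     outdir = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  hw <- config$region_halfwidth
  k <- length(as_motif(config$motif)$sets)

  # --- gene layout ------------------------------------------------------
  chrom_names <- sprintf("chr%d", seq_len(config$n_chroms))
  chrom_of <- rep(chrom_names, length.out = config$n_genes)
  genes <- data.frame(
    gene_id = sprintf("SYNG%04d", seq_len(config$n_genes)),
    chrom = sort(chrom_of),
    stringsAsFactors = FALSE
  )
  genes$strand <- sample(c("+", "-"), config$n_genes, replace = TRUE)
  body_len <- sample(config$body_length[1L]:config$body_length[2L],
                     config$n_genes, replace = TRUE)
  genes$body_start <- NA_integer_
  genes$body_end <- NA_integer_
  chrom_len <- setNames(integer(config$n_chroms), chrom_names)
  margin <- 5000L
  for (cc in chrom_names) {
    idx <- which(genes$chrom == cc)
    x <- margin
    for (i in idx) {
      genes$body_start[i] <- x
      genes$body_end[i] <- x + body_len[i]
      x <- genes$body_end[i] +
        sample(config$min_gap:config$max_gap, 1L)
    }
    chrom_len[cc] <- x + margin
  }
  if (!is.null(config$chrom_length)) {
    if (any(chrom_len > config$chrom_length)) {
      stop("configured chrom_length too small: genes do not fit",
           call. = FALSE)
    }
    chrom_len[] <- as.integer(config$chrom_length)
  }
  # generator keeps CDS == body; GFF3 round-trip covers distinct spans
  genes$cds_start <- genes$body_start
  genes$cds_end <- genes$body_end

  # --- placements and planted motif instances --------------------------
  target_idx <- sort(sample(config$n_genes, config$n_target_genes))
  classes <- names(config$placement_mixture)
  n_regions_t <- config$n_target_genes * config$regions_per_target
  planted <- list()  # per chrom: data.frame(offset, strand)
  for (cc in chrom_names) planted[[cc]] <-
    data.frame(offset = integer(0), strand = character(0))
  placement <- character(0); summits <- integer(0)
  reg_chrom <- character(0); reg_gene <- character(0)
  overlaps_planted <- function(cc, lo, hi) {
    p <- planted[[cc]]
    any(p$offset < hi & (p$offset + k) > lo)
  }
  for (i in target_idx) {
    for (r in seq_len(config$regions_per_target)) {
      placed <- FALSE
      for (attempt in 1:100) {
        cls <- sample(classes, 1L, prob = config$placement_mixture)
        g <- genes[i, ]
        left <- switch(cls,  # placement on the physically-left side?
          upstream_1kb = g$strand == "+",
          downstream_1kb = g$strand == "-",
          distal = g$strand == "+",
          gene_body = NA
        )
        s <- if (cls == "gene_body") {
          sample(g$body_start:(g$body_end - 1L), 1L)
        } else {
          d <- if (cls == "distal") sample(1200:2800, 1L) else
            sample(1:999, 1L)
          if (left) g$cds_start - d else g$cds_end + d
        }
        lo <- s - 3L
        if (lo < k || s + 4L > chrom_len[g$chrom] - k) next
        if (!overlaps_planted(g$chrom, lo, lo + k)) {
          st <- sample(c("+", "-"), 1L)
          planted[[g$chrom]] <- rbind(
            planted[[g$chrom]],
            data.frame(offset = lo, strand = st,
                       stringsAsFactors = FALSE))
          placement <- c(placement, cls)
          summits <- c(summits, s)
          reg_chrom <- c(reg_chrom, g$chrom)
          reg_gene <- c(reg_gene, g$gene_id)
          placed <- TRUE
          break
        }
      }
      if (!placed) {
        stop("could not place a motif instance without overlap",
             call. = FALSE)
      }
    }
  }

  # --- background regions (motif-free) ---------------------------------
  bg_chrom <- character(0); bg_summit <- integer(0)
  for (b in seq_len(config$n_background_regions)) {
    for (attempt in 1:100) {
      cc <- sample(chrom_names, 1L)
      s <- sample(hw:(chrom_len[cc] - hw - 1L), 1L)
      if (!overlaps_planted(cc, s - hw, s + hw)) {
        bg_chrom <- c(bg_chrom, cc)
        bg_summit <- c(bg_summit, s)
        break
      }
    }
  }

  # --- genome sequence: screen, plant, repair --------------------------
  genome <- setNames(character(config$n_chroms), chrom_names)
  for (cc in chrom_names) {
    chars <- sample(c("A", "C", "G", "T"), chrom_len[cc], replace = TRUE)
    chars <- repair_motif_hits(chars, config$motif, integer(0),
                               character(0))
    p <- planted[[cc]]
    if (nrow(p) > 0L) {
      sets <- as_motif(config$motif)$sets
      for (j in seq_len(nrow(p))) {
        concrete <- vapply(sets, function(b) sample(b, 1L), "")
        inst <- paste(concrete, collapse = "")
        if (p$strand[j] == "-") inst <- revcomp(inst)
        chars[(p$offset[j] + 1L):(p$offset[j] + k)] <-
          strsplit(inst, "")[[1L]]
      }
      chars <- repair_motif_hits(chars, config$motif, p$offset, p$strand)
    }
    genome[cc] <- paste(chars, collapse = "")
  }

  # --- regions table ---------------------------------------------------
  all_chrom <- c(reg_chrom, bg_chrom)
  all_summit <- c(summits, bg_summit)
  is_target <- c(rep(TRUE, length(summits)), rep(FALSE, length(bg_summit)))
  n_reg <- length(all_summit)
  regions <- data.frame(
    region_id = sprintf("SYNR%05d", seq_len(n_reg)),
    chrom = all_chrom,
    start = pmax(all_summit - hw, 0L),
    end = pmin(all_summit + hw, chrom_len[all_chrom]),
    summit = all_summit,
    stringsAsFactors = FALSE
  )
  for (rr in seq_len(config$n_replicates)) {
    pars <- function(p) c(p[["meanlog"]], p[["sdlog"]])
    et <- pars(config$enrichment_target)
    eb <- pars(config$enrichment_background)
    enr <- ifelse(is_target,
                  rlnorm(n_reg, et[1L], et[2L]),
                  rlnorm(n_reg, eb[1L], eb[2L]))
    regions[[paste0("enrichment_", rr)]] <- round(enr, 3)
    fdr <- exp(-1.5 * enr + rnorm(n_reg, 0, 0.3))
    regions[[paste0("fdr_", rr)]] <- signif(pmin(fdr, 1), 3)
  }
  regions$rank <- as.integer(rank(-rowMeans(enrichment_matrix(regions)),
                                  ties.method = "first"))

  # --- regulation truth and probe tracks -------------------------------
  # A gene counts as bound when any planted-region summit lies within
  # the annotation window of its CDS span (regions map to every gene in
  # range, not only the gene that received the planting), computed here
  # geometrically and independently of the annotation module.
  is_planted <- genes$gene_id %in% reg_gene
  is_bound <- vapply(seq_len(config$n_genes), function(i) {
    s <- summits[reg_chrom == genes$chrom[i]]
    if (length(s) == 0L) return(FALSE)
    inside <- s >= genes$body_start[i] & s < genes$body_end[i]
    d <- pmax(genes$cds_start[i] - s, s - genes$cds_end[i], 0L)
    d[inside] <- 0L
    any(d <= config$truth_window)
  }, TRUE)
  is_down <- ifelse(is_planted,
                    runif(config$n_genes) < config$p_down_given_bound,
                    runif(config$n_genes) < config$p_down_background)
  n_tp <- length(config$timepoints)
  np <- config$probes_per_gene
  probes <- data.frame(
    gene_id = rep(genes$gene_id, each = n_tp * np),
    timepoint = rep(rep(config$timepoints, each = np), config$n_genes),
    position = rep.int(seq(0L, by = 60L, length.out = np),
                       config$n_genes * n_tp),
    stringsAsFactors = FALSE
  )
  shift <- ifelse(rep(is_down, each = n_tp * np), -config$effect_size, 0)
  probes$log_ratio <- round(rnorm(nrow(probes), shift, config$noise_sd), 4)

  truth_genes <- data.frame(
    gene_id = genes$gene_id,
    is_planted = is_planted,
    is_bound = is_bound,
    is_down = is_down,
    is_direct_target = is_bound & is_down,
    stringsAsFactors = FALSE
  )
  truth_regions <- data.frame(
    region_id = regions$region_id,
    gene_id = c(reg_gene, rep(NA_character_, length(bg_summit))),
    is_target = is_target,
    placement = c(placement, rep(NA_character_, length(bg_summit))),
    motif_offset = c(vapply(seq_along(summits), function(j)
      summits[j] - 3L, 0L), rep(NA_integer_, length(bg_summit))),
    stringsAsFactors = FALSE
  )
  out <- list(genome = genome, genes = genes, regions = regions,
              probes = probes,
              truth = list(genes = truth_genes, regions = truth_regions,
                           n_planted = sum(vapply(planted, nrow, 0L))))
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(genome, file.path(outdir, "genome.fasta"))
    write_gff3(genes, file.path(outdir, "genes.gff3"))
    write_region_table(regions, file.path(outdir, "regions.tsv"))
    write.table(probes, file.path(outdir, "probes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(truth_genes, file.path(outdir, "truth_genes.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(truth_regions, file.path(outdir, "truth_regions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}

#' Re-emit the packaged printed-table fixtures
#'
#' Copies the verbatim TSV transcriptions of the three published
#' candidate tables into `outdir`. Deterministic: re-emission is
#' byte-identical.
#'
#' @param outdir Output directory (created if needed).
#' @return Character vector of the emitted paths, invisibly.
#' @export
write_fixture_tables <- function(outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  out <- vapply(c("development", "auxin", "dual"), function(w) {
    src <- kan_fixture_path(w)
    dst <- file.path(outdir, basename(src))
    file.copy(src, dst, overwrite = TRUE)
    dst
  }, "")
  invisible(out)
}
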