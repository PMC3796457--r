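# Small configurations keep the default suite fast; the full-size
# recovery runs live in test-acceptance.R.
small_cfg <- function(seed = 5, n_target_genes = 12L, ...) {
  synthetic_config(seed = seed, n_chroms = 2L, n_genes = 40L,
                   n_target_genes = n_target_genes,
                   n_background_regions = 20L, ...)
}

test_that("generation is a deterministic function of the config", {
  a <- generate_synthetic_study(small_cfg())
  b <- generate_synthetic_study(small_cfg())
  expect_identical(a, b)
  # and file emission is byte-identical
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_synthetic_study(small_cfg(), outdir = d1)
  generate_synthetic_study(small_cfg(), outdir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  c2 <- generate_synthetic_study(small_cfg(seed = 6))
  expect_false(identical(a$genome, c2$genome))
})

test_that("planted-count conservation: genome hits equal the truth", {
  st <- generate_synthetic_study(small_cfg())
  hits <- sum(vapply(st$genome,
                     function(s) nrow(scan_sequence(s, "VGAATAW")), 0L))
  expect_equal(hits, st$truth$n_planted)
  expect_equal(st$truth$n_planted,
               sum(st$truth$regions$is_target))
  # every target region's summit sequence contains the motif
  res <- regions_with_motif(
    st$regions[st$truth$regions$is_target, ], st$genome)
  expect_equal(nrow(res$without_motif), 0L)
  # background regions are motif-free
  bg <- regions_with_motif(
    st$regions[!st$truth$regions$is_target, ], st$genome)
  expect_equal(nrow(bg$with_motif), 0L)
})

test_that("emitted files round-trip to the in-memory study", {
  d <- withr::local_tempdir()
  st <- generate_synthetic_study(small_cfg(), outdir = d)
  expect_equal(read_fasta(file.path(d, "genome.fasta")), st$genome)
  genes <- read_gff3(file.path(d, "genes.gff3"))
  genes <- genes[match(st$genes$gene_id, genes$gene_id), ]
  rownames(genes) <- NULL
  expect_equal(genes, st$genes)
  regions <- read_region_table(file.path(d, "regions.tsv"))
  expect_equal(regions$summit, st$regions$summit)
  expect_equal(regions$enrichment_1, st$regions$enrichment_1)
})

test_that("a pure upstream mixture annotates UP within 1 kb", {
  cfg <- small_cfg(placement_mixture = c(upstream_1kb = 1,
                                         gene_body = 0,
                                         downstream_1kb = 0,
                                         distal = 0))
  st <- generate_synthetic_study(cfg)
  tr <- st$truth$regions[st$truth$regions$is_target, ]
  asn <- assign_regions(st$regions[st$truth$regions$is_target, ],
                        st$genes)
  near <- asn[asn$is_nearest, ]
  expect_true(all(near$location == "UP"))
  expect_true(all(near$distance < 1000))
  expect_equal(near$gene_id, tr$gene_id)
})

test_that("truth tables are internally consistent", {
  st <- generate_synthetic_study(small_cfg())
  tg <- st$truth$genes
  expect_true(all(tg$is_bound[tg$is_planted]))
  expect_true(all(tg$is_direct_target == (tg$is_bound & tg$is_down)))
  tr <- st$truth$regions
  expect_true(all(tr$gene_id[tr$is_target] %in%
                    tg$gene_id[tg$is_planted]))
  # placement labels agree with annotation's nearest-bin classification
  asn <- assign_regions(st$regions[tr$is_target, ], st$genes)
  d <- position_distribution(asn,
                             n_regions = sum(tr$is_target))
  tab <- table(factor(tr$placement[tr$is_target],
                      levels = c("upstream_1kb", "gene_body",
                                 "downstream_1kb", "distal")))
  expect_equal(d$count, as.integer(tab))
})

test_that("zero targets yield an empty direct-target set", {
  cfg <- small_cfg(n_target_genes = 0L)
  st <- generate_synthetic_study(cfg)
  res <- run_pipeline(pipeline_config(
    regions = st$regions, genome = st$genome, genes = st$genes,
    probes = st$probes))
  expect_equal(nrow(res$targets), 0L)
})

test_that("infeasible configurations fail before output", {
  expect_error(synthetic_config(n_target_genes = 100, n_genes = 50),
               "exceeds")
  expect_error(synthetic_config(placement_mixture = c(
    upstream_1kb = 0.5, gene_body = 0.5, downstream_1kb = 0.2,
    distal = 0.2)), "sum to 1")
  expect_error(synthetic_config(placement_mixture = c(
    upstream_1kb = 0.5, gene_body = 0.5, downstream_1kb = 0.2,
    distal = -0.2)), "non-negative")
  expect_error(synthetic_config(
    enrichment_target = c(meanlog = log(2), sdlog = 0.3)),
    "filter threshold")
  expect_error(
    generate_synthetic_study(small_cfg(chrom_length = 10000L)),
    "do not fit")
})
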