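mk_gene <- function(id = "g1", strand = "+", body = c(1000L, 2000L),
                    cds = body, chrom = "chr1") {
  data.frame(gene_id = id, chrom = chrom, strand = strand,
             body_start = body[1], body_end = body[2],
             cds_start = cds[1], cds_end = cds[2],
             stringsAsFactors = FALSE)
}

mk_region <- function(summit, id = "r1", chrom = "chr1") {
  data.frame(region_id = id, chrom = chrom,
             start = summit - 10L, end = summit + 10L, summit = summit,
             enrichment_1 = 5, fdr_1 = 0.01, stringsAsFactors = FALSE)
}

test_that("assignment distance and location follow the conventions", {
  g <- mk_gene()
  # summit 500, CDS starts at 1000: 500 bp upstream of a plus gene
  a <- assign_regions(mk_region(500L), g)
  expect_equal(a$distance, 500L)
  expect_equal(a$location, "UP")
  # containment
  a <- assign_regions(mk_region(1500L), g)
  expect_equal(a$distance, 0L)
  expect_equal(a$location, "IN_CDS")
  # on a minus-strand gene the 5' side is the high-coordinate side
  a <- assign_regions(mk_region(2300L), mk_gene(strand = "-"))
  expect_equal(a$distance, 300L)
  expect_equal(a$location, "UP")
  # and the low-coordinate side is downstream
  a <- assign_regions(mk_region(700L), mk_gene(strand = "-"))
  expect_equal(a$distance, 300L)
  expect_equal(a$location, "DOWN")
  # a gene-body summit outside the strict CDS still counts as in-CDS
  g2 <- mk_gene(body = c(1000L, 2000L), cds = c(1200L, 1800L))
  a <- assign_regions(mk_region(1100L), g2)
  expect_equal(a$location, "IN_CDS")
  expect_equal(a$distance, 0L)
})

test_that("window bounds, multi-gene assignment and is_nearest ties", {
  genes <- rbind(mk_gene("gA", body = c(1000L, 2000L)),
                 mk_gene("gB", body = c(3000L, 4000L)))
  a <- assign_regions(mk_region(2500L), genes)
  expect_equal(sort(a$gene_id), c("gA", "gB"))
  expect_equal(a$distance, c(500L, 500L))
  # tie: lexicographically smaller gene id wins
  expect_equal(a$gene_id[a$is_nearest], "gA")
  expect_equal(sum(a$is_nearest), 1L)
  # window excludes far genes
  a <- assign_regions(mk_region(2500L), genes, window = 400)
  expect_equal(nrow(a), 0L)
  expect_error(assign_regions(mk_region(2500L), genes, window = 0),
               "positive")
  expect_error(assign_regions(mk_region(2500L),
                              rbind(genes, genes)), "duplicated")
})

test_that("assignment is invariant to gene order", {
  set.seed(21)
  genes <- do.call(rbind, lapply(1:30, function(i) {
    s <- i * 6000L
    mk_gene(sprintf("g%02d", i), sample(c("+", "-"), 1),
            body = c(s, s + 2000L))
  }))
  regions <- do.call(rbind, lapply(1:40, function(i)
    mk_region(sample(1000:190000, 1), sprintf("r%02d", i))))
  a1 <- assign_regions(regions, genes)
  a2 <- assign_regions(regions, genes[sample(nrow(genes)), ])
  ord <- function(x) {
    x <- x[order(x$region_id, x$gene_id), ]
    rownames(x) <- NULL
    x
  }
  expect_equal(ord(a1), ord(a2))
})

test_that("flipping every strand swaps UP and DOWN labels only", {
  set.seed(22)
  genes <- do.call(rbind, lapply(1:20, function(i) {
    s <- i * 8000L
    mk_gene(sprintf("g%02d", i), sample(c("+", "-"), 1),
            body = c(s, s + 2500L))
  }))
  regions <- do.call(rbind, lapply(1:30, function(i)
    mk_region(sample(5000:170000, 1), sprintf("r%02d", i))))
  flipped <- genes
  flipped$strand <- ifelse(genes$strand == "+", "-", "+")
  a <- assign_regions(regions, genes)
  b <- assign_regions(regions, flipped)
  expect_equal(a$distance, b$distance)
  expect_equal(a$is_nearest, b$is_nearest)
  swap <- c(UP = "DOWN", DOWN = "UP", IN_CDS = "IN_CDS")
  expect_equal(unname(swap[a$location]), b$location)
})

test_that("printed (distance, location) pairs are reproduced on toy loci", {
  for (w in c("development", "auxin")) {
    t <- kan_fixture(w)
    for (i in seq_len(nrow(t))) {
      body <- c(50000L, 52000L)
      g <- mk_gene(t$gene_id[i], "+", body)
      summit <- switch(t$location[i],
        UP = body[1] - t$distance[i],
        DOWN = body[2] + t$distance[i],
        IN_CDS = body[1] + 500L)
      a <- assign_regions(mk_region(summit), g, window = 10500)
      expect_equal(a$distance, t$distance[i])
      expect_equal(a$location, t$location[i])
    }
  }
})

test_that("position_distribution bins, sums and degenerates", {
  g <- mk_gene()
  regions <- rbind(mk_region(400L, "up"), mk_region(1500L, "in"),
                   mk_region(2600L, "down"), mk_region(8000L, "far"))
  a <- assign_regions(regions, g)
  d <- position_distribution(a, n_regions = 4)
  expect_equal(d$count, c(1L, 1L, 1L, 1L))
  expect_equal(sum(d$proportion), 1)
  # unassigned regions fall into the distal bin via n_regions
  d2 <- position_distribution(a[a$region_id != "far", ], n_regions = 4)
  expect_equal(d2$count[d2$bin == "distal"], 1L)
  # all upstream within 1 kb
  up_only <- assign_regions(rbind(mk_region(400L, "a"),
                                  mk_region(900L, "b")), g)
  d3 <- position_distribution(up_only)
  expect_equal(d3$proportion[d3$bin == "upstream_0_1kb"], 1)
  # empty input
  d4 <- position_distribution(a[0, ])
  expect_equal(d4$count, rep(0L, 4))
  expect_true(all(is.nan(d4$proportion)))
})
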