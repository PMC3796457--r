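test_that("bound-regulated intersection follows the chosen mode", {
  t1 <- kan_fixture("development")
  calls <- calls_from_flags(t1)
  res <- intersect_bound_regulated(unique(t1$gene_id), calls,
                                   "down_any")
  expect_equal(nrow(res), 19L)
  expect_equal(res$gene_id, sort(res$gene_id))
  expect_false("AT1G65620" %in% res$gene_id)  # -,- row stays out

  expect_equal(nrow(intersect_bound_regulated(character(0), calls)), 0L)
  one <- data.frame(gene_id = "g", down_80 = FALSE, down_160 = FALSE,
                    up_80 = FALSE, up_160 = FALSE)
  expect_equal(nrow(intersect_bound_regulated("g", one)), 0L)
  expect_error(intersect_bound_regulated("g", one, mode = "bogus"))
})

test_that("modes nest and the overlap is bounded by both sets", {
  set.seed(41)
  for (i in 1:20) {
    n <- 60
    calls <- data.frame(gene_id = sprintf("g%02d", 1:n),
                        down_80 = runif(n) < 0.3,
                        down_160 = runif(n) < 0.4,
                        up_80 = runif(n) < 0.1,
                        up_160 = runif(n) < 0.1)
    calls$up_80 <- calls$up_80 & !(calls$down_80 | calls$down_160)
    calls$up_160 <- calls$up_160 & !(calls$down_80 | calls$down_160)
    bound <- sample(calls$gene_id, 30)
    both <- intersect_bound_regulated(bound, calls, "down_both")
    any_ <- intersect_bound_regulated(bound, calls, "down_any")
    chg <- intersect_bound_regulated(bound, calls, "any_change")
    expect_true(all(both$gene_id %in% any_$gene_id))
    expect_true(all(any_$gene_id %in% chg$gene_id))
    n_reg <- sum(calls$down_80 | calls$down_160)
    expect_lte(nrow(any_), min(length(bound), n_reg))
    cnt <- attr(any_, "counts")
    expect_equal(unname(cnt["down_any"]),
                 unname(cnt["down_both"] + cnt["down_80_only"] +
                          cnt["down_160_only"]))
  }
})

test_that("compare_factors matches the printed pair-distance example", {
  a <- data.frame(gene_id = "TEM1", pos = 100L)
  b <- data.frame(gene_id = "TEM1", pos = 161L)
  r <- compare_factors(a, b)
  expect_equal(r$pair_distance, 61L)
  expect_true(r$proximal)
  # identical sites and the strict boundary
  expect_equal(compare_factors(a, a)$pair_distance, 0L)
  r2 <- compare_factors(data.frame(gene_id = "g", pos = 0L),
                        data.frame(gene_id = "g", pos = 100L),
                        proximity_threshold = 100)
  expect_false(r2$proximal)
  expect_error(compare_factors(data.frame(gene_id = "g", pos = NA),
                               a), "missing site position")
})

test_that("pair distance is symmetric and matches brute enumeration", {
  set.seed(42)
  genes <- sprintf("g%03d", 1:200)
  mk_sites <- function() {
    do.call(rbind, lapply(genes, function(g) {
      k <- sample(1:8, 1)
      data.frame(gene_id = g, pos = sample(0:50000, k),
                 stringsAsFactors = FALSE)
    }))
  }
  a <- mk_sites(); b <- mk_sites()
  ab <- compare_factors(a, b)
  ba <- compare_factors(b, a)
  expect_equal(ab$pair_distance, ba$pair_distance)
  for (g in sample(genes, 200)) {
    expect_equal(ab$pair_distance[ab$gene_id == g],
                 oracle_min_dist(a$pos[a$gene_id == g],
                                 b$pos[b$gene_id == g]))
  }
  # genes present in only one map are excluded but counted
  ax <- a[a$gene_id != "g001", ]
  r <- compare_factors(ax, b)
  expect_false("g001" %in% r$gene_id)
  expect_equal(unname(attr(r, "summary")["only_b"]), 1L)
})

test_that("dual_candidates collapses the fixture per gene", {
  t3 <- kan_fixture("dual")
  d <- dual_candidates(t3)
  expect_equal(nrow(d), 26L)
  expect_equal(sum(d$proximal), 5L)
  expect_equal(d$pair_distance[d$gene_id == "AT1G66140"], 26L)
  # strictness of the threshold
  d0 <- dual_candidates(t3, proximity_threshold = 14)
  expect_false(d0$proximal[d0$gene_id == "AT3G15570"])  # distance 14
})

test_that("tabulate_targets counts with and without regulation", {
  t2 <- kan_fixture("auxin")
  calls <- calls_from_flags(t2)
  records <- data.frame(gene_id = calls$gene_id,
                        regulated = calls$down_80 | calls$down_160)
  cmap <- data.frame(gene_id = unique(t2$gene_id), category = "auxin")
  tab <- tabulate_targets(records, cmap)
  expect_equal(tab$n_genes, 22L)
  expect_equal(tab$n_regulated, 21L)
  empty <- tabulate_targets(records[0, ], cmap)
  expect_equal(empty$n_genes, 0L)
})
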