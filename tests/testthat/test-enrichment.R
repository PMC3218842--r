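sizes_e <- c(chr1 = 1000000L, chr2 = 500000L)

test_that("matched random intervals preserve the length multiset and the seed", {
  set.seed(51)
  template <- random_intervals(40, sizes_e, min_w = 100, max_w = 5000)
  r1 <- random_matched_intervals(template, sizes_e, seed = 7)
  expect_equal(sort(width(r1)), sort(width(template)))
  r2 <- random_matched_intervals(template, sizes_e, seed = 7)
  expect_identical(r1, r2)
  ## in bounds
  expect_true(all(bed_end(r1) <=
                    sizes_e[as.character(seqnames(r1))]))
  ## a template longer than every chromosome is rejected
  big <- bed_ranges("chr1", 0, 999999, chrom_sizes = sizes_e)
  expect_silent(random_matched_intervals(big, sizes_e, seed = 1))
  too_big <- bed_ranges("chr1", 0, 2000000,
                        chrom_sizes = c(chr1 = 2000000L))
  expect_error(random_matched_intervals(too_big, sizes_e, seed = 1),
               "longer than every chromosome")
})

test_that("random placement of a 1-bp interval is uniform (chi-square GOF)", {
  cs <- c(c10 = 10L)
  ## placements are independent per template element, so a template of many
  ## identical 1-bp intervals yields i.i.d. uniform starts
  template <- bed_ranges(rep("c10", 20000), rep(0, 20000), rep(1, 20000),
                         chrom_sizes = cs)
  set.seed(52)
  starts <- bed_start(random_matched_intervals(template, cs))
  tab <- table(factor(starts, levels = 0:9))
  expect_gt(chisq.test(tab)$p.value, 0.001)
})

test_that("overlap fraction matches an all-pairs brute force", {
  set.seed(53)
  a <- random_intervals(60, sizes_e, min_w = 50, max_w = 2000)
  b <- random_intervals(80, sizes_e, min_w = 50, max_w = 2000)
  expect_equal(overlap_fraction(a, b), mean(brute_overlap_any(a, b)))

  whole <- bed_ranges(names(sizes_e), c(0, 0), as.numeric(sizes_e),
                      chrom_sizes = sizes_e)
  expect_equal(overlap_fraction(a, whole), 1.0)
  far_a <- bed_ranges("chr1", 0, 100, chrom_sizes = sizes_e)
  far_b <- bed_ranges("chr1", 200, 300, chrom_sizes = sizes_e)
  expect_equal(overlap_fraction(far_a, far_b), 0.0)
  ## bookended intervals (half-open) do not overlap
  expect_equal(overlap_fraction(
    bed_ranges("chr1", 0, 100, chrom_sizes = sizes_e),
    bed_ranges("chr1", 100, 200, chrom_sizes = sizes_e)), 0.0)
  expect_error(overlap_fraction(a[0], b), "empty")
})

test_that("permutation enrichment handles saturated and maximal cases", {
  set.seed(54)
  regions <- random_intervals(20, sizes_e, min_w = 200, max_w = 1000)
  whole <- bed_ranges(names(sizes_e), c(0, 0), as.numeric(sizes_e),
                      chrom_sizes = sizes_e)
  res <- permutation_enrichment(regions, whole, sizes_e, n_perm = 20,
                                seed = 1)
  expect_equal(res$observed, 1.0)
  expect_equal(res$null_mean, 1.0)
  expect_equal(res$z_score, 0)
  expect_equal(res$empirical_p, 1.0)

  ## regions identical to features: maximal enrichment
  res2 <- permutation_enrichment(regions, regions, sizes_e, n_perm = 99,
                                 seed = 2)
  expect_equal(res2$observed, 1.0)
  expect_lte(res2$empirical_p, (1 + sum(res2$null_values >= 1)) / 100)
  expect_gte(res2$empirical_p, 1 / 100)
  expect_error(permutation_enrichment(regions, regions, sizes_e,
                                      n_perm = 0), "n_perm")
})

test_that("null overlap rate matches the exact enumeration oracle", {
  ## one 1-kb region, one 100-kb feature on a 1-Mb chromosome: a random
  ## 1-kb placement overlaps iff its start is in an interval of
  ## 100000 + 999 of the 999001 valid starts
  cs <- c(chr1 = 1000000L)
  region <- bed_ranges("chr1", 0, 1000, chrom_sizes = cs)
  feature <- bed_ranges("chr1", 450000, 550000, chrom_sizes = cs)
  p_hit <- (100000 + 999) / 999001
  res <- permutation_enrichment(region, feature, cs, n_perm = 2000,
                                seed = 55)
  expect_lt(abs(res$null_mean - p_hit),
            3 * sqrt(p_hit * (1 - p_hit) / 2000))
})

test_that("empirical p is conservative and roughly uniform under the null", {
  ## enough regions that the overlap fraction is fine-grained, so the
  ## discrete empirical p is close to uniform
  cs <- c(chr1 = 1000000L)
  set.seed(56)
  features <- random_intervals(150, cs, min_w = 500, max_w = 2000)
  template <- random_intervals(60, cs, min_w = 200, max_w = 1000)
  n_perm <- 33
  ps <- vapply(seq_len(200), function(i) {
    null_regions <- random_matched_intervals(template, cs)
    permutation_enrichment(null_regions, features, cs,
                           n_perm = n_perm)$empirical_p
  }, numeric(1))
  expect_true(all(ps >= 1 / (n_perm + 1) & ps <= 1))
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.001)
  ## validity: the permutation p rejects at most at its nominal level
  for (alpha in c(0.05, 0.1, 0.2)) {
    expect_lte(mean(ps <= alpha),
               alpha + 3 * sqrt(alpha * (1 - alpha) / length(ps)))
  }
})

test_that("closest gene follows the TSS distance rule with ties and cap", {
  cs <- c(chr1 = 1000000L)
  genes <- bed_ranges("chr1", c(5000, 12000, 400000),
                      c(9000, 20000, 410000), c("+", "-", "+"),
                      chrom_sizes = cs, gene_id = c("gA", "gB", "gC"))
  ## TSS: gA 5000 (+), gB 19999 (-), gC 400000 (+)
  inside <- bed_ranges("chr1", 4500, 5500, chrom_sizes = cs)
  res <- closest_gene(inside, genes)
  expect_equal(res$gene_id, "gA")
  expect_equal(res$tss_distance, 0)

  ## distance measured from the nearest region base
  nearby <- bed_ranges("chr1", 6000, 7000, chrom_sizes = cs)
  res <- closest_gene(nearby, genes)
  expect_equal(res$gene_id, "gA")
  expect_equal(res$tss_distance, 1000)  # 6000 - 5000

  ## beyond the 100-kb cap -> unassigned
  lonely <- bed_ranges("chr1", 650000, 651000, chrom_sizes = cs)
  res <- closest_gene(lonely, genes)
  expect_true(is.na(res$gene_id))

  ## equidistant TSSs -> lexicographically smallest id
  tie_genes <- bed_ranges("chr1", c(1000, 3000), c(2000, 4000),
                          c("+", "+"), chrom_sizes = cs,
                          gene_id = c("zz", "aa"))
  mid <- bed_ranges("chr1", 1999, 2002, chrom_sizes = cs)
  ## TSS zz = 1000 (dist 999), TSS aa = 3000 (dist 999)
  res <- closest_gene(mid, tie_genes)
  expect_equal(res$gene_id, "aa")
})

test_that("closest gene matches an all-pairs oracle and shifts with coordinates", {
  cs <- c(chr1 = 200000L, chr2 = 200000L)
  set.seed(57)
  genes <- random_intervals(30, cs, min_w = 1000, max_w = 5000,
                            strand = TRUE)
  mcols(genes)$gene_id <- sprintf("g%02d", sample(30))
  regions <- random_intervals(40, cs, min_w = 100, max_w = 2000)
  res <- closest_gene(regions, genes, max_distance = 50000)

  tss <- ifelse(as.character(strand(genes)) == "+", bed_start(genes),
                bed_end(genes) - 1)
  oracle <- function(i) {
    sel <- as.character(seqnames(genes)) ==
      as.character(seqnames(regions))[i]
    if (!any(sel)) return(list(id = NA_character_, d = NA_real_))
    s <- bed_start(regions)[i]; e <- bed_end(regions)[i]
    d <- ifelse(tss[sel] >= s & tss[sel] < e, 0,
                ifelse(tss[sel] < s, s - tss[sel], tss[sel] - (e - 1)))
    dmin <- min(d)
    if (dmin > 50000) return(list(id = NA_character_, d = NA_real_))
    list(id = min(mcols(genes)$gene_id[sel][d == dmin]), d = dmin)
  }
  for (i in seq_along(regions)) {
    o <- oracle(i)
    expect_identical(res$gene_id[i], o$id)
    expect_equal(res$tss_distance[i], o$d)
  }

  ## translation invariance
  shift_gr <- function(gr, by) {
    out <- bed_ranges(as.character(seqnames(gr)), bed_start(gr) + by,
                      bed_end(gr) + by, as.character(strand(gr)),
                      chrom_sizes = c(chr1 = 300000L, chr2 = 300000L))
    mcols(out) <- mcols(gr)
    out
  }
  res_shift <- closest_gene(shift_gr(regions, 7000),
                            shift_gr(genes, 7000), max_distance = 50000)
  expect_identical(res_shift$gene_id, res$gene_id)
  expect_equal(res_shift$tss_distance, res$tss_distance)
})

test_that("cell-specific gene selection applies inclusive boundaries", {
  expr <- data.frame(
    gene_id = c("in_boundary", "below", "leaky", "strong"),
    rpkm_hesc = c(0.5, 0.4, 2.0, 8),
    rpkm_imr90 = c(0.0, 0.0, 0.1, 0))
  expect_setequal(specific_gene_set(expr), c("in_boundary", "strong"))
})

test_that("Fisher p equals the hypergeometric enumeration oracle", {
  m <- matrix(c(10, 0, 0, 10), 2, byrow = TRUE)
  res <- fisher_exact_2x2(m)
  expect_equal(res$p_value, 2 / choose(20, 10), tolerance = 1e-9)
  expect_true(is.infinite(res$odds_ratio))

  ## identical proportions -> p = 1
  eq <- matrix(c(5, 5, 5, 5), 2)
  expect_equal(fisher_exact_2x2(eq)$p_value, 1)
  expect_equal(brute_fisher_two_sided(eq), 1)

  ## degenerate margins flagged with p = 1
  degen <- matrix(c(0, 0, 7, 3), 2, byrow = TRUE)
  res_d <- fisher_exact_2x2(degen)
  expect_true(res_d$degenerate)
  expect_equal(res_d$p_value, 1)
})

test_that("gene-set overlap test builds the right table and percentages", {
  cs <- c(chr1 = 100000L)
  genes <- bed_ranges("chr1", seq(0, 90000, 10000),
                      seq(0, 90000, 10000) + 5000, "+", chrom_sizes = cs,
                      gene_id = sprintf("g%02d", 1:10))
  ## regions overlap genes 1-4
  regions <- bed_ranges("chr1", seq(0, 30000, 10000),
                        seq(0, 30000, 10000) + 1000, chrom_sizes = cs)
  special <- c("g01", "g02", "g05")
  res <- gene_set_overlap_test(special, genes, regions)
  expect_equal(unname(res$table["special", ]), c(2L, 1L))
  expect_equal(unname(res$table["other", ]), c(2L, 5L))
  expect_equal(res$pct_special, 100 * 2 / 3)
  expect_equal(res$pct_all, 100 * 4 / 10)
  expect_equal(res$p_value, brute_fisher_two_sided(res$table),
               tolerance = 1e-9)
  expect_error(gene_set_overlap_test(c("nope"), genes, regions),
               "absent")
})
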