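sizes_m <- c(chr1 = 60000L)

test_that("gene metaprofile saturates at 1 and vanishes without regions", {
  genes <- bed_ranges("chr1", 20000, 40000, "+", chrom_sizes = sizes_m,
                      gene_id = "g1")
  all_cov <- bed_ranges("chr1", 0, 60000, chrom_sizes = sizes_m)
  prof <- gene_metaprofile(all_cov, genes, sizes_m, bin_size = 300,
                           flank = 3000, n_body_bins = 50)
  expect_true(all(prof$value == 1))
  expect_true(all(prof$smoothed == 1))  # smoothing preserves constants

  prof0 <- gene_metaprofile(all_cov[0], genes, sizes_m, bin_size = 300,
                            flank = 3000, n_body_bins = 50)
  expect_true(all(prof0$value == 0))
})

test_that("a region over the 5' half fills exactly the first 25 body bins", {
  genes <- bed_ranges("chr1", 15000, 45000, "+", chrom_sizes = sizes_m,
                      gene_id = "g1")
  region <- bed_ranges("chr1", 15000, 30000, chrom_sizes = sizes_m)
  prof <- gene_metaprofile(region, genes, sizes_m, bin_size = 300,
                           flank = 15000, n_body_bins = 50, smooth = 0)
  body <- prof$value[prof$section == "body"]
  expect_equal(body[1:25], rep(1, 25))
  expect_equal(body[26:50], rep(0, 25))
  expect_true(all(prof$value[prof$section == "upstream"] == 0))
  expect_true(all(prof$value[prof$section == "downstream"] == 0))

  ## same gene on the minus strand is flipped (TSS left)
  genes_m <- bed_ranges("chr1", 15000, 45000, "-", chrom_sizes = sizes_m,
                        gene_id = "g1")
  prof_m <- gene_metaprofile(region, genes_m, sizes_m, bin_size = 300,
                             flank = 15000, n_body_bins = 50, smooth = 0)
  body_m <- prof_m$value[prof_m$section == "body"]
  expect_equal(body_m[1:25], rep(0, 25))
  expect_equal(body_m[26:50], rep(1, 25))
})

test_that("gene metaprofile equals a per-base oracle on a 10-kb toy chromosome", {
  cs <- c(chr1 = 10000L)
  set.seed(41)
  regions <- random_intervals(25, cs, min_w = 100, max_w = 600)
  genes <- bed_ranges("chr1", c(1200, 4500), c(4200, 8500), c("+", "-"),
                      chrom_sizes = cs, gene_id = c("g1", "g2"))
  bin_size <- 100; flank <- 1000; nb <- 50
  prof <- gene_metaprofile(regions, genes, cs, bin_size = bin_size,
                           flank = flank, n_body_bins = nb, smooth = 0)
  ## oracle: indicator vector + direct TSS-left local coordinates
  ind <- integer(10000)
  for (i in seq_along(regions))
    ind[(bed_start(regions)[i] + 1):bed_end(regions)[i]] <- 1L
  nf <- flank / bin_size
  oracle_gene <- function(gs, ge, minus) {
    L <- ge - gs
    stopifnot(L %% nb == 0)
    body_w <- L / nb
    widths <- c(rep(bin_size, nf), rep(body_w, nb), rep(bin_size, nf))
    t_edges <- cumsum(c(0, widths))
    vapply(seq_len(length(widths)), function(j) {
      ts <- t_edges[j]:(t_edges[j + 1] - 1)
      pos <- if (!minus) gs - flank + ts else ge + flank - 1 - ts
      pos <- pos[pos >= 0 & pos < 10000]
      mean(ind[pos + 1])
    }, numeric(1))
  }
  oracle <- (oracle_gene(1200, 4200, FALSE) +
               oracle_gene(4500, 8500, TRUE)) / 2
  expect_equal(prof$value, oracle, tolerance = 1e-9)
})

test_that("short genes use fractional body bins without error", {
  cs <- c(chr1 = 10000L)
  genes <- bed_ranges("chr1", 5000, 5030, "+", chrom_sizes = cs,
                      gene_id = "tiny")  # 30 bp << 50 bins
  region <- bed_ranges("chr1", 5000, 5030, chrom_sizes = cs)
  prof <- gene_metaprofile(region, genes, cs, bin_size = 100, flank = 500,
                           n_body_bins = 50, smooth = 0)
  expect_true(all(prof$value[prof$section == "body"] == 1))
  expect_true(all(prof$value >= 0 & prof$value <= 1))
})

test_that("profiles are invariant to region order and internal splits", {
  cs <- c(chr1 = 10000L)
  set.seed(42)
  regions <- random_intervals(15, cs, min_w = 200, max_w = 800)
  genes <- bed_ranges("chr1", 2000, 7000, "+", chrom_sizes = cs,
                      gene_id = "g")
  base <- gene_metaprofile(regions, genes, cs, bin_size = 100,
                           flank = 1000, n_body_bins = 50)
  shuffled <- regions[sample(length(regions))]
  expect_equal(gene_metaprofile(shuffled, genes, cs, bin_size = 100,
                                flank = 1000, n_body_bins = 50)$value,
               base$value)
  ## split each region at an internal point
  mid <- floor((bed_start(regions) + bed_end(regions)) / 2)
  split_regions <- c(
    bed_ranges(rep("chr1", length(regions)), bed_start(regions), mid,
               chrom_sizes = cs),
    bed_ranges(rep("chr1", length(regions)), mid, bed_end(regions),
               chrom_sizes = cs))
  expect_equal(gene_metaprofile(split_regions, genes, cs, bin_size = 100,
                                flank = 1000, n_body_bins = 50)$value,
               base$value)
})

test_that("metaprofile is invariant under coordinate mirror with strand flip", {
  cs <- c(chr1 = 10000L)
  set.seed(43)
  regions <- random_intervals(12, cs, min_w = 100, max_w = 500)
  genes <- bed_ranges("chr1", c(2000, 6000), c(4500, 9000), c("+", "-"),
                      chrom_sizes = cs, gene_id = c("a", "b"))
  mirror <- function(gr, flip_strand = TRUE) {
    s <- 10000 - bed_end(gr); e <- 10000 - bed_start(gr)
    st <- as.character(strand(gr))
    if (flip_strand) st <- chartr("+-", "-+", st)
    out <- bed_ranges(as.character(seqnames(gr)), s, e, st,
                      chrom_sizes = cs)
    mcols(out) <- mcols(gr)
    out
  }
  p1 <- gene_metaprofile(regions, genes, cs, bin_size = 100, flank = 1000,
                         n_body_bins = 50)
  p2 <- gene_metaprofile(mirror(regions, FALSE), mirror(genes), cs,
                         bin_size = 100, flank = 1000, n_body_bins = 50)
  expect_equal(p1$value, p2$value, tolerance = 1e-12)
})

test_that("expression stratification ranks, breaks ties by id, and splits evenly", {
  cs <- c(chr1 = 100000L)
  genes <- bed_ranges(rep("chr1", 4), c(0, 100, 200, 300) * 100,
                      c(50, 150, 250, 350) * 100, "+", chrom_sizes = cs,
                      gene_id = c("g9", "g7", "g3", "g1"))
  expr <- data.frame(gene_id = c("g9", "g7", "g3", "g1"),
                     rpkm = c(9, 7, 3, 1))
  st <- stratify_by_expression(genes, expr, n_strata = 2)
  expect_equal(st$stratum, c(1L, 1L, 2L, 2L))

  ## ties resolved by lexicographic id, sizes differ by <= 1
  expr_tie <- data.frame(gene_id = c("g9", "g7", "g3", "g1"),
                         rpkm = c(5, 5, 5, 5))
  st_tie <- stratify_by_expression(genes, expr_tie, n_strata = 3)
  expect_equal(table(st_tie$stratum) |> as.integer() |> sort(),
               c(1L, 1L, 2L))
  ## g1 < g3 < g7 < g9 lexicographically; stratum 1 gets the smallest ids
  expect_equal(st_tie$stratum[match(c("g1", "g3"),
                                    mcols(st_tie$genes)$gene_id)],
               c(1L, 1L))

  expect_error(stratify_by_expression(genes, expr, n_strata = 5),
               "more strata")
})

test_that("stratification matches a sort oracle on many random genes", {
  cs <- c(chr1 = 10000000L)
  n <- 1000
  set.seed(44)
  starts <- seq(0, by = 9000, length.out = n)
  genes <- bed_ranges(rep("chr1", n), starts, starts + 5000, "+",
                      chrom_sizes = cs,
                      gene_id = sprintf("g%04d", seq_len(n)))
  expr <- data.frame(gene_id = mcols(genes)$gene_id,
                     rpkm = round(rlnorm(n), 4))
  st <- stratify_by_expression(genes, expr, n_strata = 5)
  rpkm <- expr$rpkm[match(mcols(st$genes)$gene_id, expr$gene_id)]
  for (k in 1:4)
    expect_gte(min(rpkm[st$stratum == k]), max(rpkm[st$stratum == k + 1]))
  expect_true(all(abs(diff(as.integer(table(st$stratum)))) <= 1))
})

test_that("point metaprofile geometry matches hand-computed fractions", {
  cs <- c(chr1 = 10000L)
  centers <- bed_ranges("chr1", 5000, 5001, chrom_sizes = cs)
  region <- bed_ranges("chr1", 4950, 5050, chrom_sizes = cs)
  prof <- point_metaprofile(region, centers, cs, span = 2000, window = 100)
  expect_length(prof$value, 40L)
  expect_equal(prof$value[prof$offset == -100], 0.5)
  expect_equal(prof$value[prof$offset == 0], 0.5)
  expect_equal(sum(prof$value), 1.0)

  ## saturation
  whole <- bed_ranges("chr1", 0, 10000, chrom_sizes = cs)
  expect_true(all(point_metaprofile(whole, centers, cs, span = 2000,
                                    window = 100)$value == 1))
  expect_error(point_metaprofile(region, centers[0], cs), "non-empty")
})

test_that("point metaprofile equals a per-base averaging oracle", {
  cs <- c(chr1 = 20000L)
  set.seed(45)
  regions <- random_intervals(30, cs, min_w = 50, max_w = 400)
  centers <- random_intervals(8, cs, min_w = 100, max_w = 300)
  span <- 1000; win <- 100
  prof <- point_metaprofile(regions, centers, cs, span = span, window = win)
  ind <- integer(20000)
  for (i in seq_along(regions))
    ind[(bed_start(regions)[i] + 1):bed_end(regions)[i]] <- 1L
  mids <- floor((bed_start(centers) + bed_end(centers)) / 2)
  oracle <- sapply(seq_len(2 * span / win), function(j) {
    ## centers whose bin lies wholly off-chromosome drop out of the mean
    mean(vapply(mids, function(m) {
      lo <- m - span + (j - 1) * win; hi <- lo + win - 1
      pos <- lo:hi
      pos <- pos[pos >= 0 & pos < 20000]
      mean(ind[pos + 1])
    }, numeric(1)), na.rm = TRUE)
  })
  expect_equal(prof$value, oracle, tolerance = 1e-9)
})

test_that("midpoint-count estimator counts region midpoints per bin", {
  cs <- c(chr1 = 10000L)
  centers <- bed_ranges("chr1", 5000, 5001, chrom_sizes = cs)
  regions <- bed_ranges("chr1", c(4900, 4960, 5900), c(5000, 5040, 6100),
                        chrom_sizes = cs)  # midpoints 4950, 5000, 6000
  prof <- point_metaprofile(regions, centers, cs, span = 200, window = 100,
                            stat = "midpoints")
  expect_equal(prof$value[prof$offset == -100], 1)  # midpoint 4950
  expect_equal(prof$value[prof$offset == 0], 1)     # midpoint 5000
  expect_equal(prof$value[prof$offset == 100], 0)   # 6000 out of span
})

test_that("truncated smoothing preserves constants and interior mass", {
  expect_equal(moving_average(rep(0.7, 30)), rep(0.7, 30))
  ## with zero margins wider than the window, the truncated renormalized
  ## average conserves total mass exactly
  set.seed(46)
  x <- c(rep(0, 4), runif(20), rep(0, 4))
  expect_equal(sum(moving_average(x)), sum(x), tolerance = 1e-9)
  ## hand-computed edge behavior
  y <- c(1, 0, 0, 0, 0)
  expect_equal(moving_average(y), c(1 / 3, 1 / 4, 1 / 5, 0, 0))
})
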