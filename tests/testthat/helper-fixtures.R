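## Shared fixture builders and brute-force oracles. Everything is generated
## in code; no data files.

suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
})

## random interval set in BED coordinates on given chromosomes
random_intervals <- function(n, chrom_sizes, min_w = 50, max_w = 500,
                             seed = NULL, strand = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  chrom <- sample(names(chrom_sizes), n, replace = TRUE,
                  prob = chrom_sizes / sum(chrom_sizes))
  w <- if (min_w == max_w) rep(min_w, n) else
    sample(min_w:max_w, n, replace = TRUE)
  s <- floor(runif(n, 0, chrom_sizes[chrom] - w))
  bed_ranges(chrom, s, s + w,
             strand = if (strand) sample(c("+", "-"), n, TRUE) else "*",
             chrom_sizes = chrom_sizes)
}

## O(|A|*|B|) any-overlap oracle on BED coordinates
brute_overlap_any <- function(a, b) {
  as <- bed_start(a); ae <- bed_end(a)
  bs <- bed_start(b); be <- bed_end(b)
  ac <- as.character(seqnames(a)); bc <- as.character(seqnames(b))
  vapply(seq_along(a), function(i) {
    any(bc == ac[i] & bs < ae[i] & be > as[i])
  }, logical(1))
}

## from-scratch Benjamini-Hochberg on a p-vector
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

## two-sided Fisher p by hypergeometric enumeration (margins fixed)
brute_fisher_two_sided <- function(m) {
  x <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  k <- lo:hi
  pk <- dhyper(k, c1, n - c1, r1)
  sum(pk[pk <= dhyper(x, c1, n - c1, r1) * (1 + 1e-7)])
}

## upper-tail Poisson by direct summation
brute_poisson_upper <- function(x, lambda, kmax = 500) {
  k <- x:kmax
  sum(exp(-lambda + k * log(lambda) - lfactorial(k)))
}

## manually constructed window_counts object
make_window_counts <- function(counts_list, window, chrom_sizes) {
  structure(list(counts = counts_list, window = window,
                 chrom_sizes = chrom_sizes),
            class = "window_counts")
}

## tiny synthetic config for fast end-to-end tests
small_config <- function(...) {
  args <- utils::modifyList(
    list(n_chroms = 2, chrom_length = 4e6, n_true_regions = 40,
         depth = 2e4, n_genes = 60, n_enhancers = 30, n_tfbs = 20),
    list(...))
  do.call(synthetic_config, args)
}
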