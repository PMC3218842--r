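## Metaprofiles: average 5hmC region signal over scaled gene models
## (TSS -> TTS with fixed flanks, expression-stratified) and over feature
## centers. "Peak density" per bin is the mean fraction of bin bases covered
## by at least one region; a count-of-region-midpoints estimator is
## available behind the `stat` flag.

## 0/1 coverage indicator of a region set, per chromosome.
region_indicator <- function(regions, chrom_sizes) {
  gr <- GenomicRanges::granges(regions)
  GenomicRanges::strand(gr) <- "*"
  gr <- GenomicRanges::reduce(gr)
  GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
  GenomeInfoDb::seqlengths(gr) <- as.integer(chrom_sizes)
  GenomicRanges::coverage(gr)[names(chrom_sizes)]
}

## Extract indicator over BED span [s, e) on `chrom`, NA outside bounds.
indicator_window <- function(ind, chrom, s, e, chrom_sizes) {
  L <- chrom_sizes[[chrom]]
  n <- e - s
  out <- rep(NA_real_, n)
  lo <- max(s, 0); hi <- min(e, L)
  if (hi > lo) {
    v <- as.numeric(S4Vectors::window(ind[[chrom]], lo + 1, hi))
    v <- pmin(v, 1)
    out[(lo - s + 1):(hi - s)] <- v
  }
  out
}

## Mean of x over fractional index range [a, b) (0-based, may be fractional)
## using linear interpolation of cumulative sums; NA bases excluded from the
## denominator. Returns NA when no bases are counted.
fractional_bin_means <- function(x, edges) {
  n <- length(x)
  val <- ifelse(is.na(x), 0, x)
  cnt <- as.numeric(!is.na(x))
  Cv <- c(0, cumsum(val))
  Cc <- c(0, cumsum(cnt))
  interp <- function(C, t) {
    t <- pmin(pmax(t, 0), n)
    i <- floor(t)
    f <- t - i
    C[i + 1] + f * (C[pmin(i + 2, n + 1)] - C[i + 1])
  }
  a <- edges[-length(edges)]; b <- edges[-1]
  num <- interp(Cv, b) - interp(Cv, a)
  den <- interp(Cc, b) - interp(Cc, a)
  ifelse(den > 1e-9, num / den, NA_real_)
}

## Count of midpoints (0-based local positions) per fractional bin.
midpoint_bin_counts <- function(mids, edges) {
  if (!length(mids)) return(numeric(length(edges) - 1))
  idx <- findInterval(mids, edges, rightmost.closed = FALSE)
  tabulate(idx[idx >= 1 & idx <= length(edges) - 1],
           nbins = length(edges) - 1)
}

#' Truncated moving average
#'
#' Smooths by averaging over +/- `half` bins; windows are truncated at the
#' profile ends and the weights renormalized, so a constant profile is
#' preserved exactly. NAs are ignored within each window.
#'
#' @param x numeric vector.
#' @param half half-width in bins (default 2, i.e. a 5-bin window).
#' @return numeric vector of the same length.
#' @export
moving_average <- function(x, half = 2) {
  n <- length(x)
  if (n == 0 || half == 0) return(x)
  vapply(seq_len(n), function(i) {
    w <- x[max(1, i - half):min(n, i + half)]
    if (all(is.na(w))) NA_real_ else mean(w, na.rm = TRUE)
  }, numeric(1))
}

#' Rank genes into expression strata
#'
#' Genes are ranked by RPKM descending (ties broken by gene_id lexicographic
#' order) and split into `n_strata` near-equal groups, stratum 1 being the
#' most highly expressed. Genes absent from the expression table are dropped
#' with a message reporting the count.
#'
#' @param genes GRanges with a `gene_id` metadata column.
#' @param expression data.frame keyed by gene_id; `column` selects the RPKM
#'   column (default the first non-id numeric column).
#' @param n_strata number of strata (must not exceed the number of genes).
#' @param column expression column name.
#' @return list with `genes` (the retained genes) and `stratum` (integer
#'   vector, 1 = highest expression).
#' @export
stratify_by_expression <- function(genes, expression, n_strata = 5,
                                   column = NULL) {
  ids <- S4Vectors::mcols(genes)$gene_id
  if (is.null(ids)) stop("genes need a gene_id metadata column",
                         call. = FALSE)
  if (is.null(column)) {
    num <- names(expression)[vapply(expression, is.numeric, logical(1))]
    column <- num[1]
  }
  m <- match(ids, expression$gene_id)
  dropped <- sum(is.na(m))
  if (dropped) message(dropped, " gene(s) without expression values dropped")
  keep <- !is.na(m)
  genes <- genes[keep]
  rpkm <- expression[[column]][m[keep]]
  n <- length(genes)
  if (n_strata > n) stop("more strata than genes", call. = FALSE)
  ord <- order(-rpkm, S4Vectors::mcols(genes)$gene_id)
  sizes <- rep(n %/% n_strata, n_strata)
  extra <- n %% n_strata
  if (extra) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  stratum <- integer(n)
  stratum[ord] <- rep(seq_len(n_strata), times = sizes)
  list(genes = genes, stratum = stratum)
}

#' Metaprofile over scaled gene models
#'
#' Each gene contributes an upstream flank in fixed `bin_size` bins, a body
#' rescaled to `n_body_bins` bins (fractional coordinates for short genes),
#' and a downstream flank; minus-strand genes are flipped so the TSS is on
#' the left. The per-bin value is the fraction of bin bases covered by at
#' least one region (`stat = "coverage"`) or the count of region midpoints
#' (`stat = "midpoints"`), averaged across the genes of each stratum; bases
#' beyond chromosome ends are excluded from the denominator. Profiles are
#' smoothed by a truncated moving average over +/- `smooth` bins.
#'
#' @param regions GRanges of called regions.
#' @param genes GRanges of gene models (strand required; TSS is the 5' end).
#' @param chrom_sizes named chromosome lengths.
#' @param bin_size flank bin size in bp (default 300).
#' @param flank flank extent in bp (default 15000; must be a multiple of
#'   `bin_size`).
#' @param n_body_bins number of scaled gene-body bins (default 50).
#' @param stratum optional integer vector (same length as genes) of stratum
#'   labels, e.g. from \code{\link{stratify_by_expression}}.
#' @param smooth moving-average half-width in bins (default 2; 0 disables).
#' @param stat per-bin estimator (see above).
#' @return data.frame of class `metaprofile`: bin_index, section
#'   (upstream/body/downstream), stratum, value (raw), smoothed, n_genes.
#' @export
gene_metaprofile <- function(regions, genes, chrom_sizes, bin_size = 300,
                             flank = 15000, n_body_bins = 50,
                             stratum = NULL, smooth = 2,
                             stat = c("coverage", "midpoints")) {
  stat <- match.arg(stat)
  if (!length(genes)) stop("genes must be non-empty", call. = FALSE)
  if (flank %% bin_size != 0)
    stop("flank must be a multiple of bin_size", call. = FALSE)
  n_flank <- flank / bin_size
  n_bins <- 2 * n_flank + n_body_bins
  if (is.null(stratum)) stratum <- rep(1L, length(genes))
  ind <- if (stat == "coverage") region_indicator(regions, chrom_sizes)
  else NULL
  mids_by_chrom <- if (stat == "midpoints")
    split(floor((bed_start(regions) + bed_end(regions)) / 2),
          as.character(GenomicRanges::seqnames(regions)))
  else NULL

  vals <- matrix(NA_real_, nrow = length(genes), ncol = n_bins)
  for (i in seq_along(genes)) {
    chrom <- as.character(GenomicRanges::seqnames(genes[i]))
    gs <- bed_start(genes[i]); ge <- bed_end(genes[i])
    minus <- as.character(GenomicRanges::strand(genes[i])) == "-"
    span_s <- gs - flank; span_e <- ge + flank
    L <- ge - gs
    ## local fractional edges: flank bins fixed, body bins scaled
    edges <- c(seq(0, flank, by = bin_size)[-(n_flank + 1)],
               flank + L * seq(0, n_body_bins) / n_body_bins,
               flank + L + seq_len(n_flank) * bin_size)
    if (stat == "coverage") {
      x <- indicator_window(ind, chrom, span_s, span_e, chrom_sizes)
      if (minus) x <- rev(x)
      vals[i, ] <- fractional_bin_means(x, edges)
    } else {
      mids <- mids_by_chrom[[chrom]]
      loc <- (mids[mids >= span_s & mids < span_e] - span_s)
      if (minus) loc <- (span_e - span_s - 1) - loc
      vals[i, ] <- midpoint_bin_counts(loc, edges)
    }
  }
  section <- c(rep("upstream", n_flank), rep("body", n_body_bins),
               rep("downstream", n_flank))
  out <- do.call(rbind, lapply(sort(unique(stratum)), function(sl) {
    m <- vals[stratum == sl, , drop = FALSE]
    v <- colMeans(m, na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    data.frame(bin_index = seq_len(n_bins), section = section,
               stratum = sl, value = v,
               smoothed = moving_average(v, smooth),
               n_genes = sum(stratum == sl), stringsAsFactors = FALSE)
  }))
  class(out) <- c("metaprofile", class(out))
  attr(out, "params") <- list(bin_size = bin_size, flank = flank,
                              n_body_bins = n_body_bins, smooth = smooth,
                              stat = stat)
  out
}

#' Metaprofile around feature centers
#'
#' Bins of width `window` across [midpoint - span, midpoint + span) of each
#' feature; per bin the covered fraction (or midpoint count), averaged over
#' features.
#'
#' @param regions GRanges of called regions.
#' @param centers GRanges of features (midpoints are used).
#' @param chrom_sizes named chromosome lengths.
#' @param span half-width in bp (default 2000; multiple of `window`).
#' @param window bin width in bp (default 100).
#' @param smooth moving-average half-width in bins (default 0 = none).
#' @param stat per-bin estimator as in \code{\link{gene_metaprofile}}.
#' @return data.frame of class `metaprofile`: bin_index, offset (bp of bin
#'   start relative to center), value, smoothed, n_features.
#' @export
point_metaprofile <- function(regions, centers, chrom_sizes, span = 2000,
                              window = 100, smooth = 0,
                              stat = c("coverage", "midpoints")) {
  stat <- match.arg(stat)
  if (!length(centers)) stop("centers must be non-empty", call. = FALSE)
  if (span %% window != 0)
    stop("span must be a multiple of window", call. = FALSE)
  n_bins <- 2 * span / window
  ind <- if (stat == "coverage") region_indicator(regions, chrom_sizes)
  else NULL
  mids_by_chrom <- if (stat == "midpoints")
    split(floor((bed_start(regions) + bed_end(regions)) / 2),
          as.character(GenomicRanges::seqnames(regions)))
  else NULL
  edges <- seq(0, 2 * span, by = window)
  vals <- matrix(NA_real_, nrow = length(centers), ncol = n_bins)
  for (i in seq_along(centers)) {
    chrom <- as.character(GenomicRanges::seqnames(centers[i]))
    mid <- floor((bed_start(centers[i]) + bed_end(centers[i])) / 2)
    s <- mid - span; e <- mid + span
    if (stat == "coverage") {
      x <- indicator_window(ind, chrom, s, e, chrom_sizes)
      vals[i, ] <- fractional_bin_means(x, edges)
    } else {
      mids <- mids_by_chrom[[chrom]]
      loc <- mids[mids >= s & mids < e] - s
      vals[i, ] <- midpoint_bin_counts(loc, edges)
    }
  }
  v <- colMeans(vals, na.rm = TRUE)
  v[is.nan(v)] <- NA_real_
  out <- data.frame(bin_index = seq_len(n_bins),
                    offset = edges[-length(edges)] - span,
                    value = v, smoothed = moving_average(v, smooth),
                    n_features = length(centers), stringsAsFactors = FALSE)
  class(out) <- c("metaprofile", class(out))
  attr(out, "params") <- list(span = span, window = window, smooth = smooth,
                              stat = stat)
  out
}
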