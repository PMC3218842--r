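## Permutation-based overlap enrichment of called regions against feature
## sets (random draws matched in number and size distribution), the
## closest-gene rule (TSS distance, capped), and cell-specific gene-set
## overlap tests.

#' Random intervals matched in number and length
#'
#' One random interval per template interval, with the same length: the
#' chromosome is chosen with probability proportional to its length among
#' chromosomes long enough to fit the interval, and the start uniformly in
#' [0, L - len]. Draws are independent, so random intervals may overlap each
#' other. The length multiset is preserved exactly.
#'
#' @param template GRanges whose lengths are matched.
#' @param chrom_sizes named chromosome lengths.
#' @param seed optional RNG seed.
#' @param mask optional GRanges; placements overlapping the mask are redrawn
#'   (placement ignores mappability by default since the toy genome has no
#'   gaps).
#' @return GRanges of the same length as `template`.
#' @export
random_matched_intervals <- function(template, chrom_sizes, seed = NULL,
                                     mask = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(template)
  if (!n) return(bed_ranges(character(0), integer(0), integer(0),
                            chrom_sizes = chrom_sizes))
  widths <- GenomicRanges::width(template)
  if (max(widths) > max(chrom_sizes))
    stop("template interval longer than every chromosome", call. = FALSE)
  L <- as.numeric(chrom_sizes)
  chroms <- names(chrom_sizes)
  draw <- function(widths) {
    ci <- integer(length(widths))
    ## group templates by which chromosomes can hold them
    for (w in unique(widths)) {
      sel <- widths == w
      eligible <- which(L >= w)
      ci[sel] <- eligible[sample.int(length(eligible), sum(sel),
                                     replace = TRUE,
                                     prob = L[eligible] / sum(L[eligible]))]
    }
    s <- floor(stats::runif(length(widths), 0, L[ci] - widths + 1))
    bed_ranges(chroms[ci], s, s + widths, chrom_sizes = chrom_sizes)
  }
  out <- draw(widths)
  if (!is.null(mask) && length(mask)) {
    for (it in 1:100) {
      bad <- GenomicRanges::countOverlaps(out, mask) > 0
      if (!any(bad)) break
      out[bad] <- draw(widths[bad])
    }
  }
  out
}

#' Fraction of intervals in A with at least 1 bp of overlap in B
#'
#' @param a,b GRanges; `a` must be non-empty (the fraction is undefined
#'   otherwise).
#' @return numeric fraction in [0,1].
#' @export
overlap_fraction <- function(a, b) {
  if (!length(a)) stop("empty query set: overlap fraction undefined",
                       call. = FALSE)
  mean(IRanges::overlapsAny(a, b, minoverlap = 1L, ignore.strand = TRUE))
}

#' Permutation overlap enrichment
#'
#' The observed statistic is the overlap fraction of regions with features
#' (or, with `mode = "fraction_of_features"`, of features with regions).
#' The null distribution comes from `n_perm` random interval sets matched to
#' the regions in number and length. Reports the null mean and sd, a
#' z-score (0 when the null sd is 0), and the conservative empirical
#' p-value (1 + #{null >= observed}) / (n_perm + 1) for enrichment
#' (`alternative` selects depletion or two-sided).
#'
#' @param regions GRanges of called regions.
#' @param features GRanges feature set.
#' @param chrom_sizes named chromosome lengths.
#' @param n_perm number of random draws (default 100).
#' @param seed optional RNG seed.
#' @param alternative "greater" (enrichment, default), "less", "two.sided".
#' @param mode which side's fraction is the statistic.
#' @param mask optional placement mask for \code{\link{random_matched_intervals}}.
#' @return list of class `enrichment_result`: observed, null_mean, null_sd,
#'   z_score, empirical_p, n_perm, seed, alternative, mode, null_values.
#' @export
permutation_enrichment <- function(regions, features, chrom_sizes,
                                   n_perm = 100, seed = NULL,
                                   alternative = c("greater", "less",
                                                   "two.sided"),
                                   mode = c("fraction_of_regions",
                                            "fraction_of_features"),
                                   mask = NULL) {
  alternative <- match.arg(alternative)
  mode <- match.arg(mode)
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  stat <- function(rand) {
    if (mode == "fraction_of_regions") overlap_fraction(rand, features)
    else overlap_fraction(features, rand)
  }
  observed <- stat(regions)
  null_values <- vapply(seq_len(n_perm), function(i) {
    stat(random_matched_intervals(regions, chrom_sizes, mask = mask))
  }, numeric(1))
  mu <- mean(null_values)
  sdv <- stats::sd(null_values)
  if (is.na(sdv)) sdv <- 0
  z <- if (sdv > 0) (observed - mu) / sdv else 0
  p_ge <- (1 + sum(null_values >= observed)) / (n_perm + 1)
  p_le <- (1 + sum(null_values <= observed)) / (n_perm + 1)
  p <- switch(alternative,
              greater = p_ge,
              less = p_le,
              two.sided = min(1, 2 * min(p_ge, p_le)))
  structure(list(observed = observed, null_mean = mu, null_sd = sdv,
                 z_score = z, empirical_p = p, n_perm = n_perm,
                 seed = seed, alternative = alternative, mode = mode,
                 null_values = null_values),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "permutation enrichment (%s, %s): observed %.4f, null %.4f +/- %.4f, z = %.2f, p = %.4g (n_perm = %d)\n",
    x$mode, x$alternative, x$observed, x$null_mean, x$null_sd, x$z_score,
    x$empirical_p, x$n_perm))
  invisible(x)
}

#' Closest gene by TSS distance
#'
#' For each region, the distance to a gene is the minimum over the region's
#' bases of |base - TSS| (0 when the TSS falls inside the region); the
#' nearest gene wins, ties going to the lexicographically smallest gene_id,
#' and regions whose nearest TSS is farther than `max_distance` are left
#' unassigned.
#'
#' @param regions GRanges.
#' @param genes GRanges with strand and a `gene_id` metadata column (the TSS
#'   is txStart for +, txEnd - 1 for - in BED coordinates).
#' @param max_distance assignment cap in bp (default 100000).
#' @return data.frame: region_index, region_id, gene_id (NA when
#'   unassigned), tss_distance (NA when unassigned).
#' @export
closest_gene <- function(regions, genes, max_distance = 100000) {
  ids <- S4Vectors::mcols(genes)$gene_id
  if (is.null(ids)) stop("genes need a gene_id metadata column",
                         call. = FALSE)
  strand <- as.character(GenomicRanges::strand(genes))
  if (any(strand == "*"))
    stop("genes must be stranded (TSS undefined otherwise)", call. = FALSE)
  tss <- ifelse(strand == "+", bed_start(genes), bed_end(genes) - 1)
  gchrom <- as.character(GenomicRanges::seqnames(genes))
  by_chrom <- split(data.frame(tss = tss, id = ids,
                               stringsAsFactors = FALSE), gchrom)
  by_chrom <- lapply(by_chrom, function(d) d[order(d$tss, d$id), ])
  rname <- S4Vectors::mcols(regions)$name
  if (is.null(rname)) rname <- sprintf("region_%05d", seq_along(regions))
  out <- data.frame(region_index = seq_along(regions), region_id = rname,
                    gene_id = NA_character_, tss_distance = NA_real_,
                    stringsAsFactors = FALSE)
  rchrom <- as.character(GenomicRanges::seqnames(regions))
  rs <- bed_start(regions); re <- bed_end(regions)
  for (i in seq_along(regions)) {
    d <- by_chrom[[rchrom[i]]]
    if (is.null(d) || !nrow(d)) next
    dist <- ifelse(d$tss >= rs[i] & d$tss < re[i], 0,
                   ifelse(d$tss < rs[i], rs[i] - d$tss,
                          d$tss - (re[i] - 1)))
    dmin <- min(dist)
    if (dmin > max_distance) next
    cand <- d$id[dist == dmin]
    out$gene_id[i] <- min(cand)
    out$tss_distance[i] <- dmin
  }
  out
}

#' Cell-specific expressed gene set
#'
#' Genes expressed in cell A (RPKM >= `expressed_min`) and silent in cell B
#' (RPKM <= `silent_max`); both boundaries inclusive. Genes missing a value
#' in either column are excluded with a message reporting the count.
#'
#' @param expression data.frame with gene_id and two RPKM columns.
#' @param expressed_min expression threshold in cell A (default 0.5).
#' @param silent_max silence threshold in cell B (default 0).
#' @param col_a,col_b column names (defaults rpkm_hesc / rpkm_imr90).
#' @return character vector of gene ids.
#' @export
specific_gene_set <- function(expression, expressed_min = 0.5,
                              silent_max = 0, col_a = "rpkm_hesc",
                              col_b = "rpkm_imr90") {
  a <- expression[[col_a]]; b <- expression[[col_b]]
  if (is.null(a) || is.null(b))
    stop("expression table lacks column(s) ", col_a, " / ", col_b,
         call. = FALSE)
  miss <- is.na(a) | is.na(b)
  if (any(miss)) message(sum(miss), " gene(s) with missing RPKM excluded")
  sel <- !miss & a >= expressed_min & b <= silent_max
  expression$gene_id[sel]
}

#' Two-sided Fisher's exact test on a 2x2 table
#'
#' Thin wrapper around the conditional hypergeometric test; degenerate
#' margins (an empty row or column) are reported as p = 1 with a flag.
#'
#' @param m 2x2 integer matrix.
#' @return list: p_value, odds_ratio (sample odds ratio ad/bc, may be Inf),
#'   degenerate flag.
#' @export
fisher_exact_2x2 <- function(m) {
  stopifnot(is.matrix(m), all(dim(m) == 2), all(m >= 0))
  degenerate <- any(rowSums(m) == 0) || any(colSums(m) == 0)
  p <- if (degenerate) 1 else stats::fisher.test(m)$p.value
  or <- (m[1, 1] * m[2, 2]) / (m[1, 2] * m[2, 1])
  list(p_value = p, odds_ratio = or, degenerate = degenerate)
}

#' Gene-set vs region overlap test
#'
#' A gene "overlaps" when its body ([txStart, txEnd)) shares at least 1 bp
#' with any region. Builds the {special, non-special} x {overlap, no
#' overlap} table, reports the percentage of special genes and of all genes
#' overlapping, the sample odds ratio and the two-sided Fisher exact
#' p-value.
#'
#' @param special_ids character vector of gene ids (must be a subset of the
#'   genes' ids).
#' @param genes GRanges with gene_id metadata.
#' @param regions GRanges of called regions.
#' @return list of class `gene_set_overlap`: table, pct_special, pct_all,
#'   odds_ratio, p_value, degenerate.
#' @export
gene_set_overlap_test <- function(special_ids, genes, regions) {
  ids <- S4Vectors::mcols(genes)$gene_id
  if (is.null(ids)) stop("genes need a gene_id metadata column",
                         call. = FALSE)
  if (!all(special_ids %in% ids))
    stop("special gene set contains ids absent from the gene models",
         call. = FALSE)
  hit <- IRanges::overlapsAny(genes, regions, minoverlap = 1L,
                              ignore.strand = TRUE)
  special <- ids %in% special_ids
  m <- matrix(c(sum(special & hit), sum(special & !hit),
                sum(!special & hit), sum(!special & !hit)),
              nrow = 2, byrow = TRUE,
              dimnames = list(c("special", "other"),
                              c("overlap", "no_overlap")))
  ft <- fisher_exact_2x2(m)
  structure(list(table = m,
                 pct_special = 100 * mean(hit[special]),
                 pct_all = 100 * mean(hit),
                 odds_ratio = ft$odds_ratio,
                 p_value = ft$p_value,
                 degenerate = ft$degenerate),
            class = "gene_set_overlap")
}

#' @export
print.gene_set_overlap <- function(x, ...) {
  cat(sprintf(
    "gene-set overlap: %.1f%% of special genes vs %.1f%% of all genes overlap regions (OR = %.3g, Fisher p = %.3g)\n",
    x$pct_special, x$pct_all, x$odds_ratio, x$p_value))
  invisible(x)
}
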