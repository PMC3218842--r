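## Synthetic hmeDIP-seq world: a toy multi-chromosome genome with planted
## GC-skewed segments, planted 5hmC regions placed preferentially at skewed
## segments and enhancers, IP/input/no-antibody read libraries, gene models
## with a two-cell-type expression table, and an EpiMark-style qPCR table
## generated from known modification fractions. Everything is deterministic
## given the config seed.

#' Configuration for the synthetic hmeDIP-seq dataset
#'
#' Defaults describe the stated world used throughout the test suite: a
#' 100-Mb toy genome (4 x 25 Mb) sequenced to 2e5 reads per library with
#' 8-fold IP enrichment over 200 planted 5hmC regions of ~1.5 kb (the
#' average length reported for real consensus 5hmC regions). The genome
#' size sets the background occupancy to about 0.4 reads per 200-bp caller
#' window: sparse enough that, with the SICER-style eligibility floor of 2
#' reads per window, background windows rarely seed or chain into islands
#' (a fixed-threshold island caller is anti-conservative when background
#' occupancy approaches the eligibility floor, because island spans are
#' selected on high IP counts), while planted regions at 8-fold enrichment
#' carry ~3.2 reads per window (~24 per region) and are called with large
#' margins.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_length chromosome length (bp).
#' @param n_true_regions number of planted 5hmC regions.
#' @param region_length_mean,region_length_sd planted region length (bp),
#'   normal with a 300-bp floor.
#' @param skew_segment_fraction fraction of the genome given a G-over-C
#'   Watson-strand bias (in `skew_segment_length` segments).
#' @param skew_segment_length length of each skewed segment (bp).
#' @param skew_bias Watson-strand composition bias b: in the 5' half of a
#'   skewed segment P(G) = 0.25(1+b), P(C) = 0.25(1-b); mirrored in the 3'
#'   half, so the expected signed skew (G-C)/(G+C) equals +b then -b.
#' @param region_at_skew_fraction,region_at_enhancer_fraction fractions of
#'   planted regions centered on skewed-segment midpoints / enhancer
#'   midpoints; the remainder is placed uniformly.
#' @param ip_enrichment fold enrichment of IP read density inside planted
#'   regions (must be >= 1).
#' @param depth reads per library.
#' @param fragment_size,read_length library fragment and read lengths (bp);
#'   `fragment_size >= read_length`.
#' @param n_genes,n_enhancers,n_tfbs annotation counts.
#' @param specific_gene_fraction fraction of genes made hESC-specific
#'   (RPKM >= 0.5 in cell A, 0 in cell B).
#' @param qpcr_n_loci,qpcr_baseline,qpcr_background,qpcr_replicates,qpcr_noise_cv
#'   qPCR simulation: number of loci, undigested copy number, additive
#'   uncut background rate, replicates per condition, lognormal
#'   coefficient of variation.
#' @param seed RNG seed.
#' @return a validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_chroms = 4L,
                             chrom_length = 2.5e7,
                             n_true_regions = 200L,
                             region_length_mean = 1500,
                             region_length_sd = 375,
                             skew_segment_fraction = 0.05,
                             skew_segment_length = 10000,
                             skew_bias = 0.2,
                             region_at_skew_fraction = 0.5,
                             region_at_enhancer_fraction = 0.2,
                             ip_enrichment = 8,
                             depth = 2e5,
                             fragment_size = 200,
                             read_length = 50,
                             n_genes = 400L,
                             n_enhancers = 150L,
                             n_tfbs = 100L,
                             specific_gene_fraction = 0.1,
                             qpcr_n_loci = 6L,
                             qpcr_baseline = 1000,
                             qpcr_background = 0.05,
                             qpcr_replicates = 3L,
                             qpcr_noise_cv = 0.1,
                             seed = 1L) {
  cfg <- list(
    n_chroms = as.integer(n_chroms), chrom_length = as.numeric(chrom_length),
    n_true_regions = as.integer(n_true_regions),
    region_length_mean = region_length_mean,
    region_length_sd = region_length_sd,
    skew_segment_fraction = skew_segment_fraction,
    skew_segment_length = as.numeric(skew_segment_length),
    skew_bias = skew_bias,
    region_at_skew_fraction = region_at_skew_fraction,
    region_at_enhancer_fraction = region_at_enhancer_fraction,
    ip_enrichment = ip_enrichment, depth = as.numeric(depth),
    fragment_size = as.numeric(fragment_size),
    read_length = as.numeric(read_length),
    n_genes = as.integer(n_genes), n_enhancers = as.integer(n_enhancers),
    n_tfbs = as.integer(n_tfbs),
    specific_gene_fraction = specific_gene_fraction,
    qpcr_n_loci = as.integer(qpcr_n_loci), qpcr_baseline = qpcr_baseline,
    qpcr_background = qpcr_background,
    qpcr_replicates = as.integer(qpcr_replicates),
    qpcr_noise_cv = qpcr_noise_cv, seed = as.integer(seed)
  )
  stopifnot_scalar(cfg$n_chroms, "n_chroms", 1)
  stopifnot_scalar(cfg$chrom_length, "chrom_length", 1)
  stopifnot_scalar(cfg$n_true_regions, "n_true_regions", 0)
  stopifnot_scalar(cfg$region_length_mean, "region_length_mean")
  if (cfg$region_length_mean <= 0)
    stop("region_length_mean must be > 0", call. = FALSE)
  stopifnot_scalar(cfg$depth, "depth", 0)
  for (f in c("skew_segment_fraction", "region_at_skew_fraction",
              "region_at_enhancer_fraction", "specific_gene_fraction")) {
    stopifnot_scalar(cfg[[f]], f)
    if (cfg[[f]] < 0 || cfg[[f]] > 1)
      stop(sprintf("'%s' must be in [0,1]", f), call. = FALSE)
  }
  if (cfg$region_at_skew_fraction + cfg$region_at_enhancer_fraction > 1)
    stop("region placement fractions sum to more than 1", call. = FALSE)
  if (cfg$skew_bias < 0 || cfg$skew_bias > 1)
    stop("skew_bias must be in [0,1]", call. = FALSE)
  if (cfg$fragment_size < cfg$read_length)
    stop("fragment_size must be >= read_length", call. = FALSE)
  if (cfg$ip_enrichment < 1)
    stop("ip_enrichment must be >= 1", call. = FALSE)
  if (cfg$qpcr_noise_cv < 0) stop("qpcr_noise_cv must be >= 0", call. = FALSE)
  if (cfg$qpcr_baseline < 0) stop("qpcr_baseline must be >= 0", call. = FALSE)
  class(cfg) <- "synthetic_config"
  cfg
}

chrom_names <- function(cfg) paste0("chr", seq_len(cfg$n_chroms))

chrom_sizes_of <- function(cfg) {
  stats::setNames(rep(as.integer(cfg$chrom_length), cfg$n_chroms),
                  chrom_names(cfg))
}

## Draw one random DNA string of length n with base probabilities p (ACGT).
random_dna <- function(n, p = rep(0.25, 4)) {
  if (n == 0) return("")
  codes <- utf8ToInt("ACGT")
  intToUtf8(codes[sample.int(4L, n, replace = TRUE, prob = p)])
}

## Place `n` non-overlapping intervals of widths `w` uniformly on the genome,
## chromosome chosen proportional to length among those that fit. Batched
## rejection sampling: draw all outstanding intervals at once, keep a greedy
## non-overlapping subset, redraw the rest.
place_nonoverlapping <- function(n, widths, chrom_sizes, max_tries = 100L,
                                 avoid = NULL) {
  if (n == 0)
    return(bed_ranges(character(0), integer(0), integer(0),
                      chrom_sizes = chrom_sizes))
  widths <- rep_len(widths, n)
  if (max(widths) > max(chrom_sizes))
    stop("interval width exceeds every chromosome", call. = FALSE)
  chroms <- names(chrom_sizes)
  L <- as.numeric(chrom_sizes)
  draw <- function(w) {
    ci <- integer(length(w))
    for (uw in unique(w)) {
      sel <- w == uw
      eligible <- which(L >= uw)
      ci[sel] <- eligible[sample.int(length(eligible), sum(sel),
                                     replace = TRUE,
                                     prob = L[eligible] / sum(L[eligible]))]
    }
    s <- floor(stats::runif(length(w), 0, L[ci] - w + 1))
    bed_ranges(chroms[ci], s, s + w, chrom_sizes = chrom_sizes)
  }
  accepted <- GenomicRanges::GRanges()
  todo <- widths
  for (try in seq_len(max_tries)) {
    cand <- draw(todo)
    bad <- GenomicRanges::countOverlaps(cand, accepted) > 0
    if (!is.null(avoid) && length(avoid))
      bad <- bad | GenomicRanges::countOverlaps(cand, avoid) > 0
    ## greedy pass over the batch itself: keep candidates that do not
    ## overlap an earlier kept candidate
    ord <- order(as.integer(GenomicRanges::seqnames(cand)),
                 GenomicRanges::start(cand))
    last_end <- stats::setNames(rep(-1, length(chroms)), chroms)
    for (i in ord) {
      if (bad[i]) next
      ch <- as.character(GenomicRanges::seqnames(cand[i]))
      if (bed_start(cand)[i] < last_end[[ch]]) { bad[i] <- TRUE; next }
      last_end[[ch]] <- bed_end(cand)[i]
    }
    accepted <- c(accepted, cand[!bad])
    todo <- todo[bad]
    if (!length(todo)) break
  }
  if (length(todo))
    stop("could not place non-overlapping intervals; genome too crowded",
         call. = FALSE)
  sort(accepted)
}

#' Generate the toy genome with planted GC-skewed segments
#'
#' Outside skewed segments all four bases are equiprobable, so G and C
#' frequencies are symmetric in expectation. Inside a skewed segment the 5'
#' half is G-biased and the 3' half C-biased on the Watson strand (the sign
#' flips at the segment midpoint), with expected signed skew +/- `skew_bias`.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list with `genome` (DNAStringSet), `chrom_sizes` (named integer
#'   vector) and `skew_segments` (GRanges truth intervals).
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$chrom_length <= 0)
    stop("zero-length chromosomes rejected", call. = FALSE)
  set.seed(derive_seeds(config$seed, 8L)[1L])
  chrom_sizes <- chrom_sizes_of(config)
  n_seg <- round(config$skew_segment_fraction * sum(chrom_sizes) /
                   config$skew_segment_length)
  segs <- place_nonoverlapping(n_seg, config$skew_segment_length, chrom_sizes)
  b <- config$skew_bias
  p_g5 <- c(0.25, 0.25 * (1 - b), 0.25 * (1 + b), 0.25)  # A C G T, 5' half
  p_c3 <- c(0.25, 0.25 * (1 + b), 0.25 * (1 - b), 0.25)  # mirrored 3' half
  ## assemble each chromosome from background and segment-half pieces so
  ## large chromosomes are pasted once, not copied per segment
  seqs <- vapply(chrom_names(config), function(ch) {
    L <- chrom_sizes[[ch]]
    cs <- segs[as.character(GenomicRanges::seqnames(segs)) == ch]
    if (!length(cs)) return(random_dna(L))
    cs <- sort(cs)
    pieces <- character(0)
    cursor <- 0
    for (i in seq_along(cs)) {
      s <- bed_start(cs)[i]; e <- bed_end(cs)[i]
      half <- floor((e - s) / 2)
      pieces <- c(pieces, random_dna(s - cursor),
                  random_dna(half, p_g5),
                  random_dna(e - s - half, p_c3))
      cursor <- e
    }
    pieces <- c(pieces, random_dna(L - cursor))
    paste0(pieces, collapse = "")
  }, "")
  list(genome = Biostrings::DNAStringSet(seqs),
       chrom_sizes = chrom_sizes,
       skew_segments = segs)
}

## Planted 5hmC regions: a configured fraction centered on skewed-segment
## midpoints, a fraction on enhancer midpoints, the rest uniform; all
## non-overlapping and within chromosome bounds.
plant_regions <- function(config, chrom_sizes, skew_segments, enhancers) {
  n <- config$n_true_regions
  if (n == 0)
    return(bed_ranges(character(0), integer(0), integer(0),
                      chrom_sizes = chrom_sizes))
  widths <- pmax(300, round(stats::rnorm(n, config$region_length_mean,
                                         config$region_length_sd)))
  n_skew <- min(round(config$region_at_skew_fraction * n),
                length(skew_segments))
  n_enh <- min(round(config$region_at_enhancer_fraction * n),
               length(enhancers))
  centers <- numeric(0); center_chrom <- character(0)
  if (n_skew > 0) {
    pick <- sample(seq_along(skew_segments), n_skew)
    center_chrom <- c(center_chrom,
                      as.character(GenomicRanges::seqnames(skew_segments[pick])))
    centers <- c(centers, floor((bed_start(skew_segments[pick]) +
                                   bed_end(skew_segments[pick])) / 2))
  }
  if (n_enh > 0) {
    pick <- sample(seq_along(enhancers), n_enh)
    center_chrom <- c(center_chrom,
                      as.character(GenomicRanges::seqnames(enhancers[pick])))
    centers <- c(centers, floor((bed_start(enhancers[pick]) +
                                   bed_end(enhancers[pick])) / 2))
  }
  n_anchor <- length(centers)
  anchored <- NULL
  if (n_anchor > 0) {
    w <- widths[seq_len(n_anchor)]
    s <- pmax(0, pmin(centers - floor(w / 2), chrom_sizes[center_chrom] - w))
    anchored <- bed_ranges(center_chrom, s, s + w, chrom_sizes = chrom_sizes)
  }
  n_unif <- n - n_anchor
  uniform <- if (n_unif > 0)
    place_nonoverlapping(n_unif, widths[n_anchor + seq_len(n_unif)],
                         chrom_sizes, avoid = anchored)
  else NULL
  regions <- c(if (is.null(anchored)) GenomicRanges::GRanges() else anchored,
               if (is.null(uniform)) GenomicRanges::GRanges() else uniform)
  ## anchored regions may collide with each other on rare occasions;
  ## drop later duplicates so the truth set is disjoint
  regions <- sort(regions)
  keep <- !logical(length(regions))
  if (length(regions) > 1) {
    ov <- GenomicRanges::findOverlaps(regions, drop.self = TRUE,
                                      drop.redundant = TRUE)
    keep[unique(S4Vectors::subjectHits(ov))] <- FALSE
  }
  regions <- regions[keep]
  S4Vectors::mcols(regions)$name <- sprintf("truth_%04d", seq_along(regions))
  regions
}

#' Simulate IP, input and no-antibody read libraries
#'
#' IP read 5' positions are drawn from a two-component mixture: with density
#' proportional to `ip_enrichment` inside the planted regions and uniform
#' elsewhere; input and no-antibody positions are uniform. Reads are
#' `read_length` long with random strand, clamped to chromosome bounds, and
#' each library contains exactly `depth` reads.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param truth_regions GRanges of planted 5hmC regions.
#' @param chrom_sizes named chromosome lengths.
#' @param seed RNG seed for this call (default: derived from config seed).
#' @return list of GRanges: `ip`, `input`, `noab`.
#' @export
simulate_libraries <- function(config, truth_regions, chrom_sizes,
                               seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$ip_enrichment < 1)
    stop("ip_enrichment must be >= 1", call. = FALSE)
  if (is.null(seed)) seed <- derive_seeds(config$seed, 8L)[2L]
  set.seed(seed)
  G <- sum(chrom_sizes)
  R <- sum(GenomicRanges::width(truth_regions))
  if (length(truth_regions) &&
      any(bed_end(truth_regions) >
          chrom_sizes[as.character(GenomicRanges::seqnames(truth_regions))]))
    stop("truth regions extend beyond chromosome ends", call. = FALSE)
  depth <- as.integer(config$depth)
  e <- config$ip_enrichment
  p_in <- if (R > 0) (e * R) / (e * R + (G - R)) else 0

  cum <- cumsum(as.numeric(chrom_sizes))
  offset <- stats::setNames(c(0, cum[-length(cum)]), names(chrom_sizes))
  ## truth regions in global coordinates (sorted, disjoint) so the uniform
  ## background component can exclude them and the in-region read fraction
  ## follows the enrichment mixture closed form exactly
  tr_glob_s <- offset[as.character(GenomicRanges::seqnames(truth_regions))] +
    bed_start(truth_regions)
  ord <- order(tr_glob_s)
  reg_gs <- unname(tr_glob_s[ord])
  reg_ge <- reg_gs + as.numeric(GenomicRanges::width(truth_regions))[ord]
  in_truth <- function(g) {
    if (!length(reg_gs)) return(rep(FALSE, length(g)))
    i <- findInterval(g, reg_gs)
    i > 0 & g < reg_ge[pmax(i, 1)]
  }
  sample_uniform_pos <- function(n, exclude_truth = FALSE) {
    ## global 0-based positions mapped to (chrom, pos)
    g <- floor(stats::runif(n, 0, G))
    if (exclude_truth && length(reg_gs)) {
      for (it in 1:1000) {
        bad <- in_truth(g)
        if (!any(bad)) break
        g[bad] <- floor(stats::runif(sum(bad), 0, G))
      }
    }
    ci <- findInterval(g, c(0, cum), rightmost.closed = TRUE)
    list(chrom = names(chrom_sizes)[ci],
         pos = g - c(0, cum)[ci])
  }
  sample_region_pos <- function(n) {
    w <- as.numeric(GenomicRanges::width(truth_regions))
    ri <- sample.int(length(truth_regions), n, replace = TRUE, prob = w)
    off <- floor(stats::runif(n, 0, w[ri]))
    list(chrom = as.character(GenomicRanges::seqnames(truth_regions))[ri],
         pos = bed_start(truth_regions)[ri] + off)
  }
  make_reads <- function(n, enriched) {
    if (n == 0)
      return(bed_ranges(character(0), integer(0), integer(0),
                        chrom_sizes = chrom_sizes))
    if (enriched && p_in > 0) {
      n_in <- stats::rbinom(1, n, p_in)
      pin <- sample_region_pos(n_in)
      pout <- sample_uniform_pos(n - n_in, exclude_truth = TRUE)
      chrom <- c(pin$chrom, pout$chrom)
      pos <- c(pin$pos, pout$pos)
      ## shuffle so read order carries no signal
      o <- sample.int(n)
      chrom <- chrom[o]; pos <- pos[o]
    } else {
      p <- sample_uniform_pos(n)
      chrom <- p$chrom; pos <- p$pos
    }
    strand <- sample(c("+", "-"), n, replace = TRUE)
    rl <- config$read_length
    L <- chrom_sizes[chrom]
    s <- ifelse(strand == "+", pos, pos - rl + 1)
    s <- pmax(0, pmin(s, L - rl))
    bed_ranges(chrom, s, s + rl, strand, chrom_sizes = chrom_sizes)
  }
  list(ip = make_reads(depth, TRUE),
       input = make_reads(depth, FALSE),
       noab = make_reads(depth, FALSE))
}

#' Simulate an EpiMark qPCR copy-number table from known fractions
#'
#' Generative model per locus (baseline = undigested copy number, b =
#' background rate of uncut residue, hmc/mc = true modified fractions):
#' undigested (either treatment) = baseline; glucosylated + MspI =
#' baseline*(b + hmc*(1-b)); mock + MspI = baseline*b; HpaII (either
#' treatment) = baseline*(b + (hmc + mc)*(1-b)). The additive background and
#' the (1-b) signal scale are defined so that the EpiMark normalization
#' (subtract the mock+MspI background from every sample, divide by the
#' background-subtracted undigested glucosylated sample) recovers the true
#' fractions exactly at zero noise. Each measurement gets independent
#' multiplicative lognormal noise with the configured coefficient of
#' variation.
#'
#' @param locus_fractions data.frame with columns locus, hmc, mc
#'   (hmc + mc <= 1 per locus).
#' @param config a \code{\link{synthetic_config}}.
#' @param seed RNG seed (default: derived from config seed).
#' @return data.frame: locus, treatment, digestion, replicate, copies.
#' @export
simulate_qpcr <- function(locus_fractions, config, seed = NULL) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$qpcr_baseline < 0)
    stop("negative baseline rejected", call. = FALSE)
  stopifnot(all(c("locus", "hmc", "mc") %in% names(locus_fractions)))
  if (any(locus_fractions$hmc < 0 | locus_fractions$mc < 0 |
            locus_fractions$hmc + locus_fractions$mc > 1))
    stop("locus fractions must be >= 0 and sum to <= 1", call. = FALSE)
  if (is.null(seed)) seed <- derive_seeds(config$seed, 8L)[3L]
  set.seed(seed)
  base <- config$qpcr_baseline
  bg <- config$qpcr_background
  grid <- expand.grid(treatment = c("BGT", "mock"),
                      digestion = c("none", "MspI", "HpaII"),
                      replicate = seq_len(config$qpcr_replicates),
                      locus = locus_fractions$locus,
                      stringsAsFactors = FALSE)
  fr <- locus_fractions[match(grid$locus, locus_fractions$locus), ]
  expected <- ifelse(
    grid$digestion == "none", base,
    ifelse(grid$digestion == "HpaII",
           base * (bg + (fr$hmc + fr$mc) * (1 - bg)),
           ifelse(grid$treatment == "BGT",
                  base * (bg + fr$hmc * (1 - bg)),
                  base * bg)))
  cv <- config$qpcr_noise_cv
  noise <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else 1
  data.frame(locus = grid$locus, treatment = grid$treatment,
             digestion = grid$digestion, replicate = grid$replicate,
             copies = expected * noise, stringsAsFactors = FALSE)
}

## Gene models, enhancers, TFBS and histone-mark intervals plus expression.
simulate_annotations <- function(config, chrom_sizes, seed) {
  set.seed(seed)
  ## cap gene length so annotations always fit sparse toy genomes
  len_cap <- max(2000, floor(0.25 * sum(chrom_sizes) / config$n_genes))
  gene_len <- pmax(min(2000, len_cap),
                   pmin(round(stats::rlnorm(config$n_genes,
                                            log(min(20000, len_cap)), 0.6)),
                        len_cap))
  genes <- place_nonoverlapping(config$n_genes, gene_len, chrom_sizes)
  GenomicRanges::strand(genes) <- sample(c("+", "-"), length(genes),
                                         replace = TRUE)
  S4Vectors::mcols(genes)$gene_id <- sprintf("gene_%04d", seq_along(genes))
  S4Vectors::mcols(genes)$name <- S4Vectors::mcols(genes)$gene_id

  enh_len <- pmax(500, round(stats::rnorm(config$n_enhancers, 1500, 400)))
  enhancers <- place_nonoverlapping(config$n_enhancers, enh_len, chrom_sizes)
  S4Vectors::mcols(enhancers)$name <-
    sprintf("enh_%04d", seq_along(enhancers))

  tfbs_center <- place_nonoverlapping(config$n_tfbs, 200, chrom_sizes)
  S4Vectors::mcols(tfbs_center)$name <-
    sprintf("tfbs_%04d", seq_along(tfbs_center))

  ## histone marks: enhancer-flavoured intervals jittered around enhancers
  ## (emulating H3K4me1 / H3K27ac correlation with enhancers) plus noise
  mark_around <- function(frac_at_enh, n_extra, width_mean) {
    n_at <- round(frac_at_enh * length(enhancers))
    pick <- sample(seq_along(enhancers), n_at)
    w <- pmax(500, round(stats::rnorm(n_at, width_mean, width_mean / 4)))
    ctr <- floor((bed_start(enhancers[pick]) + bed_end(enhancers[pick])) / 2) +
      round(stats::rnorm(n_at, 0, 300))
    ch <- as.character(GenomicRanges::seqnames(enhancers[pick]))
    s <- pmax(0, pmin(ctr - floor(w / 2), chrom_sizes[ch] - w))
    at <- bed_ranges(ch, s, s + w, chrom_sizes = chrom_sizes)
    extra <- place_nonoverlapping(n_extra,
                                  pmax(500, round(stats::rnorm(
                                    n_extra, width_mean, width_mean / 4))),
                                  chrom_sizes)
    sort(c(at, extra))
  }
  h3k4me1 <- mark_around(0.8, 60, 2000)
  h3k27ac <- mark_around(0.6, 40, 1500)

  ## expression: lognormal RPKM in cell A; a configured subset is
  ## cell-A-specific (A >= 0.5, B = 0); some genes silent in both
  n <- length(genes)
  rpkm_a <- round(stats::rlnorm(n, log(4), 1.3), 3)
  rpkm_b <- round(stats::rlnorm(n, log(4), 1.3), 3)
  silent_a <- sample.int(n, round(0.15 * n))
  rpkm_a[silent_a] <- 0
  silent_b <- sample.int(n, round(0.15 * n))
  rpkm_b[silent_b] <- 0
  n_spec <- round(config$specific_gene_fraction * n)
  spec <- sample.int(n, n_spec)
  rpkm_a[spec] <- pmax(0.5, rpkm_a[spec])
  rpkm_b[spec] <- 0
  expression <- data.frame(gene_id = S4Vectors::mcols(genes)$gene_id,
                           rpkm_hesc = rpkm_a, rpkm_imr90 = rpkm_b,
                           stringsAsFactors = FALSE)
  list(genes = genes, enhancers = enhancers, tfbs = tfbs_center,
       histone_marks = list(H3K4me1 = h3k4me1, H3K27ac = h3k27ac),
       expression = expression)
}

#' Simulate a complete synthetic hmeDIP-seq dataset
#'
#' Runs the whole generator: genome with skewed segments, annotations,
#' planted 5hmC regions (preferentially at skewed segments and enhancers),
#' two independent antibody experiments each with IP/input/no-antibody
#' libraries, and a qPCR table whose peak loci carry 5hmC fractions in the
#' 10-36\% range and control loci in the 0.5-2.7\% range.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @return list of class `hmedip_simulation` with elements `config`,
#'   `genome`, `chrom_sizes`, `truth` (regions, skew_segments, genes,
#'   enhancers, tfbs, histone_marks, expression, locus_fractions) and
#'   `experiments` (expA, expB: each ip/input/noab GRanges), `qpcr`.
#' @export
simulate_hmedip_dataset <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  seeds <- derive_seeds(config$seed, 8L)
  gen <- generate_genome(config)
  ann <- simulate_annotations(config, gen$chrom_sizes, seeds[4L])
  set.seed(seeds[5L])
  regions <- plant_regions(config, gen$chrom_sizes, gen$skew_segments,
                           ann$enhancers)
  expA <- simulate_libraries(config, regions, gen$chrom_sizes,
                             seed = seeds[6L])
  expB <- simulate_libraries(config, regions, gen$chrom_sizes,
                             seed = seeds[7L])
  set.seed(seeds[8L])
  n_loci <- config$qpcr_n_loci
  n_peak <- ceiling(2 * n_loci / 3)
  hmc <- c(stats::runif(n_peak, 0.096, 0.364),
           stats::runif(n_loci - n_peak, 0.005, 0.027))
  mc <- stats::runif(n_loci, 0.1, pmin(0.5, 1 - hmc))
  locus_fractions <- data.frame(
    locus = c(sprintf("peak_%02d", seq_len(n_peak)),
              sprintf("control_%02d", seq_len(n_loci - n_peak))),
    hmc = hmc, mc = mc, stringsAsFactors = FALSE)
  qpcr <- simulate_qpcr(locus_fractions, config)
  structure(list(
    config = config,
    genome = gen$genome,
    chrom_sizes = gen$chrom_sizes,
    truth = c(list(regions = regions, skew_segments = gen$skew_segments),
              ann, list(locus_fractions = locus_fractions)),
    experiments = list(expA = expA, expB = expB),
    qpcr = qpcr
  ), class = "hmedip_simulation")
}

#' Write a simulated dataset to a directory of plain-text files
#'
#' Emits genome FASTA, chrom.sizes, truth/annotation BED files, per-library
#' read BEDs for both experiments, the expression TSV and the qPCR TSV.
#'
#' @param sim result of \code{\link{simulate_hmedip_dataset}}.
#' @param outdir output directory (created if absent).
#' @return invisibly, a named list of written paths.
#' @export
write_simulation <- function(sim, outdir) {
  stopifnot(inherits(sim, "hmedip_simulation"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- output_header(sim$config$seed, sim$config)
  p <- list()
  p$genome <- file.path(outdir, "genome.fa")
  write_fasta(sim$genome, p$genome)
  p$chrom_sizes <- file.path(outdir, "chrom.sizes")
  write_chrom_sizes(sim$chrom_sizes, p$chrom_sizes)
  beds <- list(truth_regions = sim$truth$regions,
               skew_segments = sim$truth$skew_segments,
               genes = sim$truth$genes,
               enhancers = sim$truth$enhancers,
               tfbs = sim$truth$tfbs,
               H3K4me1 = sim$truth$histone_marks$H3K4me1,
               H3K27ac = sim$truth$histone_marks$H3K27ac)
  for (nm in names(beds)) {
    p[[nm]] <- file.path(outdir, paste0(nm, ".bed"))
    write_bed(beds[[nm]], p[[nm]], header = hdr)
  }
  for (ex in names(sim$experiments)) {
    for (lib in names(sim$experiments[[ex]])) {
      key <- paste0(ex, "_", lib)
      p[[key]] <- file.path(outdir, paste0(key, ".bed"))
      write_bed(sim$experiments[[ex]][[lib]], p[[key]], header = hdr)
    }
  }
  p$expression <- file.path(outdir, "expression.tsv")
  write_expression(sim$truth$expression, p$expression, header = hdr)
  p$qpcr <- file.path(outdir, "qpcr.tsv")
  write_qpcr(sim$qpcr, p$qpcr, header = hdr)
  p$locus_fractions <- file.path(outdir, "locus_fractions.tsv")
  write_tsv(sim$truth$locus_fractions, p$locus_fractions, header = hdr)
  invisible(p)
}
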