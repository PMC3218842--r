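## Watson-strand base composition and GC-skew around region anchors, plus
## CpG-site counting. "5' boundary" of an unstranded region is its lower
## coordinate; the Watson strand is always the reference strand.

#' GC skew
#'
#' |G - C| / (G + C) from pooled counts; the signed variant
#' (G - C) / (G + C) carries directionality. When G + C = 0 the value is 0
#' and the position is flagged in the `undefined` attribute.
#'
#' @param g_count,c_count non-negative counts (vectorized).
#' @param signed return the signed skew.
#' @return numeric vector with logical attribute `undefined`.
#' @export
gc_skew <- function(g_count, c_count, signed = FALSE) {
  if (any(g_count < 0) || any(c_count < 0))
    stop("counts must be >= 0", call. = FALSE)
  tot <- g_count + c_count
  undef <- tot == 0
  v <- ifelse(undef, 0, (g_count - c_count) / ifelse(undef, 1, tot))
  if (!signed) v <- abs(v)
  attr(v, "undefined") <- undef
  v
}

#' Count CpG dinucleotides
#'
#' Occurrences of "CG" on the given strand (case-insensitive; occurrences
#' cannot overlap).
#'
#' @param sequence character vector (or DNAString/DNAStringSet) over
#'   A/C/G/T/N.
#' @return integer vector of counts.
#' @export
count_cpg <- function(sequence) {
  if (methods::is(sequence, "DNAString"))
    sequence <- Biostrings::DNAStringSet(sequence)
  if (!methods::is(sequence, "DNAStringSet"))
    sequence <- Biostrings::DNAStringSet(toupper(as.character(sequence)))
  as.integer(Biostrings::vcountPattern("CG", sequence))
}

#' Base composition and GC-skew profile around region anchors
#'
#' At each offset in [-flank, +flank] relative to the anchor (region start
#' for `five_prime`, end - 1 for `three_prime`, midpoint for `center`),
#' tallies Watson-strand base frequencies across all regions. Offsets that
#' fall beyond a chromosome end for a given region are simply not counted
#' for that region (the per-offset denominator tracks counted bases); N
#' bases are excluded from both numerator and denominator and reported.
#' The skew is computed from G and C counts pooled over a sliding window of
#' `window` bp centered on each offset (truncated at the profile ends).
#'
#' @param regions GRanges.
#' @param genome DNAStringSet.
#' @param anchor one of "five_prime", "three_prime", "center".
#' @param flank profile half-width in bp (default 2000).
#' @param window skew smoothing window in bp (default 100).
#' @return data.frame of class `skew_profile`: offset, fA, fC, fG, fT,
#'   n_counted, n_N, skew, skew_signed.
#' @export
base_composition_profile <- function(regions, genome,
                                     anchor = c("five_prime", "three_prime",
                                                "center"),
                                     flank = 2000, window = 100) {
  anchor <- match.arg(anchor)
  if (!length(regions)) stop("no regions", call. = FALSE)
  chrom_len <- stats::setNames(Biostrings::width(genome), names(genome))
  chrom <- as.character(GenomicRanges::seqnames(regions))
  if (!all(chrom %in% names(genome)))
    stop("regions on chromosomes absent from the genome", call. = FALSE)
  pos <- switch(anchor,
                five_prime = bed_start(regions),
                three_prime = bed_end(regions) - 1,
                center = floor((bed_start(regions) + bed_end(regions)) / 2))
  n_off <- 2 * flank + 1
  counts <- matrix(0L, nrow = 5, ncol = n_off,
                   dimnames = list(c("A", "C", "G", "T", "N"), NULL))
  for (i in seq_along(regions)) {
    L <- chrom_len[[chrom[i]]]
    lo <- max(pos[i] - flank, 0)
    hi <- min(pos[i] + flank + 1, L)
    if (hi <= lo) next
    s <- get_seq(genome, chrom[i], lo, hi)
    bases <- strsplit(s, "", fixed = TRUE)[[1]]
    bases[!bases %in% c("A", "C", "G", "T")] <- "N"
    off <- (lo - (pos[i] - flank) + 1):(hi - (pos[i] - flank))
    idx <- match(bases, c("A", "C", "G", "T", "N"))
    for (k in 1:5) {
      sel <- idx == k
      if (any(sel)) counts[k, off[sel]] <- counts[k, off[sel]] + 1L
    }
  }
  acgt <- counts[1:4, , drop = FALSE]
  n_counted <- colSums(acgt)
  freq <- sweep(acgt, 2, pmax(n_counted, 1), "/")
  freq[, n_counted == 0] <- NA_real_
  ## pooled G/C counts over sliding window (running sum, truncated)
  wr <- floor(window / 2)
  run <- function(x) {
    cs <- c(0, cumsum(as.numeric(x)))
    i <- seq_len(n_off)
    lo <- pmax(i - wr, 1); hi <- pmin(i + wr, n_off)
    cs[hi + 1] - cs[lo]
  }
  gW <- run(counts["G", ]); cW <- run(counts["C", ])
  sk <- gc_skew(gW, cW, signed = TRUE)
  out <- data.frame(offset = -flank:flank,
                    fA = freq["A", ], fC = freq["C", ],
                    fG = freq["G", ], fT = freq["T", ],
                    n_counted = n_counted, n_N = counts["N", ],
                    skew = abs(as.numeric(sk)),
                    skew_signed = as.numeric(sk))
  class(out) <- c("skew_profile", class(out))
  attr(out, "anchor") <- anchor
  attr(out, "window") <- window
  attr(out, "skew_undefined") <- attr(sk, "undefined")
  out
}

#' Classify regions by annotation overlap
#'
#' Priority order: `genic` when the region shares >= 1 bp with a gene body,
#' else `enhancer` when it overlaps an enhancer, else `other`.
#'
#' @param regions GRanges.
#' @param genes,enhancers GRanges annotation sets.
#' @return factor with levels genic, enhancer, other.
#' @export
classify_regions <- function(regions, genes, enhancers) {
  genic <- IRanges::overlapsAny(regions, genes, minoverlap = 1L,
                                ignore.strand = TRUE)
  enh <- IRanges::overlapsAny(regions, enhancers, minoverlap = 1L,
                              ignore.strand = TRUE)
  factor(ifelse(genic, "genic", ifelse(enh, "enhancer", "other")),
         levels = c("genic", "enhancer", "other"))
}
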