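## SICER-style window/island calling of 5hmC-enriched regions against two
## background controls, with Benjamini-Hochberg FDR control per
## (experiment, control) run and a cross-antibody consensus. The caller is a
## simplified fixed-window Poisson model with SICER's canonical window/gap
## defaults; the contract is "significant vs both input and no-antibody
## controls at BH FDR < 0.05, present in both antibody experiments".

#' Island caller parameters
#'
#' @param window window size in bp (default 200).
#' @param gap maximum merged gap in bp; must be a multiple of `window`
#'   (default 600).
#' @param fdr BH false discovery rate threshold (default 0.05).
#' @param min_reads_per_window minimum IP fragments (by midpoint) for a
#'   window to seed an island (default 2).
#' @return list of class `caller_params`.
#' @export
caller_params <- function(window = 200, gap = 600, fdr = 0.05,
                          min_reads_per_window = 2) {
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  if (gap %% window != 0)
    stop("gap must be a multiple of window", call. = FALSE)
  if (fdr <= 0 || fdr >= 1) stop("fdr must be in (0,1)", call. = FALSE)
  structure(list(window = as.numeric(window), gap = as.numeric(gap),
                 fdr = fdr,
                 min_reads_per_window = as.numeric(min_reads_per_window)),
            class = "caller_params")
}

#' Per-window fragment counts
#'
#' Assigns each extended fragment to the window containing its midpoint
#' (midpoint = floor((start+end)/2) in BED coordinates), preventing double
#' counting. The last partial window of each chromosome is kept.
#'
#' @param extended GRanges of extended fragments.
#' @param window window size in bp.
#' @param chrom_sizes named chromosome lengths.
#' @return list of class `window_counts`: per-chromosome integer vectors of
#'   counts plus `window` and `chrom_sizes`.
#' @export
window_counts <- function(extended, window, chrom_sizes) {
  if (window <= 0) stop("window must be > 0", call. = FALSE)
  counts <- lapply(names(chrom_sizes), function(chrom) {
    nw <- ceiling(chrom_sizes[[chrom]] / window)
    sel <- as.character(GenomicRanges::seqnames(extended)) == chrom
    if (!any(sel)) return(integer(nw))
    mid <- floor((bed_start(extended[sel]) + bed_end(extended[sel])) / 2)
    idx <- pmin(mid %/% window + 1L, nw)
    tabulate(idx, nbins = nw)
  })
  names(counts) <- names(chrom_sizes)
  structure(list(counts = counts, window = window,
                 chrom_sizes = chrom_sizes),
            class = "window_counts")
}

## Upper-tail Poisson p-value: P(X >= x | lambda).
poisson_upper_tail <- function(x, lambda) {
  stats::ppois(x - 1, lambda, lower.tail = FALSE)
}

#' Call candidate islands against one background control
#'
#' Windows with at least `min_reads_per_window` IP fragments that lie within
#' `gap` bp of each other are merged into candidate islands (the island span
#' runs from the first to the last eligible window; interior below-threshold
#' windows are absorbed). Per island, IP and control fragments are summed
#' over the span and the p-value is the upper-tail Poisson probability of
#' observing at least the IP count given lambda = max(control_count, 1) *
#' (ip_library / control_library); the floor of one control read avoids
#' zero-rate degeneracy. BH correction is applied across all islands of the
#' run.
#'
#' @param ip_counts,control_counts `window_counts` on the same grid.
#' @param ip_library,control_library library sizes (uniquely mapping reads).
#' @param params \code{\link{caller_params}}.
#' @return GRanges of islands with metadata ip_count, control_count,
#'   p_value, q_value.
#' @export
call_islands <- function(ip_counts, control_counts, ip_library,
                         control_library, params = caller_params()) {
  stopifnot(inherits(ip_counts, "window_counts"),
            inherits(control_counts, "window_counts"))
  if (control_library <= 0)
    stop("empty control library rejected", call. = FALSE)
  if (ip_counts$window != control_counts$window ||
      !identical(names(ip_counts$counts), names(control_counts$counts)))
    stop("IP and control counts must share the same window grid",
         call. = FALSE)
  w <- ip_counts$window
  gap_windows <- params$gap / w  # eligible windows <= this many apart merge
  out <- list()
  for (chrom in names(ip_counts$counts)) {
    ipc <- ip_counts$counts[[chrom]]
    ctc <- control_counts$counts[[chrom]]
    eligible <- which(ipc >= params$min_reads_per_window)
    if (!length(eligible)) next
    brk <- c(0, which(diff(eligible) > gap_windows + 1), length(eligible))
    first <- eligible[brk[-length(brk)] + 1]
    last <- eligible[brk[-1]]
    cs_ip <- c(0, cumsum(ipc)); cs_ct <- c(0, cumsum(ctc))
    ip_sum <- cs_ip[last + 1] - cs_ip[first]
    ct_sum <- cs_ct[last + 1] - cs_ct[first]
    start <- (first - 1) * w
    end <- pmin(last * w, ip_counts$chrom_sizes[[chrom]])
    out[[chrom]] <- data.frame(chrom = chrom, start = start, end = end,
                               ip_count = ip_sum, control_count = ct_sum)
  }
  if (!length(out)) {
    gr <- bed_ranges(character(0), integer(0), integer(0),
                     chrom_sizes = ip_counts$chrom_sizes)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      ip_count = integer(0), control_count = integer(0),
      p_value = numeric(0), q_value = numeric(0))
    return(gr)
  }
  df <- do.call(rbind, out)
  lambda <- pmax(df$control_count, 1) * (ip_library / control_library)
  p <- poisson_upper_tail(df$ip_count, lambda)
  q <- stats::p.adjust(p, method = "BH")
  bed_ranges(df$chrom, df$start, df$end,
             chrom_sizes = ip_counts$chrom_sizes,
             ip_count = df$ip_count, control_count = df$control_count,
             p_value = p, q_value = q)
}

#' Cross-control, cross-antibody consensus regions
#'
#' Per experiment, islands must pass BH FDR < `fdr` against BOTH the input
#' and the no-antibody control; the experiment's region set is the
#' base-pair-wise intersection of the two passing island sets. The final
#' consensus is the base-pair-wise intersection of the two experiments'
#' sets, with adjacent pieces merged. Symmetric in the two experiments by
#' construction.
#'
#' @param expA_vs_input,expA_vs_noab,expB_vs_input,expB_vs_noab island
#'   GRanges from \code{\link{call_islands}}.
#' @param fdr q-value threshold (default 0.05).
#' @return GRanges of consensus regions (name, score = -10*log10(max q)
#'   metadata columns; score from the most marginal passing island
#'   overlapping each region).
#' @export
consensus_regions <- function(expA_vs_input, expA_vs_noab,
                              expB_vs_input, expB_vs_noab, fdr = 0.05) {
  passing <- function(gr) {
    if (!length(gr)) return(GenomicRanges::GRanges())
    GenomicRanges::reduce(gr[S4Vectors::mcols(gr)$q_value < fdr])
  }
  per_exp <- function(vs_input, vs_noab) {
    GenomicRanges::intersect(passing(vs_input), passing(vs_noab))
  }
  final <- GenomicRanges::reduce(GenomicRanges::intersect(
    per_exp(expA_vs_input, expA_vs_noab),
    per_exp(expB_vs_input, expB_vs_noab)))
  if (length(final)) {
    ## score: worst (largest) passing q among contributing islands
    all_islands <- c(expA_vs_input, expA_vs_noab, expB_vs_input, expB_vs_noab)
    qmax <- vapply(seq_along(final), function(i) {
      hits <- S4Vectors::subjectHits(
        GenomicRanges::findOverlaps(final[i], all_islands))
      qs <- S4Vectors::mcols(all_islands)$q_value[hits]
      qs <- qs[qs < fdr]
      if (!length(qs)) return(NA_real_)
      max(qs)
    }, numeric(1))
    S4Vectors::mcols(final)$name <- sprintf("region_%05d", seq_along(final))
    S4Vectors::mcols(final)$score <- ifelse(is.na(qmax), 0,
                                            round(-10 * log10(qmax), 2))
  }
  final
}

#' Summary statistics of a region set
#'
#' @param regions GRanges.
#' @param chrom_sizes named chromosome lengths (for per-chromosome peak
#'   density, peaks/bp).
#' @return list with n, mean_length, median_length, and a per-chromosome
#'   data.frame (chrom, n, chrom_length, density).
#' @export
region_summary <- function(regions, chrom_sizes = NULL) {
  if (is.null(chrom_sizes)) {
    sl <- GenomeInfoDb::seqlengths(regions)
    if (length(sl) && !all(is.na(sl))) chrom_sizes <- sl
  }
  n <- length(regions)
  widths <- GenomicRanges::width(regions)
  per_chrom <- NULL
  if (!is.null(chrom_sizes)) {
    cnt <- table(factor(as.character(GenomicRanges::seqnames(regions)),
                        levels = names(chrom_sizes)))
    per_chrom <- data.frame(chrom = names(chrom_sizes),
                            n = as.integer(cnt),
                            chrom_length = as.numeric(chrom_sizes),
                            density = as.integer(cnt) /
                              as.numeric(chrom_sizes),
                            stringsAsFactors = FALSE)
  }
  list(n = n,
       mean_length = if (n) mean(widths) else 0,
       median_length = if (n) stats::median(widths) else 0,
       per_chrom = per_chrom)
}

#' Full two-experiment region calling from raw read sets
#'
#' Convenience wrapper running the whole calling pipeline: deduplicate,
#' extend to fragment size, window counts, islands of each experiment
#' against both controls, then \code{\link{consensus_regions}}.
#'
#' @param expA,expB lists with GRanges elements `ip`, `input`, `noab`.
#' @param chrom_sizes named chromosome lengths.
#' @param fragment_size fragment extension length (bp).
#' @param params \code{\link{caller_params}}.
#' @return list with `regions` (consensus GRanges) and `islands` (the four
#'   per-control island GRanges).
#' @export
call_hmedip_regions <- function(expA, expB, chrom_sizes,
                                fragment_size = 200,
                                params = caller_params()) {
  prep <- function(reads) {
    extend_reads(deduplicate_reads(reads), fragment_size)
  }
  one_exp <- function(ex) {
    libs <- lapply(ex[c("ip", "input", "noab")], prep)
    sizes <- vapply(libs, length, integer(1))
    wc <- lapply(libs, window_counts, window = params$window,
                 chrom_sizes = chrom_sizes)
    list(vs_input = call_islands(wc$ip, wc$input, sizes[["ip"]],
                                 sizes[["input"]], params),
         vs_noab = call_islands(wc$ip, wc$noab, sizes[["ip"]],
                                sizes[["noab"]], params))
  }
  a <- one_exp(expA)
  b <- one_exp(expB)
  regions <- consensus_regions(a$vs_input, a$vs_noab, b$vs_input, b$vs_noab,
                               fdr = params$fdr)
  list(regions = regions,
       islands = list(expA_vs_input = a$vs_input, expA_vs_noab = a$vs_noab,
                      expB_vs_input = b$vs_input, expB_vs_noab = b$vs_noab))
}
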