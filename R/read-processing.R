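## Post-alignment read hygiene and normalized density tracks. Reads arrive
## as aligned intervals (BED convention); trimming and alignment happen
## upstream.

#' Collapse identical reads to one read
#'
#' Identity is the (chrom, start, end, strand) tuple; by default strand is
#' part of read identity (a same-position opposite-strand read is a distinct
#' fragment end). The result is independent of input order and the operation
#' is idempotent.
#'
#' @param reads GRanges of aligned reads.
#' @param strand_aware include strand in read identity (default TRUE).
#' @return GRanges with duplicates removed.
#' @export
deduplicate_reads <- function(reads, strand_aware = TRUE) {
  if (!length(reads)) return(reads)
  if (strand_aware) {
    reads[!duplicated(reads)]
  } else {
    key <- GenomicRanges::granges(reads, use.mcols = FALSE)
    GenomicRanges::strand(key) <- "*"
    reads[!duplicated(key)]
  }
}

#' Extend reads to the library fragment size
#'
#' A plus-strand read keeps its 5' end and grows 3' to `fragment_size`; a
#' minus-strand read keeps its 3' coordinate end and grows leftward.
#' Fragments are clamped to chromosome bounds (seqlengths required for the
#' right edge).
#'
#' @param reads GRanges of (deduplicated) reads.
#' @param fragment_size target fragment length in bp; must be positive and
#'   at least the read length.
#' @return GRanges of extended fragments (strand preserved).
#' @export
extend_reads <- function(reads, fragment_size) {
  if (fragment_size <= 0) stop("fragment_size must be > 0", call. = FALSE)
  if (length(reads) && fragment_size < max(GenomicRanges::width(reads)))
    stop("fragment_size must be >= read length", call. = FALSE)
  if (!length(reads)) return(reads)
  minus <- as.character(GenomicRanges::strand(reads)) == "-"
  s <- bed_start(reads); e <- bed_end(reads)
  new_s <- ifelse(minus, e - fragment_size, s)
  new_e <- ifelse(minus, e, s + fragment_size)
  new_s <- pmax(0, new_s)
  sl <- GenomeInfoDb::seqlengths(reads)
  if (!all(is.na(sl))) {
    L <- sl[as.character(GenomicRanges::seqnames(reads))]
    new_e <- pmin(new_e, L)
  }
  out <- reads
  IRanges::ranges(out) <- IRanges::IRanges(start = new_s + 1L, end = new_e)
  out
}

#' Normalized per-base density track
#'
#' Value at base b is (number of extended fragments covering b) divided by
#' the library size in millions, i.e. reads/bp/million uniquely mapping
#' reads.
#'
#' @param extended GRanges of extended fragments (seqlengths recommended so
#'   chromosomes have a defined width).
#' @param library_size number of uniquely mapping reads (> 0).
#' @return object of class `density_track`: list with `coverage` (an
#'   RleList of per-base densities) and `library_size`.
#' @export
density_track <- function(extended, library_size) {
  if (library_size <= 0) stop("library_size must be > 0", call. = FALSE)
  cov <- GenomicRanges::coverage(extended)
  scale <- 1e6 / library_size
  structure(list(coverage = cov * scale, library_size = library_size),
            class = "density_track")
}

#' Total mass of a density track
#'
#' Equals sum(extended fragment lengths) / (library_size / 1e6); used as a
#' conservation check.
#' @param track a `density_track`.
#' @return numeric scalar.
#' @export
track_total_mass <- function(track) {
  sum(vapply(track$coverage, function(r) sum(as.numeric(S4Vectors::runValue(r)) *
                                               S4Vectors::runLength(r)),
             numeric(1)))
}

#' @export
print.density_track <- function(x, ...) {
  cat(sprintf("density_track: %d chromosome(s), library size %d\n",
              length(x$coverage), as.integer(x$library_size)))
  invisible(x)
}

#' Write a density track as bedGraph
#'
#' Equal-value runs are merged (the natural Rle representation); zero runs
#' are omitted.
#'
#' @param track a `density_track`.
#' @param path output path.
#' @param track_line prepend a `track type=bedGraph` line.
#' @param header optional `#` header lines.
#' @export
write_bedgraph <- function(track, path, track_line = FALSE, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  if (track_line) writeLines("track type=bedGraph", con)
  for (chrom in names(track$coverage)) {
    r <- track$coverage[[chrom]]
    v <- S4Vectors::runValue(r)
    len <- S4Vectors::runLength(r)
    e <- cumsum(as.numeric(len))
    s <- e - len
    keep <- v != 0
    if (!any(keep)) next
    writeLines(sprintf("%s\t%d\t%d\t%s", chrom, as.integer(s[keep]),
                       as.integer(e[keep]),
                       format(v[keep], trim = TRUE, scientific = FALSE)), con)
  }
  invisible(path)
}
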