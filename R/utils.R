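## Internal helpers shared across modules.

#' Construct genomic intervals in BED convention
#'
#' Builds a \link[GenomicRanges]{GRanges} from 0-based half-open coordinates,
#' the coordinate dialect used by every reader/writer in this package. The
#' returned object uses the usual 1-based closed GRanges representation
#' internally; conversion happens only at this boundary.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end 0-based half-open interval bounds (start < end).
#' @param strand strand, one of "+", "-", "*" (recycled).
#' @param chrom_sizes optional named integer vector of chromosome lengths,
#'   attached as seqlengths.
#' @param ... further vectors stored as metadata columns.
#' @return a GRanges.
#' @export
bed_ranges <- function(chrom, start, end, strand = "*", chrom_sizes = NULL,
                       ...) {
  if (any(end <= start))
    stop("empty or inverted interval(s): start must be < end", call. = FALSE)
  if (any(start < 0))
    stop("negative start coordinate(s)", call. = FALSE)
  sl <- NULL
  if (!is.null(chrom_sizes)) sl <- chrom_sizes
  n <- length(start)
  gr <- GenomicRanges::GRanges(
    seqnames = rep_len(chrom, n),
    ranges = IRanges::IRanges(start = start + 1L, end = end),
    strand = rep_len(strand, n)
  )
  mc <- list(...)
  if (length(mc)) S4Vectors::mcols(gr) <- S4Vectors::DataFrame(mc)
  if (!is.null(sl)) {
    GenomeInfoDb::seqlevels(gr) <- names(sl)
    GenomeInfoDb::seqlengths(gr) <- as.integer(sl)
  }
  gr
}

## BED-convention accessors (0-based half-open) for a GRanges.
bed_start <- function(gr) GenomicRanges::start(gr) - 1L
bed_end <- function(gr) GenomicRanges::end(gr)

## Deterministic sub-seeds so independent generators don't share streams.
## Kept below 2^31 (R integers are 32-bit).
derive_seeds <- function(seed, n) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(2147483646L, n)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  if (!is.null(seed)) set.seed(seed)
  expr
}

stopifnot_scalar <- function(x, name, min = NULL) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("'%s' must be a single number", name), call. = FALSE)
  if (!is.null(min) && x < min)
    stop(sprintf("'%s' must be >= %s", name, min), call. = FALSE)
  invisible(x)
}

## Header comment lines stamped into every output file: package version,
## seed, and an md5 of the parameter list, so runs are traceable.
output_header <- function(seed = NA, params = list()) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(deparse(params), tf)
  md5 <- unname(tools::md5sum(tf))
  c(
    sprintf("# hydroxyscan %s",
            as.character(utils::packageVersion("hydroxyscan"))),
    sprintf("# seed=%s config_md5=%s", as.character(seed), md5)
  )
}
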