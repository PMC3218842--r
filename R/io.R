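## Readers and writers for the plain-text formats the pipeline consumes and
## emits. All interval coordinates on disk are BED convention: 0-based,
## half-open. Hand-written rather than delegated to rtracklayer because the
## readers report invalid lines with their line numbers and the writers stamp
## a seed/config header comment into every file.

#' Read a BED file
#'
#' Accepts 3-6 tab-separated columns (chrom, start, end, name, score,
#' strand); `track`, `browser` and `#` lines are skipped. Lines with missing
#' fields, non-numeric or inverted/empty coordinates are collected and
#' reported with their line numbers (dropped with a warning by default).
#'
#' @param path file path.
#' @param chrom_sizes optional named vector of chromosome lengths; intervals
#'   on unknown chromosomes are tolerated with a warning unless `strict`.
#' @param strict error (instead of warn) on invalid lines or unknown
#'   chromosomes.
#' @return GRanges with `name` and `score` metadata columns when present.
#' @export
read_bed <- function(path, chrom_sizes = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol <- lengths(fields)
  bad <- ncol < 3L
  chrom <- vapply(fields, function(f) f[1L], "", USE.NAMES = FALSE)
  start <- suppressWarnings(as.numeric(vapply(
    fields, function(f) if (length(f) >= 2L) f[2L] else NA_character_, "")))
  end <- suppressWarnings(as.numeric(vapply(
    fields, function(f) if (length(f) >= 3L) f[3L] else NA_character_, "")))
  bad <- bad | is.na(start) | is.na(end) | (start >= end) | (start < 0)
  if (any(bad)) {
    msg <- sprintf("%d invalid BED line(s) at line number(s): %s",
                   sum(bad), paste(lineno[bad], collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  fields <- fields[!bad]
  chrom <- chrom[!bad]; start <- start[!bad]; end <- end[!bad]
  ncol <- ncol[!bad]
  if (!is.null(chrom_sizes)) {
    unknown <- !(chrom %in% names(chrom_sizes))
    if (any(unknown)) {
      msg <- sprintf("%d interval(s) on chromosome(s) absent from chrom_sizes: %s",
                     sum(unknown),
                     paste(unique(chrom[unknown]), collapse = ", "))
      if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
    }
  }
  if (!length(chrom)) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(chrom_sizes)) {
      GenomeInfoDb::seqlevels(gr) <- names(chrom_sizes)
      GenomeInfoDb::seqlengths(gr) <- as.integer(chrom_sizes)
    }
    return(gr)
  }
  name <- ifelse(ncol >= 4L,
                 vapply(fields, function(f) if (length(f) >= 4L) f[4L] else ".",
                        ""), ".")
  score <- suppressWarnings(as.numeric(ifelse(
    ncol >= 5L,
    vapply(fields, function(f) if (length(f) >= 5L) f[5L] else "0", ""), "0")))
  score[is.na(score)] <- 0
  strand <- ifelse(ncol >= 6L,
                   vapply(fields, function(f)
                     if (length(f) >= 6L) f[6L] else "*", ""), "*")
  strand[!strand %in% c("+", "-")] <- "*"
  sl <- NULL
  if (!is.null(chrom_sizes)) {
    ## tolerated unknown chromosomes get NA seqlengths
    lv <- union(names(chrom_sizes), unique(chrom))
    sl <- stats::setNames(as.integer(chrom_sizes[lv]), lv)
  }
  bed_ranges(chrom, start, end, strand, chrom_sizes = sl,
             name = name, score = score)
}

#' Write a BED6 file
#'
#' Emits 0-based half-open coordinates; `name` and `score` metadata columns
#' are used when present.
#'
#' @param gr GRanges to write.
#' @param path output path.
#' @param header optional character vector of `#` header lines (e.g. from the
#'   pipeline's seed/config stamp).
#' @export
write_bed <- function(gr, path, header = NULL) {
  mc <- S4Vectors::mcols(gr)
  name <- if ("name" %in% names(mc)) as.character(mc$name) else
    rep(".", length(gr))
  score <- if ("score" %in% names(mc)) as.numeric(mc$score) else
    rep(0, length(gr))
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  out <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                 as.character(GenomicRanges::seqnames(gr)),
                 bed_start(gr), bed_end(gr), name,
                 format(score, trim = TRUE, scientific = FALSE), strand)
  ## BED strand column uses "." for unstranded; read_bed maps it back to "*"
  writeLines(c(header, out), path)
  invisible(path)
}

#' Read a genome FASTA with random access
#'
#' @param path FASTA path; duplicate headers are rejected.
#' @return a \link[Biostrings]{DNAStringSet} (uppercased).
#' @export
read_fasta <- function(path) {
  genome <- Biostrings::readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (anyDuplicated(names(genome)))
    stop("duplicate FASTA headers: ",
         paste(unique(names(genome)[duplicated(names(genome))]),
               collapse = ", "), call. = FALSE)
  Biostrings::DNAStringSet(toupper(genome))
}

#' Slice a genome sequence (BED coordinates)
#'
#' @param genome DNAStringSet.
#' @param chrom chromosome name.
#' @param start,end 0-based half-open slice; `start == end` yields "".
#' @return character scalar (uppercase).
#' @export
get_seq <- function(genome, chrom, start, end) {
  if (!chrom %in% names(genome))
    stop("unknown chromosome: ", chrom, call. = FALSE)
  L <- length(genome[[chrom]])
  if (start < 0 || end > L || start > end)
    stop(sprintf("slice [%s,%s) out of range for %s (length %d)",
                 start, end, chrom, L), call. = FALSE)
  if (start == end) return("")
  as.character(Biostrings::subseq(genome[[chrom]], start + 1L, end))
}

#' Write a genome FASTA (60-column wrapped)
#' @param genome DNAStringSet.
#' @param path output path.
#' @export
write_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path, width = 60L)
  invisible(path)
}

#' Read/write chromosome sizes (two-column TSV)
#' @param path TSV path (chrom, length).
#' @return named integer vector.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          comment.char = "#",
                          colClasses = c("character", "numeric"))
  stats::setNames(as.integer(df$length), df$chrom)
}

#' @rdname read_chrom_sizes
#' @param chrom_sizes named integer vector.
#' @export
write_chrom_sizes <- function(chrom_sizes, path) {
  writeLines(sprintf("%s\t%d", names(chrom_sizes),
                     as.integer(chrom_sizes)), path)
  invisible(path)
}

#' Read/write an expression table
#'
#' TSV with columns gene_id, rpkm_hesc, rpkm_imr90 (RPKM units).
#' @param path TSV path.
#' @export
read_expression <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}

#' @rdname read_expression
#' @param expression data.frame.
#' @param header optional `#` header lines.
#' @export
write_expression <- function(expression, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  utils::write.table(expression, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write a qPCR copy-number table
#'
#' TSV with columns locus, treatment (BGT|mock), digestion
#' (none|MspI|HpaII), replicate, copies.
#' @param path TSV path.
#' @export
read_qpcr <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                          stringsAsFactors = FALSE)
  need <- c("locus", "treatment", "digestion", "replicate", "copies")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("qPCR table missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  df
}

#' @rdname read_qpcr
#' @param qpcr data.frame.
#' @param header optional `#` header lines.
#' @export
write_qpcr <- function(qpcr, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  utils::write.table(qpcr, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simple TSV with an optional comment header
#' @param df data.frame.
#' @param path output path.
#' @param header optional `#` header lines.
#' @export
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(header, con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
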