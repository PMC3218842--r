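## End-to-end orchestration: read inputs, process reads, call consensus
## regions, then profile/enrich/skew/quantify, writing plain-text results
## plus a manifest. Deterministic given the config seed.

#' Pipeline configuration
#'
#' Collects input paths and stage parameters; all referenced files must
#' exist at run start (fail-fast, before any output is written).
#'
#' @param genome path to the genome FASTA.
#' @param chrom_sizes path to a chrom.sizes TSV.
#' @param expA_ip,expA_input,expA_noab,expB_ip,expB_input,expB_noab read BED
#'   paths for the two antibody experiments and their controls.
#' @param genes gene BED6 path (name column = gene id).
#' @param enhancers,tfbs,h3k4me1,h3k27ac optional annotation BED paths.
#' @param expression optional expression TSV path.
#' @param qpcr optional qPCR TSV path.
#' @param fragment_size fragment extension (bp); the libraries' average
#'   fragment size.
#' @param params \code{\link{caller_params}}.
#' @param n_perm permutations for enrichment (default 100).
#' @param n_strata expression strata for the gene metaprofile (default 5).
#' @param flank,bin_size,n_body_bins gene metaprofile geometry.
#' @param span,window point metaprofile geometry.
#' @param skew_flank,skew_window composition profile geometry.
#' @param seed global RNG seed, recorded in every output header.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, chrom_sizes,
                            expA_ip, expA_input, expA_noab,
                            expB_ip, expB_input, expB_noab,
                            genes,
                            enhancers = NULL, tfbs = NULL,
                            h3k4me1 = NULL, h3k27ac = NULL,
                            expression = NULL, qpcr = NULL,
                            fragment_size = 200,
                            params = caller_params(),
                            n_perm = 100, n_strata = 5,
                            flank = 15000, bin_size = 300, n_body_bins = 50,
                            span = 2000, window = 100,
                            skew_flank = 2000, skew_window = 100,
                            seed = 1L) {
  paths <- list(genome = genome, chrom_sizes = chrom_sizes,
                expA_ip = expA_ip, expA_input = expA_input,
                expA_noab = expA_noab, expB_ip = expB_ip,
                expB_input = expB_input, expB_noab = expB_noab,
                genes = genes, enhancers = enhancers, tfbs = tfbs,
                h3k4me1 = h3k4me1, h3k27ac = h3k27ac,
                expression = expression, qpcr = qpcr)
  for (nm in names(paths)) {
    p <- paths[[nm]]
    if (!is.null(p) && !file.exists(p))
      stop(sprintf("input '%s' does not exist: %s", nm, p), call. = FALSE)
  }
  structure(list(paths = paths, fragment_size = fragment_size,
                 params = params, n_perm = n_perm, n_strata = n_strata,
                 flank = flank, bin_size = bin_size,
                 n_body_bins = n_body_bins, span = span, window = window,
                 skew_flank = skew_flank, skew_window = skew_window,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[hydroxyscan] ", fmt), ...))
}

#' Run the full hmeDIP-seq analysis pipeline
#'
#' Stages: read inputs; deduplicate and extend reads; write normalized
#' density tracks (bedGraph); call islands for each experiment against both
#' controls and form the cross-antibody consensus; summarize regions; gene
#' metaprofile stratified by expression; enhancer/TFBS-centered profiles;
#' permutation enrichment against histone marks; closest genes and
#' cell-specific gene-set test; base composition/GC-skew profiles; EpiMark
#' qPCR quantification. Optional inputs switch their stages off. Every
#' output carries a header with the package version, seed and a config hash.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param outdir output directory (created).
#' @param verbose log stage progress to stderr.
#' @return invisibly, a list with the principal in-memory results
#'   (`regions`, `summary`, `enrichment`, `gene_overlap`, `modifications`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, outdir, verbose = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  t0 <- Sys.time()
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hdr <- output_header(config$seed, config[setdiff(names(config), "paths")])
  manifest <- list(seed = config$seed)
  p <- config$paths

  log_stage(verbose, "loading inputs")
  chrom_sizes <- read_chrom_sizes(p$chrom_sizes)
  genome <- read_fasta(p$genome)
  load_reads <- function(path) read_bed(path, chrom_sizes = chrom_sizes)
  expA <- list(ip = load_reads(p$expA_ip), input = load_reads(p$expA_input),
               noab = load_reads(p$expA_noab))
  expB <- list(ip = load_reads(p$expB_ip), input = load_reads(p$expB_input),
               noab = load_reads(p$expB_noab))
  genes <- read_bed(p$genes, chrom_sizes = chrom_sizes)
  S4Vectors::mcols(genes)$gene_id <- S4Vectors::mcols(genes)$name

  log_stage(verbose, "read processing + density tracks")
  for (ex in c("expA", "expB")) {
    libs <- if (ex == "expA") expA else expB
    for (lib in names(libs)) {
      dedup <- deduplicate_reads(libs[[lib]])
      ext <- extend_reads(dedup, config$fragment_size)
      track <- density_track(ext, length(dedup))
      write_bedgraph(track, file.path(outdir,
                                      sprintf("%s_%s.bedgraph", ex, lib)),
                     header = hdr)
      manifest[[paste0(ex, "_", lib, "_dedup_reads")]] <- length(dedup)
    }
  }

  log_stage(verbose, "island calling + consensus")
  called <- call_hmedip_regions(expA, expB, chrom_sizes,
                                fragment_size = config$fragment_size,
                                params = config$params)
  regions <- called$regions
  write_bed(regions, file.path(outdir, "consensus_regions.bed"),
            header = hdr)
  summ <- region_summary(regions, chrom_sizes)
  manifest$n_consensus_regions <- summ$n
  manifest$mean_region_length <- round(summ$mean_length, 1)
  write_tsv(summ$per_chrom, file.path(outdir, "region_chrom_density.tsv"),
            header = hdr)

  log_stage(verbose, "metaprofiles")
  if (length(regions)) {
    strat <- NULL
    if (!is.null(p$expression)) {
      expr <- read_expression(p$expression)
      st <- stratify_by_expression(genes, expr, n_strata = config$n_strata)
      prof <- gene_metaprofile(regions, st$genes, chrom_sizes,
                               bin_size = config$bin_size,
                               flank = config$flank,
                               n_body_bins = config$n_body_bins,
                               stratum = st$stratum)
    } else {
      prof <- gene_metaprofile(regions, genes, chrom_sizes,
                               bin_size = config$bin_size,
                               flank = config$flank,
                               n_body_bins = config$n_body_bins)
    }
    write_tsv(prof, file.path(outdir, "gene_metaprofile.tsv"), header = hdr)
    for (nm in c("enhancers", "tfbs")) {
      if (is.null(p[[nm]])) next
      feat <- read_bed(p[[nm]], chrom_sizes = chrom_sizes)
      if (!length(feat)) next
      pp <- point_metaprofile(regions, feat, chrom_sizes,
                              span = config$span, window = config$window)
      write_tsv(pp, file.path(outdir, paste0(nm, "_profile.tsv")),
                header = hdr)
    }
  }

  log_stage(verbose, "overlap enrichment")
  enrich <- list()
  seeds <- derive_seeds(config$seed, 16L)
  si <- 1L
  if (length(regions)) {
    feature_sets <- list(genes = genes)
    for (nm in c("enhancers", "h3k4me1", "h3k27ac")) {
      if (!is.null(p[[nm]]))
        feature_sets[[nm]] <- read_bed(p[[nm]], chrom_sizes = chrom_sizes)
    }
    rows <- lapply(names(feature_sets), function(nm) {
      res <- permutation_enrichment(regions, feature_sets[[nm]], chrom_sizes,
                                    n_perm = config$n_perm,
                                    seed = seeds[si])
      si <<- si + 1L
      enrich[[nm]] <<- res
      data.frame(feature_set = nm, observed = res$observed,
                 null_mean = res$null_mean, null_sd = res$null_sd,
                 z = res$z_score, empirical_p = res$empirical_p,
                 n_perm = res$n_perm, seed = res$seed,
                 stringsAsFactors = FALSE)
    })
    write_tsv(do.call(rbind, rows), file.path(outdir, "enrichment.tsv"),
              header = hdr)
    manifest$gene_overlap_fraction <- round(enrich$genes$observed, 4)
  }

  log_stage(verbose, "closest genes + specific gene set")
  gene_overlap <- NULL
  if (length(regions)) {
    assign_df <- closest_gene(regions, genes)
    write_tsv(assign_df, file.path(outdir, "closest_genes.tsv"),
              header = hdr)
    manifest$n_regions_with_gene <- sum(!is.na(assign_df$gene_id))
    if (!is.null(p$expression)) {
      expr <- read_expression(p$expression)
      spec <- specific_gene_set(expr)
      spec <- intersect(spec, S4Vectors::mcols(genes)$gene_id)
      if (length(spec)) {
        gene_overlap <- gene_set_overlap_test(spec, genes, regions)
        write_tsv(data.frame(pct_special = gene_overlap$pct_special,
                             pct_all = gene_overlap$pct_all,
                             odds_ratio = gene_overlap$odds_ratio,
                             p_value = gene_overlap$p_value),
                  file.path(outdir, "specific_gene_overlap.tsv"),
                  header = hdr)
        manifest$pct_specific_genes_overlapping <-
          round(gene_overlap$pct_special, 1)
        manifest$pct_all_genes_overlapping <- round(gene_overlap$pct_all, 1)
      }
    }
  }

  log_stage(verbose, "base composition / GC skew")
  if (length(regions)) {
    for (anch in c("five_prime", "three_prime", "center")) {
      sp <- base_composition_profile(regions, genome, anchor = anch,
                                     flank = config$skew_flank,
                                     window = config$skew_window)
      write_tsv(sp, file.path(outdir, paste0("skew_", anch, ".tsv")),
                header = hdr)
    }
  }

  log_stage(verbose, "EpiMark quantification")
  modifications <- NULL
  if (!is.null(p$qpcr)) {
    modifications <- estimate_modifications(read_qpcr(p$qpcr))
    write_tsv(modifications, file.path(outdir, "modification_fractions.tsv"),
              header = hdr)
  }

  manifest$elapsed_sec <- round(as.numeric(difftime(Sys.time(), t0,
                                                    units = "secs")), 1)
  mdf <- data.frame(key = names(manifest),
                    value = vapply(manifest, function(v)
                      paste(format(v, trim = TRUE), collapse = ","), ""),
                    stringsAsFactors = FALSE)
  write_tsv(mdf, file.path(outdir, "manifest.tsv"), header = hdr)
  log_stage(verbose, "done: %d consensus regions in %s s",
            manifest$n_consensus_regions, manifest$elapsed_sec)
  invisible(list(regions = regions, summary = summ, enrichment = enrich,
                 gene_overlap = gene_overlap,
                 modifications = modifications, manifest = manifest))
}

#' Simulate a dataset, write it, and run the pipeline on the files
#'
#' Convenience end-to-end driver used by the acceptance script: generates
#' the synthetic dataset, writes it under `outdir/sim`, builds a
#' \code{\link{pipeline_config}} pointing at the written files and runs
#' \code{\link{run_pipeline}} into `outdir/results`.
#'
#' @param config a \code{\link{synthetic_config}}.
#' @param outdir working directory.
#' @param n_perm enrichment permutations (default 100).
#' @param verbose log stage progress.
#' @return list: `sim` (the simulation), `result` (pipeline results),
#'   `paths`.
#' @export
run_synthetic_pipeline <- function(config = synthetic_config(), outdir,
                                   n_perm = 100, verbose = TRUE) {
  sim <- simulate_hmedip_dataset(config)
  paths <- write_simulation(sim, file.path(outdir, "sim"))
  pc <- pipeline_config(
    genome = paths$genome, chrom_sizes = paths$chrom_sizes,
    expA_ip = paths$expA_ip, expA_input = paths$expA_input,
    expA_noab = paths$expA_noab, expB_ip = paths$expB_ip,
    expB_input = paths$expB_input, expB_noab = paths$expB_noab,
    genes = paths$genes, enhancers = paths$enhancers, tfbs = paths$tfbs,
    h3k4me1 = paths$H3K4me1, h3k27ac = paths$H3K27ac,
    expression = paths$expression, qpcr = paths$qpcr,
    fragment_size = config$fragment_size, n_perm = n_perm,
    seed = config$seed)
  result <- run_pipeline(pc, file.path(outdir, "results"),
                         verbose = verbose)
  list(sim = sim, result = result, paths = paths)
}
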