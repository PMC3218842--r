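## Per-locus 5hmC / 5mC / unmodified fractions from the
## beta-glucosyltransferase + MspI/HpaII qPCR assay. Glucosylation protects
## 5hmC from MspI, so (BGT, MspI) copies measure 5hmC; HpaII cuts only
## unmodified CCGG, so its copies measure 5hmC + 5mC. Background (the mock,
## MspI residual, i.e. fully cuttable DNA that still amplified) is
## subtracted from every sample and copies are normalized to the undigested
## glucosylated sample.

epimark_fractions_once <- function(copies, background = NULL) {
  ## copies: named list with BGT.none, BGT.MspI, mock.MspI, and at least one
  ## of BGT.HpaII / mock.HpaII (already replicate-averaged or single rep)
  B <- if (is.null(background)) copies[["mock.MspI"]] else background
  denom <- copies[["BGT.none"]] - B
  if (!is.finite(denom) || denom <= 0)
    stop("assay failure: undigested signal does not exceed background",
         call. = FALSE)
  hpa <- mean(c(copies[["BGT.HpaII"]], copies[["mock.HpaII"]]), na.rm = TRUE)
  hmc <- (copies[["BGT.MspI"]] - B) / denom
  resistant <- (hpa - B) / denom
  flags <- character(0)
  if (hmc < 0) { hmc <- 0; flags <- c(flags, "negative_hmc") }
  if (resistant < hmc) { resistant <- hmc
    flags <- c(flags, "resistant_below_hmc") }
  if (resistant > 1) { resistant <- 1
    flags <- c(flags, "resistant_above_one") }
  mc <- resistant - hmc
  unmod <- 1 - resistant
  if (hmc > 1) { hmc <- 1; mc <- 0; unmod <- 0
    flags <- c(flags, "hmc_above_one") }
  tot <- hmc + mc + unmod
  list(hmc = hmc / tot, mc = mc / tot, unmodified = unmod / tot,
       flags = flags)
}

#' Modification fractions for one locus
#'
#' Requires measurements for (BGT, none), (BGT, MspI), (mock, MspI) and at
#' least one HpaII digestion (either treatment; averaged when both are
#' present). Replicates are averaged before the point estimate; the
#' replicate standard deviation of each fraction comes from recomputing the
#' estimate per replicate index (only replicate indices present in all
#' required conditions contribute).
#'
#' Estimator (B = mean mock+MspI copies unless `background` is supplied):
#' hmc = (BGT,MspI - B) / (BGT,none - B);
#' resistant = (HpaII - B) / (BGT,none - B); mc = resistant - hmc;
#' unmodified = 1 - resistant. Negative intermediates are clamped to 0 and
#' flagged rather than silently truncated, and the three fractions are
#' renormalized to sum to 1.
#'
#' @param measurements data.frame with columns treatment (BGT|mock),
#'   digestion (none|MspI|HpaII), replicate, copies, for a single locus.
#' @param background optional user-supplied background copy number
#'   (overrides the mock+MspI definition).
#' @return list of class `modification_estimate`: hmc_fraction,
#'   mc_fraction, unmodified_fraction, sd (named vector, NA when fewer than
#'   two complete replicates), n_replicates, flags.
#' @export
modification_fractions <- function(measurements, background = NULL) {
  need <- c("treatment", "digestion", "replicate", "copies")
  miss <- setdiff(need, names(measurements))
  if (length(miss))
    stop("measurements missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(measurements$copies < 0))
    stop("negative copy numbers", call. = FALSE)
  key <- paste(measurements$treatment, measurements$digestion, sep = ".")
  required <- c("BGT.none", "BGT.MspI", "mock.MspI")
  absent <- setdiff(required, key)
  if (length(absent))
    stop("missing required condition(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  if (!any(key %in% c("BGT.HpaII", "mock.HpaII")))
    stop("missing required condition(s): HpaII digestion", call. = FALSE)
  avg <- tapply(measurements$copies, key, mean)
  point <- epimark_fractions_once(as.list(avg), background)

  ## per-replicate recomputation for spread
  conds <- unique(key)
  reps <- split(measurements, measurements$replicate)
  complete <- vapply(reps, function(d) {
    k <- paste(d$treatment, d$digestion, sep = ".")
    all(required %in% k) && any(k %in% c("BGT.HpaII", "mock.HpaII"))
  }, logical(1))
  per_rep <- lapply(reps[complete], function(d) {
    k <- paste(d$treatment, d$digestion, sep = ".")
    tryCatch(epimark_fractions_once(as.list(tapply(d$copies, k, mean)),
                                    background),
             error = function(e) NULL)
  })
  per_rep <- per_rep[!vapply(per_rep, is.null, logical(1))]
  sds <- if (length(per_rep) >= 2) {
    m <- vapply(per_rep, function(p)
      c(p$hmc, p$mc, p$unmodified), numeric(3))
    apply(m, 1, stats::sd)
  } else rep(NA_real_, 3)
  structure(list(hmc_fraction = point$hmc, mc_fraction = point$mc,
                 unmodified_fraction = point$unmodified,
                 sd = stats::setNames(sds, c("hmc", "mc", "unmodified")),
                 n_replicates = length(per_rep),
                 flags = point$flags),
            class = "modification_estimate")
}

#' @export
print.modification_estimate <- function(x, ...) {
  cat(sprintf("5hmC %.1f%%, 5mC %.1f%%, unmodified %.1f%%%s\n",
              100 * x$hmc_fraction, 100 * x$mc_fraction,
              100 * x$unmodified_fraction,
              if (length(x$flags))
                paste0(" [", paste(x$flags, collapse = ","), "]") else ""))
  invisible(x)
}

#' Modification fractions for every locus of a qPCR table
#'
#' @param qpcr data.frame as from \code{\link{read_qpcr}} /
#'   \code{\link{simulate_qpcr}}.
#' @param background optional background override passed through.
#' @return data.frame: locus, hmc_fraction, mc_fraction,
#'   unmodified_fraction, sd_hmc, sd_mc, sd_unmodified, n_replicates, flags
#'   (comma-separated).
#' @export
estimate_modifications <- function(qpcr, background = NULL) {
  loci <- unique(qpcr$locus)
  rows <- lapply(loci, function(l) {
    est <- modification_fractions(qpcr[qpcr$locus == l, ], background)
    data.frame(locus = l, hmc_fraction = est$hmc_fraction,
               mc_fraction = est$mc_fraction,
               unmodified_fraction = est$unmodified_fraction,
               sd_hmc = est$sd[["hmc"]], sd_mc = est$sd[["mc"]],
               sd_unmodified = est$sd[["unmodified"]],
               n_replicates = est$n_replicates,
               flags = paste(est$flags, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
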