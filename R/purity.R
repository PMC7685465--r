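#' Purity estimate container
#'
#' @param rho Estimated tumour purity, clipped to [0, 1].
#' @param method One of "regions", "mip", "combined".
#' @param components Per-region (or per-source) component estimates.
#' @param clipped TRUE if clipping to [0, 1] occurred.
#' @param flags Character vector of quality flags.
#' @return An object of class `purity_estimate`.
#' @export
purity_estimate <- function(rho, method, components = numeric(0),
                            clipped = FALSE, flags = character(0)) {
  structure(list(rho = rho, method = method, components = components,
                 clipped = clipped, flags = flags),
            class = "purity_estimate")
}

#' @export
print.purity_estimate <- function(x, ...) {
  cat(sprintf("<purity_estimate> rho = %.3f (%s)%s\n", x$rho, x$method,
              if (x$clipped) " [clipped]" else ""))
  invisible(x)
}

clip01 <- function(x) {
  list(value = min(1, max(0, x)), clipped = x < 0 || x > 1)
}

#' Purity from read depth over fixed deletion regions
#'
#' Uses regions known to carry a single-copy loss (LOH, copy number 1) or a
#' homozygous deletion (Homdel, copy number 0) in every tumour of the lineage.
#' Host cells dilute the depth drop, so under the mixture model the depth
#' ratio r = region / genome satisfies r = 1 - rho/2 for LOH and r = 1 - rho
#' for Homdel. Each region yields a component estimate (rho = 1 - r for
#' Homdel, rho = 2 * (1 - r) for LOH) and the returned purity is their mean.
#'
#' @param depth_profile data.frame of depth windows (columns `chrom`, `start`,
#'   `end`, `depth`), typically 10-kb windows with a 5-kb slide.
#' @param regions data.frame (`chrom`, `start`, `end`, `class`) with class in
#'   {"LOH", "Homdel"}.
#' @return A `purity_estimate` (method "regions") with per-region components.
#' @export
purity_from_regions <- function(depth_profile, regions) {
  if (is.null(regions) || nrow(regions) == 0) stop("empty region list")
  if (!all(regions$class %in% c("LOH", "Homdel"))) stop("region class must be LOH or Homdel")
  r_genome <- mean(depth_profile$depth)
  if (!is.finite(r_genome) || r_genome <= 0) stop("genome-wide mean depth is zero")
  comp <- numeric(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    w <- depth_profile$chrom == regions$chrom[i] &
      depth_profile$start < regions$end[i] & depth_profile$end > regions$start[i]
    if (!any(w)) stop(sprintf("region %d covers no depth window", i))
    ratio <- mean(depth_profile$depth[w]) / r_genome
    comp[i] <- if (regions$class[i] == "Homdel") 1 - ratio else 2 * (1 - ratio)
  }
  names(comp) <- paste0(regions$class, "_", seq_len(nrow(regions)))
  cl <- clip01(mean(comp))
  purity_estimate(cl$value, "regions", comp, cl$clipped,
                  flags = if (cl$clipped) "clipped" else character(0))
}

#' Purity from targeted-panel variant allele fractions
#'
#' Somatic variants at heterozygous diploid sites have expected VAF rho / 2,
#' so purity is twice the median VAF of variants passing a minimum
#' variant-read support threshold.
#'
#' @param variant_reads Integer vector of variant-supporting reads per variant.
#' @param total_reads Integer vector of total reads per variant.
#' @param min_variant_reads Minimum variant reads for a variant to count
#'   (default 3).
#' @return A `purity_estimate` (method "mip").
#' @export
purity_from_vaf <- function(variant_reads, total_reads, min_variant_reads = 3) {
  stopifnot(length(variant_reads) == length(total_reads))
  pass <- variant_reads >= min_variant_reads & total_reads > 0
  if (!any(pass)) stop("no variant passes the read-support threshold")
  vafs <- variant_reads[pass] / total_reads[pass]
  cl <- clip01(2 * stats::median(vafs))
  purity_estimate(cl$value, "mip", stats::setNames(vafs, NULL), cl$clipped,
                  flags = if (cl$clipped) "clipped" else character(0))
}

#' Combine two purity estimates by their mean
#'
#' If one estimate is `NULL` (undefined), the defined one passes through with
#' a "single_source" flag.
#'
#' @param a,b `purity_estimate` objects (either may be `NULL`).
#' @return A `purity_estimate` (method "combined").
#' @export
combine_purity <- function(a, b) {
  if (is.null(a) && is.null(b)) stop("both purity estimates undefined")
  if (is.null(a) || is.null(b)) {
    est <- if (is.null(a)) b else a
    return(purity_estimate(est$rho, "combined",
                           stats::setNames(est$rho, est$method),
                           est$clipped, flags = c(est$flags, "single_source")))
  }
  purity_estimate((a$rho + b$rho) / 2, "combined",
                  stats::setNames(c(a$rho, b$rho), c(a$method, b$method)),
                  a$clipped || b$clipped)
}

#' Sliding-window mean depth from bin counts
#'
#' Convenience bridge from 100-kb bin counts to the window table consumed by
#' [purity_from_regions()]. With `window >= bin_size` each window's depth is
#' the mean of the bins it covers, scaled to per-bin units.
#'
#' @param counts Per-bin counts for one sample.
#' @param genome A `genome_layout`.
#' @param window Window width in bp.
#' @param slide Slide in bp.
#' @return data.frame (`chrom`, `start`, `end`, `depth`).
#' @export
window_depth <- function(counts, genome, window = genome$bin_size,
                         slide = window) {
  b <- genome$bins
  out <- list()
  for (ch in genome$chrom) {
    idx <- which(b$chrom == ch)
    last <- max(b$end[idx])
    starts <- seq(0, last - window, by = slide)
    d <- vapply(starts, function(s) {
      w <- idx[b$start[idx] < s + window & b$end[idx] > s]
      mean(counts[w])
    }, 0)
    out[[ch]] <- data.frame(chrom = ch, start = starts, end = starts + window,
                            depth = d)
  }
  do.call(rbind, out)
}
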