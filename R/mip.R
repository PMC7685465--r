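## MIP panel genotyping: purity- and contamination-aware presence calls,
## matrix filters, probe QC / rebalancing, and allelic genotype fitting.

#' Expected variant-supporting reads at a heterozygous diploid site
#'
#' `total_reads * purity * 0.5`: half the tumour-derived reads carry a
#' heterozygous somatic variant.
#'
#' @param total_reads Total reads covering the site (vectorised).
#' @param purity Tumour purity in [0, 1].
#' @return Expected variant read count.
#' @export
expected_variant_reads <- function(total_reads, purity) {
  stopifnot(all(total_reads >= 0), all(purity >= 0), all(purity <= 1))
  total_reads * purity * 0.5
}

#' Empirical per-sample contamination threshold
#'
#' The per-tumour contaminating-read level is summarised as the ceiling of a
#' high quantile (default 0.95, inverse-ECDF) of variant-read counts at sites
#' known to be absent from the sample's lineage, floored at 3 reads. Samples
#' with no usable absent sites fall back to the global floor and are flagged.
#'
#' @param read_table `mip_read_table` (columns sample, probe, total_reads,
#'   variant_reads).
#' @param known_absent Named list sample -> character vector of probes known
#'   absent in that sample.
#' @param quantile Quantile of absent-site counts (default 0.95).
#' @return Named integer vector of per-sample thresholds, with a
#'   `fallback` attribute naming samples that used the floor default.
#' @export
estimate_contamination_threshold <- function(read_table, known_absent,
                                             quantile = 0.95) {
  samples <- unique(read_table$sample)
  thr <- stats::setNames(integer(length(samples)), samples)
  fallback <- character(0)
  for (s in samples) {
    probes <- known_absent[[s]]
    rows <- read_table$sample == s & read_table$probe %in% probes
    if (is.null(probes) || !any(rows)) {
      thr[s] <- 3L
      fallback <- c(fallback, s)
      next
    }
    q <- stats::quantile(read_table$variant_reads[rows], quantile, type = 1,
                         names = FALSE)
    thr[s] <- max(3L, as.integer(ceiling(q)))
  }
  structure(thr, fallback = fallback)
}

#' Call variant presence, absence, or N from MIP read counts
#'
#' Decision tree on the expected variant reads E = total * purity * 0.5:
#' \itemize{
#'   \item E >= 10: present if variant reads exceed the contamination
#'     threshold (strict >); N if threshold >= reads > 2; absent if reads <= 2.
#'   \item 5 <= E < 10: present if reads exceed the threshold, else N
#'     (too few expected reads to call absence).
#'   \item E < 5: N regardless of reads.
#' }
#'
#' @param variant_reads,total_reads Integer vectors.
#' @param purity Per-sample purity (scalar or vector).
#' @param threshold Per-sample contamination threshold (scalar or vector).
#' @return Character vector in {"present", "absent", "N"}.
#' @export
call_genotype <- function(variant_reads, total_reads, purity, threshold) {
  stopifnot(all(variant_reads >= 0), all(total_reads >= 0),
            all(variant_reads <= total_reads))
  E <- expected_variant_reads(total_reads, purity)
  n <- length(variant_reads)
  thr <- rep_len(threshold, n)
  out <- rep("N", n)
  hi <- E >= 10
  mid <- E >= 5 & E < 10
  out[hi & variant_reads > thr] <- "present"
  out[hi & variant_reads <= thr & variant_reads > 2] <- "N"
  out[hi & variant_reads <= 2] <- "absent"
  out[mid & variant_reads > thr] <- "present"
  out
}

#' Genotype a full MIP read table into a sample x probe call matrix
#'
#' Duplicate sequencing runs of the same (sample, probe) are merged by
#' summing reads before calling.
#'
#' @param read_table `mip_read_table`.
#' @param purity_map Named vector sample -> purity.
#' @param thresholds Named vector sample -> contamination threshold.
#' @return Character matrix (samples x probes) of {"present","absent","N"}.
#' @export
genotype_matrix <- function(read_table, purity_map, thresholds) {
  agg <- stats::aggregate(cbind(total_reads, variant_reads) ~ sample + probe,
                          data = read_table, FUN = sum)
  calls <- call_genotype(agg$variant_reads, agg$total_reads,
                         purity_map[agg$sample], thresholds[agg$sample])
  samples <- sort(unique(agg$sample))
  probes <- sort(unique(agg$probe))
  M <- matrix("N", length(samples), length(probes),
              dimnames = list(samples, probes))
  M[cbind(agg$sample, agg$probe)] <- calls
  M
}

#' Filter a MIP genotype matrix
#'
#' In order: (1) drop variants called present in any normal devil; (2) drop
#' variants with more than `max_n_frac` of samples at N; (3) drop samples
#' with more than `max_n_frac` of remaining variants at N.
#'
#' @param genotypes samples x probes call matrix.
#' @param normal_calls Optional normals x probes call matrix (shared probes).
#' @param max_n_frac Maximum tolerated N fraction (default 0.5, strict >).
#' @return Filtered matrix with dropped ids in attributes
#'   `dropped_variants`, `dropped_samples`.
#' @export
filter_matrix <- function(genotypes, normal_calls = NULL, max_n_frac = 0.5) {
  dropped_v <- character(0)
  if (!is.null(normal_calls)) {
    shared <- intersect(colnames(genotypes), colnames(normal_calls))
    in_normal <- shared[apply(normal_calls[, shared, drop = FALSE] == "present",
                              2, any)]
    dropped_v <- in_normal
    genotypes <- genotypes[, setdiff(colnames(genotypes), in_normal), drop = FALSE]
  }
  n_frac_v <- colMeans(genotypes == "N")
  drop2 <- colnames(genotypes)[n_frac_v > max_n_frac]
  dropped_v <- c(dropped_v, drop2)
  genotypes <- genotypes[, setdiff(colnames(genotypes), drop2), drop = FALSE]
  n_frac_s <- rowMeans(genotypes == "N")
  dropped_s <- rownames(genotypes)[n_frac_s > max_n_frac]
  genotypes <- genotypes[setdiff(rownames(genotypes), dropped_s), , drop = FALSE]
  if (nrow(genotypes) == 0 || ncol(genotypes) == 0)
    warning("all samples or variants filtered out")
  structure(genotypes, dropped_variants = dropped_v, dropped_samples = dropped_s)
}

#' Probe rebalancing factors and removal list
#'
#' Rebalancing concentration factor per probe is
#' `sqrt(overall_median / probe_median)`. Probes more than 1.5 log10-fold
#' above the overall median, with zero coverage, or with more than 50%
#' median off-target reads are listed for removal.
#'
#' @param probe_median Named vector of per-probe median coverage.
#' @param overall_median Overall median coverage.
#' @param offtarget_ratio Optional named per-probe median off-target ratio.
#' @return List: `factor` (named, NA for removed probes), `remove`.
#' @export
probe_rebalance <- function(probe_median, overall_median, offtarget_ratio = NULL) {
  remove <- names(probe_median)[probe_median == 0]
  over <- names(probe_median)[probe_median > 0 &
                                log10(probe_median / overall_median) > 1.5]
  remove <- union(remove, over)
  if (!is.null(offtarget_ratio))
    remove <- union(remove, names(offtarget_ratio)[offtarget_ratio > 0.5])
  fac <- sqrt(overall_median / probe_median)
  fac[names(fac) %in% remove] <- NA_real_
  list(factor = fac, remove = remove)
}

#' Expected VAF of a tumour genotype diluted by host cells
#'
#' `VAF = (H_alt * (1 - p) + T_alt * p) / (H_total * (1 - p) + T_total * p)`.
#' At the somatic sites under consideration the host is homozygous reference
#' (`H_alt = 0`, `H_ref = 2`).
#'
#' @param t_alt Tumour alt-allele copies.
#' @param t_total Tumour total copies.
#' @param p Purity.
#' @param h_alt,h_total Host alt and total copies (defaults 0 and 2).
#' @return Expected variant allele fraction.
#' @export
expected_vaf <- function(t_alt, t_total, p, h_alt = 0, h_total = 2) {
  denom <- h_total * (1 - p) + t_total * p
  if (any(denom == 0)) stop("undefined VAF: zero total copy mixture")
  (h_alt * (1 - p) + t_alt * p) / denom
}

#' Best-fitting allelic genotype on the half-integer grid
#'
#' Evaluates every genotype `(total_cn - a | a)` for alt copies
#' `a in {0, 0.5, ..., total_cn}` and returns the one whose expected VAF is
#' closest to the observed VAF; ties break toward the smaller alt copy
#' number.
#'
#' @param total_cn Total copy number at the site (>= 0).
#' @param observed_vaf Observed variant allele fraction.
#' @param p Purity.
#' @return List of class `allelic_genotype`: `ref`, `alt`, `expected_vaf`,
#'   `residual`.
#' @export
best_fit_genotype <- function(total_cn, observed_vaf, p) {
  stopifnot(total_cn >= 0)
  alt_grid <- seq(0, total_cn, by = 0.5)
  evaf <- vapply(alt_grid, function(a) expected_vaf(a, total_cn, p), 0)
  resid <- abs(evaf - observed_vaf)
  i <- which.min(resid) # which.min takes the first (smallest alt) on ties
  structure(list(ref = total_cn - alt_grid[i], alt = alt_grid[i],
                 expected_vaf = evaf[i], residual = resid[i]),
            class = "allelic_genotype")
}

#' @export
print.allelic_genotype <- function(x, ...) {
  cat(sprintf("<allelic_genotype> %.1f|%.1f (expected VAF %.3f, residual %.3g)\n",
              x$ref, x$alt, x$expected_vaf, x$residual))
  invisible(x)
}
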