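## Penalised least-squares segmentation and the segment merge rules.
## pcf_core is an exact dynamic program: it minimises
##   sum_bins (x_i - mu_seg(i))^2 + gamma * (number of breakpoints)
## subject to every segment spanning >= kmin bins.

# Exact DP over one vector (no NAs). Returns 1-based start indices of segments.
pcf_core <- function(x, gamma, kmin = 1L) {
  n <- length(x)
  if (n == 0) return(integer(0))
  if (n < 2 * kmin) return(1L)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  segcost <- function(i, j) { # inclusive 1-based ends, vectorised over i
    len <- j - i + 1
    (cs2[j + 1] - cs2[i]) - (cs[j + 1] - cs[i])^2 / len
  }
  best <- rep(Inf, n + 1)
  prev <- integer(n + 1)
  best[1] <- -gamma # first segment carries no breakpoint penalty
  for (j in seq_len(n)) {
    i <- which(best[seq_len(j)] < Inf)            # candidate split points (0-based i-1)
    i <- i[j - (i - 1) >= kmin]
    if (length(i) == 0) next
    cand <- best[i] + gamma + segcost(i, j)
    w <- which.min(cand)
    best[j + 1] <- cand[w]
    prev[j + 1] <- i[w]
  }
  # backtrack
  starts <- integer(0)
  j <- n
  while (j > 0) {
    s <- prev[j + 1]
    starts <- c(s, starts)
    j <- s - 1
  }
  starts
}

# Joint DP across samples with a shared breakpoint set: minimises
#   sum_s sum_bins (x - mu)^2 + gamma * n_samples * breakpoints.
multipcf_core <- function(X, gamma, kmin = 1L) {
  n <- nrow(X)
  if (n == 0) return(integer(0))
  if (n < 2 * kmin) return(1L)
  m <- ncol(X)
  cs <- rbind(0, apply(X, 2, cumsum))
  cs2 <- rbind(0, apply(X^2, 2, cumsum))
  pen <- gamma * m
  best <- rep(Inf, n + 1)
  prev <- integer(n + 1)
  best[1] <- -pen
  for (j in seq_len(n)) {
    i <- which(best[seq_len(j)] < Inf)
    i <- i[j - (i - 1) >= kmin]
    if (length(i) == 0) next
    len <- j - i + 1
    A <- matrix(cs2[j + 1, ], length(i), m, byrow = TRUE) - cs2[i, , drop = FALSE]
    B <- matrix(cs[j + 1, ], length(i), m, byrow = TRUE) - cs[i, , drop = FALSE]
    cost <- rowSums(A) - rowSums(B^2) / len
    cand <- best[i] + pen + cost
    w <- which.min(cand)
    best[j + 1] <- cand[w]
    prev[j + 1] <- i[w]
  }
  starts <- integer(0)
  j <- n
  while (j > 0) {
    s <- prev[j + 1]
    starts <- c(s, starts)
    j <- s - 1
  }
  starts
}

# Robust per-bin noise SD from first differences of the unmasked signal.
logr_noise_sd <- function(x) {
  d <- diff(x[!is.na(x)])
  s <- stats::mad(d) / sqrt(2)
  if (!is.finite(s) || s == 0) s <- stats::sd(d) / sqrt(2)
  if (!is.finite(s) || s == 0) s <- 1e-6
  s
}

segment_row <- function(sample, chrom, start, end, n_bins, mean_logr, provenance) {
  data.frame(sample = sample, chrom = chrom, start = start, end = end,
             n_bins = n_bins, mean_logr = mean_logr, provenance = provenance,
             cn_state = NA_real_, subclonal = FALSE)
}

# Build tiling segments for one chromosome from DP segment starts over the
# unmasked bins. The first segment is extended to the chromosome start and
# each boundary sits at the first unmasked bin of the next segment.
build_chrom_segments <- function(sample, chrom, bin_start, bin_end, x, starts,
                                 provenance) {
  ends_idx <- c(starts[-1] - 1, length(x))
  out <- lapply(seq_along(starts), function(k) {
    idx <- starts[k]:ends_idx[k]
    gstart <- if (k == 1) bin_start[1] else bin_start[starts[k]]
    gend <- if (k == length(starts)) bin_end[length(x)] else bin_start[starts[k + 1]]
    segment_row(sample, chrom, gstart, gend, length(idx), mean(x[idx]), provenance)
  })
  do.call(rbind, out)
}

#' Single-sample piecewise-constant segmentation
#'
#' Exact penalised least-squares segmentation of a LogR profile by dynamic
#' programming, chromosome by chromosome. The effective penalty is
#' `gamma * sigma^2` where `sigma` is the per-bin noise SD estimated from the
#' median absolute deviation of first differences (set
#' `normalize_gamma = FALSE` to use `gamma` as an absolute penalty).
#'
#' @param logr A `logr_profile` (or numeric vector with `genome` supplied).
#' @param gamma Breakpoint penalty in units of per-bin variance (default 40).
#' @param kmin Minimum segment length in bins (default 5).
#' @param normalize_gamma Scale gamma by the estimated noise variance.
#' @param genome Required when `logr` is a bare numeric vector.
#' @param sample Sample id recorded on the segments.
#' @return data.frame of segments tiling each chromosome.
#' @export
pcf_segment <- function(logr, gamma = 40, kmin = 5L, normalize_gamma = TRUE,
                        genome = NULL, sample = "tumour") {
  stopifnot(gamma > 0, kmin >= 1)
  if (inherits(logr, "logr_profile")) {
    genome <- logr$genome
    x <- logr$logr
  } else x <- logr
  if (is.null(genome)) stop("genome required")
  pen <- if (normalize_gamma) gamma * logr_noise_sd(x)^2 else gamma
  b <- genome$bins
  out <- list()
  for (ch in genome$chrom) {
    idx <- which(b$chrom == ch & !is.na(x))
    if (length(idx) == 0) next
    starts <- pcf_core(x[idx], pen, kmin)
    out[[ch]] <- build_chrom_segments(sample, ch, b$start[idx], b$end[idx],
                                      x[idx], starts, "pcf")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Multi-sample piecewise-constant segmentation with shared breakpoints
#'
#' Joint exact segmentation of a group of LogR profiles (samples assumed to
#' share breakpoints, e.g. tumours of one clonal subgroup): one breakpoint
#' set minimising the summed residual error plus `gamma * n_samples` per
#' breakpoint. Per-sample segment means are computed per segment.
#'
#' @param logrs Named list of `logr_profile` objects on a shared bin index.
#' @param gamma,kmin,normalize_gamma As in [pcf_segment()].
#' @return data.frame of per-sample segments with a common breakpoint set.
#' @export
multipcf_segment <- function(logrs, gamma = 40, kmin = 5L, normalize_gamma = TRUE) {
  if (length(logrs) == 0) stop("empty sample group")
  genome <- logrs[[1]]$genome
  X <- sapply(logrs, function(l) l$logr)
  if (is.null(names(logrs))) colnames(X) <- sprintf("tumour%d", seq_along(logrs))
  pen <- if (normalize_gamma) gamma * mean(apply(X, 2, logr_noise_sd)^2) else gamma
  b <- genome$bins
  keep <- rowSums(is.na(X)) == 0
  out <- list()
  for (ch in genome$chrom) {
    idx <- which(b$chrom == ch & keep)
    if (length(idx) == 0) next
    starts <- multipcf_core(X[idx, , drop = FALSE], pen, kmin)
    for (s in colnames(X)) {
      out[[paste(ch, s)]] <- build_chrom_segments(s, ch, b$start[idx], b$end[idx],
                                                  X[idx, s], starts, "multipcf")
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- pmax(0, pmin(e1, e2) - pmax(s1, s2))
  pmin(ov / (e1 - s1), ov / (e2 - s2))
}

# provisional nearest-integer state from a segment mean (clipped at 0)
provisional_state <- function(mean_logr, rho, psi = 2, max_cn = 9) {
  cn <- cn_from_logr(mean_logr, rho, psi)
  pmin(max_cn, pmax(0, round(cn)))
}

#' Merge single- and multi-sample segmentations within one sample
#'
#' Where a pcf and a multipcf segment share a provisional copy-number state
#' and reciprocally overlap more than `overlap` of their length, the multipcf
#' breakpoints are retained; elsewhere the union of breakpoints is kept.
#' Adjacent segments are then merged iteratively (leftmost pair first) when
#' their member-bin LogR values differ significantly in neither location
#' (Wilcoxon rank-sum) nor dispersion (Ansari-Bradley) at level `alpha`
#' (`rule = "either"` merges when at least one test is non-significant).
#'
#' @param pcf_segs,multipcf_segs Segment tables for the same sample.
#' @param logr The sample's `logr_profile`.
#' @param rho,psi Purity and ploidy for provisional state assignment.
#' @param alpha Significance level (default 0.05).
#' @param overlap Reciprocal-overlap threshold (default 0.95).
#' @param rule "both" (default, conservative) or "either".
#' @return Merged segment table tiling each chromosome.
#' @export
merge_within_sample <- function(pcf_segs, multipcf_segs, logr, rho, psi = 2,
                                alpha = 0.05, overlap = 0.95,
                                rule = c("both", "either")) {
  rule <- match.arg(rule)
  genome <- logr$genome
  x <- logr$logr
  b <- genome$bins
  out <- list()
  for (ch in genome$chrom) {
    p <- pcf_segs[pcf_segs$chrom == ch, , drop = FALSE]
    m <- multipcf_segs[multipcf_segs$chrom == ch, , drop = FALSE]
    if (nrow(p) == 0 && nrow(m) == 0) next
    chrom_start <- min(c(p$start, m$start))
    chrom_end <- max(c(p$end, m$end))
    bp_m <- setdiff(m$start, chrom_start)
    bp_p <- setdiff(p$start, chrom_start)
    drop <- numeric(0)
    if (nrow(p) > 0 && nrow(m) > 0) {
      ps <- provisional_state(p$mean_logr, rho, psi)
      ms <- provisional_state(m$mean_logr, rho, psi)
      for (i in seq_len(nrow(p))) {
        for (j in seq_len(nrow(m))) {
          if (ps[i] == ms[j] &&
              reciprocal_overlap(p$start[i], p$end[i], m$start[j], m$end[j]) > overlap) {
            drop <- c(drop, p$start[i], p$end[i])
          }
        }
      }
    }
    bps <- sort(unique(c(bp_m, setdiff(bp_p, drop))))
    edges <- c(chrom_start, bps, chrom_end)
    segs <- lapply(seq_len(length(edges) - 1), function(k) {
      idx <- which(b$chrom == ch & b$start >= edges[k] & b$start < edges[k + 1] & !is.na(x))
      segment_row(p$sample[1] %||% m$sample[1], ch, edges[k], edges[k + 1],
                  length(idx), mean(x[idx]), "merged")
    })
    segs <- do.call(rbind, segs)
    segs <- merge_adjacent_by_test(segs, x, b, alpha, rule)
    out[[ch]] <- segs
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a

segment_bin_values <- function(seg, x, bins) {
  idx <- which(bins$chrom == seg$chrom & bins$start >= seg$start &
                 bins$start < seg$end & !is.na(x))
  x[idx]
}

# leftmost-pair-first iterative merging until a full pass makes no merge
merge_adjacent_by_test <- function(segs, x, bins, alpha, rule) {
  repeat {
    merged <- FALSE
    i <- 1
    while (i < nrow(segs)) {
      a <- segment_bin_values(segs[i, ], x, bins)
      c2 <- segment_bin_values(segs[i + 1, ], x, bins)
      if (length(a) >= 2 && length(c2) >= 2) {
        p_loc <- suppressWarnings(stats::wilcox.test(a, c2, exact = FALSE)$p.value)
        p_disp <- suppressWarnings(stats::ansari.test(a, c2, exact = FALSE)$p.value)
        ok <- if (rule == "both") (p_loc > alpha && p_disp > alpha)
              else (p_loc > alpha || p_disp > alpha)
      } else ok <- TRUE # too few bins for any test: absorb
      if (ok) {
        nall <- length(a) + length(c2)
        segs$mean_logr[i] <- if (nall > 0)
          (sum(a) + sum(c2)) / nall else NA_real_
        segs$end[i] <- segs$end[i + 1]
        segs$n_bins[i] <- nall
        segs <- segs[-(i + 1), , drop = FALSE]
        merged <- TRUE
      } else i <- i + 1
    }
    if (!merged) break
  }
  rownames(segs) <- NULL
  segs
}

lower_median <- function(v) sort(v)[(length(v) + 1) %/% 2]

#' Consolidate segment boundaries across samples and filter short segments
#'
#' Non-diploid segments called in different samples are given common
#' boundaries when they reciprocally overlap more than `overlap` of their
#' length, have both breakpoints within `max_bp_dist`, and deviate from CN2
#' in the same direction. Boundaries are consolidated to the (lower) median
#' of observed positions, so the result is independent of sample order.
#' Segments shorter than `min_len` are then deleted and absorbed into the
#' neighbour whose mean LogR is closer (ties to the left).
#'
#' @param segments Segment table across all samples with provisional states
#'   in `cn_state` (fill with [provisional_state()] first).
#' @param min_len Minimum retained segment length in bp (default 500 kb).
#' @param overlap Reciprocal-overlap threshold (default 0.95).
#' @param max_bp_dist Maximum per-boundary distance in bp (default 500 kb).
#' @return Consolidated segment table; per-sample tilings are preserved.
#' @export
harmonize_across_samples <- function(segments, min_len = 5e5, overlap = 0.95,
                                     max_bp_dist = 5e5) {
  seg <- segments
  seg$.id <- seq_len(nrow(seg))
  cand <- which(!is.na(seg$cn_state) & seg$cn_state != 2)
  # union-find over qualifying cross-sample pairs
  parent <- seq_len(nrow(seg))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (length(cand) > 1) {
    for (ai in seq_along(cand)[-length(cand)]) {
      for (bi in (ai + 1):length(cand)) {
        i <- cand[ai]; j <- cand[bi]
        if (seg$sample[i] == seg$sample[j] || seg$chrom[i] != seg$chrom[j]) next
        if (sign(seg$cn_state[i] - 2) != sign(seg$cn_state[j] - 2)) next
        if (abs(seg$start[i] - seg$start[j]) > max_bp_dist ||
            abs(seg$end[i] - seg$end[j]) > max_bp_dist) next
        if (reciprocal_overlap(seg$start[i], seg$end[i], seg$start[j], seg$end[j]) <= overlap)
          next
        parent[find(i)] <- find(j)
      }
    }
  }
  comp <- vapply(seq_len(nrow(seg)), find, 0L)
  for (grp in split(seq_len(nrow(seg))[seq_len(nrow(seg)) %in% cand],
                    comp[cand])) {
    if (length(grp) < 2) next
    ns <- lower_median(seg$start[grp])
    ne <- lower_median(seg$end[grp])
    for (i in grp) {
      smp <- seg$sample[i]; ch <- seg$chrom[i]
      sel <- seg$sample == smp & seg$chrom == ch
      # shift this sample's adjacent boundaries along with the segment
      left <- sel & seg$end == seg$start[i] & seg$.id != seg$.id[i]
      right <- sel & seg$start == seg$end[i] & seg$.id != seg$.id[i]
      seg$end[left] <- ns
      seg$start[right] <- ne
      seg$start[i] <- ns
      seg$end[i] <- ne
    }
  }
  seg <- seg[seg$end > seg$start, , drop = FALSE]
  # short-segment filter with absorption into the closer-mean neighbour
  out <- list()
  for (key in unique(paste(seg$sample, seg$chrom))) {
    s <- seg[paste(seg$sample, seg$chrom) == key, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    repeat {
      short <- which(s$end - s$start < min_len)
      if (length(short) == 0 || nrow(s) == 1) break
      i <- short[1]
      has_l <- i > 1
      has_r <- i < nrow(s)
      to_left <- if (has_l && has_r) {
        dl <- abs(s$mean_logr[i - 1] - s$mean_logr[i])
        dr <- abs(s$mean_logr[i + 1] - s$mean_logr[i])
        isTRUE(dl <= dr) || (is.na(dl) && is.na(dr))
      } else has_l
      if (to_left) {
        j <- i - 1
        w <- c(s$n_bins[j], s$n_bins[i])
        s$mean_logr[j] <- stats::weighted.mean(s$mean_logr[c(j, i)], w + 1e-9)
        s$end[j] <- s$end[i]
        s$n_bins[j] <- sum(w)
      } else {
        j <- i + 1
        w <- c(s$n_bins[i], s$n_bins[j])
        s$mean_logr[j] <- stats::weighted.mean(s$mean_logr[c(i, j)], w + 1e-9)
        s$start[j] <- s$start[i]
        s$n_bins[j] <- sum(w)
      }
      s <- s[-i, , drop = FALSE]
    }
    out[[key]] <- s
  }
  res <- do.call(rbind, out)
  res <- res[order(res$sample, match(res$chrom, unique(segments$chrom)), res$start), ]
  res$.id <- NULL
  rownames(res) <- NULL
  res
}
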