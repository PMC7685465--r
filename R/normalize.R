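#' Build a panel of normals for LogR normalisation and tangent denoising
#'
#' Each normal is depth-normalised by its own autosomal median; the per-bin
#' median of normalised depth is the reference level for LogR. Principal
#' directions of the centred normal LogR matrix drive tangent denoising.
#' Bins are centred but not variance-standardised before the PCA.
#'
#' @param normals bins x samples count matrix from normal genomes.
#' @param genome A `genome_layout`.
#' @param mask Optional logical per-bin exclusion mask (TRUE = excluded).
#' @param k Number of principal directions to retain
#'   (default `min(20, n_normals - 1)`).
#' @return An object of class `panel_of_normals`.
#' @export
build_pon <- function(normals, genome, mask = NULL, k = NULL) {
  stopifnot(nrow(normals) == n_bins(genome))
  if (is.null(mask)) mask <- rep(FALSE, n_bins(genome))
  if (is.null(k)) k <- min(20L, ncol(normals) - 1L)
  if (k > ncol(normals) - 1L) stop("k must not exceed n_normals - 1")
  auto <- bin_is_autosomal(genome) & !mask
  depth <- sweep(normals, 2, apply(normals[auto, , drop = FALSE], 2, stats::median), "/")
  med <- apply(depth, 1, stats::median)
  med[mask] <- NA_real_
  bad <- !mask & med <= 0
  if (any(bad)) {
    # zero-median bins carry no usable reference level; fold into the mask
    mask[bad] <- TRUE
    med[bad] <- NA_real_
  }
  logr_n <- log2(sweep(depth, 1, med, "/"))
  logr_n[mask, ] <- NA_real_
  centre <- rowMeans(logr_n)
  centred <- logr_n - centre
  rot <- NULL
  if (k > 0) {
    sv <- svd(t(centred[!mask, , drop = FALSE]), nu = 0, nv = k)
    rot <- matrix(0, n_bins(genome), k)
    rot[!mask, ] <- sv$v
  }
  structure(list(median = med, centre = centre, rotation = rot, k = k,
                 mask = mask, n_normals = ncol(normals), genome = genome),
            class = "panel_of_normals")
}

#' @export
print.panel_of_normals <- function(x, ...) {
  cat(sprintf("<panel_of_normals> %d normals, %d/%d usable bins, k = %d\n",
              x$n_normals, sum(!x$mask), length(x$mask), x$k))
  invisible(x)
}

#' Compute a LogR profile from tumour bin counts
#'
#' Two-step normalisation: the tumour is first depth-normalised by its own
#' autosomal median, then each bin is compared to the panel's per-bin median
#' normalised depth, on log2 scale. `mode = "global"` compares to the panel's
#' global (constant) level instead, reproducing the single-median reading.
#'
#' @param tumour Integer vector of per-bin tumour counts.
#' @param pon A `panel_of_normals`.
#' @param mode `"perbin"` (default) or `"global"`.
#' @return An object of class `logr_profile`: `$logr` (NA where masked),
#'   `$counts`, `$mask`, `$genome`.
#' @export
compute_logr <- function(tumour, pon, mode = c("perbin", "global")) {
  mode <- match.arg(mode)
  genome <- pon$genome
  stopifnot(length(tumour) == n_bins(genome))
  auto <- bin_is_autosomal(genome) & !pon$mask
  med_t <- stats::median(tumour[auto])
  if (!is.finite(med_t) || med_t <= 0) stop("tumour autosomal median depth is zero")
  depth <- tumour / med_t
  logr <- if (mode == "perbin") log2(depth / pon$median) else log2(depth)
  logr[pon$mask] <- NA_real_
  structure(list(logr = logr, counts = tumour, mask = pon$mask, genome = genome),
            class = "logr_profile")
}

#' Tangent denoising against the panel of normals
#'
#' Subtracts the projection of the centred tumour LogR onto the top-k
#' principal directions of the centred normal LogR matrix, removing systematic
#' artefacts shared with normals. `k = 0` returns the input unchanged.
#'
#' @param logr A `logr_profile`.
#' @param pon The `panel_of_normals` it was computed against.
#' @param k Number of components (<= panel `k`).
#' @return A denoised `logr_profile`.
#' @export
tangent_denoise <- function(logr, pon, k = pon$k) {
  if (k > pon$k) stop("k exceeds the panel's available components")
  if (k == 0) return(logr)
  x <- logr$logr
  keep <- !pon$mask
  v <- pon$rotation[keep, seq_len(k), drop = FALSE]
  centred <- x[keep] - pon$centre[keep]
  proj <- as.vector(v %*% crossprod(v, centred))
  x[keep] <- x[keep] - proj
  logr$logr <- x
  logr
}
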