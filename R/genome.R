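#' Genome layout for binned copy-number analysis
#'
#' Describes an ordered set of chromosomes, tiles each into fixed-size bins
#' (trailing partial bins are dropped), and fixes the circular order used by
#' the permutation null: chromosomes in the given (numeric) order with X last,
#' the end of X wrapping to the start of chromosome 1.
#'
#' @param chrom Character vector of chromosome names, in numeric order with
#'   the X chromosome last.
#' @param length Integer vector of chromosome lengths in bp.
#' @param bin_size Bin width in bp (default 100,000).
#' @return An object of class `genome_layout` with the bin table in `$bins`
#'   (0-based half-open coordinates).
#' @examples
#' g <- genome_layout(c("chr1", "chrX"), c(1050000, 500000))
#' nrow(g$bins) # 10 + 5; the trailing 50 kb of chr1 yields no bin
#' @export
genome_layout <- function(chrom, length, bin_size = 100000L) {
  stopifnot(is.character(chrom), length(chrom) == length(length))
  if (anyDuplicated(chrom)) stop("duplicate chromosome names")
  length <- as.numeric(length)
  if (any(length <= 0)) stop("chromosome lengths must be > 0")
  n_bins <- floor(length / bin_size)
  if (any(n_bins < 1)) stop("every chromosome must hold at least one full bin")
  bins <- do.call(rbind, lapply(seq_along(chrom), function(i) {
    s <- seq(0, (n_bins[i] - 1) * bin_size, by = bin_size)
    data.frame(chrom = chrom[i], start = s, end = s + bin_size)
  }))
  rownames(bins) <- NULL
  # X (last chromosome) is the only allosome; everything before it is autosomal
  structure(list(
    chrom = chrom, length = stats::setNames(length, chrom),
    bin_size = as.integer(bin_size), bins = bins,
    autosomes = chrom[-length(chrom)], allosome = chrom[length(chrom)]
  ), class = "genome_layout")
}

#' @export
print.genome_layout <- function(x, ...) {
  cat(sprintf("<genome_layout> %d chromosomes, %d bins of %d bp (%.1f Mb)\n",
              length(x$chrom), nrow(x$bins), x$bin_size, sum(x$length) / 1e6))
  invisible(x)
}

#' Default compact synthetic genome
#'
#' Six autosomes plus X totalling 60 Mb (600 bins at 100 kb), small enough
#' that full-pipeline tests run in seconds. Proportions loosely mimic a
#' karyotype with a few large and a few small chromosomes.
#'
#' @param bin_size Bin width in bp.
#' @return A `genome_layout`.
#' @export
synthetic_genome <- function(bin_size = 100000L) {
  genome_layout(
    chrom = c("chr1", "chr2", "chr3", "chr4", "chr5", "chr6", "chrX"),
    length = c(12e6, 11e6, 10e6, 9e6, 8e6, 5e6, 5e6),
    bin_size = bin_size
  )
}

n_bins <- function(genome) nrow(genome$bins)

bin_is_autosomal <- function(genome) genome$bins$chrom %in% genome$autosomes

#' Per-bin exclusion mask
#'
#' Marks bins overlapping user-supplied excluded intervals. Trailing partial
#' bins never exist (the tiling drops them), so only listed regions mask bins.
#'
#' @param genome A `genome_layout`.
#' @param excluded_intervals `NULL` or a data.frame with columns
#'   `chrom`, `start`, `end` (0-based half-open, within genome bounds).
#' @return Logical vector, one element per bin; `TRUE` means masked.
#' @export
build_mask <- function(genome, excluded_intervals = NULL) {
  mask <- rep(FALSE, n_bins(genome))
  if (is.null(excluded_intervals) || nrow(excluded_intervals) == 0) return(mask)
  ex <- excluded_intervals
  stopifnot(all(c("chrom", "start", "end") %in% names(ex)))
  if (!all(ex$chrom %in% genome$chrom)) stop("excluded interval on unknown chromosome")
  if (any(ex$start < 0) || any(ex$end > genome$length[ex$chrom]) || any(ex$start >= ex$end))
    stop("excluded interval outside genome bounds")
  b <- genome$bins
  for (i in seq_len(nrow(ex))) {
    hit <- b$chrom == ex$chrom[i] & b$start < ex$end[i] & b$end > ex$start[i]
    mask[hit] <- TRUE
  }
  mask
}

# Circular bin coordinate: offset of each chromosome's first bin on the
# circularised genome (numeric order, X last, X end joined to chr1 start).
circular_offsets <- function(genome) {
  per_chrom <- table(factor(genome$bins$chrom, levels = genome$chrom))
  off <- cumsum(c(0, as.numeric(per_chrom)))
  list(offset = stats::setNames(off[-length(off)], genome$chrom),
       per_chrom = stats::setNames(as.integer(per_chrom), genome$chrom),
       total = nrow(genome$bins))
}

# Map bp interval to bin index range [first, last] (1-based rows of $bins).
interval_bins <- function(genome, chrom, start, end) {
  b <- genome$bins
  which(b$chrom == chrom & b$start < end & b$end > start)
}

# Restore .Random.seed after evaluating expr under a local seed, so no
# operation in this package touches global random state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}
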