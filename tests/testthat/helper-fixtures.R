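# Shared fixtures and independent oracles. Oracles are deliberately naive
# (exhaustive enumeration, direct formula re-evaluation) and never call the
# code paths they check.

tiny_genome <- function() genome_layout(c("chr1", "chr2", "chrX"),
                                        c(3e6, 2e6, 1e6))

# Exhaustive search over all segmentations honouring kmin: minimises
# sum (x - mu)^2 + gamma * (n_segments - 1) by plain recursion (no DP reuse).
brute_pcf_objective <- function(x, gamma, kmin = 1L) {
  n <- length(x)
  sse <- function(v) sum((v - mean(v))^2)
  rec <- function(from) {
    m <- n - from + 1
    if (m < kmin) return(Inf)
    best <- Inf
    for (l in seq(kmin, m)) {
      if (from + l <= n && n - (from + l) + 1 < kmin) next # tail too short
      head_cost <- sse(x[from:(from + l - 1)])
      rest <- if (from + l > n) 0 else gamma + rec(from + l)
      best <- min(best, head_cost + rest)
    }
    best
  }
  rec(1)
}

pcf_objective <- function(x, starts, gamma) {
  ends <- c(starts[-1] - 1, length(x))
  sum(vapply(seq_along(starts), function(k) {
    v <- x[starts[k]:ends[k]]
    sum((v - mean(v))^2)
  }, 0)) + gamma * (length(starts) - 1)
}

# Exhaustive minimum-origin count: enumerate all internal-node labellings,
# minimise total state changes (root constrained to root_state via a virtual
# edge), then the number of 0->1 edges among minimum-change labellings.
brute_min_origins <- function(tree, carriers, root_state = 0L) {
  internal <- setdiff(tree$nodes, tree$tips)
  tips_state <- stats::setNames(as.integer(tree$tips %in% carriers), tree$tips)
  best <- c(Inf, Inf)
  for (mask in 0:(2^length(internal) - 1)) {
    lab <- c(tips_state,
             stats::setNames(as.integer(bitwAnd(bitwShiftR(mask, seq_along(internal) - 1), 1)),
                             internal))
    changes <- as.integer(lab[tree$root] != root_state)
    origins <- as.integer(root_state == 0 && lab[tree$root] == 1)
    for (v in tree$nodes) {
      p <- tree$parent[[v]]
      if (is.na(p)) next
      if (lab[p] != lab[v]) changes <- changes + 1L
      if (lab[p] == 0 && lab[v] == 1) origins <- origins + 1L
    }
    if (changes < best[1] || (changes == best[1] && origins < best[2]))
      best <- c(changes, origins)
  }
  best[2]
}

# truth segments (exact per-bin copy number runs) for one rendered cohort
truth_segments <- function(rend, tree, genome) {
  do.call(rbind, lapply(tree$tips, function(s) {
    cn <- rend$truth[[s]]$cn
    b <- genome$bins
    out <- NULL
    for (ch in genome$chrom) {
      idx <- which(b$chrom == ch)
      r <- rle(cn[idx])
      e <- cumsum(r$lengths)
      st <- c(0, utils::head(e, -1))
      out <- rbind(out, data.frame(
        sample = s, chrom = ch, start = b$start[idx][st + 1], end = b$end[idx][e],
        n_bins = r$lengths, mean_logr = log2(pmax(r$values, 0.01) / 2),
        provenance = "truth", cn_state = r$values, subclonal = FALSE))
    }
    out
  }))
}

# memoised default pipeline run shared by pipeline / acceptance tests
.pipeline_cache <- new.env(parent = emptyenv())
pipeline_fixture <- function(seed = 7) {
  key <- as.character(seed)
  if (is.null(.pipeline_cache[[key]])) {
    .pipeline_cache[[key]] <- run_pipeline(
      list(seed = seed),
      outdir = file.path(tempdir(), sprintf("skimclone_fixture_%d", seed)))
  }
  .pipeline_cache[[key]]
}

# truth number of independent M5 losses on a scattered tree
truth_m5_losses <- function(tree) {
  sum(vapply(tree$branch_events, function(e)
    !is.null(e) && any(e$kind == "m5_loss"), TRUE))
}
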