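#' Simulate a clonal phylogeny with clade structure
#'
#' Builds a random rooted binary tree over `n_tips` tumour samples whose tips
#' are partitioned into `n_clades` monophyletic clade groups, emulating the
#' clade structure of a transmissible tumour cohort. Tips within a clade are
#' joined coalescent-style, then clade roots are joined the same way.
#'
#' @param n_tips Number of tumour samples (>= 2).
#' @param n_clades Number of monophyletic clade groups (<= n_tips).
#' @param seed Integer seed; all randomness is local to this call.
#' @return An object of class `clone_tree`: node ids, a parent map (root has
#'   `NA`), tip labels, per-tip clade labels, and an (initially empty) list of
#'   events per branch. The branch of node `v` is the edge parent(v) -> v; the
#'   root's own slot carries clonal (ancestral) events.
#' @export
simulate_clone_tree <- function(n_tips, n_clades, seed) {
  if (n_tips < 2) stop("n_tips must be >= 2")
  if (n_clades > n_tips) stop("n_clades must not exceed n_tips")
  if (n_clades < 1) stop("n_clades must be >= 1")
  with_seed(seed, {
    tips <- sprintf("S%03d", seq_len(n_tips))
    clade_of <- sort(rep_len(seq_len(n_clades), n_tips))
    clade_labels <- stats::setNames(sprintf("clade%d", clade_of), tips)
    parent <- character(0)
    counter <- 0L
    new_node <- function() {
      counter <<- counter + 1L
      sprintf("N%03d", counter)
    }
    # coalescent-style joining: repeatedly merge two random active nodes
    join_up <- function(active, parent) {
      while (length(active) > 1) {
        pick <- sample(length(active), 2)
        p <- new_node()
        parent[active[pick]] <- p
        active <- c(active[-pick], p)
      }
      list(root = active, parent = parent)
    }
    clade_roots <- character(n_clades)
    for (cl in seq_len(n_clades)) {
      res <- join_up(tips[clade_of == cl], parent)
      parent <- res$parent
      clade_roots[cl] <- res$root
    }
    res <- join_up(clade_roots, parent)
    parent <- res$parent
    root <- res$root
    parent[root] <- NA_character_
    nodes <- names(parent)
    structure(list(
      nodes = nodes, parent = parent, root = root, tips = tips,
      clade_labels = clade_labels,
      branch_events = stats::setNames(vector("list", length(nodes)), nodes)
    ), class = "clone_tree")
  })
}

#' @export
print.clone_tree <- function(x, ...) {
  nev <- sum(vapply(x$branch_events, function(e) if (is.null(e)) 0L else nrow(e), 0L))
  cat(sprintf("<clone_tree> %d tips, %d clades, %d nodes, %d events\n",
              length(x$tips), length(unique(x$clade_labels)), length(x$nodes), nev))
  invisible(x)
}

tree_children <- function(tree) {
  split(names(tree$parent)[!is.na(tree$parent)], tree$parent[!is.na(tree$parent)])
}

# nodes in preorder (root first); deterministic given the stored node order
tree_preorder <- function(tree) {
  kids <- tree_children(tree)
  out <- character(0)
  stack <- tree$root
  while (length(stack)) {
    v <- stack[1]
    stack <- stack[-1]
    out <- c(out, v)
    stack <- c(kids[[v]], stack)
  }
  out
}

# path of nodes from root down to (and including) node v
tree_path <- function(tree, v) {
  path <- v
  while (!is.na(tree$parent[v])) {
    v <- tree$parent[[v]]
    path <- c(v, path)
  }
  path
}

tips_below <- function(tree, v) {
  kids <- tree_children(tree)
  out <- character(0)
  stack <- v
  while (length(stack)) {
    u <- stack[1]
    stack <- stack[-1]
    if (u %in% tree$tips) out <- c(out, u) else stack <- c(kids[[u]], stack)
  }
  out
}

#' Convert a clone tree to an ape phylo object
#'
#' Tip labels carry the clade as `tip|clade` so a newick export preserves it.
#' @param tree A `clone_tree`.
#' @return An `ape::phylo`.
#' @export
clone_tree_to_phylo <- function(tree) {
  tips <- tree$tips
  internal <- setdiff(tree$nodes, tips)
  internal <- internal[order(match(internal, tree_preorder(tree)))]
  idx <- stats::setNames(c(seq_along(tips), length(tips) + seq_along(internal)),
                         c(tips, internal))
  edge <- cbind(unname(idx[tree$parent[!is.na(tree$parent)]]),
                unname(idx[names(tree$parent)[!is.na(tree$parent)]]))
  # collapse the root if it has a single child chain (binary builder never does)
  phy <- list(edge = edge, tip.label = paste(tips, tree$clade_labels[tips], sep = "|"),
              Nnode = length(internal), edge.length = rep(1, nrow(edge)))
  class(phy) <- "phylo"
  ape::reorder.phylo(phy, "cladewise")
}

#' Default three-component M5 cassette for a synthetic genome
#'
#' The small derived marker chromosome is emulated as three fixed intervals on
#' chromosomes 2, 5, and X that are gained in the cohort ancestor and lost
#' together in a single event, mirroring its composition from fragments of
#' those chromosomes.
#'
#' @param genome A `genome_layout` containing chr2, chr5 and chrX.
#' @return data.frame of the three component intervals with component names.
#' @export
m5_cassette <- function(genome) {
  need <- c("chr2", "chr5", "chrX")
  if (!all(need %in% genome$chrom)) stop("genome lacks chr2/chr5/chrX for the M5 cassette")
  data.frame(
    component = c("M5chr2", "M5chr5", "M5chrX"),
    chrom = need,
    start = c(2e6, 1e6, 1e6),
    end = c(4e6, 3e6, 2e6)
  )
}

new_event <- function(kind, chrom = NA_character_, start = NA_real_, end = NA_real_,
                      delta = 0, component = NA_character_) {
  data.frame(kind = kind, chrom = chrom, start = start, end = end,
             delta = delta, component = component)
}

#' Scatter ground-truth events on the branches of a clone tree
#'
#' CNV counts per branch are Poisson(`cnv_rate`); lengths are log-normal
#' truncated at the 500-kb detection limit and rounded up to whole bins. A
#' `hotspot_weight` fraction of events start at configured hotspot positions
#' (breakpoint reuse). With probability `m5_loss_rate` a branch loses the
#' three-component M5 cassette; with probability `wgd_probability` a branch
#' undergoes whole-genome duplication. When `m5_loss_rate > 0` the cassette is
#' first gained on the root branch, so losses return it to the diploid state.
#'
#' @param tree A `clone_tree`.
#' @param genome A `genome_layout`.
#' @param cnv_rate Mean CNV events per branch.
#' @param length_log_mean Median CNV length in bp of the log-normal (default 2 Mb).
#' @param length_log_sd Log-sd of the length distribution.
#' @param hotspot_positions Optional data.frame (`chrom`, `pos`) of reused
#'   start positions.
#' @param hotspot_weight Fraction of CNVs that start at a hotspot.
#' @param m5_loss_rate Per-branch probability of losing the M5 cassette.
#' @param wgd_probability Per-branch probability of whole-genome duplication.
#' @param seed Integer seed.
#' @param min_len Detection limit in bp (default 500 kb).
#' @return The tree with `branch_events` populated.
#' @export
scatter_events <- function(tree, genome, cnv_rate, length_log_mean = 2e6,
                           length_log_sd = 0.5, hotspot_positions = NULL,
                           hotspot_weight = 0, m5_loss_rate = 0,
                           wgd_probability = 0, seed = 1, min_len = 5e5) {
  stopifnot(cnv_rate >= 0, m5_loss_rate >= 0, wgd_probability >= 0,
            hotspot_weight >= 0, hotspot_weight <= 1)
  bs <- genome$bin_size
  draw_len <- function(chrom) {
    for (i in 1:50) {
      len <- stats::rlnorm(1, log(length_log_mean), length_log_sd)
      if (len >= min_len) break
    }
    len <- max(len, min_len)
    len <- min(ceiling(len / bs) * bs, floor(genome$length[chrom] / bs) * bs)
    len
  }
  draw_event <- function() {
    use_hot <- !is.null(hotspot_positions) && nrow(hotspot_positions) > 0 &&
      stats::runif(1) < hotspot_weight
    if (use_hot) {
      h <- hotspot_positions[sample(nrow(hotspot_positions), 1), ]
      chrom <- h$chrom
      start <- floor(h$pos / bs) * bs
    } else {
      nb <- table(factor(genome$bins$chrom, levels = genome$chrom))
      chrom <- sample(genome$chrom, 1, prob = as.numeric(nb))
      start <- sample.int(as.integer(nb[[chrom]]), 1) * bs - bs
    }
    len <- draw_len(chrom)
    end <- min(start + len, floor(genome$length[chrom] / bs) * bs)
    if (end - start < min_len) start <- max(0, end - ceiling(min_len / bs) * bs)
    kind <- sample(c("gain", "loss"), 1)
    new_event(kind, chrom, start, end, delta = if (kind == "gain") 1 else -1)
  }
  cas <- if (m5_loss_rate > 0) m5_cassette(genome) else NULL
  m5_lost <- stats::setNames(rep(FALSE, length(tree$nodes)), tree$nodes)
  with_seed(seed, {
    for (v in tree_preorder(tree)) {
      if (v != tree$root) m5_lost[v] <- m5_lost[[tree$parent[[v]]]]
      ev <- NULL
      if (v == tree$root && !is.null(cas)) {
        # ancestral marker-chromosome gain: cassette present in the MRCA
        ev <- do.call(rbind, lapply(seq_len(nrow(cas)), function(i)
          new_event("gain", cas$chrom[i], cas$start[i], cas$end[i], 1, cas$component[i])))
      }
      n_cnv <- stats::rpois(1, cnv_rate)
      if (n_cnv > 0) ev <- rbind(ev, do.call(rbind, replicate(n_cnv, draw_event(),
                                                              simplify = FALSE)))
      if (v != tree$root && !is.null(cas) && !m5_lost[[v]] &&
          stats::runif(1) < m5_loss_rate) {
        m5_lost[v] <- TRUE # a lineage carries one cassette copy; no second loss
        ev <- rbind(ev, do.call(rbind, lapply(seq_len(nrow(cas)), function(i)
          new_event("m5_loss", cas$chrom[i], cas$start[i], cas$end[i], -1,
                    cas$component[i]))))
      }
      if (v != tree$root && wgd_probability > 0 && stats::runif(1) < wgd_probability)
        ev <- rbind(ev, new_event("wgd"))
      tree$branch_events[[v]] <- ev
    }
    tree
  })
}

# True per-bin tumour copy number and ploidy for one tip, by replaying the
# events on the root-to-tip path. Copy numbers floor at zero.
sample_truth_cn <- function(tree, genome, tip) {
  cn <- rep(2, n_bins(genome))
  ploidy <- 2
  for (v in tree_path(tree, tip)) {
    ev <- tree$branch_events[[v]]
    if (is.null(ev)) next
    for (i in seq_len(nrow(ev))) {
      if (ev$kind[i] == "wgd") {
        cn <- cn * 2
        ploidy <- 4
      } else {
        idx <- interval_bins(genome, ev$chrom[i], ev$start[i], ev$end[i])
        cn[idx] <- pmax(0, cn[idx] + ev$delta[i])
      }
    }
  }
  list(cn = cn, ploidy = ploidy)
}

#' Render Poisson bin counts for tumours and a panel of normals
#'
#' Expected tumour count in bin j is
#' `mean_reads_per_bin * b_j * (2 * (1 - rho) + rho * CN_j) / psi_norm`, where
#' `b_j` is a per-bin multiplicative bias shared by all samples
#' (Gamma with mean 1 and coefficient of variation `bias_dispersion`) and
#' `psi_norm` rescales so the sample's expected autosomal median equals
#' `mean_reads_per_bin`. Counts are Poisson. Normals are pure diploid
#' (`CN = 2`, `rho = 1`).
#'
#' @param tree A `clone_tree` with events scattered.
#' @param genome A `genome_layout`.
#' @param purity_map Named numeric vector tip -> purity in (0, 1].
#' @param mean_reads_per_bin Target mean autosomal reads per bin (~100 at 1x).
#' @param n_normals Number of panel-of-normals samples.
#' @param bias_dispersion Coefficient of variation of the shared per-bin bias
#'   (0 disables bias).
#' @param seed Integer seed.
#' @return List with `tumours` (bins x samples count matrix), `normals`,
#'   `bias`, and `truth` (per-tip list: purity, ploidy, per-bin copy number).
#' @export
render_bin_counts <- function(tree, genome, purity_map, mean_reads_per_bin = 100,
                              n_normals = 20, bias_dispersion = 0, seed = 1) {
  stopifnot(mean_reads_per_bin >= 1)
  if (!all(tree$tips %in% names(purity_map))) stop("purity_map must cover every tip")
  if (any(purity_map <= 0 | purity_map > 1)) stop("purity must lie in (0, 1]")
  nb <- n_bins(genome)
  auto <- bin_is_autosomal(genome)
  with_seed(seed, {
    bias <- if (bias_dispersion > 0) {
      shape <- 1 / bias_dispersion^2
      stats::rgamma(nb, shape = shape, rate = shape)
    } else rep(1, nb)
    truth <- list()
    tum <- matrix(0L, nb, length(tree$tips), dimnames = list(NULL, tree$tips))
    for (tip in tree$tips) {
      tr <- sample_truth_cn(tree, genome, tip)
      rho <- purity_map[[tip]]
      mix <- 2 * (1 - rho) + rho * tr$cn
      psi_norm <- stats::median(mix[auto])
      lambda <- mean_reads_per_bin * bias * mix / psi_norm
      tum[, tip] <- stats::rpois(nb, lambda)
      truth[[tip]] <- list(sample = tip, purity = rho, ploidy = tr$ploidy,
                           cn = tr$cn, psi_norm = psi_norm)
    }
    nor <- matrix(stats::rpois(nb * n_normals, rep(mean_reads_per_bin * bias, n_normals)),
                  nb, n_normals, dimnames = list(NULL, sprintf("H%03d", seq_len(n_normals))))
    list(tumours = tum, normals = nor, bias = bias, truth = truth)
  })
}

#' Render MIP panel read counts with cross-contamination
#'
#' Each probe's variant is placed on a uniformly random branch of the tree;
#' tips below that branch truly carry it. Total reads per (sample, probe) are
#' negative-binomial around `median_depth`; variant-supporting reads are
#' Binomial(total, purity / 2) where the variant is present (heterozygous
#' diploid expectation) and Binomial(total, `contamination_rate`) where absent.
#'
#' @param tree A `clone_tree`.
#' @param n_probes Number of probes (>= 1).
#' @param median_depth Median total reads per probe (study-scale default 378).
#' @param purity_map Named numeric tip -> purity.
#' @param contamination_rate Per-read probability of a contaminant variant
#'   read at a truly absent site (in [0, 1)).
#' @param seed Integer seed.
#' @param nb_size Negative-binomial size (dispersion) of total reads.
#' @return data.frame (sample, probe, total_reads, variant_reads) of class
#'   `mip_read_table`, with the truth presence matrix in
#'   `attr(, "truth_presence")` and the probe branch map in `attr(, "probe_branch")`.
#' @export
render_mip_reads <- function(tree, n_probes, median_depth = 378, purity_map,
                             contamination_rate = 0.01, seed = 1, nb_size = 10) {
  stopifnot(n_probes >= 1, contamination_rate >= 0, contamination_rate < 1)
  if (!all(tree$tips %in% names(purity_map))) stop("purity_map must cover every tip")
  probes <- sprintf("MIP%04d", seq_len(n_probes))
  with_seed(seed, {
    branches <- sample(tree$nodes, n_probes, replace = TRUE)
    present <- matrix(FALSE, length(tree$tips), n_probes,
                      dimnames = list(tree$tips, probes))
    for (j in seq_len(n_probes)) present[tips_below(tree, branches[j]), j] <- TRUE
    rows <- expand.grid(probe = probes, sample = tree$tips,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows <- rows[, c("sample", "probe")]
    total <- stats::rnbinom(nrow(rows), mu = median_depth, size = nb_size)
    pres <- present[cbind(rows$sample, rows$probe)]
    p <- ifelse(pres, purity_map[rows$sample] / 2, contamination_rate)
    rows$total_reads <- total
    rows$variant_reads <- stats::rbinom(nrow(rows), total, p)
    structure(rows, truth_presence = present,
              probe_branch = stats::setNames(branches, probes),
              class = c("mip_read_table", "data.frame"))
  })
}

#' Write a bin-count matrix as TSV
#'
#' Rows are bins (`chrom`, `start`, `end`, 0-based half-open), columns samples.
#' @param counts bins x samples matrix.
#' @param genome A `genome_layout`.
#' @param path Output file.
#' @export
write_bin_counts <- function(counts, genome, path) {
  stopifnot(nrow(counts) == n_bins(genome))
  out <- cbind(genome$bins, as.data.frame(counts))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a bin-count TSV written by [write_bin_counts()]
#' @param path Input file.
#' @return List with `bins` data.frame and `counts` matrix.
#' @export
read_bin_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  list(bins = df[, c("chrom", "start", "end")],
       counts = as.matrix(df[, setdiff(names(df), c("chrom", "start", "end")),
                             drop = FALSE]))
}

#' Write a clone tree as newick with clade labels in tip names
#' @param tree A `clone_tree`.
#' @param path Output file.
#' @export
write_clone_tree <- function(tree, path) {
  ape::write.tree(clone_tree_to_phylo(tree), file = path)
  invisible(path)
}

#' Write per-sample truth as a sidecar TSV
#' @param truth The `truth` element of [render_bin_counts()] output.
#' @param genome A `genome_layout`.
#' @param path Output file.
#' @export
write_sample_truth <- function(truth, genome, path) {
  long <- do.call(rbind, lapply(truth, function(tr)
    cbind(genome$bins, sample = tr$sample, purity = tr$purity,
          ploidy = tr$ploidy, cn = tr$cn)))
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
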