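## End-to-end pipeline over a synthetic cohort plus standard-format export.
## Every stage seed derives from the single config seed, so a config fully
## determines all outputs (byte-identical on re-run).

#' Default pipeline configuration
#'
#' Returns the default configuration as a nested list; override any entry by
#' passing a partial list to [run_pipeline()]. Iteration counts are scaled so
#' the bundled fixture runs in seconds; thresholds carry the analysis
#' defaults (95% overlap, 500-kb minimum length and breakpoint distance,
#' alpha 0.05, 100-kb reuse resolution).
#'
#' @param seed Master seed; all stage seeds derive from it.
#' @return Named list of class `pipeline_config`.
#' @export
default_config <- function(seed = 1) {
  structure(list(
    seed = seed,
    simulate = list(n_tips = 8, n_clades = 2, cnv_rate = 1.2,
                    m5_loss_rate = 0.08, wgd_probability = 0,
                    purity_min = 0.7, purity_max = 1.0,
                    mean_reads_per_bin = 300, n_normals = 12,
                    bias_dispersion = 0.05, n_probes = 60,
                    median_depth = 378, contamination_rate = 0.01),
    normalize = list(k = 5, logr_mode = "perbin"),
    segment = list(gamma = 40, kmin = 5, alpha = 0.05, min_seg_len = 5e5),
    assign = list(n_iter = 1200, burn_in = 300, n_chains = 2,
                  mode = "mixture", max_cn = 9),
    permtest = list(n_perm = 200, resolution = 1e5),
    # purity_min_frac scales the variant-support threshold with panel depth,
    # so contaminant reads (~1% of 378x) never pass as real variants
    mip = list(quantile = 0.95, min_variant_reads = 3, purity_min_frac = 0.1)
  ), class = "pipeline_config")
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(override[[nm]]) && is.list(base[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

stage_seed <- function(seed, stage) {
  # small deterministic offsets keep derived seeds below 2^31
  offsets <- c(simulate = 11L, events = 23L, counts = 37L, mip = 53L,
               assign = 67L, perm = 83L, dates = 97L)
  (as.integer(seed) %% 20000000L) * 100L + offsets[[stage]]
}

#' Run the full pipeline on a synthetic cohort
#'
#' Generates a clone tree with CNV and M5 events, renders bin counts and MIP
#' reads, then executes normalisation, purity estimation, segmentation,
#' copy-number assignment, catalogue consolidation, breakpoint statistics,
#' and MIP genotyping, writing every artefact as TSV/newick/FASTA under
#' `outdir` together with a manifest of md5 checksums. Outputs are a pure
#' function of the configuration.
#'
#' @param config Partial configuration list merged over [default_config()].
#' @param outdir Output directory (created if needed).
#' @return Invisible list with in-memory results and `manifest`.
#' @export
run_pipeline <- function(config = list(), outdir = tempfile("skimclone_run_")) {
  cfg <- merge_config(default_config(), config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  genome <- synthetic_genome()
  sim <- cfg$simulate
  tree <- simulate_clone_tree(sim$n_tips, sim$n_clades,
                              seed = stage_seed(cfg$seed, "simulate"))
  tree <- scatter_events(tree, genome, cnv_rate = sim$cnv_rate,
                         m5_loss_rate = sim$m5_loss_rate,
                         wgd_probability = sim$wgd_probability,
                         seed = stage_seed(cfg$seed, "events"))
  purity_map <- with_seed(stage_seed(cfg$seed, "simulate"), {
    stats::setNames(stats::runif(length(tree$tips), sim$purity_min,
                                 sim$purity_max), tree$tips)
  })
  rend <- render_bin_counts(tree, genome, purity_map,
                            mean_reads_per_bin = sim$mean_reads_per_bin,
                            n_normals = sim$n_normals,
                            bias_dispersion = sim$bias_dispersion,
                            seed = stage_seed(cfg$seed, "counts"))
  mip <- render_mip_reads(tree, sim$n_probes, sim$median_depth, purity_map,
                          sim$contamination_rate,
                          seed = stage_seed(cfg$seed, "mip"))
  write_bin_counts(rend$tumours, genome, file.path(outdir, "tumour_counts.tsv"))
  write_bin_counts(rend$normals, genome, file.path(outdir, "normal_counts.tsv"))
  write_clone_tree(tree, file.path(outdir, "clone_tree.nwk"))
  write_sample_truth(rend$truth, genome, file.path(outdir, "truth.tsv"))

  pon <- build_pon(rend$normals, genome, k = cfg$normalize$k)
  # purity: region estimates from homozygous/single-copy deletion footprints
  # are not configured for the synthetic run; MIP-VAF purity is used.
  purity <- lapply(tree$tips, function(s) {
    rt <- mip[mip$sample == s, ]
    min_reads <- max(cfg$mip$min_variant_reads,
                     ceiling(cfg$mip$purity_min_frac *
                               stats::median(rt$total_reads)))
    est <- tryCatch(purity_from_vaf(rt$variant_reads, rt$total_reads, min_reads),
                    error = function(e) NULL)
    if (is.null(est)) purity_estimate(0.7, "mip", flags = "fallback") else est
  })
  names(purity) <- tree$tips

  seg_all <- list()
  assign_res <- list()
  for (s in tree$tips) {
    logr <- compute_logr(rend$tumours[, s], pon, mode = cfg$normalize$logr_mode)
    logr <- tangent_denoise(logr, pon)
    ps <- pcf_segment(logr, gamma = cfg$segment$gamma, kmin = cfg$segment$kmin,
                      sample = s)
    merged <- merge_within_sample(ps, ps, logr, rho = purity[[s]]$rho,
                                  alpha = cfg$segment$alpha)
    merged$sample <- s
    merged$cn_state <- provisional_state(merged$mean_logr, purity[[s]]$rho)
    seg_all[[s]] <- merged
    assign_res[[s]] <- list(logr = logr)
  }
  seg <- do.call(rbind, seg_all)
  seg <- harmonize_across_samples(seg, min_len = cfg$segment$min_seg_len)
  final <- list()
  for (s in tree$tips) {
    ss <- seg[seg$sample == s, , drop = FALSE]
    counts_per_seg <- vapply(seq_len(nrow(ss)), function(i) {
      idx <- interval_bins(genome, ss$chrom[i], ss$start[i], ss$end[i])
      mean(rend$tumours[idx, s])
    }, 0)
    # ploidy comes from the simulated karyotype flag, as in the real analysis
    res <- assign_copy_number(ss, counts_per_seg, purity[[s]],
                              psi_fixed = rend$truth[[s]]$ploidy,
                              mode = cfg$assign$mode,
                              n_iter = cfg$assign$n_iter,
                              burn_in = cfg$assign$burn_in,
                              n_chains = cfg$assign$n_chains,
                              seed = stage_seed(cfg$seed, "assign") + match(s, tree$tips))
    final[[s]] <- res$segments
  }
  segments <- do.call(rbind, final)
  rownames(segments) <- NULL
  utils::write.table(segments, file.path(outdir, "segments.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  cassette0 <- m5_cassette(genome)
  anc <- if (cfg$simulate$m5_loss_rate > 0)
    data.frame(chrom = cassette0$chrom, start = cassette0$start,
               end = cassette0$end, type = "gain")
  else NULL
  events <- consolidate_events(segments, tree, ancestral_footprints = anc)
  events <- link_events(events)
  cassette <- m5_cassette(genome)
  cassette$role <- c("mandatory", "mandatory", "optional")
  for (k in seq_len(nrow(cassette))) {
    hit <- events$chrom == cassette$chrom[k] &
      reciprocal_overlap(events$start, events$end,
                         cassette$start[k], cassette$end[k]) >= 0.5
    events$m5_component[hit] <- cassette$component[k]
  }
  utils::write.table(events, file.path(outdir, "cnv_catalogue.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  m5 <- detect_m5_loss(events, cassette, tree)
  utils::write.table(m5$status, file.path(outdir, "m5_status.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  burdens <- do.call(rbind, lapply(tree$tips, function(s)
    burden_and_genome_size(events, s)))
  utils::write.table(burdens, file.path(outdir, "burdens.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  occ <- events[events$step == 1 & !grepl("BM", events$extended_id), , drop = FALSE]
  if (nrow(occ)) occ$occ_id <- seq_len(nrow(occ))
  perm <- if (nrow(occ) >= 2)
    circular_permutation_null(occ, genome, n_perm = cfg$permtest$n_perm,
                              seed = stage_seed(cfg$seed, "perm"))
  else NULL
  if (!is.null(perm)) {
    utils::write.table(data.frame(replicate = seq_along(perm$null),
                                  statistic = perm$null),
                       file.path(outdir, "permutation_null.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }

  truth_presence <- attr(mip, "truth_presence")
  known_absent <- lapply(tree$tips, function(s)
    colnames(truth_presence)[!truth_presence[s, ]][seq_len(min(10, sum(!truth_presence[s, ])))])
  names(known_absent) <- tree$tips
  thr <- estimate_contamination_threshold(mip, known_absent, cfg$mip$quantile)
  rho_vec <- vapply(purity, function(p) p$rho, 0)
  geno <- genotype_matrix(mip, rho_vec, thr)
  geno <- filter_matrix(geno)
  utils::write.table(geno, file.path(outdir, "mip_genotypes.tsv"), sep = "\t",
                     quote = FALSE, col.names = NA)

  export_phylo_matrix(event_genotype_matrix(events, tree$tips), geno,
                      events = events,
                      fasta = file.path(outdir, "phylo_matrix.fasta"),
                      partitions = file.path(outdir, "phylo_partitions.txt"))

  files <- list.files(outdir, full.names = TRUE)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)))
  utils::write.table(manifest, file.path(outdir, "MANIFEST.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(outdir = outdir, tree = tree, purity = purity,
                 segments = segments, events = events, m5 = m5,
                 burdens = burdens, perm = perm, genotypes = geno,
                 manifest = manifest, truth = rend$truth))
}

#' Export a combined character matrix for external phylogenetics
#'
#' Writes a concatenated 0/1/N matrix (FASTA-coded, one sequence per sample)
#' combining CNV presence/absence, MIP calls, and optional mtDNA calls, plus
#' a partition file marking the blocks. M5-component CNVs and high-amplitude
#' amplicons (step > 2) are excluded from the CNV block.
#'
#' @param cnv_matrix samples x events 0/1 matrix.
#' @param mip_matrix samples x probes matrix of {"present","absent","N"}.
#' @param mtdna_matrix Optional samples x variants 0/1 matrix.
#' @param events Event table used to exclude M5/high-amplitude columns; its
#'   rows must correspond one-to-one with the columns of `cnv_matrix`.
#' @param fasta,partitions Output paths.
#' @return Invisible list of the paths.
#' @export
export_phylo_matrix <- function(cnv_matrix, mip_matrix, mtdna_matrix = NULL,
                                events = NULL, fasta, partitions) {
  samples <- intersect(rownames(cnv_matrix), rownames(mip_matrix))
  if (length(samples) == 0) stop("disjoint sample sets")
  if (!is.null(events)) {
    keep <- which(!((!is.na(events$m5_component) & events$m5_component != "") |
                      events$step > 2))
    cnv_matrix <- cnv_matrix[, keep, drop = FALSE]
  }
  mip_code <- matrix("N", length(samples), ncol(mip_matrix),
                     dimnames = list(samples, colnames(mip_matrix)))
  mm <- mip_matrix[samples, , drop = FALSE]
  mip_code[mm == "present"] <- "1"
  mip_code[mm == "absent"] <- "0"
  blocks <- list(MIP = mip_code,
                 CNV = matrix(as.character(cnv_matrix[samples, , drop = FALSE]),
                              length(samples)))
  if (!is.null(mtdna_matrix))
    blocks$mtDNA <- matrix(as.character(mtdna_matrix[samples, , drop = FALSE]),
                           length(samples))
  widths <- vapply(blocks, ncol, 0L)
  seqs <- vapply(seq_along(samples), function(i)
    paste(unlist(lapply(blocks, function(b) b[i, ])), collapse = ""), "")
  lines <- as.vector(rbind(paste0(">", samples), seqs))
  writeLines(lines, fasta)
  ends <- cumsum(widths)
  starts <- c(1, utils::head(ends, -1) + 1)
  writeLines(sprintf("%s = %d-%d", names(blocks), starts, ends), partitions)
  invisible(list(fasta = fasta, partitions = partitions))
}
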