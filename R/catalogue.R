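## Cross-cohort CNV catalogue: phylogenetically independent occurrences by
## parsimony, recurrence / back-mutation nomenclature, linkage groups, M5
## cassette machinery, burdens and rates, coinfection classification.

# Minimum-change labelling of a binary character on a clone tree, with the
# root constrained to the ancestral state 0 via a virtual root edge. Among
# minimum-change labellings the one with fewest 0->1 transitions (origins) is
# chosen, so equally parsimonious single-vs-multiple-origin ties resolve to a
# single origin. Returns origin edges (0->1) and back-mutation edges (1->0)
# with the tips below each.
fitch_label <- function(tree, carriers, root_state = 0L) {
  nodes <- tree_preorder(tree)
  kids <- tree_children(tree)
  E <- length(nodes) + 1
  BIG <- E + 2 # lexicographic weight: total changes dominate origin count
  wcost <- function(s, c2) (s != c2) * BIG + (s == 0 && c2 == 1)
  cost <- matrix(Inf, length(nodes), 2, dimnames = list(nodes, NULL))
  # postorder DP: cost[v, s+1] = cost of subtree at v given v has state s
  for (v in rev(nodes)) {
    if (v %in% tree$tips) {
      obs <- as.integer(v %in% carriers)
      cost[v, ] <- c(if (obs == 0) 0 else Inf, if (obs == 1) 0 else Inf)
    } else {
      for (s in 0:1) {
        tot <- 0
        for (ch in kids[[v]]) {
          opts <- cost[ch, ] + c(wcost(s, 0), wcost(s, 1))
          tot <- tot + min(opts)
        }
        cost[v, s + 1] <- tot
      }
    }
  }
  root_opts <- cost[tree$root, ] + c(wcost(root_state, 0), wcost(root_state, 1))
  lab <- stats::setNames(integer(length(nodes)), nodes)
  lab[tree$root] <- which.min(root_opts) - 1L
  for (v in nodes) {
    if (v %in% tree$tips) {
      lab[v] <- as.integer(v %in% carriers)
      next
    }
    for (ch in kids[[v]]) {
      opts <- cost[ch, ] + c(wcost(lab[v], 0), wcost(lab[v], 1))
      lab[ch] <- which.min(opts) - 1L
    }
  }
  origins <- list()
  backmuts <- list()
  if (lab[tree$root] == 1)
    origins[[length(origins) + 1]] <- list(node = tree$root,
                                           tips = tips_below(tree, tree$root))
  for (v in nodes) {
    p <- tree$parent[[v]]
    if (is.na(p)) next
    if (lab[p] == 0 && lab[v] == 1)
      origins[[length(origins) + 1]] <- list(node = v, tips = tips_below(tree, v))
    if (lab[p] == 1 && lab[v] == 0)
      backmuts[[length(backmuts) + 1]] <- list(node = v, tips = tips_below(tree, v))
  }
  # order origins deterministically by preorder position of the origin node
  ord <- order(match(vapply(origins, `[[`, "", "node"), nodes))
  list(origins = origins[ord], backmuts = backmuts, labelling = lab,
       n_origins = length(origins))
}

#' Minimum number of independent origins of a carrier set on a clone tree
#'
#' @param tree A `clone_tree`.
#' @param carriers Character vector of carrier tips.
#' @param irreversible If TRUE, the derived state cannot revert
#'   (Camin-Sokal parsimony): origins are the maximal subtrees whose tips all
#'   carry the character. Used for chromosome-loss status, which cannot
#'   back-mutate.
#' @return Integer minimum-origin count.
#' @export
count_origins <- function(tree, carriers, irreversible = FALSE) {
  if (length(carriers) == 0) return(0L)
  if (!irreversible) return(fitch_label(tree, carriers)$n_origins)
  kids <- tree_children(tree)
  all_lost <- stats::setNames(logical(length(tree$nodes)), tree$nodes)
  for (v in rev(tree_preorder(tree))) {
    all_lost[v] <- if (v %in% tree$tips) v %in% carriers
                   else all(all_lost[kids[[v]]])
  }
  n <- 0L
  for (v in tree_preorder(tree)) {
    p <- tree$parent[[v]]
    if (all_lost[v] && (is.na(p) || !all_lost[p])) n <- n + 1L
  }
  n
}

event_record <- function(basic_id, extended_id, type, chrom, start, end, step,
                         carriers, clades, states, origin_node, linkage_group = NA,
                         m5_component = NA_character_, post_wgd = FALSE,
                         parent_extended = NA_character_, subclonal = FALSE) {
  data.frame(basic_id = basic_id, extended_id = extended_id, type = type,
             chrom = chrom, start = start, end = end, step = step,
             carriers = paste(carriers, collapse = ","),
             clade_groups = paste(clades, collapse = ","),
             states = paste(states, collapse = ","),
             origin_node = origin_node, linkage_group = linkage_group,
             m5_component = m5_component, post_wgd = post_wgd,
             parent_extended = parent_extended, subclonal = subclonal)
}

#' Consolidate per-sample segments into cross-cohort CNV events
#'
#' Segments deviating from the diploid baseline are grouped by identical
#' coordinates, direction, and amplitude step (each step away from CN2 is a
#' separate record). Each group is split into phylogenetically independent
#' occurrences by minimum-change parsimony on the clone tree (ties resolve to
#' a single origin); the second and later origins get `R1`, `R2`, ...
#' suffixes. Carrier gaps inside an origin's subtree are emitted as inferred
#' back-mutation records (`BM` suffix, opposite direction). An observed
#' opposite-direction event nested strictly inside an ancestral event's
#' footprint is relabelled a partial back mutation (`PBM`), sharing the
#' parent's basic id. States beyond one step carry `G<occ>CN<state>` /
#' `L<occ>CN<state>` suffixes.
#'
#' @param segments Segment table across samples with final `cn_state` and
#'   `subclonal` columns.
#' @param tree A `clone_tree` whose tips are the samples.
#' @param ploidy_map Optional named vector sample -> baseline ploidy (2/4);
#'   tetraploid samples are called against baseline 4 and their event records
#'   flagged `post_wgd`.
#' @param min_len Events shorter than this are ignored (default 500 kb).
#' @param ancestral_footprints Optional data.frame (`chrom`, `start`, `end`,
#'   `type`) of events known from external evidence (e.g. karyotype) to have
#'   been present in the cohort ancestor; matching groups root at "present",
#'   so carrier gaps become back mutations instead of extra origins.
#' @return data.frame of CNV event records (one row per occurrence and step).
#' @export
consolidate_events <- function(segments, tree, ploidy_map = NULL, min_len = 5e5,
                               ancestral_footprints = NULL) {
  seg <- segments[!is.na(segments$cn_state), , drop = FALSE]
  if (!all(seg$sample %in% tree$tips)) stop("carrier sample missing from the tree")
  baseline <- function(s) if (!is.null(ploidy_map) && s %in% names(ploidy_map))
    ploidy_map[[s]] else 2
  raw <- list()
  for (i in seq_len(nrow(seg))) {
    b <- baseline(seg$sample[i])
    dev <- seg$cn_state[i] - b
    if (dev == 0 || seg$end[i] - seg$start[i] < min_len) next
    dir <- if (dev > 0) "gain" else "loss"
    nsteps <- ceiling(abs(dev))
    for (s in seq_len(nsteps)) {
      frac <- min(1, abs(dev) - (s - 1)) # 0.5 for a trailing subclonal step
      raw[[length(raw) + 1]] <- data.frame(
        sample = seg$sample[i], chrom = seg$chrom[i], start = seg$start[i],
        end = seg$end[i], type = dir, step = s, state = seg$cn_state[i],
        subclonal = frac < 1 || isTRUE(seg$subclonal[i]),
        post_wgd = b == 4)
    }
  }
  if (length(raw) == 0) return(event_record(integer(0), character(0), character(0),
    character(0), numeric(0), numeric(0), integer(0), character(0), character(0),
    character(0), character(0))[0, ])
  raw <- do.call(rbind, raw)
  key <- paste(raw$chrom, raw$start, raw$end, raw$type, raw$step)
  groups <- split(raw, key)
  # deterministic ordering: genomic, then direction, then step
  ord <- order(match(vapply(groups, function(g) g$chrom[1], ""), unique(segments$chrom)),
               vapply(groups, function(g) g$start[1], 0),
               vapply(groups, function(g) g$end[1], 0),
               vapply(groups, function(g) g$type[1], ""),
               vapply(groups, function(g) g$step[1], 0))
  groups <- groups[ord]
  records <- list()
  basic_counter <- 0L
  group_basic <- integer(length(groups))
  # assign basic ids: step-1 groups define events; higher steps share the id
  base_key <- vapply(groups, function(g) paste(g$chrom[1], g$start[1], g$end[1],
                                               g$type[1]), "")
  for (gi in seq_along(groups)) {
    prev <- which(base_key[seq_len(gi - 1)] == base_key[gi])
    if (length(prev)) group_basic[gi] <- group_basic[prev[1]]
    else {
      basic_counter <- basic_counter + 1L
      group_basic[gi] <- basic_counter
    }
  }
  for (gi in seq_along(groups)) {
    g <- groups[[gi]]
    carriers <- unique(g$sample)
    # external (e.g. karyotype) evidence that an event was present in the
    # cohort ancestor roots its character at "present"
    root_state <- 0L
    if (!is.null(ancestral_footprints)) {
      anc <- ancestral_footprints
      hit <- anc$type == g$type[1] & anc$chrom == g$chrom[1] &
        reciprocal_overlap(anc$start, anc$end, g$start[1], g$end[1]) >= 0.5
      if (any(hit)) root_state <- 1L
    }
    fl <- fitch_label(tree, carriers, root_state = root_state)
    for (oi in seq_along(fl$origins)) {
      occ <- fl$origins[[oi]]
      occ_carriers <- intersect(occ$tips, carriers)
      suffix <- if (oi > 1) sprintf("R%d", oi - 1) else ""
      if (g$step[1] > 1) {
        cn_lab <- if (g$type[1] == "gain") 2 + g$step[1] else 2 - g$step[1]
        suffix <- paste0(suffix, sprintf("%sCN%d",
                                         if (g$type[1] == "gain") paste0("G", oi)
                                         else paste0("L", oi), cn_lab))
      }
      st <- g$state[match(occ_carriers, g$sample)]
      records[[length(records) + 1]] <- event_record(
        group_basic[gi], paste0(group_basic[gi], suffix), g$type[1],
        g$chrom[1], g$start[1], g$end[1], g$step[1], occ_carriers,
        unique(tree$clade_labels[occ_carriers]), st, occ$node,
        post_wgd = any(g$post_wgd[match(occ_carriers, g$sample)]),
        subclonal = any(g$subclonal[match(occ_carriers, g$sample)]))
    }
    # inferred back mutations: tips inside an origin subtree lacking the event
    for (bm in fl$backmuts) {
      bm_tips <- bm$tips
      bmi <- sum(vapply(records, function(r)
        grepl("BM", r$extended_id) && r$basic_id == group_basic[gi], TRUE))
      records[[length(records) + 1]] <- event_record(
        group_basic[gi],
        paste0(group_basic[gi], "BM", if (bmi > 0) bmi + 1 else ""),
        if (g$type[1] == "gain") "loss" else "gain",
        g$chrom[1], g$start[1], g$end[1], g$step[1], bm_tips,
        unique(tree$clade_labels[bm_tips]),
        rep(2, length(bm_tips)), bm$node,
        parent_extended = paste0(group_basic[gi], ""))
    }
  }
  ev <- do.call(rbind, records)
  rownames(ev) <- NULL
  ev <- relabel_pbm(ev, tree)
  ev
}

# observed opposite-direction events nested strictly inside an ancestral
# event's footprint become partial back mutations sharing the parent id
relabel_pbm <- function(ev, tree) {
  if (nrow(ev) < 2) return(ev)
  for (i in seq_len(nrow(ev))) {
    if (grepl("BM", ev$extended_id[i])) next
    car_i <- strsplit(ev$carriers[i], ",")[[1]]
    for (j in seq_len(nrow(ev))) {
      if (i == j || ev$type[i] == ev$type[j] || ev$chrom[i] != ev$chrom[j]) next
      nested <- ev$start[i] >= ev$start[j] && ev$end[i] <= ev$end[j] &&
        (ev$end[i] - ev$start[i]) < (ev$end[j] - ev$start[j])
      if (!nested) next
      car_j <- strsplit(ev$carriers[j], ",")[[1]]
      if (all(car_i %in% car_j)) {
        k <- sum(grepl("PBM", ev$extended_id[ev$basic_id == ev$basic_id[j]]))
        ev$extended_id[i] <- paste0(ev$basic_id[j], "PBM",
                                    if (k > 0) k + 1 else "")
        ev$parent_extended[i] <- ev$extended_id[j]
        ev$basic_id[i] <- ev$basic_id[j]
      }
    }
  }
  ev
}

#' Assign linkage groups to consolidated events
#'
#' Events carried by exactly the same samples in the same direction share a
#' linkage group and are counted once in burden computations.
#'
#' @param events Event table from [consolidate_events()].
#' @return `events` with `linkage_group` filled.
#' @export
link_events <- function(events) {
  if (nrow(events) == 0) return(events)
  key <- paste(events$type,
               vapply(strsplit(events$carriers, ","),
                      function(s) paste(sort(s), collapse = ","), ""))
  events$linkage_group <- match(key, unique(key))
  events
}

#' Per-sample M5 cassette loss status
#'
#' A sample has lost M5 when it carries loss-direction records covering both
#' mandatory cassette components and at least one optional component.
#' Independent losses are counted by parsimony on the clone tree. Subclonal
#' component records propagate a subclonal status.
#'
#' @param events Consolidated event table.
#' @param cassette data.frame (`component`, `chrom`, `start`, `end`, `role`)
#'   with roles "mandatory" (exactly 2) and "optional" (>= 1); see
#'   [m5_cassette()] for the default intervals.
#' @param tree A `clone_tree` (for independent-loss counting).
#' @param min_overlap Reciprocal overlap needed to match a component (0.5).
#' @return List: `status` data.frame (sample, m5_lost, subclonal),
#'   `n_independent_losses`.
#' @export
detect_m5_loss <- function(events, cassette, tree, min_overlap = 0.5) {
  if (!"role" %in% names(cassette))
    cassette$role <- c("mandatory", "mandatory", "optional")[seq_len(nrow(cassette))]
  if (sum(cassette$role == "mandatory") < 2 || !any(cassette$role == "optional"))
    stop("cassette config needs two mandatory components and >= 1 optional")
  samples <- tree$tips
  carried <- matrix(FALSE, length(samples), nrow(cassette),
                    dimnames = list(samples, cassette$component))
  subc <- matrix(FALSE, length(samples), nrow(cassette),
                 dimnames = list(samples, cassette$component))
  loss_ev <- events[events$type == "loss", , drop = FALSE]
  for (k in seq_len(nrow(cassette))) {
    for (i in seq_len(nrow(loss_ev))) {
      if (loss_ev$chrom[i] != cassette$chrom[k]) next
      ro <- reciprocal_overlap(loss_ev$start[i], loss_ev$end[i],
                               cassette$start[k], cassette$end[k])
      if (ro >= min_overlap) {
        cs <- strsplit(loss_ev$carriers[i], ",")[[1]]
        carried[cs, k] <- TRUE
        if (isTRUE(loss_ev$subclonal[i])) subc[cs, k] <- TRUE
      }
    }
  }
  mand <- cassette$role == "mandatory"
  opt <- cassette$role == "optional"
  lost <- rowSums(carried[, mand, drop = FALSE]) == sum(mand) &
    rowSums(carried[, opt, drop = FALSE]) >= 1
  sub_status <- lost & (rowSums(subc) > 0)
  n_ind <- count_origins(tree, samples[lost], irreversible = TRUE)
  list(status = data.frame(sample = samples, m5_lost = unname(lost),
                           subclonal = unname(sub_status)),
       n_independent_losses = n_ind)
}

#' Two-sided Fisher exact test by hypergeometric enumeration
#'
#' Enumerates every 2x2 table with the observed margins and sums the
#' probabilities of tables at most as probable as the observed one.
#'
#' @param tab 2x2 integer matrix.
#' @return List: `p`, `odds_ratio` (sample OR).
#' @export
fisher_exact_2x2 <- function(tab) {
  stopifnot(all(dim(tab) == c(2, 2)), all(tab >= 0))
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); n <- sum(tab)
  lo <- max(0, r1 + c1 - n); hi <- min(r1, c1)
  dh <- function(a) stats::dhyper(a, c1, n - c1, r1)
  p_obs <- dh(tab[1, 1])
  p <- sum(vapply(lo:hi, function(a) {
    pa <- dh(a)
    if (pa <= p_obs * (1 + 1e-7)) pa else 0
  }, 0))
  or <- (tab[1, 1] * tab[2, 2]) / max(1e-12, tab[1, 2] * tab[2, 1])
  list(p = min(1, unname(p)), odds_ratio = unname(or))
}

#' Opportunity-corrected enrichment test for M5 loss
#'
#' Compares independent M5 loss counts between two groups (e.g. diploid vs
#' tetraploid, or one clade vs the rest) against the opportunity each lineage
#' had to lose the cassette (1 per diploid genome, 2 per tetraploid). The
#' 2x2 table is losses vs retained opportunity per group; the p-value is a
#' two-sided Fisher exact test by hypergeometric enumeration.
#'
#' @param losses Integer vector length 2: independent losses per group.
#' @param opportunity Integer vector length 2: summed opportunity per group.
#' @return List: `p`, `odds_ratio`, `table`.
#' @export
m5_enrichment_test <- function(losses, opportunity) {
  stopifnot(length(losses) == 2, length(opportunity) == 2)
  if (any(opportunity < 1)) stop("opportunity must be >= 1 in both groups")
  if (any(losses > opportunity)) stop("losses exceed opportunity")
  tab <- rbind(losses, opportunity - losses)
  ft <- fisher_exact_2x2(t(tab))
  list(p = ft$p, odds_ratio = ft$odds_ratio, table = t(tab))
}

#' CNV burden and genome size for one sample
#'
#' Burden counts linkage groups carried by the sample, with groups arising
#' after whole-genome duplication contributing 0.5 (twice the DNA, so half
#' the per-copy rate). Genome size is `2 * haploid_size` plus the summed
#' widths of clonal gains minus losses.
#'
#' @param events Linked event table ([link_events()]).
#' @param sample Sample id.
#' @param haploid_size Callable haploid genome size in bp
#'   (study-scale default 2,625,758,988).
#' @param clonal_only Exclude subclonal records from the size change (TRUE).
#' @return data.frame row: sample, burden, genome_size.
#' @export
burden_and_genome_size <- function(events, sample, haploid_size = 2625758988,
                                   clonal_only = TRUE) {
  stopifnot(haploid_size > 0)
  if (nrow(events) == 0)
    return(data.frame(sample = sample, burden = 0, genome_size = 2 * haploid_size))
  has <- vapply(strsplit(events$carriers, ","), function(s) sample %in% s, TRUE)
  ev <- events[has, , drop = FALSE]
  grp <- !duplicated(ev$linkage_group)
  burden <- sum(ifelse(ev$post_wgd[grp], 0.5, 1))
  sz <- ev
  if (clonal_only) sz <- sz[!sz$subclonal, , drop = FALSE]
  delta <- sum(ifelse(sz$type == "gain", 1, -1) * (sz$end - sz$start))
  data.frame(sample = sample, burden = burden,
             genome_size = 2 * haploid_size + delta)
}

#' CNV rate and genome-size rate regressions
#'
#' Ordinary least squares of burden on sampling date (with prediction
#' intervals), an ANOVA F-test of the date-by-clade interaction, and a Huber
#' M-estimator (robust) fit of genome size on date. Samples with a year but
#' no exact date receive a seeded uniform-random date within that year.
#'
#' @param burdens data.frame with columns `sample`, `burden`, `clade`,
#'   `genome_size`, and either `date` (Date or numeric years) or `year`.
#' @param seed Seed for imputing year-only dates.
#' @return List: `fit_burden`, `interaction_p`, `fit_size` (rlm), `data`.
#' @export
rate_regression <- function(burdens, seed = 1) {
  df <- burdens
  if (!"date" %in% names(df)) df$date <- NA
  if (inherits(df$date, "Date")) df$date <- as.numeric(df$date) / 365.25 + 1970
  miss <- is.na(df$date)
  if (any(miss)) {
    if (!"year" %in% names(df)) stop("missing dates need a year column")
    df$date[miss] <- with_seed(seed, df$year[miss] + stats::runif(sum(miss)))
  }
  if (length(unique(df$date)) < 3) stop("need >= 3 distinct dates")
  fit <- stats::lm(burden ~ date, data = df)
  interaction_p <- NA_real_
  if ("clade" %in% names(df) && length(unique(df$clade)) > 1) {
    m1 <- stats::lm(burden ~ date + clade, data = df)
    m2 <- stats::lm(burden ~ date * clade, data = df)
    interaction_p <- stats::anova(m1, m2)[2, "Pr(>F)"]
  }
  fit_size <- NULL
  if ("genome_size" %in% names(df))
    # noise-free inputs trip the IRLS convergence check; the fit is still exact
    fit_size <- suppressWarnings(MASS::rlm(genome_size ~ date, data = df,
                                           maxit = 100))
  list(fit_burden = fit, interaction_p = interaction_p, fit_size = fit_size,
       data = df)
}

#' Classify devils with multiple tumours as single infection or coinfection
#'
#' Tumour genotype vectors within one host are compared: identical vectors
#' (ignoring missing calls) mean a single infection; vectors differing only
#' at variants carried by no other devil's tumours are a single infection
#' with private polymorphism; vectors differing at variants also present in
#' other devils (or tumours from different clade groups) indicate
#' coinfection.
#'
#' @param genotypes samples x variants matrix of 0/1 (NA = undetermined).
#' @param devil_map Named vector sample -> host devil id.
#' @param clade_map Optional named vector sample -> clade group.
#' @return data.frame per devil (>= 2 tumours): devil, label, sublabel.
#' @export
coinfection_classify <- function(genotypes, devil_map, clade_map = NULL) {
  devils <- split(names(devil_map), unname(devil_map))
  out <- list()
  for (d in names(devils)) {
    tum <- devils[[d]]
    if (length(tum) < 2) next # skipped with notice
    others <- setdiff(rownames(genotypes), tum)
    if (!is.null(clade_map) && length(unique(clade_map[tum])) > 1) {
      out[[d]] <- data.frame(devil = d, label = "coinfection",
                             sublabel = "polymorphic_public")
      next
    }
    G <- genotypes[tum, , drop = FALSE]
    diff_vars <- which(apply(G, 2, function(col) {
      v <- col[!is.na(col)]
      length(unique(v)) > 1
    }))
    if (length(diff_vars) == 0) {
      out[[d]] <- data.frame(devil = d, label = "single_infection",
                             sublabel = "identical")
      next
    }
    public <- vapply(diff_vars, function(v) {
      any(genotypes[others, v] == 1, na.rm = TRUE)
    }, TRUE)
    if (any(public))
      out[[d]] <- data.frame(devil = d, label = "coinfection",
                             sublabel = "polymorphic_public")
    else
      out[[d]] <- data.frame(devil = d, label = "single_infection",
                             sublabel = "polymorphic_private")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-sample presence/absence genotypes for consolidated events
#'
#' @param events Consolidated event table.
#' @param samples Character vector of all sample ids.
#' @return samples x events 0/1 matrix (columns named by extended id).
#' @export
event_genotype_matrix <- function(events, samples) {
  M <- matrix(0L, length(samples), nrow(events),
              dimnames = list(samples, events$extended_id))
  for (i in seq_len(nrow(events))) {
    cs <- strsplit(events$carriers[i], ",")[[1]]
    M[intersect(cs, samples), i] <- 1L
  }
  M
}
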