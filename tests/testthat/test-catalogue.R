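simple_segs <- function(carriers, chrom = "chr1", start = 1e6, end = 3e6,
                        state = 1) {
  do.call(rbind, lapply(carriers, function(s)
    data.frame(sample = s, chrom = chrom, start = start, end = end,
               n_bins = (end - start) / 1e5, mean_logr = log2(max(state, 0.01) / 2),
               provenance = "merged", cn_state = state, subclonal = FALSE)))
}

test_that("consolidate_events splits occurrences by parsimony", {
  tr <- simulate_clone_tree(10, 2, 21)
  # sister tips: a parent branch can carry the event -> single origin
  sisters <- NULL
  for (v in setdiff(tr$nodes, tr$tips)) {
    below <- skimclone:::tips_below(tr, v)
    if (length(below) == 2) { sisters <- below; break }
  }
  ev1 <- consolidate_events(simple_segs(sisters), tr)
  expect_equal(nrow(ev1), 1)
  expect_equal(ev1$extended_id, "1")
  # tips in different clades with everything between absent -> R1 suffix
  far <- c(names(tr$clade_labels)[tr$clade_labels == "clade1"][1],
           names(tr$clade_labels)[tr$clade_labels == "clade2"][1])
  ev2 <- consolidate_events(simple_segs(far), tr)
  expect_equal(nrow(ev2), 2)
  expect_setequal(ev2$extended_id, c("1", "1R1"))
  expect_error(consolidate_events(simple_segs("nope"), tr), "missing")
})

test_that("parsimony origin counts match exhaustive enumeration", {
  withr::with_seed(77, {
    for (rep in 1:12) {
      tr <- simulate_clone_tree(sample(4:8, 1), 2, rep)
      carriers <- sample(tr$tips, sample(seq_along(tr$tips), 1))
      expect_equal(count_origins(tr, carriers),
                   brute_min_origins(tr, carriers),
                   info = sprintf("rep %d", rep))
    }
  })
})

test_that("multi-step states and back mutations get the catalogue suffixes", {
  tr <- simulate_clone_tree(8, 2, 33)
  # CN4 gain: two step records, the second labelled G1CN4
  segs <- simple_segs(tr$tips[1], state = 4)
  ev <- consolidate_events(segs, tr)
  expect_equal(nrow(ev), 2)
  expect_setequal(ev$extended_id, c("1", "1G1CN4"))
  expect_equal(sort(ev$step), c(1, 2))
  # ancestral event lost by one subtree -> BM record with opposite direction
  clade1 <- names(tr$clade_labels)[tr$clade_labels == "clade1"]
  carriers <- setdiff(tr$tips, clade1)
  anc <- data.frame(chrom = "chr1", start = 1e6, end = 3e6, type = "gain")
  ev2 <- consolidate_events(simple_segs(carriers, state = 3), tr,
                            ancestral_footprints = anc)
  expect_true(any(grepl("BM", ev2$extended_id)))
  bm <- ev2[grepl("BM", ev2$extended_id), ]
  expect_equal(bm$type, "loss")
  expect_setequal(strsplit(bm$carriers, ",")[[1]], clade1)
  # a nested opposite event inside the parent footprint becomes PBM
  seg3 <- rbind(simple_segs(tr$tips, state = 3),
                simple_segs(tr$tips[1], start = 1.5e6, end = 2.5e6, state = 1))
  # the nested loss (CN3 -> CN1 locally would be state 1 inside the gain)
  ev3 <- consolidate_events(seg3, tr)
  expect_true(any(grepl("PBM", ev3$extended_id)))
})

test_that("link_events groups by carrier set and direction", {
  tr <- simulate_clone_tree(6, 2, 3)
  segs <- rbind(simple_segs(c("S001", "S002"), chrom = "chr1", state = 1),
                simple_segs(c("S001", "S002"), chrom = "chr2", state = 1),
                simple_segs(c("S001", "S002"), chrom = "chr3", state = 3))
  ev <- link_events(consolidate_events(segs, tr))
  losses <- ev[ev$type == "loss", ]
  expect_equal(length(unique(losses$linkage_group)), 1)
  expect_equal(length(unique(ev$linkage_group)), 2) # gains split off
  # brute-force oracle on random events: partition by (carrier set, direction)
  withr::with_seed(9, {
    ev5 <- do.call(rbind, lapply(1:5, function(i) {
      cs <- sort(sample(tr$tips, sample(2:4, 1)))
      data.frame(basic_id = i, extended_id = as.character(i),
                 type = sample(c("gain", "loss"), 1), chrom = "chr1",
                 start = i * 1e6, end = i * 1e6 + 5e5, step = 1,
                 carriers = paste(cs, collapse = ","), clade_groups = "",
                 states = "", origin_node = "", linkage_group = NA,
                 m5_component = NA, post_wgd = FALSE, parent_extended = NA,
                 subclonal = FALSE)
    }))
    linked <- link_events(ev5)
    key <- paste(ev5$type, ev5$carriers)
    expect_equal(as.integer(factor(linked$linkage_group,
                                   levels = unique(linked$linkage_group))),
                 as.integer(factor(key, levels = unique(key))))
  })
})

test_that("detect_m5_loss applies the two-mandatory plus one-optional rule", {
  tr <- simulate_clone_tree(6, 2, 13)
  cass <- data.frame(component = c("M5chr2", "M5chr5", "M5chrX"),
                     chrom = c("chr1", "chr2", "chr3"),
                     start = 1e6, end = 3e6,
                     role = c("mandatory", "mandatory", "optional"))
  seg_all3 <- rbind(simple_segs("S001", chrom = "chr1"),
                    simple_segs("S001", chrom = "chr2"),
                    simple_segs("S001", chrom = "chr3"))
  ev <- consolidate_events(seg_all3, tr)
  st <- detect_m5_loss(ev, cass, tr)
  expect_true(st$status$m5_lost[st$status$sample == "S001"])
  expect_equal(st$n_independent_losses, 1)
  # one mandatory component alone is not a loss
  ev1 <- consolidate_events(simple_segs("S002", chrom = "chr1"), tr)
  st1 <- detect_m5_loss(ev1, cass, tr)
  expect_false(any(st1$status$m5_lost))
  # both mandatory but no optional is not a loss
  ev2 <- consolidate_events(rbind(simple_segs("S003", chrom = "chr1"),
                                  simple_segs("S003", chrom = "chr2")), tr)
  st2 <- detect_m5_loss(ev2, cass, tr)
  expect_false(any(st2$status$m5_lost))
  expect_error(detect_m5_loss(ev, cass[1:2, ], tr), "optional")
})

test_that("fisher enumeration matches stats::fisher.test", {
  tabs <- list(matrix(c(8, 2, 1, 9), 2), matrix(c(3, 3, 3, 3), 2),
               matrix(c(16, 4, 2, 18), 2), matrix(c(0, 5, 7, 1), 2))
  for (tab in tabs) {
    expect_equal(fisher_exact_2x2(tab)$p,
                 stats::fisher.test(tab)$p.value, tolerance = 1e-9)
  }
  # equal loss fraction per opportunity: OR 1, p 1
  res <- m5_enrichment_test(losses = c(4, 2), opportunity = c(8, 4))
  expect_equal(res$odds_ratio, 1)
  expect_equal(res$p, 1)
  # doubling all counts makes the evidence stronger
  p1 <- m5_enrichment_test(c(8, 1), c(10, 10))$p
  p2 <- m5_enrichment_test(c(16, 2), c(20, 20))$p
  expect_lt(p2, p1)
})

test_that("burden and genome size follow the linkage-group rules", {
  base <- data.frame(basic_id = 1:5, extended_id = as.character(1:5),
                     type = c("gain", "loss", "gain", "loss", "gain"),
                     chrom = "chr1", start = (1:5) * 1e6,
                     end = (1:5) * 1e6 + c(1e6, 3e6, 1e6, 1e6, 2e6), step = 1,
                     carriers = "s1", clade_groups = "c1", states = "3",
                     origin_node = "N1", linkage_group = c(1, 2, 3, 4, 5),
                     m5_component = NA, post_wgd = c(FALSE, FALSE, FALSE, TRUE, TRUE),
                     parent_extended = NA, subclonal = FALSE)
  b <- burden_and_genome_size(base, "s1", haploid_size = 2625758988)
  expect_equal(b$burden, 3 + 2 * 0.5)
  # no events at all: exactly twice the callable haploid size
  b0 <- burden_and_genome_size(base[0, ], "s1")
  expect_equal(b0$genome_size, 5251517976)
  # one 1-Mb gain and one 3-Mb loss: net -2 Mb
  b2 <- burden_and_genome_size(base[1:2, ], "s1", haploid_size = 1e9)
  expect_equal(b2$genome_size, 2e9 + 1e6 - 3e6)
  # burden invariant to splitting an event with identical carriers
  split_ev <- rbind(base[1, ], base[1, ])
  split_ev$end[1] <- 1.5e6
  split_ev$start[2] <- 1.5e6
  split_ev <- link_events(split_ev)
  expect_equal(burden_and_genome_size(split_ev, "s1")$burden, 1)
})

test_that("rate_regression recovers slopes and clade interactions", {
  df <- data.frame(sample = sprintf("s%d", 1:10), burden = 2 * (2010:2019) - 4000,
                   date = 2010:2019, clade = "A",
                   genome_size = 5e9 + (2010:2019) * 1e6)
  fit <- rate_regression(df)
  expect_equal(unname(coef(fit$fit_burden)[2]), 2, tolerance = 1e-8)
  expect_equal(unname(coef(fit$fit_size)[2]), 1e6, tolerance = 1e-3)
  df0 <- df; df0$burden <- 0
  expect_equal(unname(coef(rate_regression(df0)$fit_burden)[2]), 0)
  # clades with slopes 5 and 10 and noise: interaction detected
  detected <- mean(vapply(1:10, function(s) {
    withr::with_seed(s, {
      n <- 50
      d <- data.frame(sample = sprintf("t%d", 1:(2 * n)),
                      date = rep(seq(2005, 2015, length.out = n), 2),
                      clade = rep(c("A", "B"), each = n))
      d$burden <- ifelse(d$clade == "A", 5, 10) * (d$date - 2005) +
        rnorm(2 * n, 0, 2)
    })
    rate_regression(d)$interaction_p < 0.01
  }, TRUE))
  expect_gte(detected, 0.95)
  # year-only dates are imputed reproducibly
  dfy <- df; dfy$date <- NA; dfy$year <- 2010:2019
  expect_identical(rate_regression(dfy, seed = 3)$data$date,
                   rate_regression(dfy, seed = 3)$data$date)
  expect_error(rate_regression(df[c(1, 1, 1), ]), "distinct")
})

test_that("coinfection classification follows the private/public rule", {
  G <- rbind(d1t1 = c(1, 0, 0, 1), d1t2 = c(1, 0, 0, 1),  # identical
             d2t1 = c(1, 1, 0, 0), d2t2 = c(1, 0, 0, 0),  # differ at private v2
             d3t1 = c(0, 0, 1, 0), d3t2 = c(0, 0, 0, 1))  # differ at public v4
  colnames(G) <- paste0("v", 1:4)
  devil_map <- stats::setNames(c("d1", "d1", "d2", "d2", "d3", "d3"),
                               rownames(G))
  res <- coinfection_classify(G, devil_map)
  expect_equal(res$label[res$devil == "d1"], "single_infection")
  expect_equal(res$sublabel[res$devil == "d1"], "identical")
  expect_equal(res$label[res$devil == "d2"], "single_infection")
  expect_equal(res$sublabel[res$devil == "d2"], "polymorphic_private")
  expect_equal(res$label[res$devil == "d3"], "coinfection")
  # different clade groups force coinfection
  clade <- stats::setNames(c("A", "A", "A", "B", "A", "A"), rownames(G))
  res2 <- coinfection_classify(G, devil_map, clade_map = clade)
  expect_equal(res2$label[res2$devil == "d2"], "coinfection")
})
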