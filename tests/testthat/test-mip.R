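test_that("expected_variant_reads is total x purity / 2", {
  expect_equal(expected_variant_reads(100, 0.8), 40)
  expect_equal(expected_variant_reads(378, 1), 189)
  expect_equal(expected_variant_reads(0, 0.5), 0)
})

test_that("contamination thresholds come from the absent-site quantile", {
  rt <- data.frame(sample = rep(c("a", "b"), each = 5),
                   probe = rep(sprintf("p%d", 1:5), 2),
                   total_reads = 400,
                   variant_reads = c(0, 0, 1, 2, 8, 0, 0, 0, 0, 0))
  thr <- estimate_contamination_threshold(
    rt, known_absent = list(a = sprintf("p%d", 1:5), b = sprintf("p%d", 1:5)))
  expect_equal(unname(thr["a"]), 8) # 0.95 quantile (inverse ECDF) of {0,0,1,2,8}
  expect_equal(unname(thr["b"]), 3) # all-zero absent sites floor at 3
  thr2 <- estimate_contamination_threshold(rt, known_absent = list(a = "p1"))
  expect_true("b" %in% attr(thr2, "fallback"))
  # simulated 2% contamination at depth 400 lands in the expected band
  tr <- simulate_clone_tree(4, 2, 2)
  pm <- stats::setNames(rep(0.9, 4), tr$tips)
  thr_sim <- vapply(1:5, function(s) {
    mip <- render_mip_reads(tr, 300, 400, pm, contamination_rate = 0.02,
                            seed = s)
    pres <- attr(mip, "truth_presence")
    absent <- colnames(pres)[!pres[tr$tips[1], ]]
    unname(estimate_contamination_threshold(
      mip, stats::setNames(list(absent), tr$tips[1]))[tr$tips[1]])
  }, 0)
  expect_true(all(thr_sim >= 8 & thr_sim <= 16)) # ~Binom(400, .02) upper tail
})

test_that("call_genotype implements the three-tier decision tree", {
  # E = 12 (total 48 at purity 0.5): full tier
  expect_equal(call_genotype(1, 48, 0.5, 4), "absent")
  expect_equal(call_genotype(3, 48, 0.5, 4), "N")
  expect_equal(call_genotype(5, 48, 0.5, 4), "present")
  expect_equal(call_genotype(4, 48, 0.5, 4), "N") # not strictly > threshold
  # 5 <= E < 10: present or N, never absent
  expect_equal(call_genotype(0, 16, 1, 4), "N")
  expect_equal(call_genotype(5, 16, 1, 4), "present")
  # E < 5: always N
  expect_equal(call_genotype(8, 8, 1, 4), "N")
  # exhaustive small grid: monotone in variant_reads, boundaries exact
  for (total in c(8, 12, 24, 48)) {
    for (thr in c(3, 5)) {
      calls <- call_genotype(0:total, total, 1, thr)
      rank <- c(absent = 1, N = 2, present = 3)[calls]
      expect_true(all(diff(rank) >= 0),
                  info = sprintf("total %d thr %d", total, thr))
      E <- total * 0.5
      if (E >= 10) {
        expect_true(all(calls[0:2 + 1] == "absent"))
        if (thr > 2) expect_true(all(calls[3:thr + 1] == "N"))
        expect_true(all(calls[(thr + 1):total + 1] == "present"))
      } else if (E >= 5) {
        expect_true(all(calls[0:thr + 1] == "N"))
        expect_true(all(calls[(thr + 1):total + 1] == "present"))
      } else {
        expect_true(all(calls == "N"))
      }
    }
  }
})

test_that("simulated genotype error rate is below 1% at panel depth", {
  tr <- simulate_clone_tree(10, 2, 6)
  withr::with_seed(6, pm <- stats::setNames(runif(10, 0.3, 1), tr$tips))
  mip <- render_mip_reads(tr, 1000, 378, pm, contamination_rate = 0.01,
                          seed = 11)
  pres <- attr(mip, "truth_presence")
  # hundreds of lineage-absent variants are known per tumour in a cohort of
  # this kind; the empirical threshold needs that many to bound the
  # contaminant tail (false-present rate ~ 1 / (n_absent + 1))
  known_absent <- lapply(tr$tips, function(s) {
    ab <- colnames(pres)[!pres[s, ]]
    ab[seq_len(min(200, length(ab)))]
  })
  names(known_absent) <- tr$tips
  # near-max quantile: at 378x the contaminant Binomial(378, 0.01) upper tail
  # still holds ~4% above its 0.95 quantile, so an empirical threshold must
  # sit at the top of the absent-site distribution (as the per-tumour
  # thresholds in this kind of panel do)
  thr <- estimate_contamination_threshold(mip, known_absent, quantile = 0.999)
  G <- genotype_matrix(mip, pm, thr)
  truth <- ifelse(pres[rownames(G), colnames(G)], "present", "absent")
  called <- G != "N"
  flips <- sum(G[called] != truth[called])
  expect_gt(sum(called), 4000) # most absent sites carry 3+ contaminant reads -> N
  expect_lt(flips / sum(called), 0.01)
})

test_that("filter_matrix applies normals, variant-N, then sample-N filters", {
  G <- rbind(s1 = c("present", "N", "present", "absent"),
             s2 = c("absent", "N", "present", "absent"),
             s3 = c("N", "N", "N", "N"))
  colnames(G) <- paste0("v", 1:4)
  normals <- rbind(h1 = c("absent", "absent", "present", "absent"))
  colnames(normals) <- colnames(G)
  out <- filter_matrix(G, normals)
  expect_false("v3" %in% colnames(out)) # present in a normal
  expect_false("v2" %in% colnames(out)) # N in 100% of samples
  expect_false("s3" %in% rownames(out)) # N across remaining variants
  expect_setequal(colnames(out), c("v1", "v4"))
  expect_setequal(rownames(out), c("s1", "s2"))
})

test_that("probe_rebalance computes factors and removals", {
  med <- c(p1 = 250, p2 = 1000, p3 = 10^1.6 * 1000, p4 = 0)
  out <- probe_rebalance(med, overall_median = 1000)
  expect_equal(unname(out$factor["p1"]), 2) # sqrt(1000 / 250)
  expect_equal(unname(out$factor["p2"]), 1)
  expect_setequal(out$remove, c("p3", "p4")) # >1.5 log10-fold and zero coverage
  out2 <- probe_rebalance(med[1:2], 1000, offtarget_ratio = c(p1 = 0.6, p2 = 0.1))
  expect_true("p1" %in% out2$remove)
})

test_that("expected_vaf and best_fit_genotype round trip", {
  expect_equal(expected_vaf(1, 2, p = 1), 0.5)
  expect_equal(expected_vaf(2, 2, p = 0), 0)
  expect_equal(expected_vaf(2, 2, p = 0.5), 0.5)
  g <- best_fit_genotype(2, 0.5, p = 1)
  expect_equal(c(g$ref, g$alt), c(1, 1))
  g0 <- best_fit_genotype(2, 0, p = 1)
  expect_equal(c(g0$ref, g0$alt), c(2, 0))
  # total 3, VAF 0.66: closest grid point is 1.0|2.0
  g3 <- best_fit_genotype(3, 0.66, p = 1)
  expect_equal(c(g3$ref, g3$alt), c(1, 2))
  # exhaustive oracle over the 7 candidates
  cand <- seq(0, 3, by = 0.5)
  resid <- abs(cand / 3 - 0.66)
  expect_equal(g3$alt, cand[which.min(resid)])
  # round trip over all grids with total CN <= 6
  for (p in c(0.3, 0.6, 1)) {
    for (total in c(1, 2, 3, 4, 6)) {
      for (alt in seq(0, total, by = 0.5)) {
        v <- expected_vaf(alt, total, p)
        fit <- best_fit_genotype(total, v, p)
        expect_equal(fit$alt, alt,
                     info = sprintf("p %.1f total %d alt %.1f", p, total, alt))
      }
    }
  }
})
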