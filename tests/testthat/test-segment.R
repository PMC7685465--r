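test_that("pcf_segment finds obvious structure", {
  g <- tiny_genome()
  x <- rep(0, nrow(g$bins))
  segs <- pcf_segment(x + rnorm(length(x), 0, 1e-4), genome = g,
                      normalize_gamma = FALSE, gamma = 1, kmin = 3)
  expect_equal(nrow(segs), length(g$chrom)) # one segment per chromosome
  # noise-free two-level step: exactly one breakpoint at the true step
  g2 <- genome_layout("chr1", 1e7) # 100 bins
  withr::with_seed(1, y <- c(rep(0, 50), rep(1, 50)) + rnorm(100, 0, 0.01))
  s2 <- pcf_segment(y, genome = g2, gamma = 40 * 0.01^2,
                    normalize_gamma = FALSE, kmin = 3)
  expect_equal(nrow(s2), 2)
  expect_equal(s2$start[2], 50 * 1e5)
  # exhaustive oracle: the chosen breakpoint beats all single-step options
  obj <- vapply(3:97, function(b)
    pcf_objective(y, c(1, b + 1), 40 * 0.01^2), 0)
  expect_equal(which.min(obj) + 2, 50)
})

test_that("pcf DP equals brute-force optimum on small instances", {
  withr::with_seed(42, {
    for (rep in 1:40) {
      n <- sample(4:13, 1)
      x <- rnorm(n)
      gamma <- runif(1, 0.1, 3)
      kmin <- sample(1:2, 1)
      starts <- skimclone:::pcf_core(x, gamma, kmin)
      expect_equal(pcf_objective(x, starts, gamma),
                   brute_pcf_objective(x, gamma, kmin),
                   tolerance = 1e-10)
      expect_true(all(diff(c(starts, n + 1)) >= kmin))
    }
  })
})

test_that("multipcf reduces to pcf and shares breakpoints", {
  g <- genome_layout("chr1", 8e6) # 80 bins
  withr::with_seed(5, x <- c(rep(0, 40), rep(0.8, 40)) + rnorm(80, 0, 0.05))
  lr <- structure(list(logr = x, genome = g), class = "logr_profile")
  single <- multipcf_segment(list(s1 = lr), gamma = 40, kmin = 5)
  alone <- pcf_segment(lr, gamma = 40, kmin = 5, sample = "s1")
  expect_equal(single$start, alone$start)
  expect_equal(single$end, alone$end)
  # two samples sharing a true step: one shared breakpoint at the step
  withr::with_seed(6, x2 <- c(rep(0, 40), rep(0.8, 40)) + rnorm(80, 0, 0.05))
  lr2 <- structure(list(logr = x2, genome = g), class = "logr_profile")
  joint <- multipcf_segment(list(s1 = lr, s2 = lr2), gamma = 40, kmin = 5)
  expect_equal(unique(joint$start[joint$start > 0]), 4e6)
  # joint objective equals brute force on a tiny instance
  withr::with_seed(7, X <- matrix(rnorm(20), 10, 2))
  starts <- skimclone:::multipcf_core(X, gamma = 0.5, kmin = 1)
  obj <- function(st) {
    ends <- c(st[-1] - 1, nrow(X))
    sum(vapply(seq_along(st), function(k)
      sum(apply(X[st[k]:ends[k], , drop = FALSE], 2,
                function(v) sum((v - mean(v))^2))), 0)) +
      0.5 * ncol(X) * (length(st) - 1)
  }
  # enumerate all 2^9 breakpoint subsets
  best <- Inf
  for (mask in 0:(2^9 - 1)) {
    st <- c(1, which(bitwAnd(bitwShiftR(mask, 0:8), 1) == 1) + 1)
    best <- min(best, obj(st))
  }
  expect_equal(obj(starts), best, tolerance = 1e-10)
})

test_that("merge_within_sample keeps multipcf boundaries at >95% overlap", {
  g <- genome_layout("chr1", 2e7) # 200 bins
  withr::with_seed(8, x <- c(rep(0, 96), rep(1, 104)) + rnorm(200, 0, 0.03))
  lr <- structure(list(logr = x, genome = g), class = "logr_profile")
  pcf <- data.frame(sample = "s", chrom = "chr1", start = c(0, 1e7),
                    end = c(1e7, 2e7), n_bins = c(100, 100),
                    mean_logr = c(mean(x[1:100]), mean(x[101:200])),
                    provenance = "pcf", cn_state = NA, subclonal = FALSE)
  multi <- pcf
  multi$start <- c(0, 9.6e6) # 96% reciprocal overlap with the pcf segment
  multi$end <- c(9.6e6, 2e7)
  multi$mean_logr <- c(mean(x[1:96]), mean(x[97:200]))
  multi$provenance <- "multipcf"
  merged <- merge_within_sample(pcf, multi, lr, rho = 1, alpha = 1e-9)
  expect_equal(merged$start, c(0, 9.6e6)) # multipcf boundary retained
  # identical segmentations pass through unchanged
  same <- merge_within_sample(pcf, pcf, lr, rho = 1, alpha = 1e-12)
  expect_equal(same$start, pcf$start)
  expect_equal(same$end, pcf$end)
})

test_that("adjacent same-distribution segments merge at the stated rate", {
  g <- genome_layout("chr1", 1e7) # 100 bins
  merged_frac <- mean(vapply(1:60, function(s) {
    withr::with_seed(s, x <- rnorm(100, 0, 0.1))
    lr <- structure(list(logr = x, genome = g), class = "logr_profile")
    fake <- data.frame(sample = "s", chrom = "chr1", start = c(0, 5e6),
                       end = c(5e6, 1e7), n_bins = 50,
                       mean_logr = c(mean(x[1:50]), mean(x[51:100])),
                       provenance = "pcf", cn_state = NA, subclonal = FALSE)
    out <- merge_within_sample(fake, fake, lr, rho = 1, alpha = 0.05)
    nrow(out) == 1
  }, TRUE))
  expect_gte(merged_frac, 0.9)
})

test_that("harmonize_across_samples consolidates and filters", {
  seg <- function(sample, start, end, state, chrom = "chr1")
    data.frame(sample = sample, chrom = chrom, start = start, end = end,
               n_bins = (end - start) / 1e5, mean_logr = log2(state / 2),
               provenance = "merged", cn_state = state, subclonal = FALSE)
  # 97.8% overlap, offsets <= 300 kb: consolidated to median boundaries
  s1 <- rbind(seg("a", 0, 1e6, 2), seg("a", 1e6, 10e6, 1), seg("a", 10e6, 12e6, 2))
  s2 <- rbind(seg("b", 0, 1.2e6, 2), seg("b", 1.2e6, 10.3e6, 1),
              seg("b", 10.3e6, 12e6, 2))
  out <- harmonize_across_samples(rbind(s1, s2))
  a_loss <- out[out$sample == "a" & out$cn_state == 1, ]
  b_loss <- out[out$sample == "b" & out$cn_state == 1, ]
  expect_equal(a_loss$start, 1e6) # lower median of {1.0, 1.2}
  expect_equal(b_loss$start, 1e6)
  expect_equal(a_loss$end, 10e6)
  expect_equal(b_loss$end, 10e6)
  # tiling preserved per sample
  for (smp in c("a", "b")) {
    ss <- out[out$sample == smp, ]
    expect_equal(ss$start[-1], ss$end[-nrow(ss)])
  }
  # boundary offset 600 kb: not consolidated
  s3 <- rbind(seg("c", 0, 1e6, 2), seg("c", 1e6, 10e6, 1), seg("c", 10e6, 12e6, 2))
  s4 <- rbind(seg("d", 0, 1.6e6, 2), seg("d", 1.6e6, 10.1e6, 1),
              seg("d", 10.1e6, 12e6, 2))
  out2 <- harmonize_across_samples(rbind(s3, s4))
  expect_equal(out2[out2$sample == "d" & out2$cn_state == 1, "start"], 1.6e6)
  # 400-kb segment removed and absorbed
  s5 <- rbind(seg("e", 0, 5e6, 2), seg("e", 5e6, 5.4e6, 3), seg("e", 5.4e6, 12e6, 2))
  out3 <- harmonize_across_samples(s5)
  expect_false(any(out3$cn_state == 3))
  expect_equal(sum(out3$end - out3$start), 12e6)
  # order invariance of consolidation
  out_rev <- harmonize_across_samples(rbind(s2, s1))
  or1 <- out[order(out$sample, out$start), c("sample", "start", "end")]
  or2 <- out_rev[order(out_rev$sample, out_rev$start), c("sample", "start", "end")]
  expect_equal(or1, or2, ignore_attr = TRUE)
})
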