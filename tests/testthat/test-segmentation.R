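test_that("outlier smoothing shrinks singletons and lowers MAD", {
  mm <- one_chr_map(5)
  flat <- rep(0.1, 5)
  expect_identical(smooth_outliers(flat, mm, sd_estimate = 0.5), flat)
  x <- c(0, 0, 5, 0, 0)
  sm <- smooth_outliers(x, mm, sd_estimate = 0.5)
  expect_equal(sm[3], 0 + 2 * 0.5)          # shrunk to 2 SD above neighbour
  expect_identical(sm[-3], x[-3])
  # fewer than 3 markers: unchanged
  mm2 <- one_chr_map(2)
  expect_identical(smooth_outliers(c(0, 9), mm2, sd_estimate = 0.1), c(0, 9))
  # simulated noisy profile with spikes: smoothing never increases MAD
  set.seed(42)
  mm3 <- one_chr_map(200)
  prof <- rnorm(200, 0, 0.2)
  spikes <- sample(2:199, 10)
  prof[spikes] <- prof[spikes] + 3
  sm3 <- smooth_outliers(prof, mm3)
  expect_lte(compute_mad(sm3)$mad, compute_mad(prof)$mad)
})

test_that("CBS recovers exact change points and partitions the chromosome", {
  mm <- one_chr_map(100)
  # constant vector: one segment
  seg <- cbs_segment(rep(0.3, 100), mm, n_perm = 200, seed = 1)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$seg_mean, 0.3)
  expect_equal(seg$n_markers, 100L)
  # noiseless step: exactly two segments, boundary between markers 50/51
  x <- c(rep(0, 50), rep(1, 50))
  seg2 <- cbs_segment(x, mm, n_perm = 500, seed = 2)
  expect_equal(nrow(seg2), 2L)
  expect_equal(seg2$seg_mean, c(0, 1))
  expect_equal(seg2$end_pos[1], mm$position[50])
  expect_equal(seg2$start_pos[2], mm$position[51])
  # three-level noiseless profile: generating partition recovered exactly
  y <- c(rep(0, 30), rep(1, 40), rep(-0.5, 30))
  seg3 <- cbs_segment(y, mm, n_perm = 500, seed = 3)
  expect_equal(nrow(seg3), 3L)
  expect_equal(seg3$seg_mean, c(0, 1, -0.5))
  # partition property: spans disjoint and exhaustive
  expect_equal(sum(seg3$n_markers), 100L)
  # seg_mean equals the mean of member markers
  for (r in seq_len(nrow(seg3))) {
    sel <- mm$position >= seg3$start_pos[r] & mm$position <= seg3$end_pos[r]
    expect_equal(seg3$seg_mean[r], mean(y[sel]))
  }
  # non-finite input rejected
  expect_error(cbs_segment(c(NA, rep(0, 99)), mm), "finite")
})

test_that("merge_levels collapses indistinguishable levels only", {
  mm <- one_chr_map(100)
  set.seed(7)
  # two adjacent segments with identical distributions: merged
  x <- rnorm(100, 0, 0.1)
  segs <- data.frame(sample_id = "S1", chromosome = "chr1",
                     start_pos = c(10, 510), end_pos = c(500, 1000),
                     n_markers = c(50L, 50L), seg_mean = c(mean(x[1:50]),
                                                           mean(x[51:100])),
                     stringsAsFactors = FALSE)
  m <- merge_levels(segs, x, mm)
  expect_equal(nrow(m), 1L)
  expect_equal(m$seg_mean, mean(x))
  expect_equal(m$n_markers, 100L)
  # well-separated levels are not merged
  y <- c(rnorm(50, 0, 0.1), rnorm(50, 1, 0.1))
  segs$seg_mean <- c(mean(y[1:50]), mean(y[51:100]))
  m2 <- merge_levels(segs, y, mm)
  expect_equal(nrow(m2), 2L)
  # single segment: unchanged
  one <- segs[1, ]
  expect_identical(merge_levels(one, x, mm), one)
})

test_that("MAD is the unscaled median absolute deviation", {
  expect_equal(compute_mad(rep(2, 10))$mad, 0)
  # hand computation: median 0.2; |dev| {0.4,0.2,0,0.2,0.4}; median 0.2
  expect_equal(compute_mad(c(-0.2, 0, 0.2, 0.4, 0.6))$mad, 0.2)
  x <- rnorm(50)
  expect_equal(compute_mad(x)$mad, compute_mad(-x)$mad)
  expect_equal(compute_mad(x, scaled = TRUE)$mad, compute_mad(x)$mad * 1.4826)
  expect_error(compute_mad(c(NA_real_, NA_real_)), "finite")
})

test_that("CNV calls apply strict MAD thresholds over all five states", {
  seg <- function(m) data.frame(seg_mean = m)
  st <- function(m, mad = 0.2)
    call_cnv(seg(m), list(mad = mad))$state
  expect_equal(st(0), "NEUTRAL")
  expect_equal(st(0.15), "GAIN")       # 0.5*0.2 < 0.15 <= 1*0.2
  expect_equal(st(-0.25), "HOMDEL")    # below -1*0.2
  expect_equal(st(0.25), "AMP")
  expect_equal(st(-0.15), "LOSS")
  # strict boundaries: exactly at the threshold falls to the lower state
  expect_equal(st(0.1), "NEUTRAL")     # == 0.5*mad
  expect_equal(st(0.2), "GAIN")        # == 1*mad
  expect_equal(st(-0.1), "NEUTRAL")
  expect_equal(st(-0.2), "LOSS")
  # monotone in seg_mean for fixed mad
  rank <- c(HOMDEL = 1, LOSS = 2, NEUTRAL = 3, GAIN = 4, AMP = 5)
  states <- st(seq(-0.5, 0.5, by = 0.01))
  expect_true(all(diff(rank[states]) >= 0))
  # mad = 0 degenerates with a warning
  expect_warning(call_cnv(seg(0.01), list(mad = 0)), "zero")
})

test_that("gene-centric table averages covered markers and flags empties", {
  mm <- one_chr_map(10)
  lr <- matrix(seq(0.1, 1, by = 0.1), 10, 1,
               dimnames = list(mm$marker_id, "S1"))
  genes <- data.frame(gene = c("a", "b", "c", "d"),
                      chromosome = c("chr1", "chr1", "chr1", "chr9"),
                      start = c(20, 50, 105, 10), end = c(40, 50, 108, 50),
                      stringsAsFactors = FALSE)
  gc <- gene_centric_table(lr, mm, genes)
  expect_equal(gc["a", "S1"], mean(c(0.2, 0.3, 0.4)))
  expect_equal(gc["b", "S1"], 0.5)          # single marker
  expect_true(is.na(gc["c", "S1"]))         # covers no marker
  expect_true(is.na(gc["d", "S1"]))         # chromosome absent from map
  # single-marker gene equals direct lookup (oracle equivalence)
  expect_identical(gc["b", "S1"], lr[5, "S1"])
})

test_that("frequency profile counts gain/loss fractions per marker", {
  mm <- one_chr_map(10)
  calls <- data.frame(
    sample_id = c("S1", "S2", "S3", "S4"),
    chromosome = "chr1", start_pos = 10, end_pos = 100,
    n_markers = 10L, seg_mean = 0, state = "NEUTRAL",
    stringsAsFactors = FALSE)
  f0 <- frequency_profile(calls, mm)
  expect_true(all(f0$gain_freq == 0) && all(f0$loss_freq == 0))
  calls$state[1] <- "GAIN"
  calls$start_pos[1] <- 30; calls$end_pos[1] <- 60
  f1 <- frequency_profile(calls, mm)
  expect_equal(f1$gain_freq[3:6], rep(0.25, 4))
  expect_equal(f1$gain_freq[c(1, 2, 7:10)], rep(0, 6))
  expect_true(all(f1$gain_freq + f1$loss_freq <= 1))
})
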