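test_that("the minimum-SNP criterion reproduces the 55-SNP threshold", {
  r <- min_roh_snps(0.35, 410973, 2123, 0.05)
  expect_equal(r$L, 55L)
  expect_equal(round(r$expected_count, 2), 0.04)
  # minimality: one SNP fewer exceeds the tolerated expectation
  expect_gte((1 - 0.35)^(r$L - 1) * 410973 * 2123, 0.05)

  expect_equal(min_roh_snps(0.5, 1, 1, 0.05)$L, 5L)   # 0.5^5 = 0.03125
  expect_error(min_roh_snps(0, 10, 10), "\\(0, 1\\)")
  expect_error(min_roh_snps(1, 10, 10), "\\(0, 1\\)")
})

test_that("adjust_min_snps scales by the tag-group reduction", {
  expect_equal(adjust_min_snps(55, 410973, 310000), 73L)
  expect_equal(adjust_min_snps(55, 1000, 1000), 55L)
  expect_equal(adjust_min_snps(55, 1000, 500), 110L)
  expect_error(adjust_min_snps(55, 100, 0), "positive")
  expect_error(adjust_min_snps(55, 100, 200), "exceed")
})

test_that("ld_tag_groups handles the degenerate extremes", {
  set.seed(2)
  # mutually independent random columns: r2 ~ 0 at n = 200 -> m groups
  calls <- matrix(stats::rbinom(200 * 8, 2, 0.5), 200, 8)
  gm <- toy_gm(calls, pos = seq_len(8) * 1e4)
  expect_equal(ld_tag_groups(gm, 0.8, 250)$n_groups, 8L)

  # duplicated column within the window joins its twin
  calls2 <- cbind(calls, calls[, 1])
  gm2 <- toy_gm(calls2, pos = c(seq_len(8) * 1e4, 9e4 + 10))
  r <- ld_tag_groups(gm2, 0.8, 250)
  expect_equal(r$n_groups, 8L)
  expect_equal(r$groups[9], r$groups[1])

  # a duplicate beyond the window founds its own group
  gm3 <- toy_gm(calls2, pos = c(seq_len(8) * 1e4, 9e4 + 260 * 1000))
  expect_equal(ld_tag_groups(gm3, 0.8, 250)$n_groups, 9L)

  expect_error(ld_tag_groups(gm, 0.8, 0), "positive")
})

test_that("ld_tag_groups matches the exhaustive pairwise oracle", {
  set.seed(12)
  for (i in 1:10) {
    n <- 60; m <- 10
    base <- matrix(stats::rbinom(n * m, 2, 0.4), n, m)
    # copy some columns with noise to create LD blocks
    for (j in sample(2:m, 4)) {
      src <- sample(j - 1, 1)
      flip <- stats::runif(n) < 0.05
      base[, j] <- ifelse(flip, stats::rbinom(n, 2, 0.4), base[, src])
    }
    gm <- toy_gm(base, pos = sort(sample.int(5e5, m)))
    got <- ld_tag_groups(gm, 0.8, 250)
    want <- oracle_tag_groups(gm, 0.8, 250)
    expect_equal(got$groups, want$groups)
    expect_equal(got$n_groups, want$n_groups)
  }
})

# 200 SNPs spaced 20 kb; homozygous block at SNPs `block`, het elsewhere
block_gm <- function(block, m = 200, spacing = 2e4) {
  x <- rep(1L, m)
  x[block] <- 2L
  toy_gm(matrix(x, 1), pos = seq_len(m) * spacing, status = "case")
}

test_that("the windowed scan finds exactly the planted block", {
  gm <- block_gm(50:149)
  seg <- call_rohs(gm)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$start_bp, 50 * 2e4)
  expect_equal(seg$end_bp, 149 * 2e4)
  expect_equal(seg$n_snps, 100L)
  expect_equal(seg$length_kb, 1980)

  # 60-SNP block (1,180 kb) fails min_snps = 75
  expect_equal(nrow(call_rohs(block_gm(50:109))), 0L)
  # all-heterozygous individual: nothing
  expect_equal(nrow(call_rohs(block_gm(integer(0)))), 0L)
  # chromosome shorter than the window: no segments, no error
  expect_equal(nrow(call_rohs(block_gm(1:30, m = 40))), 0L)
})

test_that("threshold sharpness at +/- 1 SNP and +/- 1 kb", {
  # exactly 75 SNPs spanning >= 1000 kb (74 gaps x 14 kb = 1036 kb): emitted
  expect_equal(nrow(call_rohs(block_gm(50:124, spacing = 14000))), 1L)
  # 74 SNPs: dropped
  expect_equal(nrow(call_rohs(block_gm(50:123, spacing = 14000))), 0L)
  # 100 SNPs spanning 999 kb (99 x ~10.09 kb): fails min_kb
  expect_equal(nrow(call_rohs(block_gm(50:149, spacing = 999000 / 99))), 0L)
  # same geometry stretched to exactly 1000 kb: passes
  expect_equal(nrow(call_rohs(block_gm(50:149, spacing = 1000000 / 99))), 1L)
})

test_that("runs split at gaps above max_gap_kb", {
  pos <- seq_len(200) * 2e4
  pos[101:200] <- pos[101:200] + 1.1e6          # 1,120 kb gap at SNP 101
  x <- rep(1L, 200); x[21:180] <- 0L
  gm <- toy_gm(matrix(x, 1), pos = pos, status = "case")
  seg <- call_rohs(gm)
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$n_snps, c(80L, 80L))
})

test_that("caller equals the brute-force oracle on planted cohorts", {
  pars <- roh_params()
  set.seed(91)
  for (rep in 1:8) {
    n <- 10; m <- 400
    pos <- sort(sample.int(8e6, m))
    calls <- matrix(ifelse(stats::runif(n * m) < 0.6, 1L, 2L), n, m)
    for (s in 1:n) for (k in seq_len(sample(0:2, 1))) {
      a <- sample.int(m - 150, 1)
      calls[s, a:(a + sample(60:140, 1))] <- sample(c(0L, 2L), 1)
    }
    gm <- toy_gm(calls, pos = pos)
    got <- call_rohs(gm, pars)
    want <- oracle_rohs(gm, pars)
    expect_equal(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_equal(got$start_bp, want$start_bp)
      expect_equal(got$end_bp, want$end_bp)
      expect_equal(got$n_snps, want$n_snps)
    }
  }
})

test_that("output is invariant to sample order", {
  set.seed(17)
  fx <- make_fixture("clean_roh", seed = 17)
  seg <- call_rohs(fx$gm)
  perm <- sample(nrow(fx$gm$calls))
  seg_p <- call_rohs(subset_gm(fx$gm, samples = perm))
  o1 <- seg[order(seg$sample_id, seg$chrom, seg$start_bp), ]
  o2 <- seg_p[order(seg_p$sample_id, seg_p$chrom, seg_p$start_bp), ]
  rownames(o1) <- rownames(o2) <- NULL
  expect_equal(o1, o2)
})

test_that("missing calls obey the window allowance and do not count as SNPs", {
  # 100-SNP block with 3 missing inside: still one run, n_snps = 97
  x <- rep(1L, 200); x[50:149] <- 0L
  x[c(70, 90, 110)] <- NA
  gm <- toy_gm(matrix(x, 1), pos = seq_len(200) * 2e4, status = "case")
  seg <- call_rohs(gm)
  expect_equal(nrow(seg), 1L)
  expect_equal(seg$n_snps, 97L)

  # blanket missingness above window_miss_max kills all windows
  x2 <- rep(1L, 200); x2[50:149] <- 0L
  x2[seq(50, 149, by = 5)] <- NA                 # 10 missing per 50-SNP window
  gm2 <- toy_gm(matrix(x2, 1), pos = seq_len(200) * 2e4, status = "case")
  expect_equal(nrow(call_rohs(gm2)), 0L)
})
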