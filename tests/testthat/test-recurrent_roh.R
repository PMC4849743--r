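# a cohort whose chromosome 1 holds 100 markers every 10 kb from 1,000 kb
dense_gm <- function(n = 20) {
  set.seed(1)
  pos <- seq(1e6, by = 1e4, length.out = 100)
  calls <- matrix(stats::rbinom(n * 100, 2, 0.4), n, 100)
  toy_gm(calls, pos = pos, status = rep(c("case", "control"), each = n / 2))
}

test_that("overlapping segments pool into a recurrent consensus region", {
  gm <- dense_gm()
  # 7 individuals share a 600 kb core [1,200; 1,800] kb with >= 75 markers:
  # place segments so that the intersection spans 990 kb (100 markers)
  ids <- gm$samples$id[1:7]
  segs <- seg_df(ids, 1,
                 start_bp = c(rep(9.0e5, 3), rep(9.5e5, 4)),
                 end_bp = c(rep(2.1e6, 4), rep(2.2e6, 3)),
                 status = gm$samples$status[1:7])
  pools <- pool_rohs(segs, gm)
  expect_equal(nrow(pools), 1L)
  expect_equal(pools$n_carriers, 7L)
  expect_equal(pools$consensus_start_bp, 9.5e5)
  expect_equal(pools$consensus_end_bp, 2.1e6)
  expect_equal(pools$n_snps, 100L)
  expect_equal(pools$n_case_carriers + pools$n_control_carriers, 7L)

  # one individual with two overlapping segments counts once
  segs2 <- rbind(segs, seg_df(ids[1], 1, 9.2e5, 2.15e6))
  expect_equal(pool_rohs(segs2, gm)$n_carriers, 7L)
})

test_that("pools failing any recurrence filter are dropped", {
  gm <- dense_gm()
  ids <- gm$samples$id
  # 6 segments whose common intersection is only 400 kb
  short <- seg_df(ids[1:6], 1,
                  start_bp = c(rep(1.0e6, 3), rep(1.4e6, 3)),
                  end_bp = c(rep(1.8e6, 3), rep(2.2e6, 3)))
  expect_equal(nrow(pool_rohs(short, gm)), 0L)

  # only 5 carriers (> 5 required)
  five <- seg_df(ids[1:5], 1, rep(1e6, 5), rep(1.99e6, 5))
  expect_equal(nrow(pool_rohs(five, gm)), 0L)
  expect_equal(nrow(pool_rohs(five, gm, min_members = 5)), 1L)

  # wide enough but too few markers inside the consensus
  gm_sparse <- toy_gm(matrix(stats::rbinom(20 * 10, 2, 0.4), 20, 10),
                      pos = seq(1e6, by = 1e5, length.out = 10),
                      status = rep(c("case", "control"), each = 10))
  wide <- seg_df(gm_sparse$samples$id[1:6], 1, rep(1e6, 6), rep(1.9e6, 6))
  expect_equal(nrow(pool_rohs(wide, gm_sparse)), 0L)

  # non-overlapping segments: clusters of one, none recurrent
  solo <- seg_df(ids[1:3], 1, c(1e6, 3e6, 5e6), c(1.5e6, 3.5e6, 5.5e6))
  expect_equal(nrow(pool_rohs(solo, gm)), 0L)
  expect_equal(nrow(pool_rohs(segs_empty <- solo[0, ], gm)), 0L)
})

test_that("consensus equals the brute-force intersection on random clusters", {
  gm <- dense_gm()
  set.seed(6)
  for (i in 1:10) {
    k <- sample(6:10, 1)
    start <- 9e5 + stats::runif(k, 0, 2e5)
    end <- 1.9e6 + stats::runif(k, 0, 3e5)
    segs <- seg_df(gm$samples$id[1:k], 1, start, end,
                   status = gm$samples$status[1:k])
    pools <- pool_rohs(segs, gm, min_consensus_kb = 1, min_consensus_snps = 1)
    expect_equal(nrow(pools), 1L)
    expect_equal(pools$consensus_start_bp, max(start))
    expect_equal(pools$consensus_end_bp, min(end))
    # pool membership is invariant to input order
    perm <- sample(k)
    pools2 <- pool_rohs(segs[perm, ], gm, min_consensus_kb = 1,
                        min_consensus_snps = 1)
    expect_equal(sort(unlist(pools2$members)), sort(unlist(pools$members)))
  }
})

test_that("carrier_chi2 reproduces printed carrier statistics", {
  expect_equal(trunc_digits(carrier_chi2(7, 1, 906, 1217)$chi2), 6.59)
  expect_equal(trunc_digits(carrier_chi2(7, 2, 906, 1217)$chi2), 4.55)
  expect_equal(trunc_digits(carrier_chi2(0, 5, 906, 1217)$chi2), 3.73)
  # equal carrier proportions -> 0
  expect_equal(carrier_chi2(10, 10, 100, 100)$chi2, 0)
  # zero total carriers -> degenerate
  r <- carrier_chi2(0, 0, 100, 100)
  expect_true(r$degenerate)
  expect_equal(r$chi2, 0)
  expect_error(carrier_chi2(50, 0, 20, 100), "n_cases")
})

test_that("the carrier permutation p agrees with the analytic tail", {
  r <- carrier_chi2(7, 1, 906, 1217, n_perm = 2000, seed = 3)
  expect_true(r$p_perm > 0 && r$p_perm < 0.1)
  expect_lt(abs(r$p_perm - r$p), 0.03)
  # same seed reproduces
  expect_equal(carrier_chi2(7, 1, 906, 1217, n_perm = 500, seed = 9)$p_perm,
               carrier_chi2(7, 1, 906, 1217, n_perm = 500, seed = 9)$p_perm)
})

test_that("the consensus homozygosity t-test follows the carrier direction", {
  gm <- dense_gm()
  pool <- data.frame(chrom = 1, consensus_start_bp = 1e6,
                     consensus_end_bp = 1.99e6,
                     n_case_carriers = 7, n_control_carriers = 1)
  # identical genotype columns for cases and controls -> t = 0, p = 0.5
  n <- nrow(gm$calls)
  gm_eq <- gm
  gm_eq$calls[(n / 2 + 1):n, ] <- gm_eq$calls[1:(n / 2), ]
  r <- homozygosity_proportion_test(pool, gm_eq)
  expect_equal(r$t, 0)
  expect_equal(r$p, 0.5)

  # cases ~90% homozygous per SNP, controls ~60% (both with spread)
  set.seed(13)
  pc <- rep(c(0.85, 0.95), length.out = 100)
  pk <- rep(c(0.55, 0.65), length.out = 100)
  calls <- rbind(
    sapply(pc, function(q) ifelse(stats::runif(10) < q, 2L, 1L)),
    sapply(pk, function(q) ifelse(stats::runif(10) < q, 2L, 1L)))
  gm2 <- toy_gm(calls, pos = seq(1e6, by = 1e4, length.out = 100),
                status = rep(c("case", "control"), each = 10))
  r2 <- homozygosity_proportion_test(pool, gm2)
  expect_lt(r2$p, 0.05)
  expect_equal(r2$direction, "cases>controls")

  # swapping group labels maps p -> 1 - p under the same direction
  gm_sw <- gm2
  gm_sw$samples$status <- rev(gm2$samples$status)
  r3 <- homozygosity_proportion_test(pool, gm_sw)
  expect_equal(r3$p, 1 - r2$p, tolerance = 1e-10)

  # fewer than 2 markers -> flagged undefined
  tiny <- data.frame(chrom = 1, consensus_start_bp = 1e6,
                     consensus_end_bp = 1.0005e6,
                     n_case_carriers = 2, n_control_carriers = 0)
  expect_true(homozygosity_proportion_test(tiny, gm)$degenerate)
})

test_that("recurrent_roh_tests collates a full table and BED export works", {
  gm <- dense_gm()
  segs <- seg_df(gm$samples$id[c(1:4, 11:13)], 1, rep(9.5e5, 7),
                 rep(2.1e6, 7), status = gm$samples$status[c(1:4, 11:13)])
  pools <- pool_rohs(segs, gm)
  tab <- recurrent_roh_tests(pools, gm, n_perm = 200, seed = 4)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$n_case_carriers, 4L)
  expect_equal(tab$n_control_carriers, 3L)
  expect_true(all(c("chi2", "p", "p_perm", "p_t") %in% names(tab)))

  d <- withr::local_tempdir()
  write_pools_bed(pools, file.path(d, "p.bed"))
  bed <- utils::read.table(file.path(d, "p.bed"))
  expect_equal(bed$V2, pools$consensus_start_bp - 1)   # 0-based half-open
  expect_equal(bed$V3, pools$consensus_end_bp)
})
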