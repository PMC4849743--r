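#' Parameters of the windowed ROH scan
#'
#' Defaults follow the standard sliding-window homozygosity scan
#' configuration with the heterozygote allowance set to zero (no
#' heterozygous SNP permitted in any scanning window), a minimum run of 75
#' SNPs (the LD-adjusted equivalent of 55 independent homozygous calls, see
#' [adjust_min_snps()]) and a minimum run length of 1,000 kb.
#'
#' @param window_snps scanning-window size in SNPs.
#' @param window_het_max maximum heterozygous calls per homozygous window.
#' @param window_miss_max maximum missing calls per homozygous window.
#' @param snp_window_frac minimum fraction of homozygous windows covering a
#'   SNP for the SNP to be eligible.
#' @param min_snps minimum genotyped SNPs per emitted run.
#' @param min_kb minimum run length in kb.
#' @param max_gap_kb runs are split where adjacent SNPs are further apart.
#' @param min_density_kb_per_snp runs sparser than this (kb per SNP) are
#'   discarded.
#' @return a `roh_params` list.
#' @export
roh_params <- function(window_snps = 50, window_het_max = 0,
                       window_miss_max = 5, snp_window_frac = 0.05,
                       min_snps = 75, min_kb = 1000, max_gap_kb = 1000,
                       min_density_kb_per_snp = 50) {
  stopifnot(window_snps >= 1, window_het_max >= 0, window_miss_max >= 0,
            snp_window_frac > 0, min_snps >= 1, min_kb > 0, max_gap_kb > 0,
            min_density_kb_per_snp > 0)
  structure(list(window_snps = as.integer(window_snps),
                 window_het_max = window_het_max,
                 window_miss_max = window_miss_max,
                 snp_window_frac = snp_window_frac,
                 min_snps = as.integer(min_snps), min_kb = min_kb,
                 max_gap_kb = max_gap_kb,
                 min_density_kb_per_snp = min_density_kb_per_snp),
            class = "roh_params")
}

#' Minimum run length in SNPs to keep chance runs rare
#'
#' Returns the smallest integer L such that the expected number of purely
#' chance runs of L consecutive homozygous calls across the whole data set,
#' (1 - mean_het)^L * n_snps * n_individuals, falls below `max_expected`.
#' With mean heterozygosity 0.35, 410,973 SNPs and 2,123 individuals the
#' criterion gives L = 55 with about 0.04 expected chance runs.
#'
#' @param mean_het mean per-SNP heterozygosity, in (0, 1).
#' @param n_snps,n_individuals data-set dimensions.
#' @param max_expected tolerated expected count of chance runs.
#' @return list with `L` (integer) and `expected_count` at L.
#' @export
min_roh_snps <- function(mean_het, n_snps, n_individuals,
                         max_expected = 0.05) {
  if (mean_het <= 0 || mean_het >= 1) stop("mean_het must be in (0, 1)")
  stopifnot(max_expected > 0, n_snps >= 1, n_individuals >= 1)
  base <- n_snps * n_individuals
  L <- max(1L, ceiling(log(max_expected / base) / log(1 - mean_het)))
  while ((1 - mean_het)^L * base >= max_expected) L <- L + 1L
  while (L > 1 && (1 - mean_het)^(L - 1) * base < max_expected) L <- L - 1L
  list(L = as.integer(L), expected_count = (1 - mean_het)^L * base)
}

#' Greedy LD tag grouping
#'
#' Scans markers left to right within each chromosome.  A SNP joins the
#' group of the nearest previous tag (group founder) within `window_kb`
#' whose genotype-vector squared correlation (composite r2 over pairwise
#' non-missing samples) exceeds `r2_threshold`; otherwise it founds a new
#' group.  The group count estimates the number of separable, effectively
#' independent markers.
#'
#' @param gm a [genotype_matrix()].
#' @param r2_threshold strict lower bound on r2 for joining, default 0.8.
#' @param window_kb tag search window in kb, default 250.
#' @return list with `n_groups` and integer vector `groups` (one entry per
#'   marker).
#' @export
ld_tag_groups <- function(gm, r2_threshold = 0.8, window_kb = 250) {
  if (window_kb <= 0) stop("window_kb must be positive")
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  m <- ncol(gm$calls)
  groups <- integer(m)
  next_id <- 0L
  win_bp <- window_kb * 1000
  for (chr in unique(gm$markers$chrom)) {
    idx <- which(gm$markers$chrom == chr)
    pos <- gm$markers$pos_bp[idx]
    tags <- integer(0)                       # marker indices of founders
    tag_grp <- integer(0)
    for (k in seq_along(idx)) {
      j <- idx[k]
      cand <- which(pos[k] - gm$markers$pos_bp[tags] <= win_bp)
      assigned <- FALSE
      if (length(cand)) {
        # nearest previous tag first
        cand <- cand[order(pos[k] - gm$markers$pos_bp[tags[cand]])]
        for (t in cand) {
          r <- suppressWarnings(
            stats::cor(gm$calls[, j], gm$calls[, tags[t]],
                       use = "pairwise.complete.obs"))
          if (!is.na(r) && r^2 > r2_threshold) {
            groups[j] <- tag_grp[t]
            assigned <- TRUE
            break
          }
        }
      }
      if (!assigned) {
        next_id <- next_id + 1L
        groups[j] <- next_id
        tags <- c(tags, j)
        tag_grp <- c(tag_grp, next_id)
      }
    }
  }
  list(n_groups = next_id, groups = groups)
}

#' LD-adjust the minimum SNP count of a run
#'
#' Inflates the independent-call criterion L by the ratio of total markers
#' to separable tag groups: `L_adj = ceiling(L * n_snps / n_groups)`.  With
#' L = 55, 410,973 SNPs and about 310,000 tag groups this gives 73; the
#' pipeline default of [roh_params()] nevertheless stays at the adopted 75.
#'
#' @param L independent-call minimum from [min_roh_snps()].
#' @param n_snps total marker count.
#' @param n_groups tag-group count from [ld_tag_groups()].
#' @return integer `L_adj`.
#' @export
adjust_min_snps <- function(L, n_snps, n_groups) {
  if (n_groups <= 0) stop("n_groups must be positive")
  if (n_groups > n_snps) stop("n_groups cannot exceed n_snps")
  as.integer(ceiling(L * n_snps / n_groups))
}

#' Call runs of homozygosity with a windowed scan
#'
#' Per individual and chromosome: (1) every window of `window_snps`
#' consecutive SNPs is labelled homozygous iff it holds at most
#' `window_het_max` heterozygous and `window_miss_max` missing calls;
#' (2) a SNP is eligible iff the fraction of homozygous windows among all
#' windows containing it is at least `snp_window_frac`, or it lies in at
#' least one homozygous window (a boundary SNP of a true run is covered by
#' only a single fully homozygous window, so the bare fraction threshold
#' would otherwise shave the outermost SNPs off every run and exact segment
#' boundaries would be lost); (3) maximal runs of
#' consecutive eligible SNPs are split where adjacent SNPs are more than
#' `max_gap_kb` apart; (4) runs failing `min_snps` (genotyped SNPs),
#' `min_kb`, or the density bound are discarded.  Run bounds are the
#' positions of the first and last SNP; `length_kb = (end - start) / 1000`.
#'
#' @param gm a [genotype_matrix()].
#' @param params a [roh_params()].
#' @return data frame of segments: `sample_id`, `status`, `chrom`,
#'   `start_bp`, `end_bp`, `snp1`, `snp2` (marker ids), `n_snps`,
#'   `length_kb`, `density_kb_per_snp`.
#' @export
call_rohs <- function(gm, params = roh_params()) {
  stopifnot(inherits(params, "roh_params"))
  W <- params$window_snps
  out <- list()
  chroms <- unique(gm$markers$chrom)
  for (chr in chroms) {
    idx <- which(gm$markers$chrom == chr)
    m <- length(idx)
    if (m < W) next                      # too few SNPs to form a window
    pos <- gm$markers$pos_bp[idx]
    ids <- gm$markers$id[idx]
    gap_break <- c(FALSE, diff(pos) > params$max_gap_kb * 1000)
    nW <- m - W + 1L
    i_all <- seq_len(m)
    hi <- pmin(i_all, nW)
    lo <- pmax(i_all - W + 1L, 1L)
    n_win <- hi - lo + 1L
    for (s in seq_len(nrow(gm$calls))) {
      x <- gm$calls[s, idx]
      het <- as.integer(!is.na(x) & x == 1L)
      mis <- as.integer(is.na(x))
      csh <- cumsum(het); csm <- cumsum(mis)
      wh <- csh[W:m] - c(0, csh)[1:nW]
      wm <- csm[W:m] - c(0, csm)[1:nW]
      winhom <- as.integer(wh <= params$window_het_max &
                             wm <= params$window_miss_max)
      cw <- c(0, cumsum(winhom))
      hits <- cw[hi + 1L] - cw[lo]
      # one fully qualifying window always suffices: without this clause the
      # fraction threshold would shave the outermost SNPs off every true run
      elig <- hits >= 1L | hits / n_win >= params$snp_window_frac
      # maximal eligible runs, split at large gaps
      r <- rle(elig)
      starts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
      for (k in which(r$values)) {
        a <- starts[k]; b <- a + r$lengths[k] - 1L
        cuts <- which(gap_break[a:b][-1])      # breaks inside the run
        seg_start <- c(a, a + cuts)
        seg_end <- c(a + cuts - 1L, b)
        for (q in seq_along(seg_start)) {
          i0 <- seg_start[q]; i1 <- seg_end[q]
          n_geno <- sum(!is.na(gm$calls[s, idx[i0:i1]]))
          len_kb <- (pos[i1] - pos[i0]) / 1000
          if (n_geno < params$min_snps) next
          if (len_kb < params$min_kb) next
          if (len_kb / n_geno > params$min_density_kb_per_snp) next
          out[[length(out) + 1]] <- data.frame(
            sample_id = gm$samples$id[s], status = gm$samples$status[s],
            chrom = chr, start_bp = pos[i0], end_bp = pos[i1],
            snp1 = ids[i0], snp2 = ids[i1], n_snps = n_geno,
            length_kb = len_kb,
            density_kb_per_snp = len_kb / n_geno,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(), status = character(),
                      chrom = numeric(), start_bp = numeric(),
                      end_bp = numeric(), snp1 = character(),
                      snp2 = character(), n_snps = integer(),
                      length_kb = numeric(), density_kb_per_snp = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$sample_id, res$chrom, res$start_bp), , drop = FALSE]
}

#' Write ROH segments in a .hom-style TSV
#'
#' @param segments output of [call_rohs()].
#' @param path file path.
#' @export
write_roh_table <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
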