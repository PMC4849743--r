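# Independent oracles and small fixture builders shared across test files.

# Build a genotype_matrix from an explicit call matrix (rows = samples).
toy_gm <- function(calls, pos = NULL, chrom = NULL, status = NULL,
                   sex = NULL) {
  calls <- as.matrix(calls)
  n <- nrow(calls); m <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * 1000
  if (is.null(chrom)) chrom <- rep(1, m)
  if (is.null(status)) status <- rep(c("case", "control"), length.out = n)
  if (is.null(sex)) sex <- rep("unknown", n)
  genotype_matrix(
    calls,
    data.frame(id = sprintf("m%03d", seq_len(m)), chrom = chrom,
               pos_bp = pos, allele_a = "A", allele_b = "B",
               stringsAsFactors = FALSE),
    data.frame(id = sprintf("s%03d", seq_len(n)), sex = sex,
               status = status, stringsAsFactors = FALSE))
}

# 2x2 chi-square oracle via stats::chisq.test without continuity correction.
oracle_chi2 <- function(a, b, c, d) {
  suppressWarnings(
    stats::chisq.test(matrix(c(a, b, c, d), 2, byrow = TRUE),
                      correct = FALSE)$statistic)
}

# Brute-force ROH oracle for zero-missingness data with no heterozygote
# allowance: maximal runs of homozygous calls, split at large gaps, then
# the length/count/density filters.  Valid when min_snps >= window_snps.
oracle_rohs <- function(gm, params) {
  out <- list()
  for (chr in unique(gm$markers$chrom)) {
    idx <- which(gm$markers$chrom == chr)
    pos <- gm$markers$pos_bp[idx]
    for (s in seq_len(nrow(gm$calls))) {
      x <- gm$calls[s, idx]
      hom <- !is.na(x) & x != 1L
      brk <- c(FALSE, diff(pos) > params$max_gap_kb * 1000)
      grp <- cumsum((!hom) | brk)
      for (g in unique(grp[hom])) {
        ii <- which(grp == g & hom)
        if (!length(ii)) next
        n_snp <- length(ii)
        len_kb <- (pos[max(ii)] - pos[min(ii)]) / 1000
        if (n_snp < params$min_snps || len_kb < params$min_kb ||
            len_kb / n_snp > params$min_density_kb_per_snp) next
        out[[length(out) + 1]] <- data.frame(
          sample_id = gm$samples$id[s], chrom = chr,
          start_bp = pos[min(ii)], end_bp = pos[max(ii)], n_snps = n_snp)
      }
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(), chrom = numeric(),
                      start_bp = numeric(), end_bp = numeric(),
                      n_snps = integer()))
  res <- do.call(rbind, out)
  res[order(res$sample_id, res$chrom, res$start_bp), , drop = FALSE]
}

# Exhaustive-pairwise greedy LD grouping oracle (independent loop shape).
oracle_tag_groups <- function(gm, r2, window_kb) {
  m <- ncol(gm$calls)
  R2 <- suppressWarnings(stats::cor(gm$calls,
                                    use = "pairwise.complete.obs"))^2
  grp <- integer(m); founders <- integer(0); nid <- 0L
  for (j in seq_len(m)) {
    hit <- 0L
    cand <- founders[gm$markers$chrom[founders] == gm$markers$chrom[j] &
                       gm$markers$pos_bp[j] - gm$markers$pos_bp[founders] <=
                       window_kb * 1000]
    for (t in cand[order(gm$markers$pos_bp[j] - gm$markers$pos_bp[cand])]) {
      if (!is.na(R2[j, t]) && R2[j, t] > r2) { hit <- grp[t]; break }
    }
    if (hit == 0L) { nid <- nid + 1L; grp[j] <- nid; founders <- c(founders, j) }
    else grp[j] <- hit
  }
  list(n_groups = nid, groups = grp)
}

# Segment table builder for recurrent/burden tests.
seg_df <- function(sample_id, chrom, start_bp, end_bp, status = "case") {
  k <- length(sample_id)
  data.frame(sample_id = sample_id, status = rep_len(status, k),
             chrom = rep_len(chrom, k), start_bp = start_bp,
             end_bp = end_bp, snp1 = rep(NA_character_, k),
             snp2 = rep(NA_character_, k), n_snps = rep(NA_integer_, k),
             length_kb = (end_bp - start_bp) / 1000,
             density_kb_per_snp = rep(NA_real_, k),
             stringsAsFactors = FALSE)
}
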