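#' SNP-wise genomic inbreeding estimators
#'
#' Three per-individual genomic inbreeding coefficients computed from the
#' genotype dosage x (copies of allele b) and the sample allele frequency
#' p at each marker, with h = 2 p (1 - p):
#' \describe{
#'   \item{F1}{variance of additive genetic values:
#'     ((x - 2p)^2) / h - 1.}
#'   \item{F2}{excess SNP homozygosity: 1 - x (2 - x) / h.}
#'   \item{F3}{correlation of uniting gametes:
#'     (x^2 - (1 + 2p) x + 2 p^2) / h.}
#' }
#' Per-SNP terms are averaged over the individual's non-missing markers
#' with 0 < p < 1 ("mean of ratios", the per-SNP normalisation of the
#' classical estimators); `method = "ratio_of_sums"` instead divides summed
#' numerators by summed h.  Estimates may be negative on finite data.
#'
#' @param gm a [genotype_matrix()].
#' @param method `"mean_of_ratios"` (default) or `"ratio_of_sums"`.
#' @return data frame with `id`, `status`, `f1`, `f2`, `f3`, `n_snps`
#'   (markers contributing per sample).
#' @export
fhat_estimators <- function(gm, method = c("mean_of_ratios", "ratio_of_sums")) {
  method <- match.arg(method)
  p <- gm$markers$freq_b
  elig <- !is.na(p) & p > 0 & p < 1
  if (!any(elig)) stop("no markers with 0 < freq_b < 1")
  n_skip <- sum(!elig)
  if (n_skip) message(sprintf("fhat_estimators: skipping %d monomorphic/undefined marker(s)", n_skip))
  x <- gm$calls[, elig, drop = FALSE]
  p <- p[elig]
  h <- 2 * p * (1 - p)
  ok <- !is.na(x)
  xs <- x; xs[!ok] <- 0L                       # contributes 0, masked below
  n_i <- rowSums(ok)
  if (any(n_i == 0)) warning("sample(s) with zero eligible genotypes; estimates NA")

  t1 <- sweep(xs, 2, 2 * p)^2                  # (x - 2p)^2, wrong where !ok
  t2 <- xs * (2 - xs)                          # x (2 - x)
  t3 <- xs^2 - sweep(xs, 2, 1 + 2 * p, `*`) +
    matrix(2 * p^2, nrow(x), length(p), byrow = TRUE)
  t1[!ok] <- 0; t2[!ok] <- 0; t3[!ok] <- 0

  if (method == "mean_of_ratios") {
    hinv <- 1 / h
    f1 <- (t1 %*% hinv) / n_i - 1
    f2 <- 1 - (t2 %*% hinv) / n_i
    f3 <- (t3 %*% hinv) / n_i
  } else {
    hsum <- ok %*% h
    f1 <- rowSums(t1) / hsum - 1
    f2 <- 1 - rowSums(t2) / hsum
    f3 <- rowSums(t3) / hsum
  }
  f1 <- as.numeric(f1); f2 <- as.numeric(f2); f3 <- as.numeric(f3)
  f1[n_i == 0] <- f2[n_i == 0] <- f3[n_i == 0] <- NA_real_
  data.frame(id = gm$samples$id, status = gm$samples$status,
             f1 = f1, f2 = f2, f3 = f3, n_snps = n_i,
             stringsAsFactors = FALSE)
}

#' Segment-based inbreeding coefficient F_ROH
#'
#' F_ROH = sum of per-individual ROH lengths (bp, segments at or above
#' `min_kb`) divided by the mappable autosomal genome length L_AUTO
#' (default 2,676,172,944 bp via [genome_layout()]).
#'
#' @param segments data frame from [call_rohs()].
#' @param samples cohort `samples` data frame (all ids appear in output).
#' @param layout a [genome_layout()].
#' @param min_kb length criterion in kb, default 1000.
#' @return data frame with `id`, `status`, `f_roh`.
#' @export
f_roh <- function(segments, samples, layout = genome_layout(),
                  min_kb = 1000) {
  stopifnot(layout$total_autosomal_bp > 0)
  if (nrow(segments)) {
    lens <- layout$chrom_lengths_bp
    bad <- segments$chrom > length(lens) |
      segments$end_bp > lens[segments$chrom]
    if (any(bad))
      stop(sprintf("%d segment(s) extend beyond their chromosome bounds",
                   sum(bad)))
  }
  keep <- segments[segments$length_kb >= min_kb, , drop = FALSE]
  tot_bp <- rowsum(c(keep$end_bp - keep$start_bp, rep(0, nrow(samples))),
                   factor(c(keep$sample_id, samples$id),
                          levels = samples$id))
  data.frame(id = samples$id, status = samples$status,
             f_roh = as.numeric(tot_bp[samples$id, 1]) /
               layout$total_autosomal_bp,
             stringsAsFactors = FALSE)
}

#' Per-chromosome inbreeding profile
#'
#' The F1 estimator of [fhat_estimators()] restricted to each chromosome.
#' Also reports the per-chromosome SD of F1 across samples and its
#' correlation with chromosome length in bp (with SNP density roughly
#' uniform, shorter chromosomes carry fewer markers, so their estimates are
#' noisier and the correlation is negative).
#'
#' @param gm a [genotype_matrix()].
#' @param layout a [genome_layout()] supplying chromosome lengths for the
#'   SD-length correlation.
#' @return list with `f1` (samples x chromosomes matrix), `n_snps`
#'   (matching matrix of contributing marker counts), `sd` (per-chromosome
#'   SD across samples), and `cor_sd_length` (Pearson r of SD with
#'   chromosome bp length; NA with < 3 chromosomes).
#' @export
per_chromosome_f <- function(gm, layout = genome_layout()) {
  chroms <- sort(unique(gm$markers$chrom))
  n <- nrow(gm$calls)
  f1 <- matrix(NA_real_, n, length(chroms),
               dimnames = list(gm$samples$id, chroms))
  cnt <- matrix(0L, n, length(chroms), dimnames = dimnames(f1))
  for (k in seq_along(chroms)) {
    sub <- subset_gm(gm, markers = gm$markers$chrom == chroms[k])
    # keep cohort-wide frequencies, not per-chromosome re-estimates
    sub$markers$freq_b <- gm$markers$freq_b[gm$markers$chrom == chroms[k]]
    p <- sub$markers$freq_b
    if (!any(!is.na(p) & p > 0 & p < 1)) next  # flagged undefined column
    est <- suppressMessages(fhat_estimators(sub))
    f1[, k] <- est$f1
    cnt[, k] <- est$n_snps
  }
  sds <- apply(f1, 2, stats::sd, na.rm = TRUE)
  cl <- layout$chrom_lengths_bp[chroms]
  cor_sd_length <- if (length(chroms) >= 3 && stats::sd(sds, na.rm = TRUE) > 0)
    stats::cor(sds, cl, use = "complete.obs") else NA_real_
  list(f1 = f1, n_snps = cnt, sd = sds, cor_sd_length = cor_sd_length)
}

#' Correlations among consanguinity measures
#'
#' Pearson correlations (with p-values) between the burden statistics
#' (`n_rohs`, `total_kb`) and the inbreeding coefficients (`f1`, `f2`,
#' `f3`, `f_roh`) across individuals.
#'
#' @param profiles data frame holding `id`, `f1`, `f2`, `f3` (from
#'   [fhat_estimators()]) and `f_roh` (merged from [f_roh()]).
#' @param burdens output of [summarize_burden()].
#' @return list of matrices `r` and `p` over the available measures.
#' @export
measure_correlations <- function(profiles, burdens) {
  df <- merge(profiles, burdens[c("id", "n_rohs", "total_kb")], by = "id")
  if (nrow(df) < 3) stop("need at least 3 samples")
  vars <- intersect(c("n_rohs", "total_kb", "f1", "f2", "f3", "f_roh"),
                    names(df))
  k <- length(vars)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(vars, vars))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) { r[i, j] <- 1; p[i, j] <- 0; next }
    ct <- stats::cor.test(df[[vars[i]]], df[[vars[j]]])
    r[i, j] <- unname(ct$estimate)
    p[i, j] <- ct$p.value
  }
  list(r = r, p = p)
}
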