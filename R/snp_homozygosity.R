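# Pearson chi-square for a 2x2 table, df = 1, no continuity correction.
# Closed form N (ad - bc)^2 / (R1 R2 C1 C2); degenerate margins give NA.
.chi2_2x2 <- function(a, b, c, d) {
  a <- as.numeric(a); b <- as.numeric(b)
  c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  ifelse(den > 0, n * (a * d - b * c)^2 / den, NA_real_)
}

#' SNP-by-SNP association between homozygosity and case status
#'
#' For each marker, a 2x2 Pearson chi-square (df = 1, no continuity
#' correction) of homozygous (for either allele) versus heterozygous calls
#' against case/control status.  Missing calls are excluded marker-wise.
#' Markers with a zero margin (e.g. no heterozygote at all) get `chi2 = NA`,
#' `p = 1` and `degenerate = TRUE`.
#'
#' @param gm a [genotype_matrix()].
#' @param q FDR level for [bh_fdr()] flags, default 0.05.
#' @return data frame with one row per marker: counts
#'   (`hom_cases`, `het_cases`, `hom_controls`, `het_controls`), `chi2`,
#'   `p`, `p_adj`, `fdr_reject`, `degenerate`.
#' @export
snp_homozygosity_chi2 <- function(gm, q = 0.05) {
  case <- gm$samples$status == "case"
  if (!any(case) || all(case)) stop("need at least one case and one control")
  x <- gm$calls
  hom <- !is.na(x) & x != 1L
  het <- !is.na(x) & x == 1L
  a <- colSums(hom[case, , drop = FALSE])   # hom cases
  b <- colSums(het[case, , drop = FALSE])   # het cases
  c_ <- colSums(hom[!case, , drop = FALSE])
  d <- colSums(het[!case, , drop = FALSE])
  chi2 <- .chi2_2x2(a, b, c_, d)
  degenerate <- is.na(chi2)
  p <- ifelse(degenerate, 1, stats::pchisq(chi2, df = 1, lower.tail = FALSE))
  fdr <- bh_fdr(p, q)
  data.frame(marker = gm$markers$id, chrom = gm$markers$chrom,
             pos_bp = gm$markers$pos_bp,
             hom_cases = a, het_cases = b, hom_controls = c_,
             het_controls = d, chi2 = chi2, p = p,
             p_adj = fdr$p_adj, fdr_reject = fdr$reject,
             degenerate = degenerate, row.names = NULL)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up procedure: with ordered p-values p(1) <= ... <= p(m), reject the
#' k smallest where k = max\{i : p(i) <= i q / m\}.  Adjusted values are
#' min over j >= i of m p(j) / j, capped at 1.
#'
#' @param pvalues numeric vector in [0, 1] (`NA` allowed; never rejected,
#'   adjusted value `NA`).
#' @param q target FDR level.
#' @return list with logical `reject` and numeric `p_adj`, input order.
#' @export
bh_fdr <- function(pvalues, q = 0.05) {
  m <- length(pvalues)
  if (m == 0) return(list(reject = logical(0), p_adj = numeric(0)))
  if (any(!is.na(pvalues) & (pvalues < 0 | pvalues > 1)))
    stop("p-values must lie in [0, 1]")
  ok <- which(!is.na(pvalues))
  reject <- rep(FALSE, m)
  p_adj <- rep(NA_real_, m)
  if (length(ok)) {
    p <- pvalues[ok]
    mm <- length(p)
    o <- order(p)
    ranked <- p[o]
    adj <- rev(cummin(rev(mm * ranked / seq_len(mm))))
    adj <- pmin(adj, 1)
    k <- which(ranked <= seq_len(mm) * q / mm)
    rej <- logical(mm)
    if (length(k)) rej[seq_len(max(k))] <- TRUE
    reject[ok[o]] <- rej
    p_adj[ok[o]] <- adj
  }
  list(reject = reject, p_adj = p_adj)
}
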