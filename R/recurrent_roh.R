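#' Pool overlapping ROH segments into recurrent consensus regions
#'
#' Segments on one chromosome are clustered by single-linkage interval
#' overlap (two segments link iff their bp spans intersect).  The consensus
#' region of a cluster is the intersection of all member spans.  A cluster
#' is a recurrent region iff it holds at least `min_members` distinct
#' individuals, its consensus spans at least `min_consensus_kb`, and the
#' consensus covers at least `min_consensus_snps` genotyped markers.
#'
#' @param segments data frame from [call_rohs()].
#' @param gm the [genotype_matrix()] the segments were called on (supplies
#'   marker positions and case/control status).
#' @param min_members minimum distinct carriers, default 6 ("more than
#'   five samples").
#' @param min_consensus_kb minimum consensus span, default 500.
#' @param min_consensus_snps minimum markers inside the consensus,
#'   default 75.
#' @return data frame of pools: `pool`, `chrom`, `consensus_start_bp`,
#'   `consensus_end_bp`, `consensus_kb`, `n_snps`, `n_carriers`,
#'   `n_case_carriers`, `n_control_carriers`, plus a list column `members`
#'   of carrier sample ids.
#' @export
pool_rohs <- function(segments, gm, min_members = 6, min_consensus_kb = 500,
                      min_consensus_snps = 75) {
  empty <- data.frame(pool = character(), chrom = numeric(),
                      consensus_start_bp = numeric(),
                      consensus_end_bp = numeric(), consensus_kb = numeric(),
                      n_snps = integer(), n_carriers = integer(),
                      n_case_carriers = integer(),
                      n_control_carriers = integer())
  empty$members <- list()
  if (!nrow(segments)) return(empty)
  status <- stats::setNames(gm$samples$status, gm$samples$id)
  pools <- list()
  for (chr in sort(unique(segments$chrom))) {
    seg <- segments[segments$chrom == chr, , drop = FALSE]
    seg <- seg[order(seg$start_bp, seg$end_bp), , drop = FALSE]
    # single-linkage overlap clustering by sorted sweep
    cl <- integer(nrow(seg))
    cur <- 1L; max_end <- seg$end_bp[1]; cl[1] <- 1L
    if (nrow(seg) > 1) for (i in 2:nrow(seg)) {
      if (seg$start_bp[i] > max_end) { cur <- cur + 1L; max_end <- seg$end_bp[i] }
      else max_end <- max(max_end, seg$end_bp[i])
      cl[i] <- cur
    }
    for (k in unique(cl)) {
      mem <- seg[cl == k, , drop = FALSE]
      cs <- max(mem$start_bp); ce <- min(mem$end_bp)
      ids <- unique(mem$sample_id)
      if (ce < cs) next                     # chained cluster, empty core
      n_snp <- sum(gm$markers$chrom == chr & gm$markers$pos_bp >= cs &
                     gm$markers$pos_bp <= ce)
      kb <- (ce - cs) / 1000
      if (length(ids) < min_members) next
      if (kb < min_consensus_kb) next
      if (n_snp < min_consensus_snps) next
      pools[[length(pools) + 1]] <- list(
        chrom = chr, consensus_start_bp = cs, consensus_end_bp = ce,
        consensus_kb = kb, n_snps = n_snp, members = ids,
        n_case_carriers = sum(status[ids] == "case"),
        n_control_carriers = sum(status[ids] == "control"))
    }
  }
  if (!length(pools)) return(empty)
  out <- data.frame(
    pool = sprintf("ROH%d", seq_along(pools)),
    chrom = vapply(pools, `[[`, numeric(1), "chrom"),
    consensus_start_bp = vapply(pools, `[[`, numeric(1), "consensus_start_bp"),
    consensus_end_bp = vapply(pools, `[[`, numeric(1), "consensus_end_bp"),
    consensus_kb = vapply(pools, `[[`, numeric(1), "consensus_kb"),
    n_snps = vapply(pools, function(p) as.integer(p$n_snps), integer(1)),
    n_carriers = vapply(pools, function(p) length(p$members), integer(1)),
    n_case_carriers = vapply(pools, function(p) as.integer(p$n_case_carriers), integer(1)),
    n_control_carriers = vapply(pools, function(p) as.integer(p$n_control_carriers), integer(1)),
    stringsAsFactors = FALSE)
  out$members <- lapply(pools, `[[`, "members")
  out
}

#' Case-control carrier test for a recurrent region
#'
#' Pearson chi-square (df = 1, no continuity correction) on the 2x2 table
#' carrier/non-carrier x case/control, with an optional label-permutation
#' p-value (the carrier total is held fixed and case labels permuted, i.e.
#' hypergeometric resampling of the table).
#'
#' @param n_case_carriers,n_control_carriers carrier counts.
#' @param n_cases,n_controls group sizes.
#' @param n_perm permutation count (0 = skip).
#' @param seed RNG seed for the permutation.
#' @return list with `chi2`, `p`, `degenerate`, and `p_perm` (NA if
#'   `n_perm = 0`).
#' @export
carrier_chi2 <- function(n_case_carriers, n_control_carriers,
                         n_cases, n_controls, n_perm = 0, seed = NULL) {
  stopifnot(n_case_carriers <= n_cases, n_control_carriers <= n_controls)
  a <- n_case_carriers; c_ <- n_control_carriers
  b <- n_cases - a; d <- n_controls - c_
  k <- a + c_
  if (k == 0 || k == n_cases + n_controls)
    return(list(chi2 = 0, p = 1, degenerate = TRUE, p_perm = NA_real_))
  chi2 <- .chi2_2x2(a, b, c_, d)
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  p_perm <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    a_star <- stats::rhyper(n_perm, m = n_cases, n = n_controls, k = k)
    chi2_star <- .chi2_2x2(a_star, n_cases - a_star, k - a_star,
                           n_controls - (k - a_star))
    p_perm <- (1 + sum(chi2_star >= chi2)) / (n_perm + 1)
  }
  list(chi2 = chi2, p = p, degenerate = FALSE, p_perm = p_perm)
}

#' One-tailed test of per-SNP homozygosity within a consensus region
#'
#' For every marker inside the pool's consensus span, the proportion of
#' homozygous genotypes is computed separately among all cases and all
#' controls; the two per-SNP proportion vectors are compared with a
#' one-tailed Welch t-test.  The alternative direction follows the carrier
#' excess of the pool: more case than control carriers tests
#' mu_cases > mu_controls, otherwise mu_cases < mu_controls.
#'
#' @param pool one row of the [pool_rohs()] output (data frame of 1 row).
#' @param gm the [genotype_matrix()].
#' @return list with `t`, `p`, `direction` (`"cases>controls"` or
#'   `"cases<controls"`), `n_snps`, and `degenerate` (fewer than 2 usable
#'   markers or zero variance).
#' @export
homozygosity_proportion_test <- function(pool, gm) {
  idx <- which(gm$markers$chrom == pool$chrom &
                 gm$markers$pos_bp >= pool$consensus_start_bp &
                 gm$markers$pos_bp <= pool$consensus_end_bp)
  if (length(idx) < 2)
    return(list(t = NA_real_, p = NA_real_, direction = NA_character_,
                n_snps = length(idx), degenerate = TRUE))
  case <- gm$samples$status == "case"
  hom <- !is.na(gm$calls) & gm$calls != 1L
  nonmis <- !is.na(gm$calls)
  prop <- function(rows) {
    colSums(hom[rows, idx, drop = FALSE]) /
      pmax(1L, colSums(nonmis[rows, idx, drop = FALSE]))
  }
  pc <- prop(case); pk <- prop(!case)
  more_cases <- pool$n_case_carriers >= pool$n_control_carriers
  alt <- if (more_cases) "greater" else "less"
  if (stats::var(pc) + stats::var(pk) == 0) {
    dn <- if (more_cases) "cases>controls" else "cases<controls"
    d <- mean(pc) - mean(pk)
    p <- if (d == 0) 0.5 else {
      hit <- (more_cases && d > 0) || (!more_cases && d < 0)
      if (hit) 0 else 1
    }
    return(list(t = if (d == 0) 0 else sign(d) * Inf, p = p,
                direction = dn, n_snps = length(idx), degenerate = TRUE))
  }
  tt <- stats::t.test(pc, pk, alternative = alt, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value,
       direction = if (more_cases) "cases>controls" else "cases<controls",
       n_snps = length(idx), degenerate = FALSE)
}

#' Full recurrent-ROH analysis table
#'
#' Runs [carrier_chi2()] and [homozygosity_proportion_test()] over every
#' pool and returns a Table-3-style summary.
#'
#' @param pools output of [pool_rohs()].
#' @param gm the [genotype_matrix()].
#' @param n_perm permutations for the carrier test (0 = skip).
#' @param seed RNG seed.
#' @return data frame with carrier counts, `chi2`, `p`, `p_perm`, `p_t`
#'   and `t_direction` per pool.
#' @export
recurrent_roh_tests <- function(pools, gm, n_perm = 0, seed = NULL) {
  n_cases <- sum(gm$samples$status == "case")
  n_controls <- sum(gm$samples$status == "control")
  rows <- lapply(seq_len(nrow(pools)), function(i) {
    p <- pools[i, , drop = FALSE]
    cc <- carrier_chi2(p$n_case_carriers, p$n_control_carriers,
                       n_cases, n_controls, n_perm = n_perm, seed = seed)
    ht <- homozygosity_proportion_test(p, gm)
    data.frame(pool = p$pool, chrom = p$chrom,
               consensus_start_bp = p$consensus_start_bp,
               consensus_end_bp = p$consensus_end_bp,
               consensus_kb = p$consensus_kb, n_snps = p$n_snps,
               n_case_carriers = p$n_case_carriers,
               n_control_carriers = p$n_control_carriers,
               chi2 = cc$chi2, p = cc$p, p_perm = cc$p_perm,
               p_t = ht$p, t_direction = ht$direction,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame())
  do.call(rbind, rows)
}

#' Export consensus regions as BED
#'
#' Converts the 1-based inclusive consensus spans to BED's 0-based
#' half-open convention (`start - 1`, `end`).
#'
#' @param pools output of [pool_rohs()].
#' @param path file path.
#' @export
write_pools_bed <- function(pools, path) {
  bed <- data.frame(paste0("chr", pools$chrom),
                    format(pools$consensus_start_bp - 1, scientific = FALSE, trim = TRUE),
                    format(pools$consensus_end_bp, scientific = FALSE, trim = TRUE),
                    pools$pool)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
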