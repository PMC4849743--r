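#' Per-individual ROH burden summaries
#'
#' Counts and lengths of ROH segments per individual.  Individuals without
#' any segment appear with `n_rohs = 0`, `total_kb = 0` and `mean_kb = NA`.
#'
#' @param segments data frame from [call_rohs()].
#' @param samples the `samples` data frame of the cohort (every id appears
#'   in the output, with its status and subgroup labels carried along).
#' @return data frame with `id`, `status`, subgroup columns, `n_rohs`,
#'   `total_kb`, `mean_kb`.
#' @export
summarize_burden <- function(segments, samples) {
  out <- samples
  out$n_rohs <- 0L
  out$total_kb <- 0
  if (nrow(segments)) {
    cnt <- table(factor(segments$sample_id, levels = samples$id))
    tot <- rowsum(c(segments$length_kb, rep(0, nrow(samples))),
                  factor(c(segments$sample_id, samples$id),
                         levels = samples$id))
    out$n_rohs <- as.integer(cnt[out$id])
    out$total_kb <- as.numeric(tot[out$id, 1])
  }
  out$mean_kb <- ifelse(out$n_rohs > 0, out$total_kb / out$n_rohs, NA_real_)
  out
}

#' Case-control comparison of a burden statistic
#'
#' Two-sample t-test (Welch by default; set `var_equal = TRUE` for the
#' classical pooled-variance test) of a burden statistic between cases and
#' controls, with an optional two-sided label-permutation p-value based on
#' the absolute group-mean difference.  A case subset (e.g. one histology)
#' can be compared against all controls via `case_subset`.
#'
#' @param burden output of [summarize_burden()].
#' @param stat one of `"n_rohs"`, `"total_kb"`, `"mean_kb"`.
#' @param var_equal pooled-variance t-test instead of Welch.
#' @param n_perm label permutations (0 = skip).
#' @param seed RNG seed for the permutation.
#' @param case_subset optional logical/integer index into the case rows
#'   selecting a subgroup of cases.
#' @return list with `mean_cases`, `mean_controls`, `t`, `p`, `perm_p`,
#'   `n_cases`, `n_controls`.
#' @export
group_burden_test <- function(burden, stat = c("n_rohs", "total_kb", "mean_kb"),
                              var_equal = FALSE, n_perm = 0, seed = NULL,
                              case_subset = NULL) {
  stat <- match.arg(stat)
  cases <- burden[burden$status == "case", , drop = FALSE]
  if (!is.null(case_subset)) cases <- cases[case_subset, , drop = FALSE]
  x <- cases[[stat]]
  y <- burden[[stat]][burden$status == "control"]
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) < 2 || length(y) < 2)
    return(list(mean_cases = mean(x), mean_controls = mean(y),
                t = NA_real_, p = NA_real_, perm_p = NA_real_,
                n_cases = length(x), n_controls = length(y),
                degenerate = TRUE))
  if (stats::var(x) + stats::var(y) == 0) {
    d <- mean(x) - mean(y)
    tt <- list(statistic = c(t = if (d == 0) 0 else sign(d) * Inf),
               p.value = if (d == 0) 1 else 0)
  } else
    tt <- stats::t.test(x, y, var.equal = var_equal)
  perm_p <- NA_real_
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    obs <- abs(mean(x) - mean(y))
    z <- c(x, y); nx <- length(x)
    hits <- 0L
    tot_sum <- sum(z)
    for (b in seq_len(n_perm)) {
      sx <- sum(z[sample.int(length(z), nx)])
      d <- abs(sx / nx - (tot_sum - sx) / (length(z) - nx))
      if (d >= obs - 1e-12) hits <- hits + 1L
    }
    perm_p <- (1 + hits) / (n_perm + 1)
  }
  list(mean_cases = mean(x), mean_controls = mean(y),
       t = unname(tt$statistic), p = tt$p.value, perm_p = perm_p,
       n_cases = length(x), n_controls = length(y), degenerate = FALSE)
}

#' Median split of a burden statistic
#'
#' Splits the cohort into the strictly-below-median and at-or-above-median
#' subsets of a statistic (e.g. mean ROH size per person), reporting the
#' cut value.
#'
#' @param burden output of [summarize_burden()].
#' @param by statistic column name, default `"mean_kb"`.
#' @return list with `cut` (the median), `lower`, `upper` (data frames),
#'   and `degenerate` (TRUE when the lower set is empty, e.g. all values
#'   equal).
#' @export
median_split <- function(burden, by = "mean_kb") {
  v <- burden[[by]]
  ok <- !is.na(v)
  med <- stats::median(v[ok])
  lower <- burden[ok & v < med, , drop = FALSE]
  upper <- burden[ok & v >= med, , drop = FALSE]
  list(cut = med, lower = lower, upper = upper,
       degenerate = nrow(lower) == 0)
}

#' Quantile-binned odds ratios for a burden statistic
#'
#' Control-sided quantiles of the statistic define `n_bins` classes of
#' (approximately) equal control size; ties go to the lower bin, so
#' realised counts can be unequal.  The lowest class is the reference
#' (OR = 1); every other class is compared with the reference in a 2x2
#' table: OR = (a d_ref)/(b c_ref) with the Woolf interval
#' exp(ln OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)), the uncorrected
#' chi-square p, and a logistic-regression p for the class indicator as a
#' side-by-side alternative.  Zero cells flag the row and a
#' Haldane-corrected OR (all cells + 0.5) is reported separately.
#'
#' @param burden output of [summarize_burden()].
#' @param stat statistic column name.
#' @param n_bins number of classes, default 4.
#' @return data frame with one row per class: `bin`, `range`, `n_cases`,
#'   `n_controls`, `odds_ratio`, `ci_lo`, `ci_hi`, `chi2`, `p_chi2`,
#'   `p_logistic`, `or_haldane`, `zero_cell`.
#' @export
binned_or <- function(burden, stat = "total_kb", n_bins = 4) {
  v <- burden[[stat]]
  ok <- !is.na(v)
  vv <- v[ok]
  status <- burden$status[ok]
  ctrl <- vv[status == "control"]
  if (length(unique(ctrl)) < n_bins)
    stop("need at least n_bins distinct control values")
  edges <- stats::quantile(ctrl, probs = seq_len(n_bins - 1) / n_bins,
                           names = FALSE)
  # ties at an edge fall into the lower bin
  bin <- 1L + vapply(vv, function(z) sum(z > edges), integer(1))
  a_ref <- sum(status == "case" & bin == 1L)
  b_ref <- sum(status == "control" & bin == 1L)
  lab <- function(k) {
    lo <- if (k == 1) -Inf else edges[k - 1]
    hi <- if (k == n_bins) Inf else edges[k]
    if (k == 1) sprintf("<%.1f", hi)
    else if (k == n_bins) sprintf(">%.1f", lo)
    else sprintf("%.1f-%.1f", lo, hi)
  }
  rows <- lapply(seq_len(n_bins), function(k) {
    a <- sum(status == "case" & bin == k)
    b <- sum(status == "control" & bin == k)
    if (k == 1L)
      return(data.frame(bin = k, range = lab(k), n_cases = a, n_controls = b,
                        odds_ratio = 1, ci_lo = NA_real_, ci_hi = NA_real_,
                        chi2 = NA_real_, p_chi2 = NA_real_,
                        p_logistic = NA_real_, or_haldane = NA_real_,
                        zero_cell = FALSE, stringsAsFactors = FALSE))
    zero <- any(c(a, b, a_ref, b_ref) == 0)
    or <- if (zero) NA_real_ else (a * b_ref) / (b * a_ref)
    se <- sqrt(1 / a + 1 / b + 1 / a_ref + 1 / b_ref)
    ci <- if (zero) c(NA_real_, NA_real_) else exp(log(or) + c(-1, 1) * 1.96 * se)
    orh <- ((a + 0.5) * (b_ref + 0.5)) / ((b + 0.5) * (a_ref + 0.5))
    chi2 <- .chi2_2x2(a, b, a_ref, b_ref)
    p_chi2 <- if (is.na(chi2)) NA_real_ else
      stats::pchisq(chi2, 1, lower.tail = FALSE)
    sel <- bin %in% c(1L, k)
    p_log <- tryCatch({
      fit <- stats::glm((status[sel] == "case") ~ I(bin[sel] == k),
                        family = stats::binomial())
      summary(fit)$coefficients[2, 4]
    }, error = function(e) NA_real_)
    data.frame(bin = k, range = lab(k), n_cases = a, n_controls = b,
               odds_ratio = or, ci_lo = ci[1], ci_hi = ci[2], chi2 = chi2,
               p_chi2 = p_chi2, p_logistic = p_log, or_haldane = orh,
               zero_cell = zero, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Odds ratio and Woolf interval from explicit 2x2 counts
#'
#' Convenience for recomputing a published class-versus-reference
#' comparison directly from printed counts.
#'
#' @param n_cases,n_controls counts in the class of interest.
#' @param n_cases_ref,n_controls_ref counts in the reference class.
#' @param conf z quantile level, default 0.95.
#' @return list with `odds_ratio`, `ci_lo`, `ci_hi`, `chi2`, `p`.
#' @export
or_2x2 <- function(n_cases, n_controls, n_cases_ref, n_controls_ref,
                   conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  or <- (n_cases * n_controls_ref) / (n_controls * n_cases_ref)
  se <- sqrt(1 / n_cases + 1 / n_controls + 1 / n_cases_ref +
               1 / n_controls_ref)
  chi2 <- .chi2_2x2(n_cases, n_controls, n_cases_ref, n_controls_ref)
  list(odds_ratio = or, ci_lo = exp(log(or) - z * se),
       ci_hi = exp(log(or) + z * se), chi2 = chi2,
       p = stats::pchisq(chi2, 1, lower.tail = FALSE))
}

#' Truncate (not round) to a number of decimals
#'
#' Report tables print statistics truncated toward zero, so a computed
#' 6.5955 prints as 6.59.
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return truncated numeric.
#' @export
trunc_digits <- function(x, digits = 2) trunc(x * 10^digits) / 10^digits
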