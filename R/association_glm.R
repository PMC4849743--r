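#' Ancestry principal components from genotypes
#'
#' Markers are standardised as (x - 2p) / sqrt(2 p (1 - p)) with missing
#' entries set to zero after centring; the top-k right singular directions
#' of the standardised matrix give the sample scores.  By default the
#' computation runs on one marker per LD tag group ([ld_tag_groups()]) to
#' avoid local-LD artefacts.  The sign of each component is fixed by making
#' its largest-magnitude marker loading positive.
#'
#' @param gm a [genotype_matrix()].
#' @param k number of components, default 10 (capped implicitly by the
#'   matrix rank).
#' @param prune compute on LD-pruned markers (tag SNPs only)?
#' @param r2_threshold,window_kb pruning parameters, see [ld_tag_groups()].
#' @return samples x k matrix of scores (columns `PC1`..`PCk`).
#' @export
genotype_pca <- function(gm, k = 10, prune = TRUE, r2_threshold = 0.8,
                         window_kb = 250) {
  n <- nrow(gm$calls)
  if (k >= n) stop("k must be smaller than the number of samples")
  use <- rep(TRUE, ncol(gm$calls))
  if (prune) {
    gr <- ld_tag_groups(gm, r2_threshold, window_kb)$groups
    use <- !duplicated(gr)
  }
  p <- gm$markers$freq_b
  use <- use & !is.na(p) & p > 0 & p < 1
  x <- gm$calls[, use, drop = FALSE]
  p <- p[use]
  z <- sweep(x, 2, 2 * p)
  z <- sweep(z, 2, sqrt(2 * p * (1 - p)), `/`)
  z[is.na(z)] <- 0
  sv <- svd(z, nu = k, nv = k)
  k_eff <- min(k, length(sv$d))
  flip <- vapply(seq_len(k_eff), function(j) {
    v <- sv$v[, j]
    if (v[which.max(abs(v))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(k_eff), drop = FALSE], 2,
                  sv$d[seq_len(k_eff)] * flip, `*`)
  dimnames(scores) <- list(gm$samples$id, paste0("PC", seq_len(k_eff)))
  scores
}

# Wald p-value of column `col` of design matrix X in a logistic fit.
# Returns c(estimate, se, p); NA p on separation / non-convergence.
.logistic_wald <- function(X, y, col) {
  fit <- suppressWarnings(stats::glm.fit(X, y, family = stats::binomial(),
                                         control = stats::glm.control(epsilon = 1e-8,
                                                                      maxit = 100)))
  rk <- fit$qr$rank
  if (rk < ncol(X)) return(c(NA_real_, NA_real_, NA_real_))
  sep <- any(fit$fitted.values > 1 - 1e-10) || any(fit$fitted.values < 1e-10)
  R <- qr.R(fit$qr)[seq_len(rk), seq_len(rk), drop = FALSE]
  cov <- chol2inv(R)
  piv <- fit$qr$pivot[seq_len(rk)]
  se <- sqrt(diag(cov))[match(col, piv)]
  est <- fit$coefficients[col]
  if (!fit$converged || sep || is.na(se))
    return(c(est, NA_real_, NA_real_))
  z <- est / se
  c(est, se, 2 * stats::pnorm(-abs(z)))
}

#' Logistic regression of disease status on an inbreeding measure
#'
#' Maximum-likelihood logistic fit of the binary status (case = 1,
#' control = 0) on the explanatory measure plus optional covariates (e.g.
#' sex, ancestry PCs, per-sample missingness), with a Wald z-test on the
#' measure's coefficient.  Perfect separation is flagged (`p = NA`);
#' collinear covariates raise an error naming the offending columns.
#'
#' @param status factor/character (`"case"`/`"control"`) or 0/1 numeric.
#' @param f_measure numeric explanatory variable (positive coefficients
#'   mean higher values in cases).
#' @param covariates optional data frame or matrix of covariates; rows with
#'   missing values are dropped complete-case with a message.
#' @param alternative `"two.sided"` (default), `"greater"` or `"less"`.
#' @return list of class `glm_result`: `estimate`, `se`, `z`, `wald_p`,
#'   `n`, `separation`, `covariates` (names), plus `perm_p`/`n_perm`/`seed`
#'   slots filled by [perm_regressor_residuals()].
#' @export
logistic_glm <- function(status, f_measure, covariates = NULL,
                         alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  y <- if (is.numeric(status)) status else as.integer(status == "case")
  stopifnot(length(y) == length(f_measure))
  C <- NULL
  if (!is.null(covariates)) {
    C <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
    if (nrow(C) != length(y)) {
      keep <- stats::complete.cases(as.data.frame(covariates)) &
        !is.na(f_measure) & !is.na(y)
      message(sprintf("dropping %d incomplete row(s)", sum(!keep)))
      y <- y[keep]; f_measure <- f_measure[keep]
      C <- stats::model.matrix(~ ., data = as.data.frame(covariates)[keep, , drop = FALSE])[, -1, drop = FALSE]
    }
  }
  keep <- !is.na(y) & !is.na(f_measure)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  if (!all(keep)) {
    message(sprintf("dropping %d incomplete row(s)", sum(!keep)))
    y <- y[keep]; f_measure <- f_measure[keep]
    if (!is.null(C)) C <- C[keep, , drop = FALSE]
  }
  if (stats::var(f_measure) == 0)
    stop("explanatory measure has zero variance")
  X <- cbind(`(Intercept)` = 1, f = f_measure, C)
  if (ncol(X) >= length(y)) stop("more parameters than observations")
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("collinear covariate column(s): ", paste(bad, collapse = ", "))
  }
  w <- .logistic_wald(X, y, col = 2L)
  p <- w[3]
  if (!is.na(p) && alternative != "two.sided") {
    z <- w[1] / w[2]
    p <- if (alternative == "greater") stats::pnorm(-z) else stats::pnorm(z)
  }
  structure(list(estimate = unname(w[1]), se = unname(w[2]),
                 z = unname(w[1] / w[2]), wald_p = unname(p), n = length(y),
                 separation = is.na(w[3]) && !is.na(w[1]),
                 alternative = alternative,
                 covariates = colnames(C),
                 perm_p = NA_real_, n_perm = 0L, seed = NA_integer_),
            class = "glm_result")
}

#' @export
print.glm_result <- function(x, ...) {
  cat(sprintf("logistic GLM: beta = %.4g (se %.4g), Wald p = %.3g, n = %d\n",
              x$estimate, x$se, x$wald_p, x$n))
  if (length(x$covariates))
    cat("  covariates:", paste(x$covariates, collapse = ", "), "\n")
  if (x$n_perm > 0)
    cat(sprintf("  permutation p = %.4g (%d permutations)\n", x$perm_p, x$n_perm))
  invisible(x)
}

#' Permutation test based on regressor residuals
#'
#' The explanatory measure is regressed linearly on the covariates; its
#' residuals r carry the part of the measure not explained by the nuisance
#' structure.  The observed statistic is the Wald p of the logistic fit of
#' status on r plus the covariates.  Each permutation shuffles r and refits;
#' the add-one estimator
#' perm_p = (1 + #\{permuted p <= observed p\}) / (n_perm + 1)
#' avoids zero p-values.  With a fixed seed the result is reproducible.
#'
#' @inheritParams logistic_glm
#' @param n_perm number of permutations, at least 100.
#' @param seed integer RNG seed.
#' @return a `glm_result` (see [logistic_glm()]) with `perm_p`, `n_perm`
#'   and `seed` filled; `estimate`/`wald_p` refer to the residual
#'   regressor.
#' @export
perm_regressor_residuals <- function(status, f_measure, covariates = NULL,
                                     n_perm = 1000, seed = NULL) {
  if (n_perm < 100) stop("n_perm must be at least 100")
  y <- if (is.numeric(status)) status else as.integer(status == "case")
  C <- NULL
  if (!is.null(covariates)) {
    C <- stats::model.matrix(~ ., data = as.data.frame(covariates))[, -1, drop = FALSE]
    qx <- qr(cbind(1, C))
    if (qx$rank < ncol(C) + 1) stop("covariate matrix is singular")
  }
  keep <- !is.na(y) & !is.na(f_measure)
  if (!is.null(C)) keep <- keep & stats::complete.cases(C)
  y <- y[keep]; f_measure <- f_measure[keep]
  if (!is.null(C)) C <- C[keep, , drop = FALSE]
  Z <- cbind(rep(1, length(y)), C)
  r <- stats::lsfit(Z, f_measure, intercept = FALSE)$residuals
  X <- cbind(rep(1, length(y)), r, C)
  obs <- .logistic_wald(X, y, col = 2L)
  if (is.na(obs[3])) stop("observed fit degenerate (separation or collinearity)")
  if (!is.null(seed)) set.seed(seed)
  hits <- 0L
  n <- length(y)
  for (b in seq_len(n_perm)) {
    X[, 2] <- r[sample.int(n)]
    pb <- .logistic_wald(X, y, col = 2L)[3]
    if (!is.na(pb) && pb <= obs[3]) hits <- hits + 1L
  }
  res <- logistic_glm(y, r, covariates = if (is.null(C)) NULL else as.data.frame(C))
  res$perm_p <- (1 + hits) / (n_perm + 1)
  res$n_perm <- as.integer(n_perm)
  res$seed <- if (is.null(seed)) NA_integer_ else as.integer(seed)
  res
}
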