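#' Configuration for the synthetic case-control cohort generator
#'
#' The generator emulates the structure of a SNP-array case-control set:
#' per-marker allele frequencies drawn uniformly on `maf_range`, individual
#' genotypes drawn from the inbreeding-inflated Hardy-Weinberg trinomial
#' P(2) = p^2 + F p (1-p), P(1) = 2 p (1-p) (1-F),
#' P(0) = (1-p)^2 + F p (1-p), optional planted autozygous tracts
#' (contiguous homozygous stretches), genotype missingness, and a disease
#' model.
#'
#' @param n_cases,n_controls group sizes.
#' @param n_snps total marker count, allocated to chromosomes
#'   proportionally to their lengths.
#' @param chrom_lengths_bp per-chromosome lengths; defaults to the
#'   [genome_layout()] scaled to 2,676,172,944 bp total.
#' @param maf_range allele-frequency interval, default `c(0.05, 0.5)`.
#' @param f_model list with `mean_cases`, `sd_cases`, `mean_controls`,
#'   `sd_controls`: per-individual F is drawn normal and clamped to [0, 1].
#'   Defaults mirror the observed group means/SDs of a real outbred cohort
#'   (cases 0.002 (0.008), controls 0 (0.006)).
#' @param planted_segments `NULL` or a list of specs, each a list with
#'   `group` (`"case"`, `"control"` or `"all"`), `n_per_individual`,
#'   `length_kb` (scalar or `c(min,max)` for uniform draw).  Tracts are
#'   placed uniformly within a length-weighted random chromosome, avoiding
#'   chromosome ends; overlapping tracts of one individual are merged.
#' @param missing_rate per-call missingness probability, applied last.
#' @param disease_model `"label_driven"` (labels are the first
#'   `n_cases` rows, independent of genotypes), `"logistic_on_F"`
#'   (status ~ Bernoulli(plogis(beta0 + beta_f * F))) or
#'   `"recessive_locus"` (penetrance by genotype at marker
#'   `locus_index`).
#' @param beta0,beta_f,locus_index,penetrance disease-model parameters.
#' @param seed integer; fixed seed gives byte-identical output.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_cases = 50, n_controls = 50, n_snps = 1000,
                       chrom_lengths_bp = NULL,
                       maf_range = c(0.05, 0.5),
                       f_model = list(mean_cases = 0.002, sd_cases = 0.008,
                                      mean_controls = 0, sd_controls = 0.006),
                       planted_segments = NULL,
                       missing_rate = 0.002,
                       disease_model = c("label_driven", "logistic_on_F",
                                         "recessive_locus"),
                       beta0 = 0, beta_f = 0, locus_index = 1L,
                       penetrance = c(0.05, 0.05, 0.5),
                       seed = 1L) {
  disease_model <- match.arg(disease_model)
  layout <- genome_layout(chrom_lengths_bp)
  stopifnot(n_snps >= 1, missing_rate >= 0, missing_rate <= 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2])
  for (nm in c("mean_cases", "mean_controls"))
    if (f_model[[nm]] < 0 || f_model[[nm]] > 1)
      stop("f_model means must lie in [0, 1]")
  if (!is.null(planted_segments)) {
    for (ps in planted_segments) {
      len_bp <- max(ps$length_kb) * 1000
      if (len_bp > max(layout$chrom_lengths_bp))
        stop("planted tract longer than the longest chromosome")
    }
  }
  structure(list(n_cases = n_cases, n_controls = n_controls, n_snps = n_snps,
                 layout = layout, maf_range = maf_range, f_model = f_model,
                 planted_segments = planted_segments,
                 missing_rate = missing_rate, disease_model = disease_model,
                 beta0 = beta0, beta_f = beta_f, locus_index = locus_index,
                 penetrance = penetrance, seed = as.integer(seed)),
            class = "sim_config")
}

# draw one individual's genotype row under the trinomial law
.draw_row <- function(p, f) {
  p2 <- p^2 + f * p * (1 - p)
  p1 <- 2 * p * (1 - p) * (1 - f)
  u <- stats::runif(length(p))
  ifelse(u < p2, 2L, ifelse(u < p2 + p1, 1L, 0L))
}

#' Simulate a case-control cohort with known inbreeding and planted tracts
#'
#' @param cfg a [sim_config()].
#' @param dir optional output directory; when given, PLINK files
#'   (`cohort.ped/.map` or `.bed/.bim/.fam` per `format`), a sample table,
#'   a truth TSV (`sample_id`, `planted_f`, `n_tracts`, `total_tract_kb`),
#'   a tract TSV and a JSON config echo are written there.
#' @param format `"text"` or `"binary"` PLINK output.
#' @return list with `gm` (a [genotype_matrix()]) and `truth` (list with
#'   `samples` data frame of planted F, `tracts` data frame of realised
#'   planted segments, `markers` with the true generating allele
#'   frequencies `p_b`, and the disease-model parameters).
#' @export
simulate_cohort <- function(cfg, dir = NULL, format = c("text", "binary")) {
  stopifnot(inherits(cfg, "sim_config"))
  format <- match.arg(format)
  set.seed(cfg$seed)
  lens <- cfg$layout$chrom_lengths_bp
  n_chr <- length(lens)

  # markers: counts proportional to chromosome length, positions uniform
  alloc <- pmax(1L, round(cfg$n_snps * lens / sum(lens)))
  while (sum(alloc) > cfg$n_snps) {           # fix rounding drift
    j <- which.max(alloc); alloc[j] <- alloc[j] - 1L
  }
  while (sum(alloc) < cfg$n_snps) {
    j <- which.max(lens); alloc[j] <- alloc[j] + 1L
  }
  chrom <- rep(seq_len(n_chr), alloc)
  pos <- unlist(lapply(seq_len(n_chr), function(c) {
    p <- sort(sample.int(lens[c] - 1L, alloc[c])) ; p
  }))
  m <- cfg$n_snps
  p_b <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])

  n <- cfg$n_cases + cfg$n_controls
  grp <- rep(c("case", "control"), c(cfg$n_cases, cfg$n_controls))
  fm <- cfg$f_model
  f_ind <- ifelse(grp == "case",
                  stats::rnorm(n, fm$mean_cases, fm$sd_cases),
                  stats::rnorm(n, fm$mean_controls, fm$sd_controls))
  f_ind <- pmin(pmax(f_ind, 0), 1)

  calls <- matrix(0L, n, m)
  for (i in seq_len(n)) calls[i, ] <- .draw_row(p_b, f_ind[i])

  # plant autozygous tracts
  tracts <- list()
  if (!is.null(cfg$planted_segments)) {
    for (ps in cfg$planted_segments) {
      who <- switch(ps$group, case = which(grp == "case"),
                    control = which(grp == "control"), all = seq_len(n),
                    stop("unknown planted-segment group"))
      for (i in who) {
        iv <- matrix(numeric(0), 0, 3)        # chrom, start, end
        for (k in seq_len(ps$n_per_individual)) {
          len_kb <- if (length(ps$length_kb) == 2)
            stats::runif(1, ps$length_kb[1], ps$length_kb[2]) else ps$length_kb
          len_bp <- len_kb * 1000
          ok <- which(lens > len_bp * 1.2)    # avoid chromosome ends
          c_k <- ok[sample.int(length(ok), 1, prob = lens[ok])]
          start <- floor(stats::runif(1, 0.05 * lens[c_k],
                                      0.95 * lens[c_k] - len_bp))
          iv <- rbind(iv, c(c_k, start, start + len_bp))
        }
        iv <- .merge_intervals(iv)
        for (r in seq_len(nrow(iv))) {
          idx <- which(chrom == iv[r, 1] & pos >= iv[r, 2] & pos <= iv[r, 3])
          if (length(idx))
            calls[i, idx] <- ifelse(stats::runif(length(idx)) < p_b[idx], 2L, 0L)
          tracts[[length(tracts) + 1]] <- data.frame(
            sample_idx = i, chrom = iv[r, 1], start_bp = iv[r, 2],
            end_bp = iv[r, 3], n_snps = length(idx),
            length_kb = (iv[r, 3] - iv[r, 2]) / 1000)
        }
      }
    }
  }
  tracts <- if (length(tracts)) do.call(rbind, tracts) else
    data.frame(sample_idx = integer(), chrom = numeric(),
               start_bp = numeric(), end_bp = numeric(),
               n_snps = integer(), length_kb = numeric())

  # disease model
  status <- grp
  if (cfg$disease_model == "logistic_on_F") {
    status <- ifelse(stats::runif(n) < stats::plogis(cfg$beta0 + cfg$beta_f * f_ind),
                     "case", "control")
  } else if (cfg$disease_model == "recessive_locus") {
    g <- calls[, cfg$locus_index]
    status <- ifelse(stats::runif(n) < cfg$penetrance[g + 1L], "case", "control")
  }

  # missingness last
  if (cfg$missing_rate > 0)
    calls[stats::runif(n * m) < cfg$missing_rate] <- NA_integer_

  ids <- sprintf("S%04d", seq_len(n))
  samples <- data.frame(id = ids,
                        sex = sample(c("male", "female"), n, replace = TRUE),
                        status = status, stringsAsFactors = FALSE)
  markers <- data.frame(id = sprintf("rs%06d", seq_len(m)), chrom = chrom,
                        pos_bp = pos, allele_a = "A", allele_b = "B",
                        stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls, markers, samples)

  tracts$sample_id <- ids[tracts$sample_idx]
  truth_samples <- data.frame(
    sample_id = ids, planted_f = f_ind,
    n_tracts = as.integer(tabulate(tracts$sample_idx, n)),
    total_tract_kb = as.numeric(rowsum(c(tracts$length_kb, rep(0, n)),
                                       c(tracts$sample_idx, seq_len(n)))))
  truth <- list(samples = truth_samples, tracts = tracts,
                markers = data.frame(id = markers$id, chrom = chrom,
                                     pos_bp = pos, p_b = p_b),
                disease_model = cfg[c("disease_model", "beta0", "beta_f",
                                      "locus_index", "penetrance")])

  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    prefix <- file.path(dir, "cohort")
    if (format == "text") write_plink_text(gm, prefix)
    else write_plink_binary(gm, prefix)
    write_sample_table(gm$samples, file.path(dir, "samples.tsv"))
    utils::write.table(truth_samples, file.path(dir, "truth_samples.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(tracts, file.path(dir, "truth_tracts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    cfg_echo <- cfg
    cfg_echo$layout <- list(total_autosomal_bp = cfg$layout$total_autosomal_bp)
    jsonlite::write_json(unclass(cfg_echo), file.path(dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  list(gm = gm, truth = truth)
}

.merge_intervals <- function(iv) {
  if (nrow(iv) <= 1) return(iv)
  iv <- iv[order(iv[, 1], iv[, 2]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (r in 2:nrow(iv)) {
    last <- nrow(out)
    if (iv[r, 1] == out[last, 1] && iv[r, 2] <= out[last, 3])
      out[last, 3] <- max(out[last, 3], iv[r, 3])
    else out <- rbind(out, iv[r, , drop = FALSE])
  }
  out
}

#' Canned deterministic test cohorts
#'
#' Small cohorts (at most 50 samples x 500 SNPs) used throughout the test
#' suite:
#' \describe{
#'   \item{`"null_cohort"`}{F = 0 everywhere, no tracts, label-driven
#'     disease: genotypes carry no signal.}
#'   \item{`"clean_roh"`}{no inbreeding or missingness, one planted
#'     2,000 kb autozygous tract per case on a dense two-chromosome map
#'     (~20 kb marker spacing), so the tract holds on the order of 100
#'     SNPs.}
#'   \item{`"inbred_cases"`}{cases with mean planted F = 0.05 (SD 0.01),
#'     controls F = 0.}
#' }
#'
#' @param name registry key.
#' @param seed integer seed.
#' @return as [simulate_cohort()].
#' @export
make_fixture <- function(name, seed = 42L) {
  cfg <- switch(
    name,
    null_cohort = sim_config(
      n_cases = 25, n_controls = 25, n_snps = 500,
      f_model = list(mean_cases = 0, sd_cases = 0,
                     mean_controls = 0, sd_controls = 0),
      missing_rate = 0.002, seed = seed),
    clean_roh = sim_config(
      n_cases = 10, n_controls = 10, n_snps = 500,
      chrom_lengths_bp = c(5e6, 5e6),
      f_model = list(mean_cases = 0, sd_cases = 0,
                     mean_controls = 0, sd_controls = 0),
      planted_segments = list(list(group = "case", n_per_individual = 1,
                                   length_kb = 2000)),
      missing_rate = 0, seed = seed),
    inbred_cases = sim_config(
      n_cases = 25, n_controls = 25, n_snps = 500,
      f_model = list(mean_cases = 0.05, sd_cases = 0.01,
                     mean_controls = 0, sd_controls = 0),
      missing_rate = 0.002, seed = seed),
    stop(sprintf("unknown fixture '%s'", name)))
  simulate_cohort(cfg)
}
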