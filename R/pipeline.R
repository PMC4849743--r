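#' Pipeline configuration
#'
#' Collects every stage's parameters in one flat, serialisable list.  All
#' published analysis constants live here as named defaults: the MAF
#' filter (0.05), the ROH thresholds ([roh_params()]: 75 SNPs / 1,000 kb,
#' zero heterozygotes per window), the recurrent-pool thresholds (> 5
#' carriers, >= 500 kb, >= 75 SNPs), the quantile bin count (4), the
#' F_ROH denominator (2,676,172,944 bp) and the GLM covariate set (sex,
#' 10 ancestry PCs, per-sample missingness).
#'
#' @param input either a [sim_config()] (the cohort is simulated) or a
#'   list `list(ped=, map=)` / `list(bed=, bim=, fam=)` of PLINK paths.
#' @param out_dir output directory.
#' @param maf_min analysis-set MAF threshold.
#' @param roh a [roh_params()].
#' @param pool_min_members,pool_min_kb,pool_min_snps recurrent-pool
#'   thresholds.
#' @param n_bins odds-ratio classes.
#' @param n_pcs ancestry principal components used as covariates.
#' @param glm_covariates character subset of
#'   `c("sex", "pcs", "missing")`.
#' @param n_perm permutations for burden/carrier/GLM permutation tests.
#' @param l_auto F_ROH denominator in bp.
#' @param seed integer master seed.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(input, out_dir, maf_min = 0.05,
                            roh = roh_params(),
                            pool_min_members = 6, pool_min_kb = 500,
                            pool_min_snps = 75, n_bins = 4, n_pcs = 10,
                            glm_covariates = c("sex", "pcs", "missing"),
                            n_perm = 199, l_auto = 2676172944,
                            seed = 1L) {
  structure(list(input = input, out_dir = out_dir, maf_min = maf_min,
                 roh = roh, pool_min_members = pool_min_members,
                 pool_min_kb = pool_min_kb, pool_min_snps = pool_min_snps,
                 n_bins = n_bins, n_pcs = n_pcs,
                 glm_covariates = glm_covariates, n_perm = n_perm,
                 l_auto = l_auto, seed = as.integer(seed)),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE))
}

#' Run the full homozygosity / inbreeding pipeline
#'
#' simulate (or load) -> SNP-wise homozygosity chi-square with FDR -> ROH
#' calling -> recurrent pooling and tests -> burden summaries, group tests
#' and binned odds ratios -> inbreeding coefficients and F_ROH ->
#' covariate-adjusted GLM with the residual-permutation test.  Every stage
#' writes a TSV into `out_dir`; a manifest (config echo, input hashes,
#' seed, package version) and a plain-text report are written at the end.
#' Reruns with the same config give identical manifests.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with all stage results (`gm`, `snp_tests`,
#'   `segments`, `pools`, `pool_tests`, `burden`, `burden_tests`,
#'   `binned`, `profiles`, `glm`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!inherits(config$input, "sim_config")) {
    paths <- unlist(config$input)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
  }

  gm <- .stage("load", {
    if (inherits(config$input, "sim_config"))
      simulate_cohort(config$input)$gm
    else if (!is.null(config$input$ped))
      read_plink_text(config$input$ped, config$input$map)
    else
      read_plink_binary(config$input$bed, config$input$bim, config$input$fam)
  })
  gm <- .stage("maf_filter", filter_maf(gm, config$maf_min))

  snp_tests <- .stage("snp_homozygosity", snp_homozygosity_chi2(gm))
  utils::write.table(snp_tests, file.path(config$out_dir, "snp_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  segments <- .stage("roh", call_rohs(gm, config$roh))
  write_roh_table(segments, file.path(config$out_dir, "roh_segments.tsv"))

  pools <- .stage("recurrent", pool_rohs(segments, gm,
                                         config$pool_min_members,
                                         config$pool_min_kb,
                                         config$pool_min_snps))
  pool_tests <- .stage("recurrent", recurrent_roh_tests(
    pools, gm, n_perm = config$n_perm, seed = config$seed))
  if (nrow(pools)) {
    utils::write.table(pool_tests,
                       file.path(config$out_dir, "recurrent_pools.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_pools_bed(pools, file.path(config$out_dir, "recurrent_pools.bed"))
  }

  burden <- .stage("burden", summarize_burden(segments, gm$samples))
  utils::write.table(burden, file.path(config$out_dir, "burden.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  burden_tests <- .stage("burden", lapply(
    stats::setNames(nm = c("n_rohs", "total_kb", "mean_kb")),
    function(s) group_burden_test(burden, s, n_perm = config$n_perm,
                                  seed = config$seed)))
  binned <- .stage("burden", tryCatch(
    list(n_rohs = binned_or(burden, "n_rohs", config$n_bins),
         total_kb = binned_or(burden, "total_kb", config$n_bins)),
    error = function(e) NULL))
  if (!is.null(binned))
    utils::write.table(do.call(rbind, c(binned, make.row.names = FALSE)),
                       file.path(config$out_dir, "binned_or.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  layout <- genome_layout(l_auto = config$l_auto)
  profiles <- .stage("inbreed", {
    fh <- fhat_estimators(gm)
    fr <- f_roh(segments, gm$samples, layout, min_kb = config$roh$min_kb)
    merge(fh, fr[c("id", "f_roh")], by = "id", sort = FALSE)
  })
  utils::write.table(profiles, file.path(config$out_dir, "inbreeding.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  glm_res <- .stage("assoc", {
    covs <- NULL
    cc <- list()
    if ("sex" %in% config$glm_covariates)
      cc$sex <- as.integer(gm$samples$sex == "female")
    if ("pcs" %in% config$glm_covariates) {
      k <- min(config$n_pcs, nrow(gm$calls) - 2L)
      pcs <- genotype_pca(gm, k = k)
      for (j in seq_len(ncol(pcs))) cc[[colnames(pcs)[j]]] <- pcs[, j]
    }
    if ("missing" %in% config$glm_covariates)
      cc$missing_rate <- gm$samples$missing_rate
    cc <- Filter(function(v) stats::var(v) > 0, cc)   # drop constants
    if (length(cc)) covs <- as.data.frame(cc)
    lapply(stats::setNames(nm = c("f1", "f2", "f3", "f_roh")), function(mn) {
      f <- profiles[[mn]][match(gm$samples$id, profiles$id)]
      if (stats::var(f, na.rm = TRUE) == 0) return(NULL)
      tryCatch(
        perm_regressor_residuals(gm$samples$status, f, covs,
                                 n_perm = max(100, config$n_perm),
                                 seed = config$seed),
        error = function(e) { message("assoc (", mn, "): ",
                                      conditionMessage(e)); NULL })
    })
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("homburden")),
    seed = config$seed,
    config = .config_echo(config),
    outputs = local({
      fs <- list.files(config$out_dir, full.names = TRUE)
      fs <- fs[!grepl("manifest|report", fs)]
      as.list(tools::md5sum(sort(fs)))
    }))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  .write_report(config, snp_tests, segments, pool_tests, burden,
                burden_tests, binned, profiles, glm_res)
  invisible(list(gm = gm, snp_tests = snp_tests, segments = segments,
                 pools = pools, pool_tests = pool_tests, burden = burden,
                 burden_tests = burden_tests, binned = binned,
                 profiles = profiles, glm = glm_res))
}

.config_echo <- function(config) {
  e <- unclass(config)
  if (inherits(e$input, "sim_config")) {
    e$input <- unclass(e$input)
    e$input$layout <- list(total_autosomal_bp = e$input$layout$total_autosomal_bp)
  }
  e$roh <- unclass(e$roh)
  e
}

.write_report <- function(config, snp_tests, segments, pool_tests, burden,
                          burden_tests, binned, profiles, glm_res) {
  con <- file(file.path(config$out_dir, "report.txt"), "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("homburden pipeline report (seed %d)", config$seed)
  w("")
  w("SNP-wise homozygosity: %d markers tested, %d FDR rejections (q*=0.05)",
    nrow(snp_tests), sum(snp_tests$fdr_reject))
  w("ROH segments: %d total (%d in cases, %d in controls)",
    nrow(segments), sum(segments$status == "case"),
    sum(segments$status == "control"))
  nb <- burden
  for (g in c("case", "control")) {
    b <- nb[nb$status == g, ]
    w("  %ss: mean %.2f ROHs/person, mean total %.0f kb, mean size %.0f kb",
      g, mean(b$n_rohs), mean(b$total_kb), mean(b$mean_kb, na.rm = TRUE))
  }
  for (s in names(burden_tests)) {
    bt <- burden_tests[[s]]
    if (!is.null(bt$p) && !is.na(bt$p))
      w("  %s: t-test p = %.3g, permutation p = %.3g", s, bt$p, bt$perm_p)
  }
  w("Recurrent pools: %d", if (is.null(nrow(pool_tests))) 0L else nrow(pool_tests))
  if (!is.null(nrow(pool_tests)) && nrow(pool_tests))
    for (i in seq_len(nrow(pool_tests)))
      w("  %s chr%d %.0f kb, carriers %d/%d, chi2 = %.2f (p = %.3g)",
        pool_tests$pool[i], pool_tests$chrom[i], pool_tests$consensus_kb[i],
        pool_tests$n_case_carriers[i], pool_tests$n_control_carriers[i],
        trunc_digits(pool_tests$chi2[i]), pool_tests$p[i])
  for (mn in names(glm_res)) {
    g <- glm_res[[mn]]
    if (is.null(g)) next
    w("GLM %s: beta = %.3g, Wald p = %.3g, perm p = %.3g",
      mn, g$estimate, g$wald_p, g$perm_p)
  }
  invisible(NULL)
}

#' Command-line entry point
#'
#' Dispatches the subcommands `simulate`, `roh`, `recurrent`, `burden`,
#' `inbreed`, `assoc` and `run` (the full pipeline); `homburden --version`
#' prints the package version.  Installed as `inst/exec/homburden`, e.g.
#' `Rscript $(Rscript -e 'cat(system.file("exec/homburden", package="homburden"))') run --out out/ --seed 7`.
#'
#' @param args character vector, defaults to the trailing command-line
#'   arguments.
#' @return exit status, invisibly.
#' @export
homburden_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args) || args[1] %in% c("-h", "--help")) {
    cat("usage: homburden <simulate|roh|recurrent|burden|inbreed|assoc|run> [options]\n")
    return(invisible(0L))
  }
  if (args[1] == "--version") {
    cat(as.character(utils::packageVersion("homburden")), "\n")
    return(invisible(0L))
  }
  cmd <- args[1]; rest <- args[-1]
  opt <- .parse_kv(rest)
  seed <- as.integer(opt[["seed"]] %||% 1L)
  out <- opt[["out"]] %||% "homburden_out"
  load_gm <- function() {
    if (!is.null(opt[["ped"]])) read_plink_text(opt[["ped"]], opt[["map"]])
    else if (!is.null(opt[["bed"]]))
      read_plink_binary(opt[["bed"]], opt[["bim"]], opt[["fam"]])
    else stop("supply --ped/--map or --bed/--bim/--fam")
  }
  switch(cmd,
    simulate = {
      cfg <- sim_config(n_cases = as.integer(opt[["n-cases"]] %||% 100),
                        n_controls = as.integer(opt[["n-controls"]] %||% 100),
                        n_snps = as.integer(opt[["n-snps"]] %||% 5000),
                        seed = seed)
      simulate_cohort(cfg, dir = out,
                      format = opt[["format"]] %||% "text")
    },
    roh = {
      gm <- filter_maf(load_gm(), as.numeric(opt[["maf"]] %||% 0.05))
      pars <- roh_params(
        min_snps = as.integer(opt[["min-snps"]] %||% 75),
        min_kb = as.numeric(opt[["min-kb"]] %||% 1000),
        window_het_max = as.numeric(opt[["window-het"]] %||% 0))
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      write_roh_table(call_rohs(gm, pars), file.path(out, "roh_segments.tsv"))
    },
    run = {
      input <- if (!is.null(opt[["ped"]]))
        list(ped = opt[["ped"]], map = opt[["map"]])
      else if (!is.null(opt[["bed"]]))
        list(bed = opt[["bed"]], bim = opt[["bim"]], fam = opt[["fam"]])
      else sim_config(seed = seed)
      run_pipeline(pipeline_config(input, out, seed = seed))
    },
    {
      # remaining subcommands share: load, call, then one analysis
      gm <- filter_maf(load_gm(), as.numeric(opt[["maf"]] %||% 0.05))
      segs <- call_rohs(gm)
      dir.create(out, showWarnings = FALSE, recursive = TRUE)
      if (cmd == "recurrent") {
        pools <- pool_rohs(segs, gm)
        utils::write.table(recurrent_roh_tests(pools, gm),
                           file.path(out, "recurrent_pools.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      } else if (cmd == "burden") {
        b <- summarize_burden(segs, gm$samples)
        utils::write.table(b, file.path(out, "burden.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      } else if (cmd == "inbreed") {
        fh <- fhat_estimators(gm)
        fr <- f_roh(segs, gm$samples,
                    genome_layout(l_auto = as.numeric(opt[["l-auto"]] %||% 2676172944)),
                    min_kb = as.numeric(opt[["min-kb"]] %||% 1000))
        utils::write.table(merge(fh, fr[c("id", "f_roh")], by = "id"),
                           file.path(out, "inbreeding.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
      } else if (cmd == "assoc") {
        fh <- fhat_estimators(gm)
        res <- perm_regressor_residuals(
          gm$samples$status, fh[[opt[["measure"]] %||% "f1"]],
          n_perm = as.integer(opt[["n-perm"]] %||% 999), seed = seed)
        jsonlite::write_json(unclass(res), file.path(out, "assoc.json"),
                             auto_unbox = TRUE, digits = NA, null = "null")
      } else stop("unknown subcommand: ", cmd)
    })
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.parse_kv <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      key <- substring(a, 3)
      if (i < length(args) && !startsWith(args[i + 1], "--")) {
        out[[key]] <- args[i + 1]; i <- i + 2
      } else { out[[key]] <- "true"; i <- i + 1 }
    } else i <- i + 1
  }
  out
}
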