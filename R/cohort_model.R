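#' Genotype matrix container
#'
#' Bundles a diploid autosomal genotype call matrix with its marker map and
#' sample metadata.  Calls count copies of the "b" allele of each marker
#' (0, 1, 2) with `NA` for missing.  Markers must lie on autosomes 1-22 and
#' be sorted by chromosome and base-pair position; positions are 1-based and
#' inclusive throughout the package.
#'
#' @param calls integer matrix, samples x markers, values in {0, 1, 2, NA}.
#' @param markers data frame with columns `id`, `chrom` (1-22), `pos_bp`
#'   (>= 1), `allele_a`, `allele_b`; a `freq_b` column is (re)computed.
#' @param samples data frame with columns `id`, `sex`
#'   (`"male"`/`"female"`/`"unknown"`), `status` (`"case"`/`"control"`);
#'   further columns (e.g. `histology`, `age_group`, `mononucleosis`) are
#'   carried along as subgroup labels.  A `missing_rate` column is
#'   (re)computed.
#' @return an object of class `genotype_matrix`: a list with elements
#'   `calls`, `markers`, `samples`.
#' @export
genotype_matrix <- function(calls, markers, samples) {
  if (!is.matrix(calls)) calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  stopifnot(
    nrow(calls) == nrow(samples),
    ncol(calls) == nrow(markers),
    all(c("id", "chrom", "pos_bp") %in% names(markers)),
    all(c("id", "status") %in% names(samples))
  )
  bad <- calls[!is.na(calls)]
  if (length(bad) && (min(bad) < 0L || max(bad) > 2L))
    stop("genotype calls must be 0, 1, 2 or NA")
  if (any(markers$pos_bp < 1))
    stop("marker positions must be >= 1 (1-based, inclusive)")
  if (any(!markers$chrom %in% 1:22))
    stop("markers must lie on autosomes 1-22 (drop others before building)")
  o <- order(markers$chrom, markers$pos_bp)
  if (is.unsorted(o)) {
    markers <- markers[o, , drop = FALSE]
    calls <- calls[, o, drop = FALSE]
  }
  if (anyDuplicated(markers[c("chrom", "pos_bp")]))
    stop("duplicate marker positions within a chromosome")
  if (is.null(samples$sex)) samples$sex <- "unknown"
  if (!all(samples$status %in% c("case", "control")))
    stop("every sample needs status 'case' or 'control'")
  if (is.null(markers$allele_a)) markers$allele_a <- NA_character_
  if (is.null(markers$allele_b)) markers$allele_b <- NA_character_
  rownames(calls) <- samples$id
  colnames(calls) <- markers$id
  gm <- structure(list(calls = calls, markers = markers, samples = samples),
                  class = "genotype_matrix")
  compute_freqs(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples (%d cases / %d controls) x %d markers on %d chromosome(s)\n",
              nrow(x$calls), sum(x$samples$status == "case"),
              sum(x$samples$status == "control"), ncol(x$calls),
              length(unique(x$markers$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

#' Recompute allele frequencies and per-sample missingness
#'
#' `freq_b` is the frequency of allele b among non-missing calls at each
#' marker; a marker with all calls missing gets `freq_b = NA` (flagged,
#' excluded by downstream estimators).  `missing_rate` is the fraction of
#' missing calls per sample over all markers.
#'
#' @param gm a [genotype_matrix()].
#' @return `gm` with refreshed `markers$freq_b` and `samples$missing_rate`.
#' @export
compute_freqs <- function(gm) {
  n_ok <- colSums(!is.na(gm$calls))
  tot <- colSums(gm$calls, na.rm = TRUE)
  gm$markers$freq_b <- ifelse(n_ok > 0, tot / (2 * n_ok), NA_real_)
  gm$samples$missing_rate <- rowMeans(is.na(gm$calls))
  gm
}

#' Subset a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @param samples,markers logical or integer index over rows / columns.
#' @return a new `genotype_matrix` with frequencies recomputed on the subset.
#' @export
subset_gm <- function(gm, samples = NULL, markers = NULL) {
  if (is.null(samples)) samples <- seq_len(nrow(gm$calls))
  if (is.null(markers)) markers <- seq_len(ncol(gm$calls))
  genotype_matrix(gm$calls[samples, markers, drop = FALSE],
                  gm$markers[markers, , drop = FALSE],
                  gm$samples[samples, , drop = FALSE])
}

#' Drop markers below a minor-allele-frequency threshold
#'
#' The analysis set of the pipeline keeps markers with MAF > `maf_min`
#' (default 0.05); readers do not filter so that small fixtures survive a
#' round trip.
#'
#' @param gm a [genotype_matrix()].
#' @param maf_min markers with `min(freq_b, 1 - freq_b) <= maf_min` or with
#'   undefined frequency are dropped.
#' @return filtered `genotype_matrix`.
#' @export
filter_maf <- function(gm, maf_min = 0.05) {
  p <- gm$markers$freq_b
  keep <- !is.na(p) & pmin(p, 1 - p) > maf_min
  subset_gm(gm, markers = keep)
}

## ---- genome layout ---------------------------------------------------------

# hg18 autosome lengths (bp), used only as relative proportions
.HG18_BP <- c(
  247249719, 242951149, 199501827, 191273063, 180857866, 170899992,
  158821424, 146274826, 140273252, 135374737, 134452384, 132349534,
  114142980, 106368585, 100338915, 88827254, 78774742, 76117153,
  63811651, 62435964, 46944323, 49691432)

#' SNP-mappable autosomal genome layout
#'
#' Per-chromosome mappable lengths used as the denominator of F_ROH.  By
#' default the 22 autosome lengths are hg18 proportions rescaled so that
#' their sum equals `l_auto` = 2,676,172,944 bp, the mappable autosomal
#' total (centromeres excluded) used to normalise F_ROH.
#'
#' @param chrom_lengths_bp optional explicit per-autosome lengths.
#' @param l_auto total autosomal length the default layout is scaled to.
#' @return list with `chrom_lengths_bp` (named 1..22) and
#'   `total_autosomal_bp`.
#' @export
genome_layout <- function(chrom_lengths_bp = NULL, l_auto = 2676172944) {
  if (is.null(chrom_lengths_bp)) {
    chrom_lengths_bp <- round(.HG18_BP / sum(.HG18_BP) * l_auto)
    # absorb rounding drift into chr1 so the total is exact
    chrom_lengths_bp[1] <- chrom_lengths_bp[1] + (l_auto - sum(chrom_lengths_bp))
  }
  chrom_lengths_bp <- as.numeric(chrom_lengths_bp)
  names(chrom_lengths_bp) <- seq_along(chrom_lengths_bp)
  tot <- sum(chrom_lengths_bp)
  if (tot <= 0) stop("total autosomal length must be positive")
  list(chrom_lengths_bp = chrom_lengths_bp, total_autosomal_bp = tot)
}

## ---- PLINK text (PED/MAP) --------------------------------------------------

.sex_to_code <- function(s) c(male = 1L, female = 2L, unknown = 0L)[s]
.code_to_sex <- function(x) {
  out <- rep("unknown", length(x))
  out[x == 1] <- "male"
  out[x == 2] <- "female"
  out
}

#' Read a PLINK 1 text fileset (PED/MAP)
#'
#' The counted ("b") allele of each marker is the second distinct allele
#' observed in the PED column pair; "0 0" pairs are missing.  Phenotype 2/1
#' maps to case/control.  Non-autosomal markers are dropped with a warning.
#'
#' @param ped_path,map_path paths to the .ped and .map files.
#' @param maf_min passed to [filter_maf()]; default 0 (no filtering at load).
#' @return a [genotype_matrix()].
#' @export
read_plink_text <- function(ped_path, map_path, maf_min = 0) {
  stopifnot(file.exists(ped_path), file.exists(map_path))
  map <- utils::read.table(map_path, header = FALSE, colClasses = "character")
  if (ncol(map) != 4) stop("MAP file must have 4 columns (chrom, id, cM, bp)")
  names(map) <- c("chrom", "id", "cm", "pos_bp")
  chrom <- suppressWarnings(as.integer(map$chrom))
  auto <- !is.na(chrom) & chrom %in% 1:22
  if (!all(auto))
    warning(sprintf("dropping %d non-autosomal marker(s)", sum(!auto)))
  m_all <- nrow(map)

  lines <- readLines(ped_path)
  lines <- lines[nzchar(trimws(lines))]
  n <- length(lines)
  fields <- strsplit(trimws(lines), "[ \t]+")
  want <- 6 + 2 * m_all
  for (i in seq_len(n))
    if (length(fields[[i]]) != want)
      stop(sprintf("PED line %d has %d fields, expected %d",
                   i, length(fields[[i]]), want))
  ped <- do.call(rbind, fields)

  a1 <- ped[, 6 + 2 * seq_len(m_all) - 1, drop = FALSE]
  a2 <- ped[, 6 + 2 * seq_len(m_all), drop = FALSE]
  calls <- matrix(NA_integer_, n, m_all)
  allele_a <- allele_b <- rep(NA_character_, m_all)
  for (j in seq_len(m_all)) {
    g1 <- a1[, j]; g2 <- a2[, j]
    ok <- g1 != "0" & g2 != "0"
    als <- unique(c(rbind(g1[ok], g2[ok])))   # order of appearance
    if (length(als) > 2)
      stop(sprintf("marker %s has >2 alleles", map$id[j]))
    if (length(als) >= 1) allele_a[j] <- als[1]
    if (length(als) == 2) allele_b[j] <- als[2]
    if (length(als)) {
      b <- if (is.na(allele_b[j])) "\r<none>" else allele_b[j]
      calls[ok, j] <- (g1[ok] == b) + (g2[ok] == b)
    }
  }

  sex <- .code_to_sex(suppressWarnings(as.integer(ped[, 5])))
  ph <- ped[, 6]
  status <- ifelse(ph == "2", "case", ifelse(ph == "1", "control", NA))
  if (anyNA(status)) {
    warning("unrecognised phenotype code(s); affected samples dropped")
  }
  keep_s <- !is.na(status)
  samples <- data.frame(id = ped[keep_s, 2], sex = sex[keep_s],
                        status = status[keep_s], stringsAsFactors = FALSE)
  markers <- data.frame(id = map$id[auto], chrom = chrom[auto],
                        pos_bp = as.numeric(map$pos_bp[auto]),
                        allele_a = allele_a[auto], allele_b = allele_b[auto],
                        stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls[keep_s, auto, drop = FALSE], markers, samples)
  if (maf_min > 0) gm <- filter_maf(gm, maf_min)
  gm
}

#' Write a PLINK 1 text fileset (PED/MAP)
#'
#' Missing calls are written as "0 0"; markers whose b allele was never
#' observed are written homozygous for allele a.  Output is deterministic
#' for a fixed input.
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output path prefix; `<prefix>.ped` and `<prefix>.map` are
#'   written.
#' @return invisibly, the two file paths.
#' @export
write_plink_text <- function(gm, prefix) {
  ped_path <- paste0(prefix, ".ped")
  map_path <- paste0(prefix, ".map")
  mk <- gm$markers
  utils::write.table(
    data.frame(mk$chrom, mk$id, 0, format(mk$pos_bp, scientific = FALSE, trim = TRUE)),
    map_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  n <- nrow(gm$calls); m <- ncol(gm$calls)
  aa <- ifelse(is.na(mk$allele_a), "A", mk$allele_a)
  bb <- ifelse(is.na(mk$allele_b), aa, mk$allele_b)
  rows <- character(n)
  for (i in seq_len(n)) {
    x <- gm$calls[i, ]
    g1 <- ifelse(is.na(x), "0", ifelse(x == 2, bb, aa))  # hets as "a b"
    g2 <- ifelse(is.na(x), "0", ifelse(x >= 1, bb, aa))
    s <- gm$samples[i, ]
    rows[i] <- paste(c(s$id, s$id, 0, 0, .sex_to_code(s$sex),
                       if (s$status == "case") 2 else 1,
                       as.vector(rbind(g1, g2))), collapse = " ")
  }
  writeLines(rows, ped_path)
  invisible(c(ped = ped_path, map = map_path))
}

## ---- PLINK binary (BED/BIM/FAM) --------------------------------------------

# 2-bit codes, SNP-major: 00 = hom a1 (call 0), 01 = missing, 10 = het, 11 = hom a2
.BED_MAGIC <- as.raw(c(0x6c, 0x1b, 0x01))

#' Read a PLINK 1 binary fileset (BED/BIM/FAM)
#'
#' SNP-major BED only (magic bytes 0x6c 0x1b, mode 0x01).  The counted
#' allele is the second BIM allele column (a2), so 11 decodes to call 2.
#'
#' @param bed_path,bim_path,fam_path paths to the three files.
#' @param maf_min passed to [filter_maf()]; default 0.
#' @return a [genotype_matrix()].
#' @export
read_plink_binary <- function(bed_path, bim_path, fam_path, maf_min = 0) {
  stopifnot(file.exists(bed_path), file.exists(bim_path), file.exists(fam_path))
  bim <- utils::read.table(bim_path, header = FALSE, colClasses = "character")
  names(bim) <- c("chrom", "id", "cm", "pos_bp", "a1", "a2")
  fam <- utils::read.table(fam_path, header = FALSE, colClasses = "character")
  n <- nrow(fam); m <- nrow(bim)
  bpm <- ceiling(n / 4)                      # bytes per marker
  raw <- readBin(bed_path, "raw", n = 3 + bpm * m + 1)
  if (length(raw) < 3 || !identical(raw[1:2], .BED_MAGIC[1:2]))
    stop("not a PLINK BED file (bad magic bytes)")
  if (raw[3] != .BED_MAGIC[3])
    stop("only SNP-major BED (mode byte 0x01) is supported")
  if (length(raw) != 3 + bpm * m)
    stop(sprintf("truncated BED: expected %d data bytes, found %d",
                 bpm * m, length(raw) - 3))
  body <- as.integer(raw[-(1:3)])
  # expand each byte into 4 two-bit codes, sample 1 in the low bits
  codes <- matrix(0L, 4 * bpm, m)
  b <- matrix(body, bpm, m)
  codes[seq(1, 4 * bpm, by = 4), ] <- b %% 4L
  codes[seq(2, 4 * bpm, by = 4), ] <- (b %/% 4L) %% 4L
  codes[seq(3, 4 * bpm, by = 4), ] <- (b %/% 16L) %% 4L
  codes[seq(4, 4 * bpm, by = 4), ] <- b %/% 64L
  codes <- codes[seq_len(n), , drop = FALSE]
  calls <- matrix(NA_integer_, n, m)
  calls[codes == 0L] <- 0L
  calls[codes == 2L] <- 1L
  calls[codes == 3L] <- 2L

  chrom <- suppressWarnings(as.integer(bim$chrom))
  auto <- !is.na(chrom) & chrom %in% 1:22
  if (!all(auto))
    warning(sprintf("dropping %d non-autosomal marker(s)", sum(!auto)))
  status <- ifelse(fam[, 6] == "2", "case",
                   ifelse(fam[, 6] == "1", "control", NA))
  keep_s <- !is.na(status)
  if (!all(keep_s)) warning("unrecognised phenotype code(s); samples dropped")
  samples <- data.frame(id = fam[keep_s, 2],
                        sex = .code_to_sex(suppressWarnings(as.integer(fam[, 5])))[keep_s],
                        status = status[keep_s], stringsAsFactors = FALSE)
  markers <- data.frame(id = bim$id[auto], chrom = chrom[auto],
                        pos_bp = as.numeric(bim$pos_bp[auto]),
                        allele_a = ifelse(bim$a1[auto] == "0", NA, bim$a1[auto]),
                        allele_b = ifelse(bim$a2[auto] == "0", NA, bim$a2[auto]),
                        stringsAsFactors = FALSE)
  gm <- genotype_matrix(calls[keep_s, auto, drop = FALSE], markers, samples)
  if (maf_min > 0) gm <- filter_maf(gm, maf_min)
  gm
}

#' Write a PLINK 1 binary fileset (BED/BIM/FAM)
#'
#' Emits SNP-major BED with the standard magic bytes; missing calls encode
#' as 01.  Byte output is deterministic for fixed input.
#'
#' @param gm a [genotype_matrix()].
#' @param prefix output prefix; `.bed`, `.bim`, `.fam` are written.
#' @return invisibly, the three file paths.
#' @export
write_plink_binary <- function(gm, prefix) {
  bed_path <- paste0(prefix, ".bed")
  bim_path <- paste0(prefix, ".bim")
  fam_path <- paste0(prefix, ".fam")
  mk <- gm$markers
  utils::write.table(
    data.frame(mk$chrom, mk$id, 0,
               format(mk$pos_bp, scientific = FALSE, trim = TRUE),
               ifelse(is.na(mk$allele_a), "0", mk$allele_a),
               ifelse(is.na(mk$allele_b), "0", mk$allele_b)),
    bim_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  s <- gm$samples
  utils::write.table(
    data.frame(s$id, s$id, 0, 0, .sex_to_code(s$sex),
               ifelse(s$status == "case", 2, 1)),
    fam_path, quote = FALSE, row.names = FALSE, col.names = FALSE, sep = "\t")
  n <- nrow(gm$calls); m <- ncol(gm$calls)
  bpm <- ceiling(n / 4)
  code <- matrix(1L, 4 * bpm, m)             # pad + missing = 01
  x <- gm$calls
  cd <- matrix(1L, n, m)
  cd[!is.na(x) & x == 0L] <- 0L
  cd[!is.na(x) & x == 1L] <- 2L
  cd[!is.na(x) & x == 2L] <- 3L
  code[seq_len(n), ] <- cd
  code[seq_len(4 * bpm) > n, ] <- 0L         # pad bits are zero
  bytes <- code[seq(1, 4 * bpm, 4), , drop = FALSE] +
    4L * code[seq(2, 4 * bpm, 4), , drop = FALSE] +
    16L * code[seq(3, 4 * bpm, 4), , drop = FALSE] +
    64L * code[seq(4, 4 * bpm, 4), , drop = FALSE]
  con <- file(bed_path, "wb")
  on.exit(close(con))
  writeBin(.BED_MAGIC, con)
  writeBin(as.raw(as.vector(bytes)), con)
  invisible(c(bed = bed_path, bim = bim_path, fam = fam_path))
}

#' Write / read the sample covariate table
#'
#' Tab-separated with header; columns `id`, `sex`, `status` plus any
#' subgroup label columns present (e.g. `histology`, `age_group`,
#' `mononucleosis`) and `missing_rate`.
#'
#' @param samples the `samples` data frame of a [genotype_matrix()].
#' @param path file path.
#' @return `write_sample_table` returns the path invisibly;
#'   `read_sample_table` returns the data frame.
#' @export
write_sample_table <- function(samples, path) {
  utils::write.table(samples, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sample_table
#' @export
read_sample_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
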