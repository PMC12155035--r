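#' Construct a genotype matrix object
#'
#' Container for biallelic autosomal SNP dosages: a samples-by-variants
#' matrix of alternate-allele counts in `{0, 1, 2, NA}` plus variant
#' metadata. Missing entries stay `NA` at rest; mean imputation happens at
#' use time (PCA, association), never at read time.
#'
#' @param dosages Integer/numeric matrix, samples in rows, variants in
#'   columns; entries 0, 1, 2 or `NA`.
#' @param variants Tibble with columns `chromosome` (integer), `position_bp`,
#'   `ref`, `alt`, `id`; one row per column of `dosages`.
#' @param sample_ids Character vector of unique sample identifiers, one per
#'   row of `dosages`.
#'
#' @return An object of class `geno_matrix`.
#' @export
geno_matrix <- function(dosages, variants, sample_ids) {
  dosages <- as.matrix(dosages)
  variants <- as_tibble(variants)
  sample_ids <- as.character(sample_ids)
  if (nrow(dosages) != length(sample_ids)) {
    abort("nrow(dosages) must equal length(sample_ids).")
  }
  if (ncol(dosages) != nrow(variants)) {
    abort("ncol(dosages) must equal nrow(variants).")
  }
  if (anyDuplicated(sample_ids)) abort("sample_ids must be unique.")
  if (ncol(dosages) > 0) {
    rng <- blockwise_range(dosages)
    if (rng[1] < 0 || rng[2] > 2) abort("dosages must lie in {0, 1, 2, NA}.")
  }
  ord <- order(variants$chromosome, variants$position_bp)
  if (is.unsorted(ord)) {
    variants <- variants[ord, ]
    dosages <- dosages[, ord, drop = FALSE]
  }
  # by-reference: avoids duplicating what can be a multi-GB matrix
  data.table::setattr(dosages, "dimnames", list(sample_ids, variants$id))
  structure(
    list(dosages = dosages, variants = variants, sample_ids = sample_ids),
    class = "geno_matrix"
  )
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf(
    "<geno_matrix> %d samples x %d variants (%.2f%% missing)\n",
    n_samples(x), n_variants(x),
    100 * mean(is.na(x$dosages))
  ))
  invisible(x)
}

#' @rdname geno_matrix
#' @param x A `geno_matrix`.
#' @export
n_samples <- function(x) length(x$sample_ids)

#' @rdname geno_matrix
#' @export
n_variants <- function(x) nrow(x$variants)

#' Alternate-allele frequencies of a genotype matrix
#'
#' @param x A [geno_matrix()].
#' @return Numeric vector of per-variant alternate-allele frequencies over
#'   non-missing entries.
#' @export
allele_freqs <- function(x) {
  colMeans(x$dosages, na.rm = TRUE) / 2
}

#' Read genotypes from VCF or PLINK binary files
#'
#' Keeps biallelic autosomal SNPs only; multi-allelic records, indels and
#' non-autosomal chromosomes are dropped with a message. Dosages count the
#' alternate allele (the A1 allele for PLINK input).
#'
#' @param path Path to a `.vcf`/`.vcf.gz` file or a PLINK `.bed` file (the
#'   companion `.bim` and `.fam` must sit alongside).
#' @param format `"auto"` (from extension), `"vcf"` or `"plink"`.
#' @return A [geno_matrix()].
#' @export
read_genotypes <- function(path, format = c("auto", "vcf", "plink")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.bed$", path)) "plink" else "vcf"
  }
  switch(format,
    vcf = read_genotypes_vcf(path),
    plink = read_genotypes_plink(path)
  )
}

read_genotypes_vcf <- function(path) {
  if (!file.exists(path)) abort(sprintf("VCF not found: '%s'", path))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  chrom <- suppressWarnings(as.integer(sub("^[Cc]hr", "", fix$CHROM)))
  snp <- !is.na(chrom) & chrom >= 1L & chrom <= 22L &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    !grepl(",", fix$ALT, fixed = TRUE)
  n_drop <- sum(!snp)
  if (n_drop > 0) {
    inform(sprintf(
      "Dropped %d non-biallelic-SNP or non-autosomal record(s).", n_drop
    ))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[snp, , drop = FALSE]
  ids <- fix$ID[snp]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(chrom[snp][no_id], ":", fix$POS[snp][no_id])
  # strip phasing, count ALT alleles
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  codes <- c(
    "0/0" = 0L, "0|0" = 0L, "0/1" = 1L, "1/0" = 1L, "0|1" = 1L, "1|0" = 1L,
    "1/1" = 2L, "1|1" = 2L, "0" = 0L, "1" = 1L
  )
  dos[] <- codes[gt]
  variants <- tibble(
    chromosome = chrom[snp],
    position_bp = as.numeric(fix$POS[snp]),
    ref = fix$REF[snp], alt = fix$ALT[snp], id = ids
  )
  geno_matrix(t(dos), variants, colnames(gt))
}

#' Write genotypes to a minimal VCF
#'
#' @param x A [geno_matrix()].
#' @param path Output path (`.vcf`).
#' @return `path`, invisibly.
#' @export
write_genotypes_vcf <- function(x, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=ibdspc",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", x$sample_ids), collapse = "\t")
  ), con)
  gt_code <- c("0/0", "0/1", "1/1")
  d <- x$dosages
  for (j in seq_len(n_variants(x))) {
    gts <- ifelse(is.na(d[, j]), "./.", gt_code[d[, j] + 1L])
    writeLines(paste(c(
      x$variants$chromosome[j], format(x$variants$position_bp[j], scientific = FALSE),
      x$variants$id[j], x$variants$ref[j], x$variants$alt[j],
      ".", "PASS", ".", "GT", gts
    ), collapse = "\t"), con)
  }
  invisible(path)
}

# PLINK .bed 2-bit codes (SNP-major): 00 = hom A1, 10 = het, 11 = hom A2,
# 01 = missing. Dosage counts A1 (treated as the alternate allele).
plink_byte_table <- function() {
  codes <- c(2L, NA_integer_, 1L, 0L)  # indexed by 2-bit value 0..3
  t(vapply(0:255, function(b) {
    codes[c(
      bitwAnd(b, 3L),
      bitwAnd(bitwShiftR(b, 2L), 3L),
      bitwAnd(bitwShiftR(b, 4L), 3L),
      bitwAnd(bitwShiftR(b, 6L), 3L)
    ) + 1L]
  }, integer(4)))
}

read_genotypes_plink <- function(bed_path) {
  base <- sub("\\.bed$", "", bed_path)
  bim_path <- paste0(base, ".bim")
  fam_path <- paste0(base, ".fam")
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) abort(sprintf("PLINK companion file missing: '%s'", p))
  }
  fam <- utils::read.table(fam_path, header = FALSE,
                           colClasses = "character")
  bim <- utils::read.table(bim_path, header = FALSE,
                           colClasses = c("character", "character", "numeric",
                                          "numeric", "character", "character"))
  n <- nrow(fam)
  m <- nrow(bim)
  raw <- readBin(bed_path, "raw", n = file.size(bed_path))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    abort("Not a PLINK .bed file (bad magic number).")
  }
  if (raw[3] != as.raw(0x01)) abort("Only SNP-major .bed files are supported.")
  bpv <- ceiling(n / 4)
  if (length(raw) - 3 != bpv * m) {
    abort("PLINK .bed payload size does not match .bim/.fam dimensions.")
  }
  tab <- plink_byte_table()
  body <- matrix(as.integer(raw[-(1:3)]), nrow = bpv, ncol = m)
  dos <- matrix(NA_integer_, nrow = n, ncol = m)
  for (j in seq_len(m)) {
    vals <- t(tab[body[, j] + 1L, , drop = FALSE])
    dos[, j] <- vals[seq_len(n)]
  }
  chrom <- suppressWarnings(as.integer(sub("^[Cc]hr", "", bim[[1]])))
  keep <- !is.na(chrom) & chrom >= 1L & chrom <= 22L &
    nchar(bim[[5]]) == 1L & nchar(bim[[6]]) == 1L &
    bim[[5]] %in% c("A", "C", "G", "T") & bim[[6]] %in% c("A", "C", "G", "T")
  if (any(!keep)) {
    inform(sprintf(
      "Dropped %d non-biallelic-SNP or non-autosomal record(s).", sum(!keep)
    ))
  }
  variants <- tibble(
    chromosome = chrom[keep], position_bp = bim[[4]][keep],
    ref = bim[[6]][keep], alt = bim[[5]][keep], id = bim[[2]][keep]
  )
  geno_matrix(dos[, keep, drop = FALSE], variants, fam[[2]])
}

#' Write genotypes to PLINK .bed/.bim/.fam
#'
#' @param x A [geno_matrix()].
#' @param prefix Output path prefix (writes `prefix.bed`, `.bim`, `.fam`).
#' @return `prefix`, invisibly.
#' @export
write_genotypes_plink <- function(x, prefix) {
  n <- n_samples(x)
  m <- n_variants(x)
  fam <- data.frame(x$sample_ids, x$sample_ids, 0, 0, 0, -9)
  utils::write.table(fam, paste0(prefix, ".fam"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  bim <- data.frame(
    x$variants$chromosome, x$variants$id, 0,
    format(x$variants$position_bp, scientific = FALSE, trim = TRUE),
    x$variants$alt, x$variants$ref
  )
  utils::write.table(bim, paste0(prefix, ".bim"), quote = FALSE,
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  code_for <- c(3L, 2L, 0L)  # dosage 0,1,2 -> 2-bit code; NA -> 1
  bpv <- ceiling(n / 4)
  pad <- bpv * 4 - n
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  for (j in seq_len(m)) {
    d <- x$dosages[, j]
    bits <- ifelse(is.na(d), 1L, code_for[d + 1L])
    bits <- c(bits, rep(0L, pad))
    bytes <- bits[c(TRUE, FALSE, FALSE, FALSE)] +
      bitwShiftL(bits[c(FALSE, TRUE, FALSE, FALSE)], 2L) +
      bitwShiftL(bits[c(FALSE, FALSE, TRUE, FALSE)], 4L) +
      bitwShiftL(bits[c(FALSE, FALSE, FALSE, TRUE)], 6L)
    writeBin(as.raw(bytes), con)
  }
  invisible(prefix)
}

#' Filter variants by allele frequency or count
#'
#' Applies exactly one rule on the minor allele: `maf_gt` keeps variants with
#' minor-allele frequency strictly above the cutoff, `maf_lt` strictly below,
#' and `mac_between` keeps variants whose minor-allele count lies strictly
#' between the two bounds (so `c(10, 100)` keeps MAC 11-99). The sample set
#' is unchanged; applying the same filter twice is a no-op.
#'
#' @param x A [geno_matrix()].
#' @param maf_gt,maf_lt Frequency cutoffs (exclusive).
#' @param mac_between Length-2 numeric, exclusive minor-allele-count bounds.
#' @return A filtered [geno_matrix()]; warns (does not error) if no variant
#'   survives.
#' @export
filter_by_frequency <- function(x, maf_gt = NULL, maf_lt = NULL,
                                mac_between = NULL) {
  rules <- !vapply(list(maf_gt, maf_lt, mac_between), is.null, logical(1))
  if (sum(rules) != 1) {
    abort("Supply exactly one of maf_gt, maf_lt, mac_between.")
  }
  p <- allele_freqs(x)
  maf <- pmin(p, 1 - p)
  if (!is.null(mac_between)) {
    if (length(mac_between) != 2 || mac_between[1] >= mac_between[2]) {
      abort("mac_between must be c(lower, upper) with lower < upper.")
    }
    n_alleles <- 2 * blockwise_n_obs(x$dosages)
    mac <- round(maf * n_alleles)
    keep <- mac > mac_between[1] & mac < mac_between[2]
  } else if (!is.null(maf_gt)) {
    keep <- maf > maf_gt
  } else {
    keep <- maf < maf_lt
  }
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) warn("Frequency filter removed all variants.")
  geno_matrix(
    x$dosages[, keep, drop = FALSE],
    x$variants[keep, , drop = FALSE],
    x$sample_ids
  )
}

#' Keep a random subset of variants
#'
#' Seeded uniform thinning of the variant set, the standard shortcut when a
#' computation (e.g. a GRM) does not need every site.
#'
#' @param x A [geno_matrix()].
#' @param max_variants Number of variants to keep.
#' @param seed Integer seed.
#' @return A thinned [geno_matrix()].
#' @export
thin_variants <- function(x, max_variants, seed = 1) {
  if (n_variants(x) <= max_variants) return(x)
  set.seed(seed)
  keep <- sort(sample.int(n_variants(x), max_variants))
  geno_matrix(x$dosages[, keep, drop = FALSE],
              x$variants[keep, , drop = FALSE], x$sample_ids)
}

# column-block range that never copies the full matrix (range(x, na.rm)
# materializes an NA-masked copy, prohibitive at genome scale)
blockwise_range <- function(x, block = 20000L) {
  lo <- Inf
  hi <- -Inf
  for (start in seq(1, ncol(x), by = block)) {
    idx <- start:min(start + block - 1L, ncol(x))
    r <- suppressWarnings(range(x[, idx, drop = FALSE], na.rm = TRUE))
    lo <- min(lo, r[1])
    hi <- max(hi, r[2])
  }
  c(lo, hi)
}

# per-column count of non-missing entries, blockwise
blockwise_n_obs <- function(x, block = 20000L) {
  if (!anyNA(x)) return(rep(nrow(x), ncol(x)))
  out <- numeric(ncol(x))
  for (start in seq(1, ncol(x), by = block)) {
    idx <- start:min(start + block - 1L, ncol(x))
    out[idx] <- colSums(!is.na(x[, idx, drop = FALSE]))
  }
  out
}

# mean-impute missing dosages, column-wise (used by PCA / association)
impute_dosages <- function(dosages) {
  if (!anyNA(dosages)) return(dosages)
  mu <- colMeans(dosages, na.rm = TRUE)
  idx <- which(is.na(dosages), arr.ind = TRUE)
  dosages[idx] <- mu[idx[, 2]]
  dosages
}
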