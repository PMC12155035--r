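#' Principal components of a genotype matrix
#'
#' Standardizes each variant to mean zero and unit expected variance
#' (dividing by `sqrt(2 p (1 - p))`), mean-imputing missing entries and
#' excluding monomorphic variants, then returns the top `k` left singular
#' vectors (unit norm, sign fixed so the largest-magnitude entry is
#' positive).
#'
#' @param g A [geno_matrix()].
#' @param k Number of components.
#' @param seed Seed, used only when `max_variants` subsampling is requested.
#' @param max_variants Optional cap on the number of variants entering the
#'   PCA (seeded uniform subsample), the usual thinning shortcut for large
#'   panels.
#' @return A covariate tibble: `sample_id`, `PC1` ... `PCk`, with attribute
#'   `kind = "PC"`.
#' @export
genotype_pca <- function(g, k = 25, seed = 1, max_variants = NULL) {
  stopifnot(inherits(g, "geno_matrix"))
  n <- n_samples(g)
  if (n < k + 1) abort("need at least k + 1 samples.")
  p <- allele_freqs(g)
  keep <- which(p > 0 & p < 1)
  if (length(keep) < k) abort("need at least k polymorphic variants.")
  if (!is.null(max_variants) && length(keep) > max_variants) {
    set.seed(seed)
    keep <- sort(sample(keep, max_variants))
  }
  # accumulate the n x n kernel block-wise so the standardized matrix is
  # never materialized in full
  K <- matrix(0, n, n)
  block <- 10000L
  for (start in seq(1, length(keep), by = block)) {
    idx <- keep[start:min(start + block - 1L, length(keep))]
    X <- impute_dosages(g$dosages[, idx, drop = FALSE])
    storage.mode(X) <- "double"
    pk <- colMeans(X) / 2
    X <- sweep(X, 2, 2 * pk, "-")
    X <- sweep(X, 2, sqrt(2 * pk * (1 - pk)), "/")
    K <- K + tcrossprod(X)
  }
  eig <- eigen(K, symmetric = TRUE)
  V <- fix_signs(eig$vectors[, seq_len(k), drop = FALSE])
  colnames(V) <- paste0("PC", seq_len(k))
  out <- dplyr::bind_cols(tibble(sample_id = g$sample_ids), as_tibble(V))
  attr(out, "kind") <- "PC"
  attr(out, "eigenvalues") <- eig$values[seq_len(k)]
  out
}

# Align a covariate specification to a sample order and return a plain
# matrix (no intercept). Accepts a spectral_basis, a covariate tibble whose
# first column is sample_id, a matrix with rownames, or NULL.
as_covariate_matrix <- function(cov, sample_ids, k = NULL) {
  if (is.null(cov)) {
    return(matrix(numeric(0), nrow = length(sample_ids), ncol = 0))
  }
  if (inherits(cov, "spectral_basis")) cov <- tidy(cov)
  if (is.data.frame(cov)) {
    idx <- match(sample_ids, as.character(cov[[1]]))
    if (anyNA(idx)) abort("covariate table is missing some samples.")
    M <- as.matrix(cov[idx, -1, drop = FALSE])
  } else {
    M <- as.matrix(cov)
    if (!is.null(rownames(M))) {
      idx <- match(sample_ids, rownames(M))
      if (anyNA(idx)) abort("covariate matrix is missing some samples.")
      M <- M[idx, , drop = FALSE]
    } else if (nrow(M) != length(sample_ids)) {
      abort("covariate matrix rows do not match the samples.")
    }
  }
  storage.mode(M) <- "double"
  if (!all(is.finite(M))) abort("covariates must be finite.")
  if (!is.null(k)) {
    if (ncol(M) < k) abort(sprintf("requested %d covariates, found %d.", k, ncol(M)))
    M <- M[, seq_len(k), drop = FALSE]
  }
  M
}

as_phenotype_vector <- function(y, sample_ids = NULL) {
  if (inherits(y, "pheno_result")) y <- y$values
  if (is.data.frame(y)) {
    if (is.null(sample_ids)) {
      return(list(ids = as.character(y[[1]]), values = as.numeric(y$value)))
    }
    idx <- match(sample_ids, as.character(y[[1]]))
    if (anyNA(idx)) abort("phenotype table is missing some samples.")
    return(list(ids = sample_ids, values = as.numeric(y$value[idx])))
  }
  list(ids = sample_ids, values = as.numeric(y))
}

# drop collinear columns (with a warning) and return an orthonormal basis
# for the column space of [1, C]
design_q <- function(C, n) {
  W <- cbind(`(Intercept)` = 1, C)
  qrW <- qr(W)
  if (qrW$rank < ncol(W)) {
    warn(sprintf("dropping %d collinear covariate column(s).",
                 ncol(W) - qrW$rank))
  }
  list(Q = qr.Q(qrW)[, seq_len(qrW$rank), drop = FALSE], rank = qrW$rank)
}

#' Proportion of phenotypic variance explained by covariates
#'
#' Least squares of the phenotype on an intercept plus the covariate
#' columns; reports raw and adjusted R-squared. At small sample sizes the
#' raw value sits at the chance level `c/n`, so model comparisons should
#' use the adjusted value.
#'
#' @param y A phenotype: `pheno_result`, tibble (`sample_id`, `value`), or
#'   numeric vector.
#' @param covariates A covariate tibble ([genotype_pca()] output), a
#'   [spectral_basis], or a matrix.
#' @param k Use only the first `k` covariate columns (default all).
#' @return One-row tibble: `r2`, `r2_adjusted`, `c` (covariate count after
#'   collinearity pruning), `n`.
#' @export
pve <- function(y, covariates, k = NULL) {
  ph <- as_phenotype_vector(y)
  C <- as_covariate_matrix(covariates, ph$ids, k = k)
  yv <- ph$values
  n <- length(yv)
  if (n <= ncol(C) + 1) abort("need n > c + 1 samples.")
  dq <- design_q(C, n)
  c_eff <- dq$rank - 1L
  yc <- yv - mean(yv)
  fit <- dq$Q %*% crossprod(dq$Q, yv)
  r2 <- 1 - sum((yv - fit)^2) / sum(yc^2)
  r2 <- max(0, min(1, r2))
  tibble(
    r2 = r2,
    r2_adjusted = 1 - (1 - r2) * (n - 1) / (n - c_eff - 1),
    c = c_eff,
    n = n
  )
}

#' How well do covariates predict deme-of-origin coordinates?
#'
#' Two least-squares fits — vertical (row) and horizontal (column) deme
#' index on the covariates — reporting the R-squared of each, the standard
#' summary of how much fine-scale structure a covariate set captures.
#'
#' @param covariates Covariate tibble, [spectral_basis], or matrix.
#' @param labels Deme labels (`sample_id`, `row`, `col`).
#' @param k Use only the first `k` covariate columns.
#' @return One-row tibble: `r2_vertical`, `r2_horizontal`, `c`, `n`.
#' @export
coordinate_r2 <- function(covariates, labels, k = NULL) {
  check_labels(labels)
  v <- pve(tibble(sample_id = labels$sample_id, value = labels$row),
           covariates, k = k)
  h <- pve(tibble(sample_id = labels$sample_id, value = labels$col),
           covariates, k = k)
  tibble(r2_vertical = v$r2, r2_horizontal = h$r2, c = v$c, n = v$n)
}

#' Covariate-adjusted per-variant linear association scan
#'
#' Residualizes the phenotype and every genotype column on the intercept
#' plus covariates through one QR factorization, then fits the per-variant
#' slope on the residuals — numerically identical to the full multiple
#' regression of `y` on `[1, covariates, g_j]` variant by variant.
#'
#' @param g A [geno_matrix()].
#' @param y Phenotype (`pheno_result`, tibble, or vector in sample order).
#' @param covariates Optional covariate tibble / [spectral_basis] / matrix.
#' @param k Use only the first `k` covariate columns.
#' @param block_size Variants per block (memory control).
#' @return A `gwas_result` tibble: `id`, `chromosome`, `position_bp`, `maf`,
#'   `beta`, `se`, `statistic` (t), `p` (floored at 1e-300), `chisq`
#'   (`t^2`), `n_used`, `monomorphic`. Monomorphic variants carry
#'   `beta = 0`, `p = 1` and are flagged for exclusion from inflation.
#' @export
gwas_linear <- function(g, y, covariates = NULL, k = NULL,
                        block_size = 4000) {
  stopifnot(inherits(g, "geno_matrix"))
  ph <- as_phenotype_vector(y, g$sample_ids)
  yv <- ph$values
  n <- n_samples(g)
  C <- as_covariate_matrix(covariates, g$sample_ids, k = k)
  if (n <= ncol(C) + 2) abort("need n > c + 2 samples.")
  dq <- design_q(C, n)
  Q <- dq$Q
  df <- n - dq$rank - 1L

  yres <- yv - Q %*% crossprod(Q, yv)
  yss <- sum(yres^2)

  m <- n_variants(g)
  beta <- se <- tstat <- pval <- numeric(m)
  n_used <- integer(m)
  mono <- logical(m)
  p_all <- allele_freqs(g)

  for (start in seq(1, m, by = block_size)) {
    idx <- start:min(start + block_size - 1, m)
    G <- impute_dosages(g$dosages[, idx, drop = FALSE])
    storage.mode(G) <- "double"
    Gres <- G - Q %*% crossprod(Q, G)
    gss <- colSums(Gres^2)
    gy <- as.numeric(crossprod(Gres, yres))
    ok <- gss > 1e-10
    b <- ifelse(ok, gy / gss, 0)
    rss <- pmax(yss - b^2 * gss, 0)
    s2 <- rss / df
    s <- ifelse(ok, sqrt(s2 / pmax(gss, 1e-300)), NA_real_)
    tv <- ifelse(ok & s > 0, b / s, 0)
    pv <- ifelse(ok, pmax(2 * pt(-abs(tv), df), 1e-300), 1)
    beta[idx] <- b; se[idx] <- s; tstat[idx] <- tv; pval[idx] <- pv
    mono[idx] <- !ok
    n_used[idx] <- colSums(!is.na(g$dosages[, idx, drop = FALSE]))
  }

  out <- tibble(
    id = g$variants$id,
    chromosome = g$variants$chromosome,
    position_bp = g$variants$position_bp,
    maf = pmin(p_all, 1 - p_all),
    beta = beta, se = se, statistic = tstat, p = pval,
    chisq = tstat^2, n_used = n_used, monomorphic = mono
  )
  attr(out, "df") <- df
  attr(out, "n") <- n
  attr(out, "kind") <- attr(covariates, "kind") %||%
    if (inherits(covariates, "spectral_basis")) "SPC" else "custom"
  class(out) <- c("gwas_result", class(out))
  out
}

#' Genomic inflation factor with bootstrap confidence interval
#'
#' `lambda = median(chisq) / 0.4549364231` (the chi-square(1) median),
#' computed over usable (non-monomorphic) variants, with a seeded
#' percentile bootstrap over variants for the confidence interval.
#'
#' @param res A [gwas_linear()] result, or a numeric vector of chi-square
#'   statistics.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param conf Confidence level.
#' @return One-row tibble: `lambda`, `ci_low`, `ci_high`, `n_variants`,
#'   `n_boot`.
#' @export
genomic_inflation <- function(res, n_boot = 1000, seed = 1, conf = 0.95) {
  chisq <- if (is.numeric(res)) res else res$chisq[!res$monomorphic]
  chisq <- chisq[is.finite(chisq)]
  if (length(chisq) < 100) {
    abort(sprintf("need at least 100 usable variants, got %d.", length(chisq)))
  }
  chi_med <- 0.4549364231
  lambda <- median(chisq) / chi_med
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    median(chisq[sample.int(length(chisq), replace = TRUE)]) / chi_med
  }, numeric(1))
  a <- (1 - conf) / 2
  ci <- quantile(boots, c(a, 1 - a), names = FALSE)
  tibble(
    lambda = lambda,
    ci_low = min(ci[1], lambda),
    ci_high = max(ci[2], lambda),
    n_variants = length(chisq),
    n_boot = n_boot
  )
}

#' Moran's I spatial autocorrelation
#'
#' `I = (n / W) * sum_ij w_ij (x_i - xbar)(x_j - xbar) / sum_i (x_i -
#' xbar)^2` with `W` the total weight. The null expectation under random
#' permutation of values is `-1/(n-1)`.
#'
#' @param values Numeric vector of per-unit values (e.g. per-deme phenotype
#'   means).
#' @param weights Symmetric non-negative weight matrix with zero diagonal.
#' @param row_standardize Divide each row of `weights` by its sum first?
#' @return One-row tibble: `I`, `expected_null`, `n`, `W`.
#' @export
morans_i <- function(values, weights, row_standardize = FALSE) {
  values <- as.numeric(values)
  n <- length(values)
  if (n < 3) abort("need at least 3 units.")
  weights <- as.matrix(weights)
  if (!isTRUE(all.equal(weights, t(weights))) && !row_standardize) {
    abort("weights must be symmetric (or row-standardized).")
  }
  if (any(diag(weights) != 0)) abort("weights must have a zero diagonal.")
  if (any(weights < 0)) abort("weights must be non-negative.")
  if (row_standardize) {
    rs <- rowSums(weights)
    rs[rs == 0] <- 1
    weights <- weights / rs
  }
  W <- sum(weights)
  if (W == 0) abort("all weights are zero.")
  x <- values - mean(values)
  denom <- sum(x^2)
  if (denom == 0) abort("values are constant; Moran's I is undefined.")
  I <- (n / W) * as.numeric(t(x) %*% weights %*% x) / denom
  tibble(I = I, expected_null = -1 / (n - 1), n = n, W = W)
}

#' Rook-adjacency weights over the demes of a grid
#'
#' @param labels Deme labels (`sample_id`, `row`, `col`).
#' @return Binary adjacency matrix over the distinct demes (sorted by row,
#'   then column), with dimnames `"row_col"`.
#' @export
deme_rook_weights <- function(labels) {
  check_labels(labels)
  demes <- dplyr::distinct(labels[, c("row", "col")])
  demes <- arrange(demes, .data$row, .data$col)
  nm <- paste0(demes$row, "_", demes$col)
  nd <- nrow(demes)
  Wm <- matrix(0, nd, nd, dimnames = list(nm, nm))
  for (i in seq_len(nd)) {
    adj <- abs(demes$row - demes$row[i]) + abs(demes$col - demes$col[i]) == 1
    Wm[i, adj] <- 1
  }
  Wm
}

#' Moran's I of per-deme phenotype means
#'
#' Averages a per-sample phenotype (typically residuals after covariate
#' adjustment) within demes and computes Moran's I under rook adjacency.
#'
#' @param y Phenotype (`pheno_result`, tibble, or vector in label order).
#' @param labels Deme labels.
#' @param covariates Optional covariates to residualize on first.
#' @param k Use only the first `k` covariate columns.
#' @return As [morans_i()].
#' @export
moran_deme <- function(y, labels, covariates = NULL, k = NULL) {
  check_labels(labels)
  ph <- as_phenotype_vector(y, labels$sample_id)
  yv <- ph$values
  if (!is.null(covariates)) {
    C <- as_covariate_matrix(covariates, labels$sample_id, k = k)
    Q <- design_q(C, length(yv))$Q
    yv <- as.numeric(yv - Q %*% crossprod(Q, yv))
  }
  key <- paste0(labels$row, "_", labels$col)
  Wm <- deme_rook_weights(labels)
  mu <- tapply(yv, key, mean)[rownames(Wm)]
  morans_i(as.numeric(mu), Wm)
}

#' Compare two association scans stratified by causal status
#'
#' Classifies variants as `causal`, `ld` (maximum r-squared with any causal
#' variant within `window_bp` strictly exceeds `ld_r2`), or `non_causal`,
#' then runs a Wilcoxon rank-sum test on `-log10(p)` between the two scans
#' within each stratum and reports the mean absolute effect size per
#' stratum per scan.
#'
#' @param res_a,res_b Two [gwas_linear()] results over identical variants.
#' @param causal Causal variant ids (e.g. `pheno$causal_set$id`).
#' @param g The [geno_matrix()] the scans were run on (for LD).
#' @param ld_r2 LD classification threshold (strict `>`).
#' @param window_bp Window around each causal variant searched for LD.
#' @return Tibble: one row per non-empty stratum with `stratum`,
#'   `n_variants`, `wilcoxon_p`, `mean_abs_beta_a`, `mean_abs_beta_b`,
#'   `mean_mlog10p_a`, `mean_mlog10p_b`.
#' @export
stratified_pvalue_comparison <- function(res_a, res_b, causal, g,
                                         ld_r2 = 0.1, window_bp = 1e6) {
  if (!identical(res_a$id, res_b$id)) {
    abort("the two scans must cover identical variant lists.")
  }
  ids <- res_a$id
  is_causal <- ids %in% causal
  in_ld <- rep(FALSE, length(ids))
  if (any(is_causal) && any(!is_causal)) {
    X <- impute_dosages(g$dosages)
    storage.mode(X) <- "double"
    pos <- g$variants$position_bp
    chr <- g$variants$chromosome
    causal_idx <- which(is_causal)
    for (ci in causal_idx) {
      near <- which(chr == chr[ci] & abs(pos - pos[ci]) <= window_bp &
                      !is_causal & !in_ld)
      if (length(near) == 0) next
      r <- suppressWarnings(stats::cor(X[, ci], X[, near, drop = FALSE]))
      r2 <- as.numeric(r)^2
      r2[is.na(r2)] <- 0
      in_ld[near[r2 > ld_r2]] <- TRUE
    }
  }
  stratum <- ifelse(is_causal, "causal", ifelse(in_ld, "ld", "non_causal"))
  purrr::map_dfr(c("causal", "ld", "non_causal"), function(s) {
    sel <- stratum == s
    if (!any(sel)) return(NULL)
    la <- -log10(res_a$p[sel])
    lb <- -log10(res_b$p[sel])
    wp <- if (isTRUE(all.equal(la, lb))) 1 else
      suppressWarnings(wilcox.test(la, lb)$p.value)
    tibble(
      stratum = s, n_variants = sum(sel), wilcoxon_p = wp,
      mean_abs_beta_a = mean(abs(res_a$beta[sel])),
      mean_abs_beta_b = mean(abs(res_b$beta[sel])),
      mean_mlog10p_a = mean(la), mean_mlog10p_b = mean(lb)
    )
  })
}

#' Haseman-Elston heritability regression
#'
#' Moment-based narrow-sense heritability: the genetic relatedness matrix
#' (GRM) is built from standardized genotypes (`GRM = Z Z' / M`), the
#' phenotype is residualized on the intercept plus covariates and
#' re-standardized, and the slope of `y_i * y_j` on `GRM_ij` over all
#' `i < j` pairs estimates `h2` (clipped to `[0, 1]`). The standard error
#' is a delete-one-sample jackknife.
#'
#' @param g A [geno_matrix()], or a precomputed symmetric GRM matrix.
#' @param y Phenotype.
#' @param covariates Optional covariates to residualize on.
#' @param k Use only the first `k` covariate columns.
#' @return One-row tibble: `h2`, `se`, `slope` (unclipped), `n`, `m_pairs`.
#' @export
he_heritability <- function(g, y, covariates = NULL, k = NULL) {
  if (inherits(g, "geno_matrix")) {
    ids <- g$sample_ids
    pall <- allele_freqs(g)
    poly <- which(pall > 0 & pall < 1)
    K <- matrix(0, n_samples(g), n_samples(g))
    block <- 10000L
    for (start in seq(1, length(poly), by = block)) {
      idx <- poly[start:min(start + block - 1L, length(poly))]
      X <- impute_dosages(g$dosages[, idx, drop = FALSE])
      storage.mode(X) <- "double"
      p <- colMeans(X) / 2
      Z <- sweep(sweep(X, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
      K <- K + tcrossprod(Z)
    }
    K <- K / length(poly)
  } else {
    K <- as.matrix(g)
    ids <- rownames(K)
  }
  n <- nrow(K)
  if (n < 50) abort("Haseman-Elston regression needs n >= 50 samples.")
  ph <- as_phenotype_vector(y, ids)
  yv <- ph$values
  C <- as_covariate_matrix(covariates, ids %||% seq_len(n), k = k)
  Q <- design_q(C, n)$Q
  yv <- as.numeric(yv - Q %*% crossprod(Q, yv))
  yv <- (yv - mean(yv)) / sd(yv)

  P <- tcrossprod(yv)  # y_i y_j
  diag(K) <- 0
  diag(P) <- 0
  # per-sample row aggregates; each unordered pair appears once in i<j sums
  rx <- rowSums(K); rp <- rowSums(P)
  rxx <- rowSums(K^2); rxy <- rowSums(K * P)
  Sx <- sum(rx) / 2; Sy <- sum(rp) / 2
  Sxx <- sum(rxx) / 2; Sxy <- sum(rxy) / 2
  m <- n * (n - 1) / 2

  he_slope <- function(sx, sy, sxx, sxy, mm) {
    (sxy - sx * sy / mm) / (sxx - sx^2 / mm)
  }
  slope <- he_slope(Sx, Sy, Sxx, Sxy, m)
  loo <- vapply(seq_len(n), function(i) {
    he_slope(Sx - rx[i], Sy - rp[i], Sxx - rxx[i], Sxy - rxy[i],
             m - (n - 1))
  }, numeric(1))
  se <- sqrt((n - 1) / n * sum((loo - mean(loo))^2))
  tibble(
    h2 = max(0, min(1, slope)),
    se = se, slope = slope, n = n, m_pairs = m
  )
}
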