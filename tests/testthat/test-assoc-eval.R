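test_that("PCA separates two diverged populations with full sign concordance", {
  g <- make_two_pop_genotypes(n_per_pop = 40, m = 300, fst_delta = 0.4)
  pc <- genotype_pca(g, k = 4)
  pc1 <- pc$PC1
  pop <- rep(1:2, each = 40)
  conc <- max(mean(sign(pc1) == ifelse(pop == 1, 1, -1)),
              mean(sign(pc1) == ifelse(pop == 1, -1, 1)))
  expect_equal(conc, 1)
})

test_that("PCA matches the dense SVD oracle", {
  g <- make_null_genotypes(n = 25, m = 120, seed = 19)
  k <- 24
  pc <- genotype_pca(g, k = k)
  # oracle: explicit standardization + svd
  X <- ibdspc:::impute_dosages(g$dosages)
  storage.mode(X) <- "double"
  p <- colMeans(X) / 2
  keep <- p > 0 & p < 1
  X <- X[, keep, drop = FALSE]
  p <- p[keep]
  X <- sweep(sweep(X, 2, 2 * p, "-"), 2, sqrt(2 * p * (1 - p)), "/")
  U <- svd(X)$u[, 1:k]
  sv <- svd(crossprod(as.matrix(pc[, -1]), U))$d
  expect_equal(sv, rep(1, k), tolerance = 1e-8)
})

test_that("PVE is exact for self-prediction and near chance for noise", {
  set.seed(41)
  n <- 1000
  y <- rnorm(n)
  ids <- sprintf("x%04d", 1:n)
  ytab <- tibble::tibble(sample_id = ids, value = y)
  self <- tibble::tibble(sample_id = ids, v = y)
  expect_equal(pve(ytab, self)$r2, 1, tolerance = 1e-12)

  C <- matrix(rnorm(n * 25), n, 25)
  noise <- dplyr::bind_cols(tibble::tibble(sample_id = ids),
                            tibble::as_tibble(C, .name_repair = "minimal"))
  names(noise)[-1] <- paste0("C", 1:25)
  pv <- pve(ytab, noise)
  expect_lt(abs(pv$r2 - 25 / n), 0.02)
  expect_lt(abs(pv$r2_adjusted), 0.02)
})

test_that("PVE is invariant to invertible remixing of covariates", {
  set.seed(43)
  n <- 300
  C <- matrix(rnorm(n * 6), n, 6)
  y <- C %*% rnorm(6) + rnorm(n)
  M <- matrix(rnorm(36), 6, 6)
  while (abs(det(M)) < 1e-3) M <- matrix(rnorm(36), 6, 6)
  ids <- sprintf("s%03d", 1:n)
  ytab <- tibble::tibble(sample_id = ids, value = as.numeric(y))
  a <- pve(ytab, `rownames<-`(C, ids))
  b <- pve(ytab, `rownames<-`(C %*% M, ids))
  expect_equal(a$r2, b$r2, tolerance = 1e-10)
})

test_that("coordinate R2 is 1 for one-hot deme indicators, chance for noise", {
  labels <- make_grid_labels(3, 30)
  deme <- factor(paste(labels$row, labels$col))
  onehot <- stats::model.matrix(~ deme - 1)
  rownames(onehot) <- labels$sample_id
  # the intercept makes the full one-hot basis rank-deficient by one;
  # both axis fits warn once
  expect_warning(
    expect_warning(r <- coordinate_r2(onehot, labels), "collinear"),
    "collinear"
  )
  expect_equal(r$r2_vertical, 1, tolerance = 1e-10)
  expect_equal(r$r2_horizontal, 1, tolerance = 1e-10)

  set.seed(3)
  noise <- matrix(rnorm(nrow(labels) * 10), ncol = 10)
  rownames(noise) <- labels$sample_id
  rn <- coordinate_r2(noise, labels)
  expect_lt(rn$r2_vertical, 10 / nrow(labels) + 0.05)
})

test_that("per-variant scan equals the full multiple-regression oracle", {
  set.seed(47)
  g <- make_null_genotypes(n = 120, m = 100, seed = 53)
  C <- matrix(rnorm(120 * 3), 120, 3)
  rownames(C) <- g$sample_ids
  y <- rnorm(120) + C %*% c(0.5, -0.3, 0.2)
  ytab <- tibble::tibble(sample_id = g$sample_ids, value = as.numeric(y))
  res <- gwas_linear(g, ytab, C)
  expect_equal(res$chisq, res$statistic^2, tolerance = 1e-9)
  for (j in sample(100, 20)) {
    x <- ibdspc:::impute_dosages(g$dosages[, j, drop = FALSE])
    fit <- summary(lm(y ~ C + x))$coefficients
    expect_equal(res$beta[j], fit["x", 1], tolerance = 1e-8)
    expect_equal(res$p[j], fit["x", 4], tolerance = 1e-8)
  }
})

test_that("a phenotype duplicated as a variant maxes out the scan", {
  set.seed(59)
  n <- 80
  y <- rnorm(n)
  dos <- pmin(pmax(round(y - min(y)) %% 3, 0), 2)
  g <- geno_matrix(
    cbind(v1 = dos, v2 = stats::rbinom(n, 2, 0.4)),
    tibble::tibble(chromosome = 1L, position_bp = c(100, 200), ref = "A",
                   alt = "G", id = c("v1", "v2")),
    sprintf("s%02d", 1:n)
  )
  ytab <- tibble::tibble(sample_id = g$sample_ids, value = as.numeric(dos))
  res <- gwas_linear(g, ytab)
  expect_equal(res$beta[1], 1, tolerance = 1e-9)
  expect_equal(res$p[1], 1e-300)  # underflow floor
})

test_that("null GWAS p-values are uniform", {
  g <- make_null_genotypes(n = 250, m = 5000, seed = 61)
  set.seed(62)
  ytab <- tibble::tibble(sample_id = g$sample_ids, value = rnorm(250))
  res <- gwas_linear(g, ytab)
  ks <- stats::ks.test(res$p[!res$monomorphic], "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("monomorphic variants are flagged and excluded from inflation", {
  dos <- cbind(v1 = rep(1L, 60), v2 = stats::rbinom(60, 2, 0.5))
  dos[, 1] <- 1L
  g <- geno_matrix(
    dos,
    tibble::tibble(chromosome = 1L, position_bp = c(1, 2) * 100, ref = "A",
                   alt = "G", id = c("v1", "v2")),
    sprintf("s%02d", 1:60)
  )
  set.seed(5)
  ytab <- tibble::tibble(sample_id = g$sample_ids, value = rnorm(60))
  res <- gwas_linear(g, ytab)
  expect_true(res$monomorphic[1])
  expect_equal(res$p[1], 1)
  expect_equal(res$beta[1], 0)
})

test_that("genomic inflation is exact on constants and scale-equivariant", {
  chi_med <- 0.4549364231
  x <- rep(chi_med, 500)
  expect_equal(genomic_inflation(x, n_boot = 50)$lambda, 1)
  set.seed(8)
  z <- stats::rchisq(5000, 1)
  l1 <- genomic_inflation(z, n_boot = 50, seed = 2)$lambda
  l2 <- genomic_inflation(2 * z, n_boot = 50, seed = 2)$lambda
  expect_equal(l2, 2 * l1, tolerance = 1e-12)
  expect_error(genomic_inflation(z[1:50]), "at least 100")
})

test_that("chi-square(1) draws give lambda near 1 with covering CI", {
  set.seed(71)
  z <- stats::rchisq(10000, 1)
  inf <- genomic_inflation(z, n_boot = 500, seed = 3)
  expect_equal(inf$lambda, 1, tolerance = 0.03)
  expect_lte(inf$ci_low, 1)
  expect_gte(inf$ci_high, 1)
  expect_true(inf$ci_low <= inf$lambda && inf$lambda <= inf$ci_high)
})

test_that("Moran's I matches hand-computed values", {
  # chain 1-2-3-4 with values 1,2,3,4, raw binary weights:
  # deviations (-1.5,-0.5,.5,1.5), cross-sum 2*(0.75-0.25+0.75)=2.5,
  # denominator 5, W=6  ->  I = (4/6)*(2.5/5) = 1/3
  W <- matrix(0, 4, 4)
  for (i in 1:3) W[i, i + 1] <- W[i + 1, i] <- 1
  expect_equal(morans_i(1:4, W)$I, 1 / 3, tolerance = 1e-12)
  # same chain row-standardized: cross-sum 2, total weight 4 -> I = 0.4
  expect_equal(morans_i(1:4, W, row_standardize = TRUE)$I, 0.4,
               tolerance = 1e-12)

  # checkerboard on a 4x4 rook grid: perfect alternation gives I = -1
  grid <- expand.grid(row = 0:3, col = 0:3)
  Wg <- matrix(0, 16, 16)
  for (i in 1:16) {
    for (j in 1:16) {
      Wg[i, j] <- as.numeric(
        abs(grid$row[i] - grid$row[j]) + abs(grid$col[i] - grid$col[j]) == 1
      )
    }
  }
  vals <- (-1)^(grid$row + grid$col)
  expect_equal(morans_i(vals, Wg)$I, -1, tolerance = 1e-12)

  # permutation null mean is -1/(n-1)
  set.seed(81)
  x <- rnorm(16)
  perms <- replicate(10000, morans_i(sample(x), Wg)$I)
  expect_lt(abs(mean(perms) + 1 / 15), 0.01)

  expect_error(morans_i(rep(1, 4), W), "constant")
  expect_error(morans_i(1:4, W * 0), "zero")
})

test_that("stratified comparison classifies by LD and degenerates sanely", {
  g <- make_null_genotypes(n = 150, m = 60, seed = 83)
  # make v2 a near-copy of v1 (high LD), v50 far away
  g$dosages[, 2] <- g$dosages[, 1]
  flip <- sample(150, 8)
  g$dosages[flip, 2] <- 2L - g$dosages[flip, 2]
  set.seed(84)
  ytab <- tibble::tibble(sample_id = g$sample_ids, value = rnorm(150))
  res <- gwas_linear(g, ytab)
  rep_res <- stratified_pvalue_comparison(res, res, causal = "v1", g = g,
                                          ld_r2 = 0.1, window_bp = 1e5)
  expect_true(all(rep_res$wilcoxon_p == 1))
  expect_equal(rep_res$n_variants[rep_res$stratum == "causal"], 1)
  expect_gte(rep_res$n_variants[rep_res$stratum == "ld"], 1)

  # empty truth: everything non-causal
  rep2 <- stratified_pvalue_comparison(res, res, causal = character(0), g = g)
  expect_equal(rep2$stratum, "non_causal")
  expect_equal(rep2$n_variants, 60)
})

test_that("LD classification uses a strict threshold", {
  set.seed(85)
  g <- make_null_genotypes(n = 200, m = 10, seed = 86)
  res <- gwas_linear(
    g, tibble::tibble(sample_id = g$sample_ids, value = rnorm(200))
  )
  r2_with_v1 <- sapply(2:10, function(j) {
    cor(g$dosages[, 1], g$dosages[, j])^2
  })
  thr <- max(r2_with_v1)  # exactly at the maximum: strict > excludes it
  rep_res <- stratified_pvalue_comparison(res, res, causal = "v1", g = g,
                                          ld_r2 = thr, window_bp = 1e9)
  expect_true(!"ld" %in% rep_res$stratum)
})

test_that("Haseman-Elston recovers heritability and the null", {
  g <- make_null_genotypes(n = 400, m = 2000, seed = 91)
  ph <- simulate_polygenic(g, h2 = 0.8, seed = 92)
  est <- he_heritability(g, ph)
  expect_lt(abs(est$h2 - 0.8), 3 * est$se)

  set.seed(93)
  noise <- tibble::tibble(sample_id = g$sample_ids, value = rnorm(400))
  est0 <- he_heritability(g, noise)
  expect_lt(est0$slope, 2 * est0$se + 0.05)

  # single-variant genetic limit
  g1 <- make_null_genotypes(n = 200, m = 1, seed = 94)
  z <- scale(ibdspc:::impute_dosages(g1$dosages))[, 1]
  yg <- tibble::tibble(sample_id = g1$sample_ids, value = z)
  expect_gt(he_heritability(g1, yg)$h2, 0.95)

  expect_error(he_heritability(make_null_genotypes(n = 20, m = 10), noise[1:20, ]),
               "n >= 50")
})
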