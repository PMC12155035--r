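#' Environmental smooth phenotype
#'
#' A non-heritable phenotype with a North-South gradient: values are drawn
#' independently from `Normal(mean_row, sigma^2)` where the row mean falls
#' linearly from `2*sigma` on the top row to 0 on the bottom row, i.e.
#' `mean_row(r) = 2*sigma*(R-1-r)/(R-1)` for row `r` in `0..R-1` counted
#' from the top. On a 5-row grid the row means are `2, 1.5, 1, 0.5, 0`
#' (times sigma).
#'
#' @param labels Deme labels tibble (`sample_id`, `row`, `col`) as produced
#'   by [simulate_grid()].
#' @param sigma Within-deme standard deviation.
#' @param seed Integer seed.
#' @return An object of class `pheno_result`; `tidy()` gives a tibble of
#'   `sample_id`, `value`.
#' @export
simulate_smooth <- function(labels, sigma = 1, seed = 1) {
  check_labels(labels)
  if (sigma <= 0) abort("sigma must be > 0.")
  rows <- sort(unique(labels$row))
  R <- length(rows)
  if (R < 2) abort("smooth phenotype needs a grid with at least 2 rows.")
  r_idx <- match(labels$row, rows) - 1L  # 0-based from the top
  mu <- 2 * sigma * (R - 1 - r_idx) / (R - 1)
  set.seed(seed)
  values <- rnorm(nrow(labels), mean = mu, sd = sigma)
  new_pheno_result(labels$sample_id, values, kind = "smooth",
                   params = list(sigma = sigma, seed = seed))
}

#' Environmental sharp phenotype
#'
#' A non-heritable phenotype concentrated in one deme: samples in the target
#' deme are drawn from `Normal(mu, (sd_multiplier*sigma)^2)`, everyone else
#' from `Normal(0, sigma^2)`. `sd_multiplier = 1` is the baseline design;
#' `sd_multiplier = 2` doubles the target deme's spread, the variant used
#' when stressing non-linear environmental effects.
#'
#' @inheritParams simulate_smooth
#' @param mu Mean in the target deme.
#' @param target_deme Length-2 integer `(row, col)` of the affected deme.
#' @param sd_multiplier Standard-deviation multiplier for the target deme.
#' @return A `pheno_result`.
#' @export
simulate_sharp <- function(labels, mu = 2, sigma = 1,
                           target_deme = c(0, 0), sd_multiplier = 1,
                           seed = 1) {
  check_labels(labels)
  if (sigma <= 0) abort("sigma must be > 0.")
  in_target <- labels$row == target_deme[1] & labels$col == target_deme[2]
  if (!any(in_target)) {
    abort(sprintf("target deme (%d, %d) is not on the grid.",
                  target_deme[1], target_deme[2]))
  }
  set.seed(seed)
  values <- rnorm(
    nrow(labels),
    mean = ifelse(in_target, mu, 0),
    sd = ifelse(in_target, sd_multiplier * sigma, sigma)
  )
  new_pheno_result(labels$sample_id, values, kind = "sharp",
                   params = list(mu = mu, sigma = sigma,
                                 target_deme = target_deme,
                                 sd_multiplier = sd_multiplier, seed = seed))
}

#' Polygenic phenotype
#'
#' A heritable phenotype with no deme-level environmental effect. One causal
#' SNP is chosen uniformly at random from every 1 kb window (half-open
#' `[w*window_bp, (w+1)*window_bp)` per chromosome) that contains at least
#' one segregating site. Effect sizes are frequency-scaled,
#' `beta_j ~ Normal(0, [2 p_j (1 - p_j)]^alpha)`; `alpha = -1` equalizes
#' each variant's expected contribution regardless of frequency, damping
#' drift-driven deme differences in the genetic score. The raw score
#' `G = X beta` is rescaled so its in-sample variance is exactly `h2`, and
#' the noise term is residualized against `G` and rescaled to variance
#' `1 - h2`, so the realized heritability equals `h2` to machine precision.
#'
#' @param g A [geno_matrix()].
#' @param h2 Target narrow-sense heritability in `(0, 1]`.
#' @param alpha Frequency-scaling exponent.
#' @param window_bp Causal-window width in bp.
#' @param seed Integer seed.
#' @return A `pheno_result` with `causal_set` (tibble of variant `id`,
#'   `beta`) and `realized_h2`.
#' @export
simulate_polygenic <- function(g, h2 = 0.8, alpha = -1, window_bp = 1000,
                               seed = 1) {
  stopifnot(inherits(g, "geno_matrix"))
  if (h2 <= 0 || h2 > 1) abort("h2 must be in (0, 1].")
  if (window_bp < 1) abort("window_bp must be >= 1.")
  p <- allele_freqs(g)
  segregating <- which(p > 0 & p < 1)
  if (length(segregating) == 0) abort("no segregating sites available.")

  set.seed(seed)
  win <- paste0(
    g$variants$chromosome, ":",
    (g$variants$position_bp - 1) %/% window_bp
  )
  causal <- vapply(
    split(segregating, win[segregating]),
    function(idx) if (length(idx) == 1) idx else sample(idx, 1),
    integer(1)
  )
  causal <- sort(unname(causal))

  pj <- p[causal]
  beta <- rnorm(length(causal), 0, sqrt((2 * pj * (1 - pj))^alpha))
  X <- impute_dosages(g$dosages[, causal, drop = FALSE])
  G <- as.numeric(X %*% beta)
  G <- G - mean(G)
  sdG <- sd(G)
  if (sdG == 0) abort("degenerate genetic score (all-equal); try another seed.")
  scale_g <- sqrt(h2) / sdG
  G <- G * scale_g

  eps <- rnorm(nrow(X))
  if (h2 < 1) {
    eps <- eps - mean(eps)
    eps <- eps - G * sum(eps * G) / sum(G * G)  # kill in-sample correlation
    eps <- eps * sqrt(1 - h2) / sd(eps)
  } else {
    eps <- 0
  }
  values <- G + eps
  realized <- var(G) / var(values)

  res <- new_pheno_result(
    g$sample_ids, values, kind = "polygenic",
    params = list(h2 = h2, alpha = alpha, window_bp = window_bp, seed = seed)
  )
  res$causal_set <- tibble(
    id = g$variants$id[causal],
    index = causal,
    beta = beta * scale_g
  )
  res$realized_h2 <- realized
  res$genetic_score <- G
  res
}

new_pheno_result <- function(sample_ids, values, kind, params) {
  structure(
    list(
      values = tibble(sample_id = sample_ids, value = values),
      kind = kind,
      params = params,
      causal_set = tibble(id = character(), index = integer(),
                          beta = double()),
      realized_h2 = NULL
    ),
    class = "pheno_result"
  )
}

#' @export
print.pheno_result <- function(x, ...) {
  cat(sprintf("<pheno_result> '%s', %d samples", x$kind, nrow(x$values)))
  if (!is.null(x$realized_h2)) {
    cat(sprintf(", realized h2 = %.3f", x$realized_h2))
  }
  cat("\n")
  invisible(x)
}

#' @rdname simulate_smooth
#' @param x A `pheno_result`.
#' @param ... Unused.
#' @export
tidy.pheno_result <- function(x, ...) x$values

#' Write a phenotype in PLINK convention (`FID IID value`)
#'
#' @param x A `pheno_result` or tibble with `sample_id`, `value`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotype <- function(x, path) {
  if (inherits(x, "pheno_result")) x <- x$values
  utils::write.table(
    data.frame(x$sample_id, x$sample_id,
               format(x$value, digits = 15, trim = TRUE)),
    path, quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

check_labels <- function(labels) {
  if (!all(c("sample_id", "row", "col") %in% names(labels))) {
    abort("labels must have columns sample_id, row, col.")
  }
  invisible(labels)
}
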