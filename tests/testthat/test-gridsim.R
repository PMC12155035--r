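test_that("config validation and chromosome metadata", {
  expect_error(deme_grid_config(grid_n = 0), "grid_n")
  expect_error(deme_grid_config(t_ancestral = 100, t_dtwf = 200), "t_dtwf")
  expect_error(deme_grid_config(migration_rate = -0.1), "rates")

  tb <- chromosome_table("chr1")
  expect_equal(tb$length_bp, 248956422)
  expect_equal(tb$recomb_rate, 1.149e-8)
  expect_equal(nrow(chromosome_table("all")), 22)

  p <- grid_preset("small4x4")
  expect_equal(p$grid_n * p$grid_n * p$diploids_per_deme, 1600L)
  p8 <- grid_preset("full8k")
  expect_equal(p8$grid_n^2 * p8$diploids_per_deme, 8000L)
  expect_equal(nrow(p8$chromosomes), 22)
})

test_that("simulated cohorts have the right shape and labels", {
  sim <- tiny_sim()
  cfg <- sim$config
  expect_equal(n_samples(sim$genotypes),
               cfg$grid_n^2 * cfg$diploids_per_deme)
  expect_equal(nrow(sim$labels), n_samples(sim$genotypes))
  expect_equal(nrow(dplyr::distinct(sim$labels[, c("row", "col")])),
               cfg$grid_n^2)
  expect_true(all(sim$labels$row >= 0 & sim$labels$row < cfg$grid_n))
  expect_true(all(sim$labels$col >= 0 & sim$labels$col < cfg$grid_n))
  expect_true(all(sim$genotypes$dosages %in% 0:2))
  expect_false(is.unsorted(sim$genotypes$variants$position_bp))
})

test_that("the same seed reproduces genotypes and IBD bit-identically", {
  cfg <- deme_grid_config(
    grid_n = 2, diploids_per_deme = 15,
    chromosomes = tibble::tibble(name = "1", length_bp = 8e6,
                                 recomb_rate = 1.149e-8),
    max_variants = 1000, seed = 77
  )
  a <- simulate_grid(cfg)
  b <- simulate_grid(cfg)
  expect_identical(a$genotypes$dosages, b$genotypes$dosages)
  expect_identical(a$labels, b$labels)
  ia <- extract_true_ibd(a, min_cM = 3)
  ib <- extract_true_ibd(b, min_cM = 3)
  expect_identical(as.data.frame(ia), as.data.frame(ib))
})

test_that("true IBD respects the length floor and shrinks as it rises", {
  sim <- tiny_sim()
  expect_error(extract_true_ibd(sim, min_cM = 0), "min_cM")
  totals <- sapply(c(2, 3, 5), function(mc) {
    seg <- extract_true_ibd(sim, min_cM = mc)
    expect_gte(min(seg$length_cM), mc)
    sum(aggregate_pairwise(seg)$total_cM)
  })
  expect_true(all(diff(totals) <= 0))
})

test_that("IBD sharing decays with grid distance", {
  sim <- tiny_sim()  # 3x3 grid
  seg <- extract_true_ibd(sim, min_cM = 3)
  pairs <- aggregate_pairwise(seg)
  deme_of <- setNames(paste0(sim$labels$row, "_", sim$labels$col),
                      sim$labels$sample_id)
  rc <- function(id) as.integer(strsplit(deme_of[[id]], "_")[[1]])
  dist_class <- mapply(function(a, b) {
    d <- sum(abs(rc(a) - rc(b)))
    if (d == 0) "within" else if (d == 1) "adjacent" else "far"
  }, pairs$id_a, pairs$id_b)
  # mean per-pair total over *all* pairs in each class (non-sharing pairs
  # count zero)
  n_per_deme <- sim$config$diploids_per_deme
  n_demes <- sim$config$grid_n^2
  tot <- tapply(pairs$total_cM, dist_class, sum)
  n_within_pairs <- n_demes * choose(n_per_deme, 2)
  n_adj_pairs <- 12 * n_per_deme^2  # 12 rook-adjacent deme pairs on 3x3
  mean_within <- tot[["within"]] / n_within_pairs
  mean_adj <- tot[["adjacent"]] / n_adj_pairs
  expect_gt(mean_within, mean_adj)
  if (!is.na(tot["far"])) {
    n_far_pairs <- (choose(n_demes, 2) - 12) * n_per_deme^2
    expect_gt(mean_adj, tot[["far"]] / n_far_pairs)
  }
})

test_that("adjacent demes are weakly but positively differentiated", {
  sim <- tiny_sim()
  g <- filter_by_frequency(sim$genotypes, maf_gt = 0.05)
  deme <- paste0(sim$labels$row, "_", sim$labels$col)
  # Hudson-style Fst between two adjacent demes, averaged over variants
  fst_pair <- function(d1, d2) {
    i1 <- deme == d1
    i2 <- deme == d2
    p1 <- colMeans(g$dosages[i1, , drop = FALSE]) / 2
    p2 <- colMeans(g$dosages[i2, , drop = FALSE]) / 2
    n1 <- sum(i1) * 2
    n2 <- sum(i2) * 2
    num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
    den <- p1 * (1 - p2) + p2 * (1 - p1)
    sum(num) / sum(den)
  }
  adj <- list()
  for (r in 0:2) for (co in 0:2) {
    if (co < 2) adj <- c(adj, list(c(paste0(r, "_", co), paste0(r, "_", co + 1))))
    if (r < 2) adj <- c(adj, list(c(paste0(r, "_", co), paste0(r + 1, "_", co))))
  }
  fsts <- vapply(adj, function(p) fst_pair(p[1], p[2]), numeric(1))
  # per-pair estimates are noisy at 25 diploids/deme; the mean over all 12
  # rook-adjacent pairs is the stable quantity
  expect_gt(mean(fsts), 0)
  expect_lt(mean(fsts), 0.01)
  expect_true(all(fsts < 0.02))
})

test_that("frequency filters apply strict bounds and are idempotent", {
  # engineered frequencies: p = 0.005, 0.05, 0.5 over 200 samples
  n <- 200
  dos <- cbind(
    v1 = c(rep(1L, 2), rep(0L, n - 2)),        # p = 0.005
    v2 = c(rep(1L, 20), rep(0L, n - 20)),      # p = 0.05
    v3 = c(rep(1L, n / 2), rep(0L, n / 2)),    # p = 0.25 -> use dosage 2
    v4 = rep(1L, n)                            # p = 0.5 het everywhere
  )
  g <- geno_matrix(
    dos,
    tibble::tibble(chromosome = 1L, position_bp = 1:4 * 100, ref = "A",
                   alt = "G", id = paste0("v", 1:4)),
    sprintf("s%03d", 1:n)
  )
  kept <- filter_by_frequency(g, maf_gt = 0.01)
  expect_equal(kept$variants$id, c("v2", "v3", "v4"))
  again <- filter_by_frequency(kept, maf_gt = 0.01)
  expect_equal(again$variants$id, kept$variants$id)

  # strict MAC bounds: MAC 10 excluded, 11 kept; 99 kept, 100 excluded
  mk <- function(mac) c(rep(1L, mac), rep(0L, n - mac))
  g2 <- geno_matrix(
    cbind(a = mk(10), b = mk(11), c = mk(99), d = mk(100)),
    tibble::tibble(chromosome = 1L, position_bp = 1:4 * 100, ref = "A",
                   alt = "G", id = letters[1:4]),
    sprintf("s%03d", 1:n)
  )
  got <- filter_by_frequency(g2, mac_between = c(10, 100))
  expect_equal(got$variants$id, c("b", "c"))

  expect_warning(filter_by_frequency(g2, maf_gt = 0.9), "removed all")
  expect_error(filter_by_frequency(g2, maf_gt = 0.1, maf_lt = 0.2),
               "exactly one")
})

test_that("a panmictic single-deme control simulates cleanly", {
  cfg <- deme_grid_config(
    grid_n = 1, diploids_per_deme = 30,
    chromosomes = tibble::tibble(name = "1", length_bp = 5e6,
                                 recomb_rate = 1.149e-8),
    max_variants = 500, seed = 55
  )
  sim <- simulate_grid(cfg)
  expect_equal(n_samples(sim$genotypes), 30)
  expect_true(all(sim$labels$row == 0 & sim$labels$col == 0))
  # no gradient is definable on a single row
  expect_error(simulate_smooth(sim$labels), "2 rows")
})

test_that("simulation outputs round-trip through the IBD text dialect", {
  sim <- tiny_sim()
  seg <- extract_true_ibd(sim, min_cM = 4)
  f <- tempfile(fileext = ".tsv")
  write_ibd_segments(seg, f)
  back <- read_ibd_segments(f, "generic6")
  expect_equal(nrow(back), nrow(seg))
  expect_equal(sum(back$length_cM), sum(seg$length_cM), tolerance = 1e-9)
})
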