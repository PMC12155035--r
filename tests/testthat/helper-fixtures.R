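# Programmatic fixtures shared across test files.

# write a generic6 IBD file from a tibble-like list of rows
write_ibd_fixture <- function(rows, path = tempfile(fileext = ".tsv")) {
  writeLines(vapply(rows, paste, character(1), collapse = "\t"), path)
  path
}

# small random genotype matrix with two diverged populations
make_two_pop_genotypes <- function(n_per_pop = 30, m = 200, fst_delta = 0.4,
                                   seed = 42) {
  set.seed(seed)
  n <- 2 * n_per_pop
  p1 <- runif(m, 0.1, 0.9)
  p2 <- pmin(pmax(p1 + sample(c(-1, 1), m, TRUE) * fst_delta, 0.02), 0.98)
  dos <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    dos[, j] <- c(
      stats::rbinom(n_per_pop, 2, p1[j]),
      stats::rbinom(n_per_pop, 2, p2[j])
    )
  }
  variants <- tibble::tibble(
    chromosome = 1L, position_bp = seq_len(m) * 1000,
    ref = "A", alt = "G", id = paste0("v", seq_len(m))
  )
  geno_matrix(dos, variants, sprintf("P%03d", seq_len(n)))
}

# random genotype matrix with no structure
make_null_genotypes <- function(n = 100, m = 500, seed = 7) {
  set.seed(seed)
  p <- runif(m, 0.05, 0.95)
  dos <- matrix(stats::rbinom(n * m, 2, rep(p, each = n)), n, m)
  variants <- tibble::tibble(
    chromosome = 1L, position_bp = seq_len(m) * 500,
    ref = "A", alt = "G", id = paste0("v", seq_len(m))
  )
  geno_matrix(dos, variants, sprintf("N%03d", seq_len(n)))
}

# random Erdos-Renyi-ish adjacency over n vertices
make_random_adjacency <- function(n, p_edge = 0.1, seed = 1) {
  set.seed(seed)
  A <- matrix(0, n, n)
  A[upper.tri(A)] <- as.numeric(runif(n * (n - 1) / 2) < p_edge)
  A <- A + t(A)
  dimnames(A) <- list(paste0("v", 1:n), paste0("v", 1:n))
  A
}

# grid labels without running the simulator
make_grid_labels <- function(grid_n = 4, per_deme = 25) {
  demes <- expand.grid(row = 0:(grid_n - 1), col = 0:(grid_n - 1))
  demes <- demes[order(demes$row, demes$col), ]
  tibble::tibble(
    sample_id = sprintf("S%04d", seq_len(grid_n^2 * per_deme)),
    row = rep(demes$row, each = per_deme),
    col = rep(demes$col, each = per_deme)
  )
}

python_available <- function() {
  !inherits(try(ibdspc:::find_python(), silent = TRUE), "try-error")
}

# one small simulated cohort shared by simulation-dependent unit tests
.sim_cache <- new.env(parent = emptyenv())
tiny_sim <- function() {
  if (is.null(.sim_cache$sim)) {
    cfg <- deme_grid_config(
      grid_n = 3, diploids_per_deme = 25,
      chromosomes = tibble::tibble(name = "1", length_bp = 2e7,
                                   recomb_rate = 1.149e-8),
      max_variants = 4000, seed = 321
    )
    .sim_cache$sim <- simulate_grid(cfg)
  }
  .sim_cache$sim
}
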