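#' Configure a deme-grid coalescent simulation
#'
#' Describes an `grid_n` x `grid_n` stepping-stone grid of demes with
#' symmetric rook (4-neighbour) migration, a single ancestral merge
#' `t_ancestral` generations ago, and a hybrid simulation model: the most
#' recent `t_dtwf` generations under discrete-time Wright-Fisher dynamics
#' (realistic long-IBD length distribution), standard coalescent earlier.
#' Defaults mirror the reference design: a 4x4 grid, migration rate 0.05
#' (which yields neighbouring-deme divergence comparable to adjacent
#' administrative counties in a homogeneous national cohort), merge at 300
#' generations, DTWF for 150.
#'
#' @param grid_n Demes per side.
#' @param diploids_per_deme Diploid samples drawn per deme.
#' @param deme_size Diploid effective size of each deme (unobserved in the
#'   reference design; 1000 by default).
#' @param migration_rate Per-generation migration fraction between rook
#'   neighbours.
#' @param t_ancestral Generations to the single ancestral merge.
#' @param t_dtwf Generations simulated under DTWF (must be <= `t_ancestral`).
#' @param chromosomes Tibble with columns `name`, `length_bp`, `recomb_rate`
#'   (per bp per generation); see [chromosome_table()].
#' @param mutation_rate Per-bp per-generation mutation rate.
#' @param max_variants Retain at most this many segregating sites (seeded
#'   uniform thinning across the genome); `NULL` (the default) keeps all.
#'   Thinning trades memory for a known finite-sample artifact: principal
#'   components computed from few variants absorb extra phenotypic variance
#'   through the bulk-eigenvalue edge, so leave thinning off when PCA-based
#'   variance decompositions are the endpoint.
#' @param seed Integer seed; the same seed reproduces genotypes and IBD
#'   bit-identically.
#' @return An object of class `deme_grid_config`.
#' @export
deme_grid_config <- function(grid_n = 4, diploids_per_deme = 500,
                             deme_size = 1000, migration_rate = 0.05,
                             t_ancestral = 300, t_dtwf = 150,
                             chromosomes = chromosome_table("chr1"),
                             mutation_rate = 1.25e-8,
                             max_variants = NULL, seed = 1) {
  if (grid_n < 1) abort("grid_n must be >= 1.")
  if (diploids_per_deme < 1) abort("diploids_per_deme must be >= 1.")
  if (t_dtwf > t_ancestral) abort("t_dtwf must be <= t_ancestral.")
  if (migration_rate < 0 || mutation_rate < 0) abort("rates must be >= 0.")
  chromosomes <- as_tibble(chromosomes)
  stopifnot(all(c("name", "length_bp", "recomb_rate") %in% names(chromosomes)))
  structure(
    list(
      grid_n = as.integer(grid_n),
      diploids_per_deme = as.integer(diploids_per_deme),
      deme_size = deme_size,
      migration_rate = migration_rate,
      t_ancestral = t_ancestral,
      t_dtwf = t_dtwf,
      chromosomes = chromosomes,
      mutation_rate = mutation_rate,
      max_variants = max_variants,
      seed = as.integer(seed)
    ),
    class = "deme_grid_config"
  )
}

#' Named simulation presets
#'
#' \describe{
#'   \item{`"small4x4"`}{4x4 grid, 100 diploids/deme (1,600 samples), one
#'     50 Mb chromosome at the chromosome-1 recombination rate — the
#'     desk-scale workhorse, minutes on one CPU.}
#'   \item{`"full8k"`}{4x4 grid, 500 diploids/deme (8,000 samples), 22
#'     full-length autosomes — the full-scale design; cluster-scale,
#'     documented but not run by the test suite.}
#'   \item{`"full50k"`}{5x5 grid, 2,000 diploids/deme (50,000 samples),
#'     chromosome 1 only — the rare-variant design at full scale.}
#' }
#'
#' @param name Preset name.
#' @param seed Seed forwarded to [deme_grid_config()].
#' @return A `deme_grid_config`.
#' @export
grid_preset <- function(name = c("small4x4", "full8k", "full50k"), seed = 1) {
  name <- match.arg(name)
  switch(name,
    small4x4 = deme_grid_config(
      grid_n = 4, diploids_per_deme = 100,
      chromosomes = tibble(name = "1", length_bp = 5e7, recomb_rate = 1.149e-8),
      seed = seed
    ),
    full8k = deme_grid_config(
      grid_n = 4, diploids_per_deme = 500,
      chromosomes = chromosome_table(), seed = seed
    ),
    full50k = deme_grid_config(
      grid_n = 5, diploids_per_deme = 2000,
      chromosomes = chromosome_table("chr1"), seed = seed
    )
  )
}

#' Autosome length table
#'
#' Standard GRCh38 autosome lengths. The chromosome-1 recombination rate
#' (1.149e-8 per bp per generation) is applied to every chromosome by
#' default; supply per-chromosome rates to override.
#'
#' @param which `"all"` or `"chr1"`.
#' @param recomb_rate Recombination rate applied to each chromosome.
#' @return Tibble with `name`, `length_bp`, `recomb_rate`.
#' @export
chromosome_table <- function(which = c("all", "chr1"), recomb_rate = 1.149e-8) {
  which <- match.arg(which)
  lens <- c(
    248956422, 242193529, 198295559, 190214555, 181538259, 170805979,
    159345973, 145138636, 138394717, 133797422, 135086622, 133275309,
    114364328, 107043718, 101991189, 90338345, 83257441, 80373285,
    58617616, 64444167, 46709983, 50818468
  )
  tb <- tibble(
    name = as.character(seq_along(lens)),
    length_bp = lens,
    recomb_rate = recomb_rate
  )
  if (which == "chr1") tb[1, ] else tb
}

# chunked reader for the backend's digit-matrix format: one line per
# variant, one character (0/1/2) per sample; keeps transient memory small
read_dosage_lines <- function(path, n, m, chunk_variants = 20000L) {
  dos <- matrix(0L, nrow = n, ncol = m)
  con <- file(path, "rb")
  on.exit(close(con))
  filled <- 0L
  line_bytes <- n + 1L  # trailing newline
  while (filled < m) {
    take <- min(chunk_variants, m - filled)
    raw <- readBin(con, "raw", n = as.numeric(take) * line_bytes)
    if (length(raw) < take * line_bytes) {
      abort("dosages.txt is truncated.")
    }
    block <- matrix(as.integer(raw), nrow = line_bytes)
    dos[, (filled + 1L):(filled + take)] <- block[seq_len(n), ] - 48L
    filled <- filled + take
  }
  dos
}

pkg_env <- new.env(parent = emptyenv())

find_python <- function() {
  if (!is.null(pkg_env$python)) return(pkg_env$python)
  cand <- Sys.getenv("IBDSPC_PYTHON", "")
  if (cand == "") cand <- Sys.which("python3")
  if (cand == "") cand <- Sys.which("python")
  if (cand == "") abort("No python interpreter found on PATH.")
  ok <- suppressWarnings(system2(
    cand, c("-c", shQuote("import msprime, tskit")),
    stdout = FALSE, stderr = FALSE
  )) == 0
  if (!ok) {
    abort(paste0(
      "The python interpreter at '", cand,
      "' cannot import msprime/tskit, which the simulation module requires."
    ))
  }
  pkg_env$python <- cand
  cand
}

run_gridsim_py <- function(mode, cfg) {
  python <- find_python()
  script <- system.file("python", "gridsim.py", package = "ibdspc")
  if (script == "") abort("bundled gridsim.py not found; reinstall the package.")
  cfg_path <- tempfile(fileext = ".json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA)
  status <- system2(python, c(script, mode, cfg_path),
                    stdout = "", stderr = "")
  if (status != 0) abort(sprintf("gridsim.py %s failed (exit %d).", mode, status))
  invisible(NULL)
}

#' Simulate a deme-grid cohort
#'
#' Runs the coalescent backend and returns genotypes plus deme-of-origin
#' labels. The per-chromosome ancestry (tree sequences) is kept on disk in
#' `out_dir` so that [extract_true_ibd()] can be called afterwards.
#'
#' @param config A [deme_grid_config()] or preset name for [grid_preset()].
#' @param out_dir Directory for the backend's outputs; defaults to a
#'   session temporary directory.
#' @return An object of class `grid_sim`: `genotypes` (a [geno_matrix()]),
#'   `labels` (tibble `sample_id`, `row`, `col`, `deme`), `config`, `meta`.
#' @examples
#' \dontrun{
#' sim <- simulate_grid(grid_preset("small4x4", seed = 1))
#' ibd <- extract_true_ibd(sim, min_cM = 3)
#' }
#' @export
simulate_grid <- function(config, out_dir = tempfile("gridsim")) {
  if (is.character(config)) config <- grid_preset(config)
  stopifnot(inherits(config, "deme_grid_config"))
  cfg <- list(
    grid_n = config$grid_n,
    diploids_per_deme = config$diploids_per_deme,
    deme_size = config$deme_size,
    migration_rate = config$migration_rate,
    t_ancestral = config$t_ancestral,
    t_dtwf = config$t_dtwf,
    chromosomes = lapply(seq_len(nrow(config$chromosomes)), function(i) {
      as.list(config$chromosomes[i, ])
    }),
    mutation_rate = config$mutation_rate,
    max_variants = config$max_variants %||% -1,
    seed = config$seed,
    out_dir = out_dir
  )
  run_gridsim_py("simulate", cfg)
  load_grid_sim(out_dir, config)
}

#' Load a previously simulated cohort from its output directory
#'
#' @param out_dir Directory written by [simulate_grid()].
#' @param config Optional [deme_grid_config()] echo to attach.
#' @return A `grid_sim` object.
#' @export
load_grid_sim <- function(out_dir, config = NULL) {
  meta <- jsonlite::read_json(file.path(out_dir, "meta.json"),
                              simplifyVector = TRUE)
  labels <- utils::read.table(
    file.path(out_dir, "samples.tsv"), header = FALSE, sep = "\t",
    col.names = c("sample_id", "row", "col", "deme"),
    colClasses = c("character", "integer", "integer", "character")
  )
  labels <- as_tibble(labels)
  variants <- utils::read.table(
    file.path(out_dir, "variants.tsv"), header = FALSE, sep = "\t",
    col.names = c("chromosome", "position_bp", "ref", "alt", "id"),
    colClasses = c("integer", "numeric", "character", "character", "character")
  )
  n <- nrow(labels)
  m <- nrow(variants)
  dos <- read_dosage_lines(file.path(out_dir, "dosages.txt"), n, m)
  genotypes <- geno_matrix(dos, as_tibble(variants), labels$sample_id)

  structure(
    list(
      genotypes = genotypes,
      labels = labels,
      config = config,
      meta = meta,
      out_dir = out_dir
    ),
    class = "grid_sim"
  )
}

#' @export
print.grid_sim <- function(x, ...) {
  cat(sprintf(
    "<grid_sim> %dx%d grid, %d samples, %d variants (of %d sites)\n",
    x$config$grid_n, x$config$grid_n, n_samples(x$genotypes),
    n_variants(x$genotypes), x$meta$n_sites_before_thinning
  ))
  invisible(x)
}

#' True IBD segments from a simulated cohort
#'
#' Extracts contiguous shared-ancestry segments between all haplotype pairs
#' from the retained tree sequences, converts physical spans to genetic
#' length using the chromosome's recombination rate (cM = bp span x rate x
#' 100), keeps segments of at least `min_cM`, maps haplotypes up to diploid
#' individuals, and drops within-individual pairs.
#'
#' @param sim A [simulate_grid()] result.
#' @param min_cM Minimum segment genetic length in cM; must be positive
#'   (the unfiltered segment set is unbounded in size). Default 3 cM, a
#'   typical detection floor for IBD callers.
#' @return A segment tibble in the same shape as [read_ibd_segments()].
#' @export
extract_true_ibd <- function(sim, min_cM = 3) {
  stopifnot(inherits(sim, "grid_sim"))
  if (min_cM <= 0) abort("min_cM must be > 0.")
  trees <- sim$meta$trees
  if (is.data.frame(trees)) {
    trees <- lapply(seq_len(nrow(trees)), function(i) as.list(trees[i, ]))
  }
  missing_trees <- vapply(trees, function(t) !file.exists(t$path), logical(1))
  if (any(missing_trees)) {
    abort("tree-sequence files from simulate_grid() no longer exist.")
  }
  out_path <- tempfile(fileext = ".tsv")
  run_gridsim_py("ibd", list(trees = trees, min_cM = min_cM,
                             out_path = out_path))
  read_ibd_segments(out_path, "generic6")
}
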