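#' Symmetrically normalized Laplacian of a relatedness graph
#'
#' Builds `L_sym = I - D^(+1/2) A D^(+1/2)`, where `D` is the degree diagonal
#' (neighbour count, or weighted degree in weighted mode) and `D^+` its
#' Moore-Penrose inverse: `d_ii^(-1/2)` where `d_ii > 0` and 0 where
#' `d_ii = 0`. Rows and columns of isolated vertices therefore equal the
#' corresponding identity rows, so each isolated vertex contributes the
#' eigen-pair `(1, e_i)`. All eigenvalues of `L_sym` lie in `[0, 2]`.
#'
#' @param A Symmetric adjacency matrix with zero diagonal and non-negative
#'   entries, as from [to_adjacency()].
#' @return An object of class `laplacian_op` with elements `L` (sparse
#'   symmetric), `degrees`, `n` and `sample_ids`.
#' @export
build_laplacian <- function(A) {
  A <- methods::as(as_dgc(A), "generalMatrix")
  n <- nrow(A)
  if (ncol(A) != n) abort("adjacency matrix must be square.")
  if (!Matrix::isSymmetric(A, tol = 0)) abort("adjacency matrix must be symmetric.")
  if (any(Matrix::diag(A) != 0)) abort("adjacency matrix must have a zero diagonal.")
  if (length(A@x) && min(A@x) < 0) abort("adjacency weights must be non-negative.")
  d <- Matrix::rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  Dinv <- Matrix::Diagonal(n, dinv)
  L <- Matrix::Diagonal(n) - Dinv %*% A %*% Dinv
  L <- Matrix::forceSymmetric((L + Matrix::t(L)) / 2)
  structure(
    list(L = L, degrees = d, n = n, sample_ids = rownames(A) %||% as.character(seq_len(n))),
    class = "laplacian_op"
  )
}

as_dgc <- function(A) {
  if (is.matrix(A)) A <- Matrix::Matrix(A, sparse = TRUE)
  methods::as(methods::as(A, "CsparseMatrix"), "dMatrix")
}

#' @export
print.laplacian_op <- function(x, ...) {
  cat(sprintf("<laplacian_op> n = %d, %d isolated vertex(es)\n",
              x$n, sum(x$degrees == 0)))
  invisible(x)
}

#' Spectral components: low eigenvectors of the normalized Laplacian
#'
#' Returns the `k` eigen-pairs of `L_sym` with the smallest eigenvalues, in
#' ascending order. Zero eigenvalues are included by default: for a connected
#' graph the single zero eigenvector is proportional to the square root of
#' the degrees, and for a disconnected graph the zero eigenspace encodes
#' component membership — both are population-structure signal. Set
#' `skip_trivial = TRUE` to drop eigenvalues below `1e-10` (for models that
#' carry their own intercept).
#'
#' Eigenvector signs are fixed so the largest-magnitude entry of each column
#' is positive (ties broken by lowest index). Within degenerate eigenspaces
#' the returned orthonormal basis is arbitrary; compare subspaces, not
#' individual vectors.
#'
#' @param L A [build_laplacian()] result (or an adjacency matrix, which is
#'   converted first).
#' @param k Number of components, `1 <= k < n`; defaults to 25, the covariate
#'   count conventionally compared against 25 genotype PCs.
#' @param seed Integer seed for the iterative solver's start vector.
#' @param method `"auto"` (dense up to n = 2000, Lanczos beyond), `"dense"`,
#'   or `"arpack"`.
#' @param skip_trivial Drop eigenvalues `< 1e-10`?
#' @return An object of class `spectral_basis`: `eigenvalues` (ascending),
#'   `vectors` (n x k, orthonormal columns), `k`, `sample_ids`, `source`.
#' @examples
#' A <- rbind(c(0, 1), c(1, 0))  # single edge: eigenvalues 0 and 2
#' compute_spcs(build_laplacian(A), k = 1)$eigenvalues
#' @export
compute_spcs <- function(L, k = 25, seed = 1,
                         method = c("auto", "dense", "arpack"),
                         skip_trivial = FALSE) {
  method <- match.arg(method)
  if (!inherits(L, "laplacian_op")) L <- build_laplacian(L)
  n <- L$n
  if (k < 1 || k >= n) {
    abort(sprintf("k must satisfy 1 <= k < n (requested k = %d, n = %d).", k, n))
  }
  m <- if (skip_trivial) min(n - 1L, k + 8L) else k
  repeat {
    eig <- low_eigenpairs(L, m, seed, method, n)
    keep <- if (skip_trivial) eig$values >= 1e-10 else rep(TRUE, length(eig$values))
    if (sum(keep) >= k || m >= n - 1L) break
    m <- min(n - 1L, m + 32L)
  }
  if (sum(keep) < k) {
    abort("Not enough non-trivial eigenvalues: graph has too many components.")
  }
  idx <- which(keep)[seq_len(k)]
  vals <- eig$values[idx]
  vecs <- fix_signs(eig$vectors[, idx, drop = FALSE])
  rownames(vecs) <- L$sample_ids
  colnames(vecs) <- paste0("SPC", seq_len(k))
  structure(
    list(
      eigenvalues = vals,
      vectors = vecs,
      k = k,
      sample_ids = L$sample_ids,
      sign_convention = "largest-magnitude entry positive",
      source = list(n = n, n_isolated = sum(L$degrees == 0))
    ),
    class = "spectral_basis"
  )
}

# smallest-m eigenpairs of L_sym, ascending
low_eigenpairs <- function(L, m, seed, method, n) {
  if (method == "auto") method <- if (n <= 2000) "dense" else "arpack"
  if (method == "dense") {
    eig <- eigen(as.matrix(L$L), symmetric = TRUE)  # descending
    sel <- seq(n, n - m + 1L)
    return(list(values = eig$values[sel], vectors = eig$vectors[, sel, drop = FALSE]))
  }
  # Lanczos on M = I - L_sym: its largest eigenvalues are L's smallest,
  # better conditioned than shift-invert near zero.
  Lm <- L$L
  f <- function(x, extra) as.numeric(x - Lm %*% x)
  set.seed(seed)
  res <- tryCatch(
    igraph::arpack(
      f, sym = TRUE,
      options = list(
        n = n, nev = m, ncv = min(n, max(2L * m + 1L, 20L)),
        which = "LA", maxiter = 5000, start = runif(n, -1, 1)
      )
    ),
    error = function(e) {
      if (n <= 2000) {
        return(NULL)
      }
      abort(paste0(
        "Sparse eigensolver failed to converge (", conditionMessage(e),
        "); the dense fallback is only attempted for n <= 2000."
      ))
    }
  )
  if (is.null(res)) return(low_eigenpairs(L, m, seed, "dense", n))
  ord <- order(res$values, decreasing = TRUE)[seq_len(m)]
  vals <- 1 - res$values[ord]
  vecs <- res$vectors[, ord, drop = FALSE]
  # re-orthonormalize (ARPACK output is orthonormal to machine precision,
  # but degenerate clusters benefit from a QR pass)
  qr_v <- qr(vecs)
  list(values = pmax(vals, 0), vectors = qr.Q(qr_v))
}

fix_signs <- function(V) {
  for (j in seq_len(ncol(V))) {
    i <- which.max(abs(V[, j]))
    if (V[i, j] < 0) V[, j] <- -V[, j]
  }
  V
}

#' @export
print.spectral_basis <- function(x, ...) {
  cat(sprintf("<spectral_basis> %d components over %d samples\n",
              x$k, length(x$sample_ids)))
  cat("  eigenvalues:", paste(signif(head(x$eigenvalues, 8), 4), collapse = " "),
      if (x$k > 8) "...", "\n")
  invisible(x)
}

#' @rdname compute_spcs
#' @param x A `spectral_basis`.
#' @param ... Unused.
#' @export
tidy.spectral_basis <- function(x, ...) {
  dplyr::bind_cols(tibble(sample_id = x$sample_ids), as_tibble(x$vectors))
}

#' @rdname compute_spcs
#' @export
glance.spectral_basis <- function(x, ...) {
  tibble(
    n = length(x$sample_ids), k = x$k,
    lambda_min = min(x$eigenvalues), lambda_max = max(x$eigenvalues),
    n_zero = sum(x$eigenvalues < 1e-10),
    n_isolated = x$source$n_isolated %||% NA_integer_
  )
}

#' Spectral components straight from an IBD segment file
#'
#' End-to-end composition: read segments, aggregate per-pair totals, build
#' the thresholded graph, form the normalized Laplacian, and extract the
#' low-eigenvalue basis.
#'
#' @inheritParams read_ibd_segments
#' @inheritParams build_graph
#' @inheritParams compute_spcs
#' @return A `spectral_basis`; errors with "graph has no edges" if the
#'   threshold removes every pair.
#' @export
spcs_from_ibd <- function(path, dialect = "generic6", threshold_cM = 6,
                          k = 25, samples = NULL, mode = "binary",
                          seed = 1, skip_trivial = FALSE,
                          method = "auto") {
  seg <- read_ibd_segments(path, dialect)
  pairs <- aggregate_pairwise(seg)
  graph <- build_graph(pairs, threshold_cM = threshold_cM, mode = mode,
                       samples = samples)
  if (nrow(graph$edges) == 0) {
    abort(sprintf("graph has no edges at threshold %g cM.", threshold_cM))
  }
  L <- build_laplacian(to_adjacency(graph))
  basis <- compute_spcs(L, k = k, seed = seed, skip_trivial = skip_trivial,
                        method = method)
  basis$source <- c(basis$source, list(
    threshold_cM = threshold_cM, mode = mode, n_edges = nrow(graph$edges)
  ))
  basis
}
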