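#' Aggregate IBD segments into per-pair sharing totals
#'
#' Sums the genetic length of every IBD segment shared between each unordered
#' pair of individuals, across all chromosomes and haplotype pairings.
#' Overlapping segments between the same pair are summed, not merged.
#'
#' @param segments Segment tibble from [read_ibd_segments()] or
#'   [extract_true_ibd()].
#' @return A tibble of class `pairwise_ibd` with columns `id_a`, `id_b`
#'   (canonically ordered so `id_a < id_b`) and `total_cM`, one row per
#'   sharing pair.
#' @examples
#' seg <- tibble::tibble(
#'   id_a = c("S1", "S2"), id_b = c("S2", "S1"), chromosome = c(1L, 2L),
#'   start_bp = c(1e6, 2e6), end_bp = c(5e6, 6e6), length_cM = c(4, 3)
#' )
#' aggregate_pairwise(seg)  # one pair, 7 cM
#' @export
aggregate_pairwise <- function(segments) {
  if (nrow(segments) == 0) {
    out <- tibble(id_a = character(), id_b = character(), total_cM = double())
    class(out) <- c("pairwise_ibd", class(out))
    return(out)
  }
  if (any(segments$id_a == segments$id_b)) {
    abort("segments contain self-pairs; read_ibd_segments() removes these.")
  }
  a <- pmin(segments$id_a, segments$id_b)
  b <- pmax(segments$id_a, segments$id_b)
  dt <- data.table::data.table(id_a = a, id_b = b, len = segments$length_cM)
  tot <- dt[, list(total_cM = sum(len)), by = c("id_a", "id_b")]
  out <- arrange(as_tibble(tot), .data$id_a, .data$id_b)
  class(out) <- c("pairwise_ibd", class(out))
  out
}

#' Build the thresholded IBD relatedness graph
#'
#' An undirected graph over individuals with an edge wherever the aggregated
#' IBD sharing strictly exceeds `threshold_cM` (the pair's sharing must
#' surpass the threshold, so a total exactly at the threshold draws no edge).
#' Samples with no qualifying edge are kept as isolated vertices so that
#' downstream covariates exist for every analysed sample.
#'
#' @param pairs Pair totals from [aggregate_pairwise()].
#' @param threshold_cM Minimum aggregated sharing in centimorgans; the
#'   default 6 cM is the operating threshold, with 10 and 15 the usual
#'   sensitivity settings.
#' @param mode `"binary"` (unweighted edges) or `"weighted"` (edges carry the
#'   cM total).
#' @param samples Optional character vector fixing the vertex set and order;
#'   defaults to the samples appearing in `pairs`, sorted.
#' @param drop_isolated Remove vertices without edges?
#' @return An object of class `relatedness_graph`.
#' @export
build_graph <- function(pairs, threshold_cM = 6, mode = c("binary", "weighted"),
                        samples = NULL, drop_isolated = FALSE) {
  mode <- match.arg(mode)
  if (threshold_cM < 0) abort("threshold_cM must be >= 0.")
  edges <- filter(as_tibble(pairs), .data$total_cM > threshold_cM)
  if (is.null(samples)) {
    samples <- sort(unique(c(pairs$id_a, pairs$id_b)))
  } else {
    samples <- as.character(samples)
    if (anyDuplicated(samples)) abort("samples must be unique.")
    unknown <- setdiff(unique(c(edges$id_a, edges$id_b)), samples)
    if (length(unknown) > 0) {
      abort(sprintf(
        "%d edge sample(s) missing from the supplied sample list (e.g. '%s').",
        length(unknown), unknown[1]
      ))
    }
  }
  if (drop_isolated) {
    samples <- samples[samples %in% c(edges$id_a, edges$id_b)]
  }
  structure(
    list(
      samples = samples,
      edges = edges,
      threshold_cM = threshold_cM,
      mode = mode
    ),
    class = "relatedness_graph"
  )
}

#' @export
print.relatedness_graph <- function(x, ...) {
  cat(sprintf(
    "<relatedness_graph> %d vertices, %d edges (%s, > %g cM)\n",
    length(x$samples), nrow(x$edges), x$mode, x$threshold_cM
  ))
  invisible(x)
}

#' Adjacency matrix of a relatedness graph
#'
#' @param graph A [build_graph()] result.
#' @return A symmetric sparse [Matrix::sparseMatrix()] with zero diagonal;
#'   entries are 1 in binary mode, the aggregated cM total in weighted mode.
#'   Row/column names give the sample order.
#' @export
to_adjacency <- function(graph) {
  n <- length(graph$samples)
  idx <- setNames(seq_len(n), graph$samples)
  i <- idx[graph$edges$id_a]
  j <- idx[graph$edges$id_b]
  w <- if (graph$mode == "weighted") graph$edges$total_cM else rep(1, nrow(graph$edges))
  A <- Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = c(w, w),
    dims = c(n, n), dimnames = list(graph$samples, graph$samples)
  )
  Matrix::forceSymmetric(A)
}

#' Summarise a relatedness graph
#'
#' @param graph A [build_graph()] result.
#' @return One-row tibble: vertex/edge counts, connected components, isolated
#'   vertices and degree quantiles (0/25/50/75/100%).
#' @export
graph_summary <- function(graph) {
  n <- length(graph$samples)
  deg <- setNames(numeric(n), graph$samples)
  tab_a <- table(graph$edges$id_a)
  tab_b <- table(graph$edges$id_b)
  deg[names(tab_a)] <- deg[names(tab_a)] + as.numeric(tab_a)
  deg[names(tab_b)] <- deg[names(tab_b)] + as.numeric(tab_b)
  g <- igraph::graph_from_data_frame(
    graph$edges[, c("id_a", "id_b")], directed = FALSE,
    vertices = data.frame(name = graph$samples)
  )
  comp <- igraph::components(g)
  q <- if (n > 0) quantile(deg, c(0, .25, .5, .75, 1)) else rep(NA_real_, 5)
  tibble(
    n_vertices = n,
    n_edges = nrow(graph$edges),
    n_components = comp$no,
    n_isolated = sum(deg == 0),
    degree_min = q[[1]], degree_q25 = q[[2]], degree_median = q[[3]],
    degree_q75 = q[[4]], degree_max = q[[5]]
  )
}
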