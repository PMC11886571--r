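#' Spatial k-nearest-neighbour adjacency
#'
#' Links every spot to its \code{k} nearest neighbours by Euclidean distance
#' in the coordinate plane (itself excluded), then symmetrizes by union: an
#' edge is present if either endpoint selects the other, so every node ends
#' up with degree >= k. Distance ties are broken by ascending node index, so
#' the construction is deterministic, and duplicate coordinates are allowed.
#'
#' @param coords numeric N x 2 coordinate matrix, finite entries.
#' @param k number of neighbours per spot (default 3); must satisfy
#'   \code{N > k >= 1}.
#' @return a binary symmetric N x N \code{\link[Matrix]{sparseMatrix}} with
#'   zero diagonal.
#' @export
build_knn_graph <- function(coords, k = 3) {
  coords <- as.matrix(coords)
  n <- nrow(coords)
  if (k < 1) stop("k must be >= 1", call. = FALSE)
  if (n <= k) stop("need more spots (", n, ") than neighbours k = ", k,
                   call. = FALSE)
  if (any(!is.finite(coords))) stop("coords contain non-finite values",
                                    call. = FALSE)
  d2 <- squared_distances(coords)
  diag(d2) <- Inf
  # per row: k smallest distances, ties broken by column index
  nbr <- t(apply(d2, 1L, function(row) order(row, seq_len(n))[seq_len(k)]))
  a <- Matrix::sparseMatrix(i = rep(seq_len(n), each = k),
                            j = as.integer(t(nbr)),
                            x = 1, dims = c(n, n))
  a <- ((a + Matrix::t(a)) > 0) * 1            # union symmetrization
  # keep general (non-symmetric-storage) form so edge enumeration sees
  # both triangles
  methods::as(methods::as(a, "generalMatrix"), "CsparseMatrix")
}

squared_distances <- function(coords) {
  sq <- rowSums(coords^2)
  d2 <- outer(sq, sq, "+") - 2 * tcrossprod(coords)
  d2[d2 < 0] <- 0
  d2
}

#' Assemble the spatial graph G = (V, A, X)
#'
#' Combines the kNN adjacency built from spot coordinates with the
#' preprocessed expression matrix as node features. kNN graphs need not be
#' connected; a disconnected graph is reported with a warning (training and
#' propagation still work per component).
#'
#' @param ds a preprocessed \code{\link{spatial_dataset}}.
#' @param k neighbours per spot (default 3).
#' @return an object of class \code{spatial_graph}: list with
#'   \code{n_nodes}, \code{adjacency} (sparse binary symmetric),
#'   \code{features} (dense N x d_in), \code{k}, \code{spot_ids}, plus the
#'   precomputed edge list (with self-loops) used by the attention layers.
#' @export
assemble_graph <- function(ds, k = 3) {
  a <- build_knn_graph(ds$coords, k)
  n <- nrow(a)
  comps <- igraph::components(
    igraph::graph_from_adjacency_matrix(a, mode = "undirected"))
  if (comps$no > 1L)
    warning("spatial kNN graph is disconnected (", comps$no, " components)",
            call. = FALSE)
  g <- structure(
    list(n_nodes = n, adjacency = a, features = as.matrix(ds$matrix),
         k = k, spot_ids = ds$spot_ids, labels = ds$labels),
    class = "spatial_graph")
  g$edges <- graph_edge_index(a)
  g
}

# Edge list with self-loops, plus per-target grouping used by the softmax
# in the attention layers. ei = receiving node, ej = neighbour attended to.
graph_edge_index <- function(a) {
  n <- nrow(a)
  tr <- Matrix::summary(methods::as(methods::as(a, "generalMatrix"), "TsparseMatrix"))
  ei <- c(tr$i, seq_len(n))
  ej <- c(tr$j, seq_len(n))
  ord <- order(ei, ej)
  ei <- ei[ord]; ej <- ej[ord]
  list(ei = ei, ej = ej, n = n,
       groups = split(seq_along(ei), ei))
}

#' @export
print.spatial_graph <- function(x, ...) {
  cat("spatial_graph: ", x$n_nodes, " nodes, ",
      as.integer(Matrix::nnzero(x$adjacency)) / 2L, " undirected edges (k = ",
      x$k, "), ", ncol(x$features), " features/node\n", sep = "")
  invisible(x)
}

#' Export the adjacency as an edge list or MTX file
#'
#' @param graph a \code{spatial_graph} (or a bare adjacency matrix).
#' @param path output file path.
#' @param format \code{"edge_list"} (TSV of node index pairs i < j) or
#'   \code{"mtx"}.
#' @return \code{path}, invisibly.
#' @export
write_graph <- function(graph, path, format = c("edge_list", "mtx")) {
  format <- match.arg(format)
  a <- if (inherits(graph, "spatial_graph")) graph$adjacency else graph
  if (format == "mtx") {
    Matrix::writeMM(methods::as(a, "CsparseMatrix"), path)
  } else {
    tr <- Matrix::summary(methods::as(methods::as(a, "generalMatrix"), "TsparseMatrix"))
    keep <- tr$i < tr$j
    utils::write.table(data.frame(i = tr$i[keep], j = tr$j[keep]),
                       path, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
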