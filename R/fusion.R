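#' Parameter-free multi-hop propagation
#'
#' Propagates the one-hop embedding through \code{n} steps of GCN-style
#' aggregation without any learnable parameters:
#' \code{H_D = A_hat^n H}, where
#' \code{A_hat = D_hat^{-1/2} (A + I) D_hat^{-1/2}} is the symmetrically
#' normalized adjacency with self-loops. A mean-over-closed-neighbourhood
#' aggregator (\code{D_hat^{-1} (A + I)}) is available as an alternative.
#'
#' @param H N x d embedding matrix.
#' @param adjacency binary N x N adjacency (no self-loops) or a
#'   \code{spatial_graph}.
#' @param n number of hops (default 3).
#' @param aggregator \code{"sym"} (symmetric normalization, default) or
#'   \code{"mean"}.
#' @return N x d propagated embedding H_D.
#' @export
multi_hop <- function(H, adjacency, n = 3, aggregator = c("sym", "mean")) {
  aggregator <- match.arg(aggregator)
  stopifnot(n >= 1)
  a <- if (inherits(adjacency, "spatial_graph")) adjacency$adjacency
       else adjacency
  ah <- normalized_adjacency(a, aggregator)
  out <- H
  for (i in seq_len(n)) out <- as.matrix(ah %*% out)
  out
}

normalized_adjacency <- function(a, aggregator = "sym") {
  n <- nrow(a)
  ai <- a + Matrix::Diagonal(n)
  deg <- as.numeric(Matrix::rowSums(ai))
  if (aggregator == "sym") {
    dmh <- Matrix::Diagonal(n, 1 / sqrt(deg))
    dmh %*% ai %*% dmh
  } else {
    Matrix::Diagonal(n, 1 / deg) %*% ai
  }
}

#' Fuse one-hop and multi-hop embeddings
#'
#' Elementwise sum \code{H_out = H + H_D}: the final representation used
#' for clustering combines the specific one-hop features with the smoothed
#' multi-hop context.
#'
#' @param H N x d one-hop embedding.
#' @param H_D N x d multi-hop embedding.
#' @return N x d fused embedding.
#' @export
fuse <- function(H, H_D) {
  if (!all(dim(H) == dim(H_D)))
    stop("H and H_D must have identical dimensions", call. = FALSE)
  H + H_D
}

#' Compute the embedding set of a trained model
#'
#' Applies the trained encoder to the clean graph (one-hop H), propagates
#' it \code{hops} steps (multi-hop H_D), and fuses both.
#'
#' @param fit a \code{\link{train}} result.
#' @param graph the \code{spatial_graph} the model was trained on.
#' @param hops number of propagation steps (defaults to the trained
#'   config's value).
#' @param aggregator passed to \code{\link{multi_hop}}.
#' @return object of class \code{embedding_set}: list with matrices
#'   \code{H}, \code{H_D}, \code{H_out} and the \code{spot_ids}.
#' @export
embedding_set <- function(fit, graph, hops = fit$cfg$hops,
                          aggregator = "sym") {
  H <- encode(graph, graph$features, fit$model$enc)
  H_D <- multi_hop(H, graph$adjacency, hops, aggregator)
  structure(list(H = H, H_D = H_D, H_out = fuse(H, H_D),
                 spot_ids = graph$spot_ids),
            class = "embedding_set")
}

#' @export
print.embedding_set <- function(x, ...) {
  cat("embedding_set: ", nrow(x$H), " spots x ", ncol(x$H),
      " dims (H, H_D, H_out)\n", sep = "")
  invisible(x)
}
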