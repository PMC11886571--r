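#' Build the shuffled (corrupted) graph
#'
#' Data augmentation for the contrastive task: the gene-expression feature
#' rows are randomly permuted among the nodes while the graph topology is
#' left untouched, so node identities and spatial context no longer match
#' their expression profiles.
#'
#' @param graph a \code{spatial_graph}.
#' @param seed optional integer for a reproducible permutation (local RNG
#'   stream; the caller's RNG state is restored).
#' @param permutation optional explicit permutation of \code{1..N}
#'   (overrides the random draw; useful for testing).
#' @return list of class \code{shuffled_graph} with \code{features}
#'   (row-permuted X), \code{permutation} and \code{seed}; the adjacency is
#'   the original graph's, by construction.
#' @export
shuffle_graph <- function(graph, seed = NULL, permutation = NULL) {
  n <- graph$n_nodes
  if (n < 2) stop("need at least 2 nodes to shuffle", call. = FALSE)
  if (is.null(permutation)) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    permutation <- sample.int(n)
  }
  stopifnot(length(permutation) == n, all(sort(permutation) == seq_len(n)))
  structure(list(features = graph$features[permutation, , drop = FALSE],
                 permutation = permutation, seed = seed),
            class = "shuffled_graph")
}

#' Per-node discrimination scores
#'
#' DGI-style readout: the original graph's projected embeddings Z are
#' averaged into a global summary \code{s = sigmoid(colMeans(Z))}; each
#' node (from the original and from the shuffled graph) is scored against
#' that summary by a dot product through a sigmoid,
#' \code{g_i = sigmoid(z_i . s)}, \code{g'_i = sigmoid(z'_i . s)}.
#' Scores are clamped to \code{[eps, 1 - eps]} so the cross-entropy stays
#' finite.
#'
#' @param Z N x d' projected embeddings of the original graph.
#' @param Z_prime N x d' projected embeddings of the shuffled graph.
#' @param eps clamping constant (default 1e-7).
#' @return list of class \code{discrimination_scores} with vectors \code{g}
#'   and \code{g_prime} in (0, 1) and the summary vector \code{s}.
#' @export
summary_scores <- function(Z, Z_prime, eps = 1e-7) {
  stopifnot(ncol(Z) == ncol(Z_prime), nrow(Z) == nrow(Z_prime))
  s <- sigmoid(colMeans(Z))
  clamp <- function(v) pmin(pmax(v, eps), 1 - eps)
  structure(list(g = clamp(sigmoid(drop(Z %*% s))),
                 g_prime = clamp(sigmoid(drop(Z_prime %*% s))),
                 s = s),
            class = "discrimination_scores")
}

#' Node discrimination loss
#'
#' Binary cross-entropy distinguishing original-graph node summaries
#' (label 1) from shuffled-graph summaries (label 0):
#' \code{L = (1/N) sum_i [ log(1/g_i) + log(1/(1 - g'_i)) ]} (natural log).
#' At chance level (all scores 0.5) the loss is \code{2 log 2}.
#'
#' @param scores a \code{\link{summary_scores}} result.
#' @return scalar loss >= 0.
#' @export
discrimination_loss <- function(scores) {
  mean(-log(scores$g) - log1p(-scores$g_prime))
}

# Forward + gradients of the full discrimination branch given projected
# embeddings: returns loss and dZ, dZ_prime (gradient of the MEAN loss).
# The summary s depends on Z only; gradients of the clamped tails use the
# unclamped sigmoid path (clamping only guards the reported loss value).
discrimination_forward_backward <- function(Z, Z_prime, eps = 1e-7) {
  n <- nrow(Z)
  m <- colMeans(Z)
  s <- sigmoid(m)
  u <- drop(Z %*% s)
  up <- drop(Z_prime %*% s)
  g <- pmin(pmax(sigmoid(u), eps), 1 - eps)
  gp <- pmin(pmax(sigmoid(up), eps), 1 - eps)
  loss <- mean(-log(g) - log1p(-gp))
  du <- (sigmoid(u) - 1) / n              # d loss / d u_i
  dup <- sigmoid(up) / n
  dZ <- outer(du, s)
  dZp <- outer(dup, s)
  ds <- drop(crossprod(Z, du)) + drop(crossprod(Z_prime, dup))
  dm <- ds * s * (1 - s)
  dZ <- dZ + matrix(dm / n, n, length(m), byrow = TRUE)
  list(loss = loss, dZ = dZ, dZ_prime = dZp)
}
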