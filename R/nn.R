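# Neural building blocks: a single-head graph-attention (GAT) layer used for
# both the encoder (d_in -> d) and the decoder (d -> d_in), and two-layer
# MLPs for the regularization projector and the contrastive projection head.
# Gradients are derived analytically; each *_forward returns a cache consumed
# by the matching *_backward.

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
elu_grad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))
lrelu <- function(x, slope = 0.2) ifelse(x > 0, x, slope * x)
lrelu_grad <- function(x, slope = 0.2) ifelse(x > 0, 1, slope)
sigmoid <- function(x) 1 / (1 + exp(-x))

glorot <- function(n_in, n_out) {
  lim <- sqrt(6 / (n_in + n_out))
  matrix(stats::runif(n_in * n_out, -lim, lim), n_in, n_out)
}

#' Initialize graph-attention layer parameters
#'
#' A single-head GAT layer: features are linearly projected by \code{W}
#' (no bias), edge scores are \code{LeakyReLU(a1 . s_i + a2 . s_j)}
#' (slope 0.2), softmax-normalized over each node's closed one-hop
#' neighbourhood (self-loop included), and the aggregate is passed through
#' the output nonlinearity.
#'
#' @param d_in input width.
#' @param d_out output width.
#' @param act output nonlinearity, \code{"elu"} or \code{"identity"}.
#' @return list of parameters (class \code{gat_params}).
#' @export
init_gat_params <- function(d_in, d_out, act = c("elu", "identity")) {
  act <- match.arg(act)
  structure(list(W = glorot(d_in, d_out),
                 a1 = stats::runif(d_out, -0.1, 0.1),
                 a2 = stats::runif(d_out, -0.1, 0.1),
                 act = act),
            class = "gat_params")
}

#' Initialize two-layer MLP parameters
#'
#' \code{out = elu(X W1 + b1) W2 + b2}; used for the regularization
#' projector (d -> d -> d) and the contrastive head (d -> d -> d').
#'
#' @param d_in input width.
#' @param d_hidden hidden width.
#' @param d_out output width.
#' @return list of parameters (class \code{mlp_params}).
#' @export
init_mlp_params <- function(d_in, d_hidden, d_out) {
  structure(list(W1 = glorot(d_in, d_hidden), b1 = numeric(d_hidden),
                 W2 = glorot(d_hidden, d_out), b2 = numeric(d_out)),
            class = "mlp_params")
}

# group-sum of a vector over integer groups 1..n (all groups present)
rowsum_vec <- function(x, g, n) {
  out <- numeric(n)
  agg <- rowsum(x, g)
  out[as.integer(rownames(agg))] <- agg[, 1]
  out
}

# ---- GAT layer ------------------------------------------------------------

gat_forward <- function(edges, X, p, keep_cache = TRUE) {
  ei <- edges$ei; ej <- edges$ej; n <- edges$n
  S <- X %*% p$W
  f1 <- drop(S %*% p$a1)
  f2 <- drop(S %*% p$a2)
  sc_pre <- f1[ei] + f2[ej]
  sc <- lrelu(sc_pre)
  gm <- vapply(edges$groups, function(s) max(sc[s]), numeric(1))
  ex <- exp(sc - gm[ei])
  den <- rowsum_vec(ex, ei, n)
  alpha <- ex / den[ei]
  asp <- Matrix::sparseMatrix(i = ei, j = ej, x = alpha, dims = c(n, n))
  pre <- as.matrix(asp %*% S)
  out <- if (p$act == "elu") elu(pre) else pre
  if (!keep_cache) return(list(out = out, alpha = alpha))
  list(out = out, alpha = alpha,
       cache = list(X = X, S = S, sc_pre = sc_pre, alpha = alpha,
                    asp = asp, pre = pre, edges = edges))
}

gat_backward <- function(dOut, cache, p) {
  ed <- cache$edges
  ei <- ed$ei; ej <- ed$ej; n <- ed$n
  S <- cache$S; alpha <- cache$alpha
  dPre <- if (p$act == "elu") dOut * elu_grad(cache$pre) else dOut
  dS <- as.matrix(Matrix::crossprod(cache$asp, dPre))
  dalpha <- rowSums(dPre[ei, , drop = FALSE] * S[ej, , drop = FALSE])
  gsum <- rowsum_vec(alpha * dalpha, ei, n)
  de <- alpha * (dalpha - gsum[ei])
  dsc <- de * lrelu_grad(cache$sc_pre)
  df1 <- rowsum_vec(dsc, ei, n)
  df2 <- rowsum_vec(dsc, ej, n)
  da1 <- drop(crossprod(S, df1))
  da2 <- drop(crossprod(S, df2))
  dS <- dS + outer(df1, p$a1) + outer(df2, p$a2)
  list(W = crossprod(cache$X, dS), a1 = da1, a2 = da2,
       dX = tcrossprod(dS, p$W))
}

# ---- MLP ------------------------------------------------------------------

mlp_forward <- function(X, p, keep_cache = TRUE) {
  h_pre <- sweep(X %*% p$W1, 2, p$b1, "+")
  h <- elu(h_pre)
  out <- sweep(h %*% p$W2, 2, p$b2, "+")
  if (!keep_cache) return(list(out = out))
  list(out = out, cache = list(X = X, h_pre = h_pre, h = h))
}

mlp_backward <- function(dOut, cache, p) {
  dW2 <- crossprod(cache$h, dOut)
  db2 <- colSums(dOut)
  dh <- tcrossprod(dOut, p$W2)
  dh_pre <- dh * elu_grad(cache$h_pre)
  list(W1 = crossprod(cache$X, dh_pre), b1 = colSums(dh_pre),
       W2 = dW2, b2 = db2, dX = tcrossprod(dh_pre, p$W1))
}

# ---- public module surface ------------------------------------------------

#' Encode node features into latent embeddings
#'
#' One masked-attention aggregation round over each node's closed one-hop
#' neighbourhood, projected to the latent width: \code{H = f_E(A, X)}.
#' Deterministic given fixed parameters.
#'
#' @param graph a \code{\link{assemble_graph}} result.
#' @param features N x d_in feature matrix (defaults to
#'   \code{graph$features}).
#' @param params encoder \code{gat_params}.
#' @return N x d latent matrix.
#' @export
encode <- function(graph, features = graph$features, params) {
  if (nrow(features) != graph$n_nodes)
    stop("features row count != number of nodes", call. = FALSE)
  out <- gat_forward(graph$edges, features, params, keep_cache = FALSE)$out
  if (anyNA(out) || any(!is.finite(out)))
    stop("non-finite values in encoder output (training divergence?)",
         call. = FALSE)
  out
}

#' Decode latent embeddings back to feature space
#'
#' The same single-layer attention mechanism as \code{\link{encode}},
#' mapping the latent width d back to d_in: \code{Z = f_D(A, H)}.
#'
#' @param graph a \code{spatial_graph}.
#' @param latent N x d latent matrix.
#' @param params decoder \code{gat_params}.
#' @return N x d_in reconstructed feature matrix.
#' @export
decode <- function(graph, latent, params) {
  if (nrow(latent) != graph$n_nodes)
    stop("latent row count != number of nodes", call. = FALSE)
  out <- gat_forward(graph$edges, latent, params, keep_cache = FALSE)$out
  if (anyNA(out) || any(!is.finite(out)))
    stop("non-finite values in decoder output (training divergence?)",
         call. = FALSE)
  out
}

#' Regularization projector g
#'
#' Two-layer MLP mapping the latent space onto itself; used to project both
#' the masked-graph and full-graph embeddings into the space where the
#' regularization loss is measured.
#'
#' @param latent N x d matrix.
#' @param params projector \code{mlp_params}.
#' @return N x d matrix.
#' @export
project_regularizer <- function(latent, params) {
  mlp_forward(latent, params, keep_cache = FALSE)$out
}

#' Contrastive projection head p
#'
#' Two-layer MLP mapping latent embeddings to the (narrower) space where
#' node-discrimination scores are computed.
#'
#' @param latent N x d matrix.
#' @param params head \code{mlp_params}.
#' @return N x d' matrix.
#' @export
project_head <- function(latent, params) {
  mlp_forward(latent, params, keep_cache = FALSE)$out
}

#' Initialize the full model
#'
#' Shared encoder, decoder, regularization projector and contrastive head.
#' Widths follow standard graph-attention conventions: a single attention
#' head, latent width \code{d}, head output width \code{d_prime}.
#'
#' @param d_in input feature width.
#' @param d latent width (default 64).
#' @param d_prime contrastive head output width (default 32).
#' @return list with elements \code{enc}, \code{dec}, \code{proj},
#'   \code{head} and the recorded widths.
#' @export
init_model <- function(d_in, d = 64, d_prime = 32) {
  list(enc = init_gat_params(d_in, d, act = "elu"),
       dec = init_gat_params(d, d_in, act = "identity"),
       proj = init_mlp_params(d, d, d),
       head = init_mlp_params(d, d, d_prime),
       d_in = d_in, d = d, d_prime = d_prime)
}
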