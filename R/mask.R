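#' Draw a masking plan
#'
#' Samples the set of nodes whose input features are masked (size
#' \code{round(mask_rate * n)}) and, independently, K re-mask sets used to
#' corrupt the latent matrix before each decoding view. Every node has equal
#' probability of being selected in each re-mask draw, regardless of whether
#' it was masked at the input.
#'
#' @param n number of nodes.
#' @param mask_rate fraction of nodes masked at the input, in [0, 1].
#' @param remask_views number of re-masked decoding views K (default 3).
#' @param remask_rate fraction of latent rows zeroed per view; defaults to
#'   \code{mask_rate}.
#' @param seed optional integer; if given, the draw is made reproducible by
#'   seeding a local RNG stream (the caller's RNG state is restored).
#' @return object of class \code{mask_plan}: list with \code{masked_nodes},
#'   \code{remask_sets} (list of K integer vectors), and the rates.
#' @export
mask_plan <- function(n, mask_rate = 0.5, remask_views = 3,
                      remask_rate = mask_rate, seed = NULL) {
  stopifnot(mask_rate >= 0, mask_rate <= 1,
            remask_rate >= 0, remask_rate <= 1, remask_views >= 1)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  n_mask <- round(mask_rate * n)
  masked <- sort(sample.int(n, n_mask))
  n_remask <- round(remask_rate * n)
  remask_sets <- lapply(seq_len(remask_views),
                        function(j) sort(sample.int(n, n_remask)))
  structure(list(mask_rate = mask_rate, masked_nodes = masked,
                 remask_views = remask_views, remask_rate = remask_rate,
                 remask_sets = remask_sets, seed = seed),
            class = "mask_plan")
}

#' Mask node features
#'
#' Replaces the feature rows of the planned nodes with all-zero vectors;
#' every other row is returned bit-identical.
#'
#' @param X N x d_in feature matrix.
#' @param plan a \code{\link{mask_plan}}.
#' @return the masked matrix X-tilde.
#' @export
mask_features <- function(X, plan) {
  if (length(plan$masked_nodes)) X[plan$masked_nodes, ] <- 0
  X
}

#' Re-mask the latent matrix for one decoding view
#'
#' Zeroes the latent rows of view \code{j}'s re-mask set, forcing the
#' decoder to reconstruct from a partial observation of the embeddings.
#'
#' @param H N x d latent matrix.
#' @param plan a \code{\link{mask_plan}}.
#' @param view view index j in 1..K.
#' @return the re-masked latent matrix.
#' @export
remask_latent <- function(H, plan, view) {
  stopifnot(view >= 1, view <= plan$remask_views)
  rows <- plan$remask_sets[[view]]
  if (length(rows)) H[rows, ] <- 0
  H
}

#' Scaled cosine error
#'
#' \code{(1 - cos(x, z))^gamma} with \code{gamma >= 1}: the reconstruction
#' criterion. Raising gamma damps the contribution of rows that are already
#' well reconstructed (cosine error < 1). A zero-norm vector makes the
#' cosine undefined; that degenerate row contributes 1 (i.e. cosine treated
#' as 0) with a warning.
#'
#' @param x,z numeric vectors of equal length.
#' @param gamma scaling exponent, >= 1.
#' @return scalar in [0, 2^gamma].
#' @export
scaled_cosine_error <- function(x, z, gamma = 2) {
  stopifnot(gamma >= 1, length(x) == length(z))
  nx <- sqrt(sum(x^2)); nz <- sqrt(sum(z^2))
  if (nx == 0 || nz == 0) {
    warning("zero-norm vector in scaled cosine error; contributing 1^gamma",
            call. = FALSE)
    return(1)
  }
  (1 - sum(x * z) / (nx * nz))^gamma
}

# Vectorized scaled-cosine-error over selected rows, with the gradient wrt
# Z on those rows (and optionally wrt X, for two-sided objectives).
# Zero-norm rows contribute `1` with zero gradient. Returns sum over rows
# (unnormalized).
sce_rows <- function(X, Z, rows, gamma, grad = TRUE, grad_x = FALSE) {
  xs <- X[rows, , drop = FALSE]
  zs <- Z[rows, , drop = FALSE]
  nx <- sqrt(rowSums(xs^2)); nz <- sqrt(rowSums(zs^2))
  ok <- nx > 0 & nz > 0
  cosv <- numeric(length(rows))
  cosv[ok] <- rowSums(xs * zs)[ok] / (nx[ok] * nz[ok])
  cosv <- pmin(pmax(cosv, -1), 1)
  loss <- sum((1 - cosv)^gamma)
  if (!grad) return(list(loss = loss))
  dc <- -gamma * (1 - cosv)^(gamma - 1)          # d loss / d cos
  dz <- matrix(0, length(rows), ncol(Z))
  if (any(ok)) {
    i <- which(ok)
    dz[i, ] <- dc[i] * (xs[i, , drop = FALSE] / (nx[i] * nz[i]) -
                          cosv[i] / (nz[i]^2) * zs[i, , drop = FALSE])
  }
  dZ <- matrix(0, nrow(Z), ncol(Z))
  dZ[rows, ] <- dz
  out <- list(loss = loss, dZ = dZ)
  if (grad_x) {
    dx <- matrix(0, length(rows), ncol(X))
    if (any(ok)) {
      i <- which(ok)
      dx[i, ] <- dc[i] * (zs[i, , drop = FALSE] / (nx[i] * nz[i]) -
                            cosv[i] / (nx[i]^2) * xs[i, , drop = FALSE])
    }
    dX <- matrix(0, nrow(X), ncol(X))
    dX[rows, ] <- dx
    out$dX <- dX
  }
  out
}

#' Masked reconstruction loss
#'
#' Aggregates the scaled cosine error between the original features and the
#' K re-masked decoding views, summed over the originally masked node set
#' and normalized by its size only (so the loss scales linearly with K):
#' \code{L_recon = (1/|Vm|) sum_j sum_{i in Vm} sce(x_i, z_i^(j))}.
#'
#' @param X N x d_in original feature matrix.
#' @param Z_views list of K reconstructed N x d_in matrices, one per view.
#' @param plan the \code{\link{mask_plan}} whose \code{masked_nodes} define
#'   the summation set.
#' @param gamma scaling exponent.
#' @return scalar loss >= 0.
#' @export
reconstruction_loss <- function(X, Z_views, plan, gamma = 2) {
  rows <- plan$masked_nodes
  if (!length(rows))
    stop("mask plan has no masked nodes: nothing to reconstruct",
         call. = FALSE)
  tot <- 0
  for (Z in Z_views) tot <- tot + sce_rows(X, Z, rows, gamma, grad = FALSE)$loss
  tot / length(rows)
}

#' Regularization loss
#'
#' Projects the masked-graph embedding and the full-graph embedding through
#' the projector g and measures the mean scaled cosine error between them.
#' The full-graph projection is the prediction target and is treated as a
#' constant (no gradient flows through it during training).
#'
#' @param H_masked N x d embedding of the masked graph.
#' @param H_full N x d embedding of the unmasked graph.
#' @param projector projector \code{mlp_params}.
#' @param gamma scaling exponent.
#' @return scalar loss >= 0.
#' @export
regularization_loss <- function(H_masked, H_full, projector, gamma = 2) {
  zbar <- project_regularizer(H_masked, projector)
  xbar <- project_regularizer(H_full, projector)
  sce_rows(xbar, zbar, seq_len(nrow(zbar)), gamma, grad = FALSE)$loss /
    nrow(zbar)
}
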