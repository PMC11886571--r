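# Fixture builders and independent brute-force oracles shared across tests.

# small labelled dataset on a grid, built directly (not via the generator)
toy_dataset <- function(n_spots = 9, n_genes = 4, seed = 1) {
  set.seed(seed)
  m <- matrix(rpois(n_spots * n_genes, 5), n_spots, n_genes)
  side <- ceiling(sqrt(n_spots))
  coords <- cbind(x = ((seq_len(n_spots) - 1) %% side),
                  y = ((seq_len(n_spots) - 1) %/% side))
  spatial_dataset(m, coords,
                  spot_ids = paste0("s", seq_len(n_spots)),
                  gene_ids = paste0("g", seq_len(n_genes)))
}

# a small preprocessed graph for neural-layer tests
toy_graph <- function(n_side = 5, n_genes = 30, seed = 3, k = 3) {
  spec <- synthetic_spec(grid_shape = c(n_side, n_side), n_domains = 2,
                         n_genes = n_genes,
                         n_marker_genes_per_domain = min(5, n_genes %/% 2),
                         seed = seed)
  ds <- generate_synthetic(spec)
  pp <- preprocess(ds, n_top = n_genes)
  g <- assemble_graph(pp$dataset, k = k)
  g$labels <- ds$labels
  g
}

# O(N^2) brute-force kNN adjacency with union symmetrization and
# ascending-index tie-breaks; the independent oracle for build_knn_graph
brute_knn <- function(coords, k) {
  n <- nrow(coords)
  a <- matrix(0, n, n)
  for (i in seq_len(n)) {
    d <- sqrt(colSums((t(coords) - coords[i, ])^2))
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]
    a[i, nb] <- 1
  }
  (a + t(a) > 0) * 1
}

# dense single-head graph-attention oracle: plain loops over nodes
brute_gat <- function(adj, X, p) {
  n <- nrow(adj)
  S <- X %*% p$W
  lrelu <- function(v) ifelse(v > 0, v, 0.2 * v)
  out <- matrix(0, n, ncol(S))
  for (i in seq_len(n)) {
    nbr <- c(which(adj[i, ] > 0), i)      # closed neighbourhood
    nbr <- sort(unique(nbr))
    sc <- sapply(nbr, function(j) lrelu(sum(S[i, ] * p$a1) +
                                          sum(S[j, ] * p$a2)))
    al <- exp(sc - max(sc)); al <- al / sum(al)
    agg <- colSums(al * S[nbr, , drop = FALSE])
    out[i, ] <- if (p$act == "elu") ifelse(agg > 0, agg, exp(agg) - 1) else agg
  }
  out
}

# symmetric-normalized adjacency with self-loops, dense
brute_ahat <- function(adj) {
  ai <- as.matrix(adj) + diag(nrow(adj))
  d <- rowSums(ai)
  diag(1 / sqrt(d)) %*% ai %*% diag(1 / sqrt(d))
}

# exhaustive best one-to-one matching accuracy for small cluster counts
brute_acc <- function(truth, pred) {
  truth <- as.integer(factor(truth)); pred <- as.integer(factor(pred))
  ct <- length(unique(truth)); cp <- length(unique(pred))
  stopifnot(max(ct, cp) <= 5)
  perms <- function(v) if (length(v) <= 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  best <- 0
  for (p in perms(seq_len(max(ct, cp))))
    best <- max(best, sum(p[pred] == truth))
  best / length(truth)
}
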