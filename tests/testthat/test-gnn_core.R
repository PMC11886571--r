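test_that("encoder output matches the dense attention oracle", {
  g <- toy_graph(n_side = 4, n_genes = 12)
  set.seed(5)
  p <- init_gat_params(12, 6, act = "elu")
  expect_equal(encode(g, g$features, p),
               brute_gat(as.matrix(g$adjacency), g$features, p),
               tolerance = 1e-12)
})

test_that("decoder output matches the dense attention oracle", {
  g <- toy_graph(n_side = 4, n_genes = 12)
  set.seed(6)
  enc <- init_gat_params(12, 6)
  dec <- init_gat_params(6, 12, act = "identity")
  H <- encode(g, g$features, enc)
  Z <- decode(g, H, dec)
  expect_equal(dim(Z), c(16L, 12L))
  expect_equal(Z, brute_gat(as.matrix(g$adjacency), H, dec),
               tolerance = 1e-12)
})

test_that("attention weights are a simplex over each closed neighbourhood", {
  g <- toy_graph(n_side = 5, n_genes = 10)
  set.seed(7)
  p <- init_gat_params(10, 4)
  fw <- stgmae:::gat_forward(g$edges, g$features, p)
  expect_true(all(fw$alpha >= 0))
  sums <- as.numeric(tapply(fw$alpha, g$edges$ei, sum))
  expect_equal(sums, rep(1, g$n_nodes), tolerance = 1e-12)
})

test_that("star graph with identical features gives uniform attention", {
  # hub node 1 linked to 4 identical leaves
  a <- matrix(0, 5, 5); a[1, 2:5] <- 1; a[2:5, 1] <- 1
  X <- matrix(1, 5, 3)
  edges <- stgmae:::graph_edge_index(Matrix::Matrix(a, sparse = TRUE))
  set.seed(8)
  p <- init_gat_params(3, 2)
  fw <- stgmae:::gat_forward(edges, X, p)
  hub <- as.numeric(fw$alpha[edges$ei == 1])
  expect_equal(hub, rep(1 / 5, 5), tolerance = 1e-12)
})

test_that("permutation equivariance: relabeling nodes permutes outputs", {
  g <- toy_graph(n_side = 4, n_genes = 10)
  set.seed(9)
  p <- init_gat_params(10, 5)
  H <- encode(g, g$features, p)
  perm <- sample(g$n_nodes)
  a2 <- as.matrix(g$adjacency)[perm, perm]
  edges2 <- stgmae:::graph_edge_index(Matrix::Matrix(a2, sparse = TRUE))
  H2 <- stgmae:::gat_forward(edges2, g$features[perm, ], p)$out
  expect_equal(H2, H[perm, ], tolerance = 1e-10)
})

test_that("one-hop locality: features outside the closed neighbourhood are inert", {
  g <- toy_graph(n_side = 5, n_genes = 8)
  set.seed(10)
  p <- init_gat_params(8, 4)
  H <- encode(g, g$features, p)
  a <- as.matrix(g$adjacency)
  i <- 1L
  outside <- which(a[i, ] == 0 & seq_len(g$n_nodes) != i)
  X2 <- g$features
  X2[outside[1], ] <- X2[outside[1], ] + 100
  H2 <- encode(g, X2, p)
  expect_equal(H2[i, ], H[i, ], tolerance = 1e-12)
})

test_that("projector and head match a dense affine+ELU oracle", {
  set.seed(11)
  p <- init_mlp_params(6, 6, 3)
  Z <- matrix(rnorm(12), 2, 6)
  hand <- {
    h <- Z %*% p$W1 + matrix(p$b1, 2, 6, byrow = TRUE)
    h <- ifelse(h > 0, h, exp(h) - 1)
    h %*% p$W2 + matrix(p$b2, 2, 3, byrow = TRUE)
  }
  expect_equal(project_head(Z, p), hand, tolerance = 1e-12)
  # zero input through zero-bias MLP stays zero only at zero hidden bias
  p0 <- p; p0$b1[] <- 0; p0$b2[] <- 0
  expect_equal(project_head(matrix(0, 2, 6), p0), matrix(0, 2, 3))
  # identity-weight single-path check for the square projector
  pI <- init_mlp_params(3, 3, 3)
  pI$W1 <- diag(3); pI$b1[] <- 0; pI$W2 <- diag(3); pI$b2[] <- 0
  Zpos <- matrix(abs(rnorm(6)) + 0.1, 2, 3)   # ELU is identity on positives
  expect_equal(project_regularizer(Zpos, pI), Zpos, tolerance = 1e-12)
})

test_that("model initialization records widths and shapes", {
  set.seed(12)
  m <- init_model(20, d = 8, d_prime = 4)
  expect_equal(dim(m$enc$W), c(20L, 8L))
  expect_equal(dim(m$dec$W), c(8L, 20L))
  expect_equal(dim(m$proj$W2), c(8L, 8L))
  expect_equal(dim(m$head$W2), c(8L, 4L))
})
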