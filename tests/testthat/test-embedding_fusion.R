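test_that("one propagation step equals the dense normalized-adjacency product", {
  a <- Matrix::Matrix(rbind(c(0, 1), c(1, 0)), sparse = TRUE)
  H <- rbind(c(1, 2), c(3, -4))
  expect_equal(multi_hop(H, a, n = 1), brute_ahat(a) %*% H,
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("n hops equal n explicit dense products on random graphs", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- sample(8:20, 1)
    coords <- matrix(runif(2 * n), n, 2)
    a <- build_knn_graph(coords, 2)
    H <- matrix(rnorm(n * 4), n, 4)
    ah <- brute_ahat(a)
    dense <- H
    for (hop in 1:4) {
      dense <- ah %*% dense
      expect_equal(multi_hop(H, a, n = hop), dense, ignore_attr = TRUE,
                   tolerance = 1e-10)
    }
  }
})

test_that("multi-hop composes: n steps = n successive single steps", {
  g <- toy_graph(n_side = 5, n_genes = 10)
  H <- matrix(rnorm(g$n_nodes * 6), g$n_nodes, 6)
  step <- multi_hop(H, g$adjacency, 1)
  step <- multi_hop(step, g$adjacency, 1)
  step <- multi_hop(step, g$adjacency, 1)
  expect_equal(multi_hop(H, g$adjacency, 3), step, tolerance = 1e-12)
})

test_that("identical node features are a fixed point on regular graphs", {
  # 4-cycle: all degrees equal, so constant rows are preserved exactly
  a <- Matrix::Matrix(rbind(c(0, 1, 0, 1), c(1, 0, 1, 0),
                            c(0, 1, 0, 1), c(1, 0, 1, 0)), sparse = TRUE)
  H <- matrix(rep(c(2, -1), each = 4), 4, 2)
  for (n in c(1, 3, 5))
    expect_equal(multi_hop(H, a, n), H, ignore_attr = TRUE,
                 tolerance = 1e-12)
})

test_that("locality radius: H_D[i] depends only on nodes within n hops", {
  # path graph 1-2-3-4-5; with n = 1, node 1 ignores nodes 3..5
  a <- Matrix::Matrix(0, 5, 5, sparse = TRUE)
  for (i in 1:4) { a[i, i + 1] <- 1; a[i + 1, i] <- 1 }
  H <- matrix(rnorm(10), 5, 2)
  H2 <- H; H2[4:5, ] <- 99
  expect_equal(multi_hop(H, a, 1)[1:2, ], multi_hop(H2, a, 1)[1:2, ],
               tolerance = 1e-12)
  expect_equal(multi_hop(H, a, 2)[1, ], multi_hop(H2, a, 2)[1, ],
               tolerance = 1e-12)
})

test_that("row variance is non-increasing over 1..10 hops (over-smoothing)", {
  g <- toy_graph(n_side = 6, n_genes = 12, seed = 9)
  set.seed(2)
  H <- matrix(rnorm(g$n_nodes * 8), g$n_nodes, 8)
  rowvar <- function(M) mean(apply(M, 2, var))
  v <- vapply(1:10, function(n) rowvar(multi_hop(H, g$adjacency, n)),
              numeric(1))
  expect_true(all(diff(v) <= 1e-10))
})

test_that("fusion is the elementwise sum with strict shape checking", {
  H <- matrix(1:6, 2, 3); D <- matrix(6:1, 2, 3)
  expect_equal(fuse(H, D), H + D)
  expect_equal(fuse(H, H * 0), H)
  expect_error(fuse(H, t(D)), "identical dimensions")
})

test_that("embedding_set fuses encoder output with its propagation", {
  g <- toy_graph(n_side = 5, n_genes = 12, seed = 10)
  fit <- train(g, training_config(epochs = 2, latent_dim = 6, head_dim = 4,
                                  seed = 1))
  emb <- embedding_set(fit, g)
  expect_equal(emb$H_out, emb$H + emb$H_D, tolerance = 1e-12)
  expect_equal(emb$H, encode(g, g$features, fit$model$enc))
  expect_equal(emb$H_D, multi_hop(emb$H, g$adjacency, 3), tolerance = 1e-12)
  expect_true(all(is.finite(emb$H_out)))
})
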