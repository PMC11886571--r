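test_that("mask plans have the planned size and are reproducible", {
  p1 <- mask_plan(10, mask_rate = 0.3, remask_views = 2, seed = 4)
  p2 <- mask_plan(10, mask_rate = 0.3, remask_views = 2, seed = 4)
  expect_length(p1$masked_nodes, 3L)
  expect_identical(p1$masked_nodes, p2$masked_nodes)
  expect_identical(p1$remask_sets, p2$remask_sets)
  X <- matrix(rnorm(40), 10, 4)
  Xm <- mask_features(X, p1)
  expect_equal(sum(rowSums(Xm != 0) == 0), 3L)
  expect_identical(Xm[-p1$masked_nodes, ], X[-p1$masked_nodes, ])
})

test_that("mask rate 0 and 1 are the identity and the zero matrix", {
  X <- matrix(1, 6, 3)
  expect_identical(mask_features(X, mask_plan(6, 0, seed = 1)), X)
  expect_equal(mask_features(X, mask_plan(6, 1, seed = 1)), matrix(0, 6, 3))
  H <- matrix(2, 6, 2)
  expect_identical(remask_latent(H, mask_plan(6, 0.5, 1, remask_rate = 0,
                                              seed = 1), 1), H)
  expect_equal(remask_latent(H, mask_plan(6, 0.5, 1, remask_rate = 1,
                                          seed = 1), 1), matrix(0, 6, 2))
})

test_that("re-mask views draw independently of the input mask and each other", {
  differs <- vapply(1:20, function(s) {
    p <- mask_plan(40, 0.5, remask_views = 2, seed = s)
    !identical(p$remask_sets[[1]], p$remask_sets[[2]])
  }, logical(1))
  expect_gt(mean(differs), 0.9)
  # remask draws cover masked and unmasked nodes alike
  p <- mask_plan(200, 0.5, remask_views = 1, seed = 2)
  overlap <- length(intersect(p$remask_sets[[1]], p$masked_nodes))
  expect_gt(overlap, 25)   # ~50 expected under equal-probability draws
  expect_lt(overlap, 75)
})

test_that("scaled cosine error matches direct evaluation and its bounds", {
  x <- c(1, 0); z <- c(1, 1)
  expect_equal(scaled_cosine_error(x, z, gamma = 2), (1 - 1 / sqrt(2))^2)
  expect_equal(scaled_cosine_error(x, x, gamma = 2), 0)
  expect_equal(scaled_cosine_error(c(1, 0), c(0, 1), gamma = 1), 1)
  expect_equal(scaled_cosine_error(c(1, 0), c(-1, 0), gamma = 3), 8)
  expect_warning(out <- scaled_cosine_error(c(0, 0), z, gamma = 2),
                 "zero-norm")
  expect_equal(out, 1)
  # raising gamma damps easy rows (cosine error < 1)
  set.seed(3)
  for (i in 1:10) {
    x <- abs(rnorm(4)) + 0.5; z <- x + rnorm(4) * 0.1
    expect_lte(scaled_cosine_error(x, z, 3), scaled_cosine_error(x, z, 2))
  }
})

test_that("reconstruction loss matches a brute-force double sum", {
  set.seed(13)
  X <- matrix(rnorm(4 * 3), 4, 3)
  plan <- mask_plan(4, 0.5, remask_views = 2, seed = 5)
  Z1 <- matrix(rnorm(12), 4, 3)
  Z2 <- matrix(rnorm(12), 4, 3)
  got <- reconstruction_loss(X, list(Z1, Z2), plan, gamma = 2)
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  hand <- 0
  for (Z in list(Z1, Z2))
    for (i in plan$masked_nodes)
      hand <- hand + (1 - cosv(X[i, ], Z[i, ]))^2
  hand <- hand / length(plan$masked_nodes)
  expect_equal(got, hand, tolerance = 1e-12)
  # perfect reconstruction gives zero; K identical views scale linearly
  expect_equal(reconstruction_loss(X, list(X, X), plan, 2), 0)
  l1 <- reconstruction_loss(X, list(Z1), plan, 2)
  l2 <- reconstruction_loss(X, list(Z1, Z1), plan, 2)
  expect_equal(l2, 2 * l1)
  expect_error(reconstruction_loss(X, list(Z1), mask_plan(4, 0, seed = 1), 2),
               "no masked nodes")
})

test_that("rows outside the masked set contribute nothing to the loss", {
  set.seed(14)
  X <- matrix(rnorm(20), 5, 4)
  plan <- mask_plan(5, 0.4, remask_views = 1, seed = 6)
  Z <- X
  out <- setdiff(seq_len(5), plan$masked_nodes)
  Z[out, ] <- matrix(rnorm(length(out) * 4), length(out), 4)
  expect_equal(reconstruction_loss(X, list(Z), plan, 2), 0)
})

test_that("regularization loss is the mean row-wise scaled cosine error", {
  set.seed(15)
  p <- init_mlp_params(4, 4, 4)
  Hm <- matrix(rnorm(12), 3, 4)
  Hf <- matrix(rnorm(12), 3, 4)
  got <- regularization_loss(Hm, Hf, p, gamma = 2)
  zb <- project_regularizer(Hm, p)
  xb <- project_regularizer(Hf, p)
  cosv <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  hand <- mean(sapply(1:3, function(i) (1 - cosv(xb[i, ], zb[i, ]))^2))
  expect_equal(got, hand, tolerance = 1e-12)
  expect_equal(regularization_loss(Hf, Hf, p, 2), 0)
  # anti-parallel projections contribute 2 per row at gamma = 1
  scores <- stgmae:::sce_rows(rbind(c(1, 0)), rbind(c(-1, 0)), 1, gamma = 1,
                              grad = FALSE)
  expect_equal(scores$loss, 2)
})

test_that("loss gradients match finite differences on a tiny graph", {
  g <- toy_graph(n_side = 3, n_genes = 8, seed = 4)
  cfg <- training_config(latent_dim = 4, head_dim = 3, epochs = 1,
                         mask_rate = 0.4, remask_views = 2, seed = 1)
  set.seed(21)
  model <- init_model(8, 4, 3)
  plan <- mask_plan(9, 0.4, 2, seed = 3)
  perm <- sample(9)
  lag <- stgmae:::loss_and_grads(g$features, g$edges, model, cfg, plan, perm)
  loss_of <- function(m)
    stgmae:::loss_and_grads(g$features, g$edges, m, cfg, plan, perm)$loss
  eps <- 1e-5
  for (mod in c("enc", "dec", "proj", "head")) {
    f <- if (mod %in% c("enc", "dec")) "W" else "W1"
    set.seed(22)
    for (i in sample(length(model[[mod]][[f]]), 4)) {
      m1 <- model; m1[[mod]][[f]][i] <- m1[[mod]][[f]][i] + eps
      m2 <- model; m2[[mod]][[f]][i] <- m2[[mod]][[f]][i] - eps
      num <- (loss_of(m1) - loss_of(m2)) / (2 * eps)
      expect_equal(lag$grads[[mod]][[f]][i], num, tolerance = 1e-4,
                   info = paste(mod, f, i))
    }
  }
})
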