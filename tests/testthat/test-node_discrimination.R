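test_that("shuffling permutes features, keeps topology, and is reproducible", {
  g <- toy_graph(n_side = 4, n_genes = 10)
  s1 <- shuffle_graph(g, seed = 3)
  s2 <- shuffle_graph(g, seed = 3)
  expect_identical(s1$permutation, s2$permutation)
  expect_identical(s1$features, g$features[s1$permutation, ])
  # multiset of rows is preserved for any seed
  for (seed in 1:3) {
    sh <- shuffle_graph(g, seed = seed)
    expect_equal(sh$features[order(sh$permutation), ], g$features)
  }
  # forcing the identity permutation reproduces the input
  sid <- shuffle_graph(g, permutation = seq_len(g$n_nodes))
  expect_identical(sid$features, g$features)
})

test_that("summary scores follow the readout closed forms", {
  # all-zero projections: summary is sigmoid(0) = 0.5, scores sigmoid(0)
  sc <- summary_scores(matrix(0, 3, 2), matrix(0, 3, 2))
  expect_equal(sc$s, c(0.5, 0.5))
  expect_equal(sc$g, rep(0.5, 3))
  expect_equal(sc$g_prime, rep(0.5, 3))
  # hand-set 2 x 2 case against a scalar mean/sigmoid/dot oracle
  Z <- rbind(c(1, -1), c(3, 0.5))
  Zp <- rbind(c(-2, 1), c(0, 0))
  got <- summary_scores(Z, Zp)
  sig <- function(x) 1 / (1 + exp(-x))
  s <- c(sig(mean(c(1, 3))), sig(mean(c(-1, 0.5))))
  expect_equal(got$s, s)
  expect_equal(got$g, c(sig(sum(Z[1, ] * s)), sig(sum(Z[2, ] * s))))
  expect_equal(got$g_prime, c(sig(sum(Zp[1, ] * s)), sig(sum(Zp[2, ] * s))))
  # scaling aligned embeddings pushes scores toward 1, capped by clamping
  big <- summary_scores(matrix(50, 3, 2), matrix(-50, 3, 2))
  expect_true(all(big$g >= 1 - 1e-6 & big$g < 1))
  expect_true(all(big$g_prime <= 1e-6 & big$g_prime > 0))
})

test_that("discrimination loss matches its closed forms and brute force", {
  n <- 4
  chance <- list(g = rep(0.5, n), g_prime = rep(0.5, n))
  expect_equal(discrimination_loss(chance), 2 * log(2))
  perfect <- list(g = rep(1 - 1e-7, n), g_prime = rep(1e-7, n))
  expect_lt(discrimination_loss(perfect), 1e-5)
  hand <- list(g = c(0.9, 0.8), g_prime = c(0.2, 0.1))
  expect_equal(discrimination_loss(hand),
               (log(1 / 0.9) + log(1 / (1 - 0.2)) +
                  log(1 / 0.8) + log(1 / (1 - 0.1))) / 2)
  # strictly decreasing in g, increasing in g'
  l0 <- discrimination_loss(hand)
  expect_lt(discrimination_loss(list(g = c(0.95, 0.8), g_prime = hand$g_prime)), l0)
  expect_gt(discrimination_loss(list(g = hand$g, g_prime = c(0.3, 0.1))), l0)
})

test_that("an untrained encoder scores near chance level on shuffled graphs", {
  g <- toy_graph(n_side = 6, n_genes = 20, seed = 8)
  losses <- vapply(1:5, function(s) {
    set.seed(100 + s)
    model <- init_model(20, 16, 8)
    sh <- shuffle_graph(g, seed = s)
    Z <- project_head(encode(g, g$features, model$enc), model$head)
    Zp <- project_head(encode(g, sh$features, model$enc), model$head)
    discrimination_loss(summary_scores(Z, Zp))
  }, numeric(1))
  expect_equal(mean(losses), 2 * log(2), tolerance = 0.35)
})

test_that("training teaches the model to separate original from shuffled", {
  g <- toy_graph(n_side = 6, n_genes = 20, seed = 9)
  cfg <- training_config(epochs = 150, latent_dim = 16, head_dim = 8,
                         seed = 2)
  fit <- train(g, cfg)
  sh <- shuffle_graph(g, seed = 11)
  Z <- project_head(encode(g, g$features, fit$model$enc), fit$model$head)
  Zp <- project_head(encode(g, sh$features, fit$model$enc), fit$model$head)
  sc <- summary_scores(Z, Zp)
  expect_gt(mean(sc$g), mean(sc$g_prime))
})
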