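test_that("band layout tiles the grid into equal contiguous domains", {
  spec <- synthetic_spec(grid_shape = c(10, 10), n_domains = 5, seed = 1)
  ds <- generate_synthetic(spec)
  expect_equal(dim(ds$matrix), c(100L, 200L))
  expect_equal(as.integer(table(ds$labels)), rep(20L, 5))
  # bands are contiguous in y: label is a monotone function of the row
  expect_true(all(diff(ds$labels[order(ds$coords[, "y"])]) >= 0))
})

test_that("fixed seeds give byte-identical draws; layouts stay non-empty", {
  spec <- synthetic_spec(seed = 42)
  expect_identical(generate_synthetic(spec)$matrix,
                   generate_synthetic(spec)$matrix)
  for (lay in c("bands", "blocks", "voronoi")) {
    s <- synthetic_spec(grid_shape = c(12, 12), n_domains = 4, layout = lay,
                        seed = 3)
    d <- generate_synthetic(s)
    expect_equal(length(unique(d$labels)), 4L, info = lay)
  }
})

test_that("marker programs shift domain means as specified", {
  spec <- synthetic_spec(grid_shape = c(20, 20), seed = 7,
                         marker_fold_change = 4, baseline_mean = 2)
  ds <- generate_synthetic(spec)
  m <- as.matrix(ds$matrix)
  # markers of domain 1 are genes 1..20
  in1 <- ds$labels == 1
  expect_equal(mean(m[in1, 1:20]), 8, tolerance = 0.5)
  expect_equal(mean(m[!in1, 1:20]), 2, tolerance = 0.25)
  # fold change 1 plants no signal
  null_spec <- synthetic_spec(grid_shape = c(10, 10), marker_fold_change = 1,
                              seed = 8)
  nd <- generate_synthetic(null_spec)
  nm <- as.matrix(nd$matrix)
  expect_lt(abs(mean(nm[nd$labels == 1, 1:20]) -
                  mean(nm[nd$labels != 1, 1:20])), 0.3)
})

test_that("oracle classification on true domain means recovers planted labels", {
  # noise-free expectation matrix: recovery is exact
  spec <- synthetic_spec(seed = 21)
  ds <- generate_synthetic(spec)
  mu <- matrix(spec$baseline_mean, nrow(ds$matrix), spec$n_genes)
  for (d in 1:5)
    mu[ds$labels == d, ((d - 1) * 20 + 1):(d * 20)] <-
      spec$baseline_mean * spec$marker_fold_change
  dsm <- spatial_dataset(mu, ds$coords, ds$spot_ids, ds$gene_ids, ds$labels)
  Xm <- preprocess(dsm)$dataset$matrix
  musm <- t(sapply(1:5, function(d) colMeans(Xm[ds$labels == d, , drop = FALSE])))
  d2m <- outer(rowSums(Xm^2), rowSums(musm^2), "+") - 2 * tcrossprod(Xm, musm)
  expect_equal(ari(ds$labels, max.col(-d2m)), 1)
  # overdispersed dropout-free draws: near-exact recovery across seeds
  aris <- vapply(c(21, 22, 23), function(s) {
    d <- generate_synthetic(synthetic_spec(seed = s))
    X <- preprocess(d)$dataset$matrix
    mus <- t(sapply(1:5, function(k) colMeans(X[d$labels == k, , drop = FALSE])))
    dd <- outer(rowSums(X^2), rowSums(mus^2), "+") - 2 * tcrossprod(X, mus)
    ari(d$labels, max.col(-dd))
  }, numeric(1))
  expect_true(all(aris >= 0.99))
})

test_that("dropout zeroes entries at the requested binomial rate", {
  spec <- synthetic_spec(grid_shape = c(10, 10), n_genes = 50,
                         n_marker_genes_per_domain = 5, baseline_mean = 20,
                         seed = 5)
  ds <- generate_synthetic(spec)
  expect_identical(apply_dropout(ds, 0, seed = 1)$matrix, ds$matrix)
  expect_true(all(apply_dropout(ds, 1, seed = 1)$matrix == 0))
  nz_before <- sum(ds$matrix != 0)
  out <- apply_dropout(ds, 0.5, seed = 9)
  zeroed <- sum(ds$matrix != 0 & out$matrix == 0)
  # within 3 sigma of Binomial(nz_before, 0.5)
  expect_lt(abs(zeroed - 0.5 * nz_before), 3 * sqrt(nz_before * 0.25))
  expect_identical(out$coords, ds$coords)
  expect_identical(out$labels, ds$labels)
})

test_that("dropout commutes with row subsetting", {
  spec <- synthetic_spec(grid_shape = c(6, 6), n_genes = 40,
                         n_marker_genes_per_domain = 5, seed = 6)
  ds <- generate_synthetic(spec)
  keep <- c(3, 7, 20, 31)
  a <- stgmae:::subset_dataset(apply_dropout(ds, 0.4, seed = 2), spots = keep)
  b <- apply_dropout(stgmae:::subset_dataset(ds, spots = keep), 0.4, seed = 2)
  expect_identical(a$matrix, b$matrix)
})

test_that("a single-rate sweep at dropout 0 equals the clean pipeline", {
  spec <- synthetic_spec(grid_shape = c(8, 8), n_domains = 2, n_genes = 60,
                         n_marker_genes_per_domain = 15, seed = 12)
  cfg <- training_config(epochs = 20, latent_dim = 8, head_dim = 4, seed = 1)
  sw <- dropout_sweep(spec, rates = 0, cfg = cfg, n_top = 60)
  ds <- generate_synthetic(spec)
  direct <- spatial_domains(ds, 2, cfg = cfg, n_top = 60)
  expect_equal(sw$ari, ari(ds$labels, direct$assignment$labels))
})
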