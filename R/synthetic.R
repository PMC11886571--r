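#' Specification of a planted-domain synthetic tissue
#'
#' Describes a grid of spots partitioned into contiguous spatial domains
#' (layered bands by default, emulating cortex-like laminae), each with a
#' program of marker genes whose mean expression is elevated by
#' \code{marker_fold_change}, with negative-binomial count noise and an
#' optional random-zeroing dropout corruption. Defaults emulate a small
#' Visium-like section: 20 x 20 spots, 5 band domains, 200 genes with 20
#' markers per domain, baseline mean 2 counts/gene, fold change 4,
#' negative-binomial size 2 (overdispersed).
#'
#' @param grid_shape integer (rows, cols) of the spot grid.
#' @param n_domains number of planted domains D (>= 2).
#' @param layout \code{"bands"} (parallel layers), \code{"blocks"}
#'   (checker blocks), or \code{"voronoi"} (nearest of D random centers).
#' @param n_genes total number of genes G.
#' @param n_marker_genes_per_domain markers per domain (disjoint sets).
#' @param baseline_mean negative-binomial mean of non-marker expression.
#' @param marker_fold_change multiplicative mean shift of a domain's
#'   markers inside that domain; 1 plants no signal.
#' @param dispersion negative-binomial size parameter (smaller = more
#'   overdispersed).
#' @param dropout_rate probability that an entry is zeroed after counts are
#'   drawn, in [0, 1].
#' @param seed integer seed; generation is deterministic per seed.
#' @return object of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(grid_shape = c(20, 20), n_domains = 5,
                           layout = c("bands", "blocks", "voronoi"),
                           n_genes = 200, n_marker_genes_per_domain = 20,
                           baseline_mean = 2, marker_fold_change = 4,
                           dispersion = 2, dropout_rate = 0, seed = 1) {
  layout <- match.arg(layout)
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1), n_domains >= 2,
            n_genes >= n_domains * n_marker_genes_per_domain,
            baseline_mean > 0, marker_fold_change > 0, dispersion > 0,
            dropout_rate >= 0, dropout_rate <= 1)
  structure(list(grid_shape = as.integer(grid_shape),
                 n_domains = as.integer(n_domains), layout = layout,
                 n_genes = as.integer(n_genes),
                 n_marker_genes_per_domain =
                   as.integer(n_marker_genes_per_domain),
                 baseline_mean = baseline_mean,
                 marker_fold_change = marker_fold_change,
                 dispersion = dispersion, dropout_rate = dropout_rate,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# planted domain label per spot for a given layout
planted_layout <- function(spec, rows, cols) {
  d <- spec$n_domains
  ri <- rep(seq_len(rows), each = cols)
  ci <- rep(seq_len(cols), times = rows)
  if (spec$layout == "bands") {
    # contiguous horizontal bands of (near-)equal height
    pmin(ceiling(ri / (rows / d)), d)
  } else if (spec$layout == "blocks") {
    nbr <- ceiling(sqrt(d))
    nbc <- ceiling(d / nbr)
    br <- pmin(ceiling(ri / (rows / nbr)), nbr)
    bc <- pmin(ceiling(ci / (cols / nbc)), nbc)
    pmin((br - 1L) * nbc + bc, d)
  } else {  # voronoi: nearest of D random centers
    ctr <- cbind(stats::runif(d, 1, cols), stats::runif(d, 1, rows))
    xy <- cbind(ci, ri)
    max.col(-squared_distances_to(xy, ctr))
  }
}

squared_distances_to <- function(x, centers) {
  outer(rowSums(x^2), rowSums(centers^2), "+") - 2 * tcrossprod(x, centers)
}

#' Generate a planted-domain synthetic dataset
#'
#' Draws counts \code{NB(mu, size = dispersion)} with
#' \code{mu = baseline_mean * fold} where \code{fold =
#' marker_fold_change} for a domain's markers inside that domain and 1
#' elsewhere, applies the spec's dropout corruption, and returns a
#' labelled \code{\link{spatial_dataset}}. Byte-identical across runs for
#' a fixed spec.
#'
#' @param spec a \code{\link{synthetic_spec}}.
#' @return a \code{spatial_dataset} with planted domain \code{labels}.
#' @export
generate_synthetic <- function(spec) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  rows <- spec$grid_shape[1]; cols <- spec$grid_shape[2]
  n <- rows * cols; g <- spec$n_genes
  labels <- planted_layout(spec, rows, cols)
  if (length(unique(labels)) < spec$n_domains)
    stop("layout produced an empty domain; enlarge the grid", call. = FALSE)
  # disjoint marker sets: domain d owns genes (d-1)*m+1 .. d*m
  m <- spec$n_marker_genes_per_domain
  mu <- matrix(spec$baseline_mean, n, g)
  for (d in seq_len(spec$n_domains)) {
    genes <- ((d - 1) * m + 1):(d * m)
    mu[labels == d, genes] <- spec$baseline_mean * spec$marker_fold_change
  }
  counts <- matrix(stats::rnbinom(n * g, mu = mu, size = spec$dispersion),
                   n, g)
  coords <- cbind(x = rep(seq_len(cols), times = rows),
                  y = rep(seq_len(rows), each = cols))
  ds <- spatial_dataset(counts, coords,
                        spot_ids = sprintf("spot_%04d", seq_len(n)),
                        gene_ids = sprintf("gene_%04d", seq_len(g)),
                        labels = labels)
  if (spec$dropout_rate > 0)
    ds <- apply_dropout(ds, spec$dropout_rate, seed = spec$seed + 1L)
  ds
}

# deterministic per-spot sub-seed so dropout draws depend only on
# (seed, spot id, gene count), never on row order
spot_subseed <- function(seed, spot_id) {
  h <- 0
  for (v in utf8ToInt(spot_id)) h <- (h * 131 + v) %% 2147483647
  as.integer((h + as.double(seed) * 7919) %% 2147483647)
}

#' Random dropout corruption
#'
#' Independently zeroes each matrix entry with probability \code{rate},
#' emulating technical dropout; coordinates and labels are unchanged. The
#' per-entry draws are keyed by spot id, so corrupting then subsetting
#' rows equals subsetting then corrupting.
#'
#' @param ds a \code{\link{spatial_dataset}}.
#' @param rate zeroing probability in [0, 1].
#' @param seed integer seed.
#' @return the corrupted \code{spatial_dataset}.
#' @export
apply_dropout <- function(ds, rate, seed = 0) {
  stopifnot(rate >= 0, rate <= 1)
  if (rate == 0) return(ds)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  m <- as.matrix(ds$matrix)
  g <- ncol(m)
  for (i in seq_len(nrow(m))) {
    set.seed(spot_subseed(seed, ds$spot_ids[i]))
    m[i, stats::runif(g) < rate] <- 0
  }
  ds$matrix <- m
  ds
}

#' Dropout robustness sweep
#'
#' For each dropout rate, corrupts a freshly generated dataset, runs the
#' full pipeline (preprocess, graph, train, fuse, GMM cluster) and records
#' the ARI against the planted labels — the robustness curve of the
#' method.
#'
#' @param spec a \code{\link{synthetic_spec}} describing the clean data.
#' @param rates numeric vector of dropout rates in [0, 1].
#' @param cfg a \code{\link{training_config}}.
#' @param n_top,k passed to the pipeline (HVG count, graph neighbours).
#' @return data.frame with columns \code{rate}, \code{ari}.
#' @export
dropout_sweep <- function(spec, rates = seq(0, 0.9, by = 0.1),
                          cfg = training_config(), n_top = 3000, k = 3) {
  stopifnot(all(rates >= 0 & rates <= 1))
  res <- vapply(rates, function(r) {
    ds <- generate_synthetic(spec)
    ds <- apply_dropout(ds, r, seed = spec$seed + 100L)
    out <- spatial_domains(ds, n_clusters = spec$n_domains, cfg = cfg,
                           n_top = n_top, k = k)
    ari(ds$labels, out$assignment$labels)
  }, numeric(1))
  data.frame(rate = rates, ari = res)
}
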