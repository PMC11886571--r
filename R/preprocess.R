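#' Remove outlier spots by total count
#'
#' Drops spots whose total expression count falls below \code{min_counts};
#' coordinates and labels are filtered consistently and surviving rows are
#' left untouched.
#'
#' @param ds a \code{\link{spatial_dataset}}.
#' @param min_counts minimum total count a spot must reach to be kept
#'   (default 1, i.e. drop empty spots).
#' @return list with elements \code{dataset} (filtered) and \code{report}
#'   (a \code{preprocess_report}).
#' @export
remove_outlier_spots <- function(ds, min_counts = 1) {
  stopifnot(min_counts >= 0)
  totals <- as.numeric(Matrix::rowSums(ds$matrix))
  keep <- totals >= min_counts
  if (!any(keep))
    stop("all spots fall below min_counts = ", min_counts, call. = FALSE)
  out <- subset_dataset(ds, spots = which(keep))
  rep <- preprocess_report(n_spots_removed = sum(!keep),
                           n_genes_input = ncol(ds$matrix))
  list(dataset = out, report = rep)
}

preprocess_report <- function(n_spots_removed = 0L, n_genes_input = NA_integer_,
                              n_hvg_selected = NA_integer_,
                              transform_applied = "passthrough") {
  stopifnot(is.na(n_hvg_selected) || is.na(n_genes_input) ||
              n_hvg_selected <= n_genes_input)
  structure(list(n_spots_removed = as.integer(n_spots_removed),
                 n_genes_input = as.integer(n_genes_input),
                 n_hvg_selected = as.integer(n_hvg_selected),
                 transform_applied = transform_applied),
            class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat("preprocess_report: removed ", x$n_spots_removed, " spot(s); ",
      x$n_genes_input, " genes in, ",
      if (is.na(x$n_hvg_selected)) "all" else x$n_hvg_selected,
      " HVGs kept; transform = ", x$transform_applied, "\n", sep = "")
  invisible(x)
}

#' Library-size normalization and log transform
#'
#' Scales each spot so its total equals \code{scale_total} (spots with zero
#' total are left as all zeros), then applies \code{log(1 + x)} elementwise —
#' the standard total-count ("CPM-like") normalization used for ST counts.
#'
#' @param ds a \code{\link{spatial_dataset}} with non-negative entries.
#' @param scale_total target row total (default 1e4).
#' @return the transformed \code{spatial_dataset} (dense matrix).
#' @export
lognormalize <- function(ds, scale_total = 1e4) {
  m <- as.matrix(ds$matrix)
  totals <- rowSums(m)
  fac <- ifelse(totals > 0, scale_total / totals, 0)
  m <- log1p(m * fac)
  dimnames(m) <- list(ds$spot_ids, ds$gene_ids)
  ds$matrix <- m
  ds
}

#' Highly variable gene selection
#'
#' Ranks genes by a normalized-dispersion score: per-gene dispersion
#' (variance / mean of the log-normalized values, zero-mean genes scoring 0)
#' is z-scored within 20 equal-frequency mean bins, so that variability is
#' judged relative to genes of similar abundance. The top \code{n_top} genes
#' are kept; ties are broken by ascending gene id so the selection is
#' deterministic. If \code{n_top >= n_genes} the dataset is returned intact.
#'
#' @param ds a \code{\link{spatial_dataset}} (typically log-normalized).
#' @param n_top number of genes to keep (default 3000).
#' @param n_bins number of mean-abundance bins (default 20).
#' @return the \code{spatial_dataset} restricted to the selected genes, in
#'   score order (descending).
#' @export
select_hvg <- function(ds, n_top = 3000, n_bins = 20) {
  stopifnot(n_top >= 1)
  g <- ncol(ds$matrix)
  if (n_top >= g) return(ds)
  m <- ds$matrix
  mu <- as.numeric(Matrix::colMeans(m))
  ex2 <- as.numeric(Matrix::colMeans(m * m))
  n <- nrow(m)
  v <- (ex2 - mu^2) * n / max(n - 1, 1)
  disp <- ifelse(mu > 0, v / mu, 0)
  # z-score dispersion within equal-frequency mean bins; keep bins
  # populated (>= ~20 genes each) so small panels fall back to a global
  # dispersion ranking
  n_bins <- max(1, min(n_bins, g %/% 20))
  br <- unique(stats::quantile(mu, probs = seq(0, 1, length.out = n_bins + 1)))
  bins <- if (length(br) > 2) cut(mu, breaks = br, include.lowest = TRUE)
          else factor(rep(1L, g))
  bm <- tapply(disp, bins, mean)
  bs <- tapply(disp, bins, stats::sd)
  bs[is.na(bs) | bs == 0] <- 1
  score <- (disp - bm[bins]) / bs[bins]
  ord <- order(-score, ds$gene_ids)
  subset_dataset(ds, genes = ord[seq_len(n_top)])
}

#' Gene-wise unit-variance scaling
#'
#' Centers each gene to mean zero and scales to unit variance
#' (zero-variance genes become all-zero), clipping values above
#' \code{max_value}. Standard final preprocessing step before the scaled
#' cosine criterion: without centering, all-positive expression vectors
#' have near-identical cosines and the reconstruction objective is weakly
#' discriminative. The output contains negative values; the dataset is
#' flagged as transformed so downstream validation accepts it.
#'
#' @param ds a \code{\link{spatial_dataset}} (typically log-normalized).
#' @param max_value clip ceiling after scaling (default 10).
#' @return the scaled \code{spatial_dataset}.
#' @export
scale_genes <- function(ds, max_value = 10) {
  m <- as.matrix(ds$matrix)
  mu <- colMeans(m)
  sdv <- apply(m, 2, stats::sd)
  sdv[sdv == 0 | is.na(sdv)] <- Inf   # constant genes -> all zeros
  m <- sweep(sweep(m, 2, mu, "-"), 2, sdv, "/")
  m[m > max_value] <- max_value
  dimnames(m) <- list(ds$spot_ids, ds$gene_ids)
  ds$matrix <- m
  ds$transformed <- TRUE
  ds
}

#' Full preprocessing pipeline
#'
#' Outlier-spot removal, total-count normalization to \code{scale_total},
#' \code{log1p}, highly-variable-gene selection, and gene-wise
#' unit-variance scaling, in that order; the output matrix is the
#' node-feature matrix X of the spatial graph.
#'
#' @inheritParams remove_outlier_spots
#' @inheritParams lognormalize
#' @inheritParams select_hvg
#' @param normalize if \code{FALSE}, skip normalization/log (input already
#'   transformed).
#' @param scale if \code{FALSE}, skip the final \code{\link{scale_genes}}
#'   step.
#' @return list with \code{dataset} and a \code{preprocess_report}.
#' @export
preprocess <- function(ds, min_counts = 1, scale_total = 1e4, n_top = 3000,
                       normalize = TRUE, scale = TRUE) {
  filt <- remove_outlier_spots(ds, min_counts)
  out <- filt$dataset
  if (normalize) out <- lognormalize(out, scale_total)
  out <- select_hvg(out, n_top)
  if (scale) out <- scale_genes(out)
  rep <- preprocess_report(
    n_spots_removed = filt$report$n_spots_removed,
    n_genes_input = ncol(ds$matrix),
    n_hvg_selected = ncol(out$matrix),
    transform_applied = if (normalize && scale) "lognorm_scaled"
                        else if (normalize) "lognorm" else "passthrough")
  list(dataset = out, report = rep)
}
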