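#' Domain assignment container
#'
#' @param labels integer cluster label per spot (1..C).
#' @param responsibilities N x C matrix of soft assignments, rows summing
#'   to 1 (one-hot for hard methods).
#' @param method one of \code{"gmm"}, \code{"kmeans"}, \code{"louvain"}.
#' @param loglik_trace optional per-iteration log-likelihood (GMM).
#' @return object of class \code{domain_assignment}.
#' @export
domain_assignment <- function(labels, responsibilities, method,
                              loglik_trace = NULL) {
  stopifnot(nrow(responsibilities) == length(labels),
            max(abs(rowSums(responsibilities) - 1)) < 1e-9)
  structure(list(labels = as.integer(labels),
                 responsibilities = responsibilities,
                 n_clusters = ncol(responsibilities),
                 method = method, loglik_trace = loglik_trace),
            class = "domain_assignment")
}

#' @export
print.domain_assignment <- function(x, ...) {
  cat("domain_assignment (", x$method, "): ", length(x$labels),
      " spots in ", x$n_clusters, " domains\n", sep = "")
  print(table(domain = x$labels))
  invisible(x)
}

# k-means++ seeding (deterministic given the current RNG state)
kmeanspp_centers <- function(Y, k) {
  n <- nrow(Y)
  centers <- matrix(0, k, ncol(Y))
  idx <- sample.int(n, 1)
  centers[1, ] <- Y[idx, ]
  d2 <- rowSums((Y - matrix(centers[1, ], n, ncol(Y), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx <- sample.int(n, 1, prob = p)
    centers[j, ] <- Y[idx, ]
    d2 <- pmin(d2, rowSums((Y - matrix(centers[j, ], n, ncol(Y),
                                       byrow = TRUE))^2))
  }
  centers
}

# log N(y | mu, Sigma) for all rows and components, shared or per-component
# covariance given as a list of Cholesky factors
mvn_logdens <- function(Y, mu, chol_list) {
  n <- nrow(Y); k <- nrow(mu); d <- ncol(Y)
  out <- matrix(0, n, k)
  for (j in seq_len(k)) {
    ch <- chol_list[[min(j, length(chol_list))]]
    ctr <- sweep(Y, 2, mu[j, ], "-")
    z <- forwardsolve(t(ch), t(ctr))
    out[, j] <- -0.5 * (d * log(2 * pi) + 2 * sum(log(diag(ch))) +
                          colSums(z^2))
  }
  out
}

#' Gaussian-mixture clustering of embeddings
#'
#' Model-based clustering of the fused embeddings by an EM-fitted Gaussian
#' mixture with a fixed number of components. The default covariance model
#' is a single covariance matrix shared by all components (mclust's "EEE"
#' family); \code{covariance = "full"} gives each component its own. EM is
#' initialized from a deterministic k-means++ hard assignment; the best of
#' \code{restarts} seedings by final log-likelihood is kept. When a
#' component empties, the fit is re-initialized (up to 5 times) before
#' failing. For annotated data set \code{n_clusters} to the number of
#' annotated domains.
#'
#' @param H_out N x d embedding matrix.
#' @param n_clusters number of mixture components C (>= 2, < N).
#' @param seed integer seed making the fit reproducible.
#' @param covariance \code{"shared"} (default) or \code{"full"}.
#' @param restarts number of k-means++ seedings (default 10).
#' @param max_iter EM iteration cap per fit.
#' @param tol relative log-likelihood convergence tolerance.
#' @return a \code{\link{domain_assignment}} with soft responsibilities and
#'   the log-likelihood trace of the winning fit.
#' @export
cluster_gmm <- function(H_out, n_clusters, seed = 0,
                        covariance = c("shared", "full"), restarts = 10,
                        max_iter = 200, tol = 1e-6) {
  covariance <- match.arg(covariance)
  Y <- as.matrix(H_out)
  n <- nrow(Y)
  stopifnot(n_clusters >= 2, n > n_clusters)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- tryCatch(gmm_em_once(Y, n_clusters, covariance, max_iter, tol),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$loglik > best$loglik))
      best <- fit
  }
  if (is.null(best))
    stop("GMM failed to fit: all ", restarts, " initializations degenerated",
         call. = FALSE)
  domain_assignment(best$labels, best$resp, "gmm",
                    loglik_trace = best$trace)
}

gmm_em_once <- function(Y, k, covariance, max_iter, tol, reinit_max = 5) {
  n <- nrow(Y); d <- ncol(Y)
  for (attempt in seq_len(reinit_max)) {
    centers <- kmeanspp_centers(Y, k)
    km <- suppressWarnings(stats::kmeans(Y, centers = centers,
                                         iter.max = 50,
                                         algorithm = "Lloyd"))
    resp <- diag(k)[km$cluster, , drop = FALSE]
    trace <- numeric(0)
    prev <- -Inf
    ok <- TRUE
    for (it in seq_len(max_iter)) {
      # M-step
      nk <- colSums(resp)
      if (any(nk < 1e-8)) { ok <- FALSE; break }
      w <- nk / n
      mu <- crossprod(resp, Y) / nk
      ridge <- 1e-6 * mean(apply(Y, 2, stats::var)) + 1e-10
      if (covariance == "shared") {
        sig <- matrix(0, d, d)
        for (j in seq_len(k)) {
          ctr <- sweep(Y, 2, mu[j, ], "-")
          sig <- sig + crossprod(ctr * resp[, j], ctr)
        }
        sig <- sig / n + diag(ridge, d)
        chol_list <- list(chol(sig))
      } else {
        chol_list <- lapply(seq_len(k), function(j) {
          ctr <- sweep(Y, 2, mu[j, ], "-")
          chol(crossprod(ctr * resp[, j], ctr) / nk[j] + diag(ridge, d))
        })
      }
      # E-step
      ld <- sweep(mvn_logdens(Y, mu, chol_list), 2, log(w), "+")
      m <- apply(ld, 1, max)
      lse <- m + log(rowSums(exp(ld - m)))
      resp <- exp(ld - lse)
      ll <- sum(lse)
      trace <- c(trace, ll)
      if (is.finite(prev) && abs(ll - prev) < tol * (abs(prev) + 1)) break
      prev <- ll
    }
    if (ok)
      return(list(labels = max.col(resp), resp = resp,
                  loglik = trace[length(trace)], trace = trace))
  }
  stop("EM degenerated (empty component) after ", reinit_max, " re-inits",
       call. = FALSE)
}

#' k-means clustering of embeddings
#'
#' Lloyd iterations from a deterministic k-means++ seeding; best of
#' \code{restarts} seedings by total within-cluster sum of squares.
#' Responsibilities are one-hot.
#'
#' @inheritParams cluster_gmm
#' @param restarts number of seedings.
#' @return a \code{\link{domain_assignment}}.
#' @export
cluster_kmeans <- function(H_out, n_clusters, seed = 0, restarts = 10) {
  Y <- as.matrix(H_out)
  stopifnot(n_clusters >= 2, nrow(Y) > n_clusters)
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- kmeanspp_centers(Y, n_clusters)
    km <- tryCatch(
      suppressWarnings(stats::kmeans(Y, centers = centers, iter.max = 100,
                                     algorithm = "Lloyd")),
      error = function(e) NULL)
    if (!is.null(km) && (is.null(best) || km$tot.withinss < best$tot.withinss))
      best <- km
  }
  if (is.null(best)) stop("k-means failed on all restarts", call. = FALSE)
  resp <- diag(n_clusters)[best$cluster, , drop = FALSE]
  domain_assignment(best$cluster, resp, "kmeans")
}

#' Louvain community clustering of embeddings
#'
#' Builds a k-nearest-neighbour graph in embedding space and partitions it
#' by Louvain modularity optimization; the number of domains is emergent.
#'
#' @inheritParams cluster_gmm
#' @param resolution Louvain resolution parameter.
#' @param knn neighbours per node of the embedding graph.
#' @return a \code{\link{domain_assignment}} (one-hot responsibilities).
#' @export
cluster_louvain <- function(H_out, resolution = 1, seed = 0, knn = 15) {
  Y <- as.matrix(H_out)
  knn <- min(knn, nrow(Y) - 1)
  a <- build_knn_graph(Y, k = knn)
  g <- igraph::graph_from_adjacency_matrix(a, mode = "undirected")
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = resolution)
  labels <- as.integer(igraph::membership(cl))
  resp <- diag(max(labels))[labels, , drop = FALSE]
  domain_assignment(labels, resp, "louvain")
}
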