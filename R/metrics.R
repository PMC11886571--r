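# Clustering-agreement metrics: ARI, NMI and Hungarian-matched accuracy.
# All three are invariant to relabeling of either partition.

check_label_pair <- function(labels_true, labels_pred) {
  if (length(labels_true) != length(labels_pred))
    stop("label vectors differ in length (", length(labels_true), " vs ",
         length(labels_pred), ")", call. = FALSE)
  list(true = as.integer(factor(labels_true)),
       pred = as.integer(factor(labels_pred)))
}

#' Adjusted Rand index
#'
#' Pair-counting agreement between two partitions, corrected for chance:
#' 1 for identical partitions (up to relabeling), expectation ~0 for
#' independent random partitions.
#'
#' @param labels_true,labels_pred equal-length label vectors (any types
#'   coercible to factors).
#' @return scalar ARI (<= 1).
#' @export
ari <- function(labels_true, labels_pred) {
  l <- check_label_pair(labels_true, labels_pred)
  tab <- table(l$true, l$pred)
  n <- length(l$true)
  sij <- sum(choose(tab, 2))
  a <- sum(choose(rowSums(tab), 2))
  b <- sum(choose(colSums(tab), 2))
  expected <- a * b / choose(n, 2)
  maxi <- (a + b) / 2
  if (maxi == expected) return(1)  # both partitions trivial and identical
  (sij - expected) / (maxi - expected)
}

#' Normalized mutual information
#'
#' Mutual information between the two partitions normalized by the
#' arithmetic mean of their entropies; in [0, 1].
#'
#' @inheritParams ari
#' @return scalar NMI in [0, 1].
#' @export
nmi <- function(labels_true, labels_pred) {
  l <- check_label_pair(labels_true, labels_pred)
  n <- length(l$true)
  tab <- table(l$true, l$pred) / n
  pi <- rowSums(tab); pj <- colSums(tab)
  nz <- tab > 0
  mi <- sum(tab[nz] * log(tab[nz] / outer(pi, pj)[nz]))
  h <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  denom <- (h(pi) + h(pj)) / 2
  if (denom == 0) return(1)  # both partitions trivial and identical
  max(0, min(1, mi / denom))
}

#' Hungarian-matched clustering accuracy
#'
#' Fraction of spots correctly labelled after predicted cluster ids are
#' matched one-to-one to true ids by the maximum-agreement assignment
#' (solved as a maximum-weight bipartite matching on the contingency
#' table).
#'
#' @inheritParams ari
#' @return scalar accuracy in [0, 1].
#' @export
acc <- function(labels_true, labels_pred) {
  l <- check_label_pair(labels_true, labels_pred)
  tab <- unclass(table(l$true, l$pred))
  match_weight <- max_assignment_weight(tab)
  match_weight / length(l$true)
}

# maximum one-to-one assignment weight of a non-negative matrix, via
# maximum-weight bipartite matching (igraph)
max_assignment_weight <- function(w) {
  r <- nrow(w); c <- ncol(w)
  idx <- which(w > 0, arr.ind = TRUE)
  if (!nrow(idx)) return(0)
  edges <- rbind(idx[, 1], r + idx[, 2])
  g <- igraph::make_bipartite_graph(c(rep(FALSE, r), rep(TRUE, c)),
                                    as.vector(edges))
  igraph::E(g)$weight <- w[idx]
  m <- igraph::max_bipartite_match(g)
  m$matching_weight
}

#' Evaluate a domain assignment against reference labels
#'
#' @param labels_true reference labels.
#' @param labels_pred predicted labels or a \code{domain_assignment}.
#' @return named list with \code{acc}, \code{ari}, \code{nmi}.
#' @export
evaluate_clustering <- function(labels_true, labels_pred) {
  if (inherits(labels_pred, "domain_assignment"))
    labels_pred <- labels_pred$labels
  list(acc = acc(labels_true, labels_pred),
       ari = ari(labels_true, labels_pred),
       nmi = nmi(labels_true, labels_pred))
}
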