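#' Identify spatial domains end to end
#'
#' The full method on an in-memory dataset: preprocessing (outlier removal,
#' log-normalization, HVG selection), spatial kNN graph assembly,
#' self-supervised training, one-hop/multi-hop fusion, and clustering of
#' the fused embedding. If the dataset carries reference labels, agreement
#' metrics (ACC/ARI/NMI) are computed.
#'
#' @param ds a \code{\link{spatial_dataset}} of raw counts (or set
#'   \code{normalize = FALSE} for pre-transformed values).
#' @param n_clusters number of spatial domains to extract; for annotated
#'   data use the annotated domain count.
#' @param cfg a \code{\link{training_config}}.
#' @param k spatial graph neighbours (default 3).
#' @param min_counts outlier-spot threshold.
#' @param scale_total normalization target.
#' @param n_top HVGs kept (default 3000).
#' @param cluster_method \code{"gmm"} (default), \code{"kmeans"} or
#'   \code{"louvain"}.
#' @param normalize apply log-normalization (default TRUE).
#' @param scale apply gene-wise unit-variance scaling (default TRUE).
#' @param resolution Louvain resolution (only used by that method).
#' @return object of class \code{stgmae_result}: list with the
#'   preprocessed \code{dataset}, \code{report}, \code{graph}, \code{fit},
#'   \code{embeddings}, \code{assignment}, and \code{metrics} (NULL
#'   without reference labels).
#' @export
spatial_domains <- function(ds, n_clusters, cfg = training_config(), k = 3,
                            min_counts = 1, scale_total = 1e4, n_top = 3000,
                            cluster_method = c("gmm", "kmeans", "louvain"),
                            normalize = TRUE, scale = TRUE, resolution = 1) {
  cluster_method <- match.arg(cluster_method)
  pp <- preprocess(ds, min_counts = min_counts, scale_total = scale_total,
                   n_top = n_top, normalize = normalize, scale = scale)
  graph <- assemble_graph(pp$dataset, k = k)
  fit <- train(graph, cfg)
  emb <- embedding_set(fit, graph)
  assignment <- switch(cluster_method,
    gmm = cluster_gmm(emb$H_out, n_clusters, seed = cfg$seed),
    kmeans = cluster_kmeans(emb$H_out, n_clusters, seed = cfg$seed),
    louvain = cluster_louvain(emb$H_out, resolution = resolution,
                              seed = cfg$seed))
  metrics <- if (!is.null(pp$dataset$labels))
    evaluate_clustering(pp$dataset$labels, assignment$labels)
  structure(list(dataset = pp$dataset, report = pp$report, graph = graph,
                 fit = fit, embeddings = emb, assignment = assignment,
                 metrics = metrics),
            class = "stgmae_result")
}

#' @export
print.stgmae_result <- function(x, ...) {
  cat("stgmae_result: ", length(x$assignment$labels), " spots -> ",
      x$assignment$n_clusters, " domains (", x$assignment$method, ")\n",
      sep = "")
  if (!is.null(x$metrics))
    cat(sprintf("  vs reference labels: ACC %.3f  ARI %.3f  NMI %.3f\n",
                x$metrics$acc, x$metrics$ari, x$metrics$nmi))
  invisible(x)
}

default_pipeline_config <- function() {
  c(unclass(training_config()),
    list(n_clusters = NULL, k = 3, min_counts = 1, scale_total = 1e4,
         n_top = 3000, cluster_method = "gmm", normalize = TRUE,
         scale = TRUE, resolution = 1, format = "mtx_dir"))
}

#' Load and resolve a pipeline configuration
#'
#' Reads a YAML file whose keys mirror \code{\link{training_config}} plus
#' the pipeline keys (\code{n_clusters}, \code{k}, \code{n_top},
#' \code{min_counts}, \code{scale_total}, \code{cluster_method},
#' \code{normalize}, \code{resolution}, \code{format}); unknown keys are a
#' hard error, as is a missing \code{n_clusters}.
#'
#' @param path YAML file, or NULL for defaults.
#' @param overrides named list overriding file values.
#' @return named list of resolved settings.
#' @export
load_pipeline_config <- function(path = NULL, overrides = list()) {
  cfg <- default_pipeline_config()
  user <- if (!is.null(path)) yaml::read_yaml(path) else list()
  for (src in list(user, overrides)) {
    bad <- setdiff(names(src), names(cfg))
    if (length(bad))
      stop("unknown config key(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    cfg[names(src)] <- src
  }
  if (is.null(cfg$n_clusters))
    stop("missing required config key: n_clusters", call. = FALSE)
  cfg
}

pipeline_training_config <- function(cfg) {
  keys <- names(formals(training_config))
  do.call(training_config, cfg[intersect(names(cfg), keys)])
}

#' Run the pipeline from files to files
#'
#' Command-line-grade entry point: reads the input dataset, resolves the
#' YAML config, runs \code{\link{spatial_domains}}, and writes domain
#' labels, the three embedding matrices, the loss trace, a resolved config
#' snapshot (sufficient to replay the run bit-for-bit) and a timestamped
#' log into \code{out}.
#'
#' @param input dataset path (see \code{\link{read_dataset}}).
#' @param config YAML config path (NULL = defaults + \code{overrides}).
#' @param out output directory (created).
#' @param overrides named list of config overrides (e.g. from CLI flags).
#' @return exit status, invisibly: 0 on success.
#' @export
run_pipeline <- function(input, config = NULL, out, overrides = list()) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(out, "run.log")
  log_line <- function(...) {
    msg <- paste0(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), ...)
    cat(msg, "\n", file = logf, append = TRUE, sep = "")
    message(msg)
  }
  stage <- "config"
  status <- tryCatch({
    cfg <- load_pipeline_config(config, overrides)
    yaml::write_yaml(cfg, file.path(out, "config_resolved.yaml"))
    log_line("config resolved; seed = ", cfg$seed)
    stage <- "read"
    ds <- read_dataset(input, format = cfg$format)
    log_line("read ", nrow(ds$matrix), " spots x ", ncol(ds$matrix), " genes")
    stage <- "pipeline"
    res <- spatial_domains(
      ds, n_clusters = cfg$n_clusters, cfg = pipeline_training_config(cfg),
      k = cfg$k, min_counts = cfg$min_counts, scale_total = cfg$scale_total,
      n_top = cfg$n_top, cluster_method = cfg$cluster_method,
      normalize = cfg$normalize, scale = cfg$scale,
      resolution = cfg$resolution)
    stage <- "write"
    utils::write.csv(data.frame(spot_id = res$dataset$spot_ids,
                                domain = res$assignment$labels),
                     file.path(out, "domains.csv"), row.names = FALSE)
    for (nm in c("H", "H_D", "H_out"))
      utils::write.csv(data.frame(spot_id = res$embeddings$spot_ids,
                                  res$embeddings[[nm]]),
                       file.path(out, paste0(nm, ".csv")), row.names = FALSE)
    utils::write.csv(res$fit$trace, file.path(out, "trace.csv"),
                     row.names = FALSE)
    if (!is.null(res$metrics)) {
      jsonlite::write_json(res$metrics, file.path(out, "metrics.json"),
                           auto_unbox = TRUE, digits = NA)
      log_line(sprintf("metrics: ACC %.4f ARI %.4f NMI %.4f",
                       res$metrics$acc, res$metrics$ari, res$metrics$nmi))
    }
    log_line("done: ", length(res$assignment$labels), " spots in ",
             res$assignment$n_clusters, " domains")
    0L
  }, error = function(e) {
    log_line("ERROR in stage '", stage, "': ", conditionMessage(e))
    1L
  })
  invisible(status)
}
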