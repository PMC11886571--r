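#' Spatial expression dataset
#'
#' The universal input container of the package: a non-negative spots x genes
#' expression matrix (dense or \pkg{Matrix} sparse), 2D spatial coordinates in
#' the same row order, unique spot and gene identifiers, and optional
#' per-spot domain labels (e.g. a manual annotation or planted ground truth).
#'
#' @param matrix numeric spots x genes matrix (base matrix or a
#'   \code{\link[Matrix]{sparseMatrix}}); all entries must be finite and >= 0.
#' @param coords numeric spots x 2 matrix of spatial coordinates, same row
#'   order as \code{matrix}.
#' @param spot_ids character vector of unique spot identifiers; defaults to
#'   rownames of \code{matrix} or \code{"spot<i>"}.
#' @param gene_ids character vector of unique gene identifiers; defaults to
#'   colnames of \code{matrix} or \code{"gene<j>"}.
#' @param labels optional per-spot domain labels (integer, character or
#'   factor), length equal to the number of spots.
#'
#' @return An object of class \code{spatial_dataset}: a list with elements
#'   \code{matrix}, \code{coords}, \code{spot_ids}, \code{gene_ids},
#'   \code{labels}.
#' @export
spatial_dataset <- function(matrix, coords, spot_ids = NULL, gene_ids = NULL,
                            labels = NULL) {
  if (is.data.frame(matrix)) matrix <- as.matrix(matrix)
  if (is.data.frame(coords)) coords <- as.matrix(coords)
  if (is.null(spot_ids)) {
    spot_ids <- rownames(matrix)
    if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(nrow(matrix)))
  }
  if (is.null(gene_ids)) {
    gene_ids <- colnames(matrix)
    if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(matrix)))
  }
  ds <- structure(
    list(matrix = matrix, coords = coords,
         spot_ids = as.character(spot_ids),
         gene_ids = as.character(gene_ids),
         labels = labels),
    class = "spatial_dataset"
  )
  validate_spatial_dataset(ds)
  ds
}

#' @rdname spatial_dataset
#' @param ds a \code{spatial_dataset}.
#' @export
validate_spatial_dataset <- function(ds) {
  m <- ds$matrix
  if (!(is.matrix(m) || inherits(m, "Matrix")))
    stop("`matrix` must be a base matrix or a Matrix object", call. = FALSE)
  vals <- if (inherits(m, "sparseMatrix")) m@x else as.vector(m)
  if (length(vals) && (anyNA(vals) || any(!is.finite(vals))))
    stop("expression matrix contains non-finite entries", call. = FALSE)
  if (length(vals) && any(vals < 0) && !isTRUE(ds$transformed))
    stop("expression matrix contains negative entries", call. = FALSE)
  if (nrow(ds$coords) != nrow(m))
    stop("coords row count (", nrow(ds$coords),
         ") != matrix row count (", nrow(m), ")", call. = FALSE)
  if (ncol(ds$coords) != 2L)
    stop("coords must have exactly 2 columns", call. = FALSE)
  if (any(!is.finite(ds$coords)))
    stop("coords contain non-finite entries", call. = FALSE)
  if (length(ds$spot_ids) != nrow(m))
    stop("spot_ids length != number of spots", call. = FALSE)
  if (anyDuplicated(ds$spot_ids))
    stop("spot_ids are not unique", call. = FALSE)
  if (length(ds$gene_ids) != ncol(m))
    stop("gene_ids length != number of genes", call. = FALSE)
  if (anyDuplicated(ds$gene_ids))
    stop("gene_ids are not unique", call. = FALSE)
  if (!is.null(ds$labels) && length(ds$labels) != nrow(m))
    stop("labels length != number of spots", call. = FALSE)
  invisible(ds)
}

#' @export
print.spatial_dataset <- function(x, ...) {
  cat("spatial_dataset: ", nrow(x$matrix), " spots x ", ncol(x$matrix),
      " genes", if (!is.null(x$labels)) paste0(
        " (", length(unique(x$labels)), " labelled domains)"), "\n", sep = "")
  invisible(x)
}

#' @export
dim.spatial_dataset <- function(x) dim(x$matrix)

# Row/column subsetting that keeps matrix, coords, ids and labels in step.
subset_dataset <- function(ds, spots = NULL, genes = NULL) {
  if (!is.null(spots)) {
    ds$matrix <- ds$matrix[spots, , drop = FALSE]
    ds$coords <- ds$coords[spots, , drop = FALSE]
    ds$spot_ids <- ds$spot_ids[spots]
    if (!is.null(ds$labels)) ds$labels <- ds$labels[spots]
  }
  if (!is.null(genes)) {
    ds$matrix <- ds$matrix[, genes, drop = FALSE]
    ds$gene_ids <- ds$gene_ids[genes]
  }
  ds
}

#' Read a spatial expression dataset
#'
#' Reads a spots x genes matrix plus spot coordinates from disk. Two on-disk
#' layouts are supported:
#' \describe{
#'   \item{\code{mtx_dir}}{a directory holding \code{matrix.mtx} (genes x
#'     spots, MatrixMarket, the 10x convention), \code{barcodes.tsv} (spot
#'     ids), \code{features.tsv} or \code{genes.tsv} (gene ids), and
#'     \code{coordinates.tsv} / \code{.csv} with columns
#'     \code{spot_id, x, y}.}
#'   \item{\code{table}}{a dense delimited table (CSV/TSV) of spots x genes
#'     with spot ids in the first column, plus a sibling coordinates table
#'     \code{<stem>_coords.<ext>} or an explicit \code{coords_path}.}
#' }
#' Coordinates are matched to the matrix by spot id; a spot with no
#' coordinate row is a hard error naming the spot.
#'
#' @param path file or directory path.
#' @param format one of \code{"mtx_dir"}, \code{"table"}, \code{"h5ad"}.
#' @param coords_path optional explicit path to the coordinates table.
#' @param labels_path optional path to a two-column table
#'   (\code{spot_id, label}).
#' @return a \code{\link{spatial_dataset}}.
#' @export
read_dataset <- function(path, format = c("mtx_dir", "table", "h5ad"),
                         coords_path = NULL, labels_path = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path, call. = FALSE)
  if (format == "h5ad")
    stop("h5ad input is not supported in this build (no HDF5 bindings); ",
         "export to an MTX directory or a dense table instead", call. = FALSE)
  if (format == "mtx_dir") read_mtx_dir(path, coords_path, labels_path)
  else read_table_dataset(path, coords_path, labels_path)
}

read_delim_auto <- function(path, header = TRUE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  utils::read.table(path, header = header, sep = sep,
                    stringsAsFactors = FALSE, check.names = FALSE,
                    comment.char = "")
}

find_one <- function(dir, candidates, what) {
  for (f in candidates) {
    p <- file.path(dir, f)
    if (file.exists(p)) return(p)
  }
  stop("no ", what, " file found in ", dir, " (looked for ",
       paste(candidates, collapse = ", "), ")", call. = FALSE)
}

read_mtx_dir <- function(dir, coords_path = NULL, labels_path = NULL) {
  mtx <- find_one(dir, c("matrix.mtx"), "matrix.mtx")
  bc  <- find_one(dir, c("barcodes.tsv", "barcodes.csv"), "barcodes")
  ft  <- find_one(dir, c("features.tsv", "genes.tsv", "features.csv"),
                  "features")
  if (is.null(coords_path))
    coords_path <- find_one(dir, c("coordinates.tsv", "coordinates.csv",
                                   "coords.tsv", "coords.csv"), "coordinates")
  m <- Matrix::readMM(mtx)            # genes x spots (10x convention)
  spot_ids <- read_delim_auto(bc, header = FALSE)[[1]]
  gene_ids <- read_delim_auto(ft, header = FALSE)[[1]]
  if (nrow(m) != length(gene_ids) || ncol(m) != length(spot_ids))
    stop("matrix.mtx dimensions do not match barcodes/features", call. = FALSE)
  mat <- Matrix::t(m)                 # spots x genes
  rownames(mat) <- spot_ids; colnames(mat) <- gene_ids
  coords <- read_coords_for(coords_path, spot_ids)
  if (is.null(labels_path) && file.exists(file.path(dir, "labels.tsv")))
    labels_path <- file.path(dir, "labels.tsv")
  labels <- if (!is.null(labels_path)) read_labels_for(labels_path, spot_ids)
  spatial_dataset(mat, coords, spot_ids, gene_ids, labels)
}

read_table_dataset <- function(path, coords_path = NULL, labels_path = NULL) {
  tab <- read_delim_auto(path)
  if (!ncol(tab) || !all(vapply(tab[-1], is.numeric, TRUE)))
    stop("non-numeric entries in expression table ", path, call. = FALSE)
  spot_ids <- as.character(tab[[1]])
  mat <- as.matrix(tab[-1])
  rownames(mat) <- spot_ids
  if (is.null(coords_path)) {
    stem <- sub("\\.[^.]+$", "", path)
    ext <- sub(".*(\\.[^.]+)$", "\\1", path)
    coords_path <- paste0(stem, "_coords", ext)
    if (!file.exists(coords_path))
      stop("no coordinates table found (expected ", coords_path,
           " or an explicit coords_path)", call. = FALSE)
  }
  coords <- read_coords_for(coords_path, spot_ids)
  labels <- if (!is.null(labels_path)) read_labels_for(labels_path, spot_ids)
  spatial_dataset(mat, coords, spot_ids, colnames(mat), labels)
}

read_coords_for <- function(path, spot_ids) {
  ct <- read_delim_auto(path)
  if (ncol(ct) < 3L)
    stop("coordinates table must have columns spot_id, x, y", call. = FALSE)
  idx <- match(spot_ids, as.character(ct[[1]]))
  if (anyNA(idx)) {
    missing <- spot_ids[is.na(idx)]
    stop("missing coordinates for spot(s): ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  }
  xy <- ct[idx, 2:3]
  if (!all(vapply(xy, is.numeric, TRUE)))
    stop("non-numeric entries in coordinates table", call. = FALSE)
  coords <- as.matrix(xy)
  dimnames(coords) <- list(spot_ids, c("x", "y"))
  coords
}

read_labels_for <- function(path, spot_ids) {
  lt <- read_delim_auto(path)
  idx <- match(spot_ids, as.character(lt[[1]]))
  if (anyNA(idx))
    stop("missing labels for spot(s): ",
         paste(utils::head(spot_ids[is.na(idx)], 10), collapse = ", "),
         call. = FALSE)
  lt[idx, 2]
}

#' Write a spatial expression dataset
#'
#' Inverse of \code{\link{read_dataset}}: writes either an MTX directory
#' (\code{matrix.mtx} in genes x spots orientation, \code{barcodes.tsv},
#' \code{features.tsv}, \code{coordinates.tsv}, optional \code{labels.tsv})
#' or a dense CSV pair.
#'
#' @param ds a \code{\link{spatial_dataset}}.
#' @param path output directory (\code{mtx_dir}) or file stem (\code{table}).
#' @param format \code{"mtx_dir"} or \code{"table"}.
#' @return \code{path}, invisibly.
#' @export
write_dataset <- function(ds, path, format = c("mtx_dir", "table")) {
  format <- match.arg(format)
  if (format == "mtx_dir") {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    m <- methods::as(methods::as(Matrix::Matrix(Matrix::t(ds$matrix),
                                                sparse = TRUE), "generalMatrix"),
                     "CsparseMatrix")
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    writeLines(ds$spot_ids, file.path(path, "barcodes.tsv"))
    writeLines(ds$gene_ids, file.path(path, "features.tsv"))
    utils::write.table(
      data.frame(spot_id = ds$spot_ids, x = ds$coords[, 1], y = ds$coords[, 2]),
      file.path(path, "coordinates.tsv"),
      sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(ds$labels))
      utils::write.table(
        data.frame(spot_id = ds$spot_ids, label = ds$labels),
        file.path(path, "labels.tsv"),
        sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
    tab <- data.frame(spot_id = ds$spot_ids,
                      as.matrix(ds$matrix), check.names = FALSE)
    utils::write.csv(tab, paste0(path, ".csv"), row.names = FALSE, quote = FALSE)
    utils::write.csv(
      data.frame(spot_id = ds$spot_ids, x = ds$coords[, 1], y = ds$coords[, 2]),
      paste0(path, "_coords.csv"), row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
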