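#' Spatial weight matrix
#'
#' Nonnegative n-by-n weights with a zero diagonal in base form (a nonzero
#' diagonal appears only in the self-inclusive star variant used by the
#' Gi* statistic). Row standardisation rescales each nonzero row to sum
#' to 1 so that spatial lags are neighbourhood averages.
#'
#' @param w numeric n x n matrix, nonnegative.
#' @param labels unit labels (defaults to the matrix row names).
#' @param standardized \code{"none"} or \code{"row"}.
#' @return object of class \code{spatial_weights}.
#' @export
spatial_weights <- function(w, labels = NULL, standardized = "none") {
  w <- as.matrix(w)
  if (nrow(w) != ncol(w)) stop("weight matrix must be square")
  if (any(w < 0)) stop("weights must be nonnegative")
  if (is.null(labels)) labels <- rownames(w)
  if (is.null(labels)) labels <- paste0("U", seq_len(nrow(w)))
  dimnames(w) <- list(labels, labels)
  structure(list(labels = labels, w = w, standardized = standardized),
            class = "spatial_weights")
}

#' @export
print.spatial_weights <- function(x, ...) {
  nz <- sum(x$w != 0)
  cat(sprintf("Spatial weights: %d units, %d nonzero links, standardized: %s\n",
              length(x$labels), nz, x$standardized))
  invisible(x)
}

#' Binary contiguity weights from an undirected edge list
#'
#' @param edges two-column matrix/data frame of unit labels, or the path of
#'   a whitespace-separated two-column text file. Edges are undirected; the
#'   result is symmetric with zero diagonal.
#' @param labels ordered unit labels defining the matrix dimension.
#' @return a \code{\link{spatial_weights}} object (unstandardised).
#' @export
build_contiguity <- function(edges, labels) {
  if (is.character(edges) && length(edges) == 1L) {
    if (!file.exists(edges)) stop("edge-list file not found: ", edges)
    edges <- utils::read.table(edges, header = FALSE,
                               stringsAsFactors = FALSE)
  }
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  unknown <- setdiff(unique(as.vector(edges)), labels)
  if (length(unknown))
    stop("edge list references unknown label(s): ",
         paste(unknown, collapse = ", "))
  n <- length(labels)
  w <- matrix(0, n, n, dimnames = list(labels, labels))
  for (e in seq_len(nrow(edges))) {
    i <- match(edges[e, 1], labels); j <- match(edges[e, 2], labels)
    if (i == j) next
    w[i, j] <- 1; w[j, i] <- 1
  }
  spatial_weights(w, labels, "none")
}

#' Row-standardise a weight matrix
#'
#' Divides each nonzero row by its sum; all-zero rows (islands) are left
#' zero with a warning. Idempotent.
#'
#' @param W a \code{\link{spatial_weights}} object or plain matrix.
#' @return row-standardised \code{\link{spatial_weights}}.
#' @export
row_standardize <- function(W) {
  w <- if (inherits(W, "spatial_weights")) W$w else as.matrix(W)
  labels <- if (inherits(W, "spatial_weights")) W$labels else rownames(w)
  rs <- rowSums(w)
  isl <- rs == 0
  if (any(isl))
    warning("island row(s) with no neighbours left at zero: ",
            paste(which(isl), collapse = ", "))
  w[!isl, ] <- w[!isl, , drop = FALSE] / rs[!isl]
  spatial_weights(w, labels, "row")
}

#' Inverse-distance weights
#'
#' w_ij = 1/d_ij for pairs within the cutoff, zero otherwise and on the
#' diagonal.
#'
#' @param coords data frame or matrix with columns (label, x, y) or a
#'   two-column numeric matrix with row names.
#' @param cutoff distance beyond which weights are zero (default
#'   \code{Inf}).
#' @return a \code{\link{spatial_weights}} object (unstandardised).
#' @export
inverse_distance_weights <- function(coords, cutoff = Inf) {
  if (is.data.frame(coords) && ncol(coords) >= 3) {
    labels <- as.character(coords[[1]])
    xy <- as.matrix(coords[, 2:3])
  } else {
    xy <- as.matrix(coords)
    labels <- rownames(xy)
    if (is.null(labels)) labels <- paste0("U", seq_len(nrow(xy)))
  }
  d <- as.matrix(stats::dist(xy))
  if (any(d[upper.tri(d)] == 0))
    stop("coincident points give infinite weight")
  w <- ifelse(d > 0 & d <= cutoff, 1 / d, 0)
  diag(w) <- 0
  if (any(rowSums(w) == 0))
    warning("cutoff leaves island unit(s) with no neighbours")
  spatial_weights(w, labels, "none")
}

#' Packaged contiguity matrix for the 31 provincial units
#'
#' Queen-style land-border adjacency among the 31 units plus the
#' Hainan-Guangdong sea link (the usual convention that avoids island
#' rows), keyed by the same pinyin labels as the packaged efficiency
#' fixture. Override by supplying your own edge list to
#' \code{\link{build_contiguity}}.
#'
#' @param standardize row-standardise the result (default \code{TRUE}).
#' @return a \code{\link{spatial_weights}} object.
#' @export
china_adjacency <- function(standardize = TRUE) {
  path <- system.file("extdata", "china_adjacency.txt",
                      package = "effspace")
  W <- build_contiguity(path, labels = names(.china_nbs_regions))
  if (standardize) row_standardize(W) else W
}
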