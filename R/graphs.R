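#' Pairwise cosine distance between samples
#'
#' `d_ij = 1 - cos(x_i, x_j)` with `d_ii = 0`. Samples with zero norm have no
#' defined direction and are rejected by name.
#'
#' @param view An [omics_view()] or a numeric matrix with sample row names.
#' @return Symmetric numeric matrix of cosine distances.
#' @export
cosine_distance_matrix <- function(view) {
  x <- if (inherits(view, "omics_view")) view$matrix else view
  stopifnot(is.matrix(x), is.numeric(x))
  nrm <- sqrt(rowSums(x * x))
  if (any(nrm == 0)) {
    bad <- rownames(x)[nrm == 0]
    if (is.null(bad)) bad <- which(nrm == 0)
    stop("cosine distance undefined for zero-norm sample(s): ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  s <- tcrossprod(x / nrm)
  d <- 1 - s
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Choose a global distance threshold for a target mean degree
#'
#' The threshold is the `(k * N)`-th smallest off-diagonal distance over
#' ordered (directed) sample pairs, so that thresholding retains
#' approximately `k * N` directed edges, i.e. a mean degree of about `k`.
#'
#' @param distances Symmetric distance matrix from
#'   [cosine_distance_matrix()].
#' @param edge_per_node Target mean number of neighbors `k` (`1 <= k < N`).
#' @return The scalar distance threshold.
#' @export
pick_threshold <- function(distances, edge_per_node) {
  n <- nrow(distances)
  k <- edge_per_node
  if (k < 1) stop("`edge_per_node` must be >= 1")
  if (k >= n) stop("`edge_per_node` must be < number of samples (", n, ")")
  off <- distances[row(distances) != col(distances)]
  m <- as.integer(round(k * n))
  if (m > length(off)) {
    stop("k * N = ", m, " exceeds the ", length(off), " ordered sample pairs")
  }
  sort(off, partial = m)[m]
}

#' Build a per-modality sample-similarity graph
#'
#' Pairs within the global distance threshold are connected with weight
#' `s_ij = max(0, 1 - d_ij)` (cosine similarity, clipped so that the rare
#' negative cosines of z-scored data cannot produce negative weights). A
#' self-loop of weight 1 is added to every sample, then each row is
#' L1-normalized so the adjacency is row-stochastic.
#'
#' @param view An [omics_view()] or numeric matrix with sample row names.
#' @param edge_per_node Target mean degree `k`.
#' @return A `sample_graph`: list with `adjacency` (sparse row-stochastic
#'   `dgCMatrix`), `edge_per_node`, `threshold`, `sample_ids`.
#' @export
build_graph <- function(view, edge_per_node) {
  x <- if (inherits(view, "omics_view")) view$matrix else view
  d <- cosine_distance_matrix(x)
  thr <- pick_threshold(d, edge_per_node)
  w <- 1 - d
  w[w < 0] <- 0
  w[d > thr] <- 0
  diag(w) <- 1
  w <- w / rowSums(w)
  structure(
    list(
      adjacency = Matrix::drop0(Matrix::Matrix(w, sparse = TRUE)),
      edge_per_node = edge_per_node,
      threshold = thr,
      sample_ids = rownames(x)
    ),
    class = "sample_graph"
  )
}

#' @export
print.sample_graph <- function(x, ...) {
  n <- nrow(x$adjacency)
  deg <- (Matrix::nnzero(x$adjacency) - n) / n
  cat(sprintf(
    "<sample_graph> %d samples, threshold=%.4f, mean directed degree=%.2f\n",
    n, x$threshold, deg
  ))
  invisible(x)
}

#' Mean directed degree of a sample graph (self-loops excluded)
#' @param graph A `sample_graph`.
#' @return Mean number of non-zero off-diagonal entries per row.
#' @export
mean_degree <- function(graph) {
  a <- graph$adjacency
  (Matrix::nnzero(a) - sum(Matrix::diag(a) > 0)) / nrow(a)
}

#' Build a transductive train+test graph
#'
#' Concatenates training and test samples (both already normalized with the
#' training statistics) and applies the same global thresholding rule to the
#' union, so test samples are embedded relative to the training samples
#' without using any label information. Edges may exist within and across
#' the partitions.
#'
#' @param train_view,test_view [omics_view()] objects sharing feature names.
#' @param edge_per_node Target mean degree `k`.
#' @return A list with `graph` (`sample_graph` over the union, train rows
#'   first) and `test_idx` (row indices of the test samples).
#' @export
build_transductive_graph <- function(train_view, test_view, edge_per_node) {
  stopifnot(inherits(train_view, "omics_view"))
  if (is.null(test_view) || nrow(test_view$matrix) == 0L) {
    g <- build_graph(train_view, edge_per_node)
    return(list(graph = g, test_idx = integer()))
  }
  stopifnot(inherits(test_view, "omics_view"))
  if (!identical(feature_names(train_view), feature_names(test_view))) {
    stop("train and test views must share the same feature space")
  }
  x <- rbind(train_view$matrix, test_view$matrix)
  g <- build_graph(x, edge_per_node)
  list(graph = g, test_idx = nrow(train_view$matrix) + seq_len(nrow(test_view$matrix)))
}

#' Export a graph as an edge list
#'
#' @param graph A `sample_graph`.
#' @param path Output TSV path (columns `i`, `j`, `weight`, using sample
#'   identifiers).
#' @return The path, invisibly.
#' @export
write_graph_edgelist <- function(graph, path) {
  a <- methods::as(graph$adjacency, "TsparseMatrix")
  dt <- data.table::data.table(
    i = graph$sample_ids[a@i + 1L],
    j = graph$sample_ids[a@j + 1L],
    weight = a@x
  )
  data.table::setorder(dt, i, j)
  data.table::fwrite(dt, path, sep = "\t")
  invisible(path)
}
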