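#' Binary undirected network
#'
#' Wraps a symmetric 0/1 adjacency matrix with zero diagonal, recording the
#' achieved sparsity (edge count over `n(n-1)/2`).
#'
#' @param adjacency symmetric 0/1 matrix, zero diagonal.
#' @return an object of class `binary_network` with elements `adjacency`
#'   (integer matrix), `n_nodes`, `n_edges`, `sparsity`.
#' @export
binary_network <- function(adjacency) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (n != ncol(adjacency)) stop_covnet("adjacency must be square")
  if (!all(adjacency %in% c(0, 1))) stop_covnet("adjacency must be 0/1")
  if (any(diag(adjacency) != 0)) stop_covnet("adjacency must have zero diagonal")
  if (!isTRUE(all.equal(adjacency, t(adjacency), check.attributes = FALSE)))
    stop_covnet("adjacency must be symmetric")
  storage.mode(adjacency) <- "integer"
  n_edges <- sum(adjacency) / 2
  structure(
    list(adjacency = adjacency, n_nodes = n, n_edges = as.integer(n_edges),
         sparsity = if (n > 1) n_edges / (n * (n - 1) / 2) else NA_real_),
    class = "binary_network"
  )
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> %d nodes, %d edges (sparsity %.4f)\n",
              x$n_nodes, x$n_edges, x$sparsity))
  invisible(x)
}

#' Sparsity grid
#'
#' Ordered sparsity levels for the threshold sweep. The default grid,
#' 0.36 to 0.50 in steps of 0.01 (15 levels), is the range over which the
#' network comparisons are swept.
#'
#' @param from,to,by grid limits and step, each in (0, 1].
#' @return numeric vector of strictly increasing sparsities.
#' @export
sparsity_grid <- function(from = 0.36, to = 0.5, by = 0.01) {
  values <- round(seq(from, to, by = by), 10)
  if (any(values <= 0) || any(values > 1) || any(diff(values) <= 0))
    stop_covnet("sparsity grid values must be strictly increasing, in (0, 1]")
  values
}

#' Binarize a correlation matrix at fixed sparsity
#'
#' Keeps the `E = round(s * n(n-1)/2)` strongest edges (halves rounded away
#' from zero). With `ranking = "signed"` (default) correlations are ranked
#' as signed values so the strongest positive covariances survive; with
#' `"absolute"`, by magnitude. Ties at the cutoff are broken by ascending
#' `(i, j)` lexicographic order so binarization is fully deterministic.
#'
#' @param cmat a [correlation_matrix()] (or bare symmetric matrix).
#' @param s target sparsity in (0, 1].
#' @param ranking `"signed"` or `"absolute"`.
#' @return a [binary_network()]; its `sparsity` is the achieved
#'   `E / (n(n-1)/2)`, which matches `s` to within one half edge.
#' @examples
#' r <- cor(matrix(rnorm(80), 20, 4))
#' binarize_at_sparsity(r, 0.5)
#' @export
binarize_at_sparsity <- function(cmat, s, ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  r <- if (inherits(cmat, "correlation_matrix")) cmat$r else as.matrix(cmat)
  n <- nrow(r)
  if (s <= 0 || s > 1) stop_covnet("sparsity must be in (0, 1]")
  max_e <- n * (n - 1) / 2
  n_edges <- round_half_away(s * max_e)
  if (n_edges < 1) stop_covnet("requested sparsity yields an empty network")
  ut <- which(upper.tri(r), arr.ind = TRUE)
  val <- r[ut]
  if (ranking == "absolute") val <- abs(val)
  ord <- order(-val, ut[, 1], ut[, 2])
  keep <- ord[seq_len(n_edges)]
  adj <- matrix(0L, n, n)
  adj[ut[keep, , drop = FALSE]] <- 1L
  adj <- adj + t(adj)
  binary_network(adj)
}

#' Sweep a sparsity grid
#'
#' One binarized network per grid value, all derived from the same edge
#' ranking so the networks are nested: every edge present at a lower
#' sparsity is present at any higher one.
#'
#' @inheritParams binarize_at_sparsity
#' @param grid a [sparsity_grid()].
#' @return named list of [binary_network()]s, one per grid value.
#' @export
sweep_networks <- function(cmat, grid = sparsity_grid(), ranking = c("signed", "absolute")) {
  ranking <- match.arg(ranking)
  nets <- lapply(grid, function(s) binarize_at_sparsity(cmat, s, ranking))
  names(nets) <- formatC(grid, format = "f", digits = 4)
  nets
}

#' Size of the largest connected component
#'
#' @param net a [binary_network()].
#' @return node count of the largest connected component.
#' @examples
#' largest_component_size(make_fixture_graph("star4"))
#' @export
largest_component_size <- function(net) {
  d <- cpp_bfs_distances(net$adjacency)
  max(rowSums(is.finite(d)))
}
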