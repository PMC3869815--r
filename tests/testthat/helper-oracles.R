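# Independent brute-force oracles for the graph metrics, deliberately
# implemented with different algorithms than the package (Floyd-Warshall
# distances, explicit shortest-path enumeration) so agreement is a real
# cross-check.

oracle_floyd_warshall <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj == 1, 1, Inf)
  diag(d) <- 0
  for (k in seq_len(n)) d <- pmin(d, outer(d[, k], d[k, ], `+`))
  d
}

oracle_global_efficiency <- function(adj) {
  d <- oracle_floyd_warshall(adj)
  n <- nrow(adj)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

oracle_regional_efficiency <- function(adj) {
  d <- oracle_floyd_warshall(adj)
  inv <- 1 / d
  diag(inv) <- 0
  rowSums(inv) / (nrow(adj) - 1)
}

oracle_local_efficiency <- function(adj) {
  n <- nrow(adj)
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] == 1)
    if (length(nb) < 2) return(0)
    oracle_global_efficiency(adj[nb, nb, drop = FALSE])
  }, 0)
  mean(vals)
}

oracle_vulnerability <- function(adj) {
  e0 <- oracle_global_efficiency(adj)
  vapply(seq_len(nrow(adj)), function(i)
    (e0 - oracle_global_efficiency(adj[-i, -i, drop = FALSE])) / e0, 0)
}

# All shortest paths between h and j as lists of node sequences,
# reconstructed by walking back along distance-decreasing neighbors.
oracle_all_shortest_paths <- function(adj, d, h, j) {
  if (!is.finite(d[h, j])) return(list())
  if (h == j) return(list(h))
  walk <- function(v) {
    if (v == h) return(list(h))
    preds <- which(adj[, v] == 1 & d[h, ] == d[h, v] - 1)
    out <- list()
    for (p in preds)
      out <- c(out, lapply(walk(p), function(pa) c(pa, v)))
    out
  }
  walk(j)
}

# Betweenness by explicit enumeration of every shortest path.
oracle_betweenness <- function(adj) {
  n <- nrow(adj)
  d <- oracle_floyd_warshall(adj)
  b <- numeric(n)
  for (h in seq_len(n - 1)) for (j in (h + 1):n) {
    paths <- oracle_all_shortest_paths(adj, d, h, j)
    if (!length(paths)) next
    inner <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
    if (length(inner)) {
      counts <- table(inner)
      b[as.integer(names(counts))] <- b[as.integer(names(counts))] +
        as.numeric(counts) / length(paths)
    }
  }
  b
}

# Benjamini-Hochberg step-up by direct definition (independent of p.adjust).
oracle_bh_stepup <- function(p, q) {
  m <- length(p)
  if (!m) return(logical(0))
  ord <- order(p)
  ps <- p[ord]
  ok <- which(ps <= seq_len(m) * q / m)
  if (!length(ok)) return(rep(FALSE, m))
  p[seq_len(m)] <= ps[max(ok)]
}

random_graph <- function(n, p_edge) {
  adj <- matrix(0L, n, n)
  ut <- which(upper.tri(adj), arr.ind = TRUE)
  on <- runif(nrow(ut)) < p_edge
  adj[ut[on, , drop = FALSE]] <- 1L
  adj + t(adj)
}

small_null_cohort <- function(seed, n_per_group = 20, n_regions = 40) {
  generate_cohort(cohort_spec(n_subjects = c(n_per_group, n_per_group),
                              n_regions = n_regions, seed = seed))
}
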