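as_adjacency <- function(net) {
  if (inherits(net, "binary_network")) net$adjacency
  else binary_network(net)$adjacency
}

#' All-pairs shortest-path lengths
#'
#' Unweighted breadth-first-search distances (hops); disconnected pairs
#' are `Inf`.
#'
#' @param net a [binary_network()].
#' @return numeric node x node distance matrix.
#' @export
shortest_paths <- function(net) {
  cpp_bfs_distances(as_adjacency(net))
}

# mean of reciprocal off-diagonal distances, 1/Inf = 0
efficiency_from_distances <- function(d) {
  n <- nrow(d)
  if (n < 2) return(0)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

#' Global efficiency
#'
#' `E_glob = (1/(n(n-1))) * sum_{i != j} 1/L_ij`, the inverse of the
#' harmonic mean of the shortest-path lengths; disconnected pairs
#' contribute 0, so `E_glob` is defined on fragmented graphs, and equals 1
#' only for the complete graph.
#'
#' @param net a [binary_network()] with at least 2 nodes.
#' @return efficiency in `[0, 1]`.
#' @examples
#' global_efficiency(make_fixture_graph("path3"))  # 5/6
#' @export
global_efficiency <- function(net) {
  adj <- as_adjacency(net)
  if (nrow(adj) < 2) stop_covnet("global_efficiency needs >= 2 nodes")
  efficiency_from_distances(cpp_bfs_distances(adj))
}

#' Local efficiency
#'
#' Mean over nodes of the global efficiency of each node's neighbour
#' subgraph (the node itself excluded); a node with fewer than two
#' neighbours contributes 0. High local efficiency indicates locally
#' clustered, fault-tolerant wiring.
#'
#' @inheritParams global_efficiency
#' @return efficiency in `[0, 1]`.
#' @export
local_efficiency <- function(net) {
  adj <- as_adjacency(net)
  n <- nrow(adj)
  if (n < 2) stop_covnet("local_efficiency needs >= 2 nodes")
  vals <- vapply(seq_len(n), function(i) {
    nb <- which(adj[i, ] != 0)
    if (length(nb) < 2) return(0)
    sub <- adj[nb, nb, drop = FALSE]
    efficiency_from_distances(cpp_bfs_distances(sub))
  }, 0)
  mean(vals)
}

#' Betweenness centrality
#'
#' Exact betweenness `b_i = sum_{h != j != i} sigma_hj(i) / sigma_hj` over
#' unordered node pairs, where `sigma_hj` counts shortest paths between
#' `h` and `j` and `sigma_hj(i)` those passing through `i` (Brandes
#' accumulation in compiled code).
#'
#' @param net a [binary_network()].
#' @return numeric per-node betweenness values.
#' @examples
#' betweenness(make_fixture_graph("star4"))  # center 3, leaves 0
#' @export
betweenness <- function(net) {
  cpp_betweenness(as_adjacency(net))
}

#' Normalized betweenness
#'
#' `nb_i = b_i / mean(b)`; has mean 1 by construction, which makes hub
#' thresholds comparable across networks and sparsities.
#'
#' @param b per-node betweenness values from [betweenness()].
#' @return per-node normalized betweenness.
#' @export
normalized_betweenness <- function(b) {
  mb <- mean(b)
  if (mb <= 0)
    stop_covnet("mean betweenness is 0; normalized betweenness undefined")
  b / mb
}

#' Hub identification
#'
#' Hubs are the nodes whose normalized betweenness is at least one
#' standard deviation above the mean normalized betweenness:
#' `nb_i >= 1 + sd(nb)`, with the population (n-denominator) SD. When
#' `sd(nb) = 0` (perfectly regular intermediation) no node stands out and
#' the hub set is empty.
#'
#' @param nb normalized betweenness from [normalized_betweenness()].
#' @return integer vector of hub node indices (1-based matrix columns).
#' @export
identify_hubs <- function(nb) {
  if (length(nb) < 2) stop_covnet("identify_hubs needs >= 2 nodes")
  sd_pop <- sqrt(mean((nb - mean(nb))^2))
  if (sd_pop == 0) return(integer(0))
  which(nb >= mean(nb) + sd_pop)
}

#' Regional efficiency
#'
#' `e_i = (1/(n-1)) * sum_{j != i} 1/L_ij`: the inverse harmonic mean of
#' the shortest-path lengths from node `i` to every other node. Its mean
#' over nodes equals [global_efficiency()].
#'
#' @param net a [binary_network()] with >= 2 nodes.
#' @param i optional node index (1-based); default all nodes.
#' @return regional efficiency value(s) in `[0, 1]`.
#' @export
regional_efficiency <- function(net, i = NULL) {
  adj <- as_adjacency(net)
  n <- nrow(adj)
  if (n < 2) stop_covnet("regional_efficiency needs >= 2 nodes")
  d <- cpp_bfs_distances(adj)
  inv <- 1 / d
  diag(inv) <- 0
  e <- rowSums(inv) / (n - 1)
  if (is.null(i)) e else e[i]
}

#' Nodal vulnerability
#'
#' `V_i = (E_glob(G) - E_glob(G - i)) / E_glob(G)`: the relative drop in
#' global efficiency when node `i` and its edges are deleted (the reduced
#' graph is evaluated over its own `n - 1` nodes). Negative values are
#' possible - removing a peripheral node can raise the mean efficiency of
#' the remaining pairs.
#'
#' @param net a [binary_network()] with >= 3 nodes and `E_glob > 0`.
#' @param i optional node index (1-based); default all nodes.
#' @return vulnerability value(s).
#' @export
vulnerability <- function(net, i = NULL) {
  adj <- as_adjacency(net)
  n <- nrow(adj)
  if (n < 3) stop_covnet("vulnerability needs >= 3 nodes")
  e_full <- efficiency_from_distances(cpp_bfs_distances(adj))
  if (e_full == 0) stop_covnet("vulnerability undefined: global efficiency is 0")
  nodes <- i %||% seq_len(n)
  v <- vapply(nodes, function(k) {
    red <- adj[-k, -k, drop = FALSE]
    (e_full - efficiency_from_distances(cpp_bfs_distances(red))) / e_full
  }, 0)
  if (length(v) == 1 && !is.null(i)) v[[1]] else v
}

#' Global graph metrics bundle
#'
#' @param net a [binary_network()] with >= 3 nodes.
#' @return list with `E_glob`, `E_loc`, `mean_betweenness` and `V_glob`
#'   (the maximum nodal vulnerability).
#' @export
global_metrics <- function(net) {
  adj <- as_adjacency(net)
  if (nrow(adj) < 3) stop_covnet("global_metrics needs >= 3 nodes")
  list(
    E_glob = global_efficiency(net),
    E_loc = local_efficiency(net),
    mean_betweenness = mean(betweenness(net)),
    V_glob = max(vulnerability(net))
  )
}

#' Nodal metrics table
#'
#' Betweenness, normalized betweenness, regional efficiency and
#' vulnerability for every region, keyed by atlas region id.
#'
#' @param net a [binary_network()].
#' @param atlas optional [region_atlas()] to attach region names.
#' @return data.frame with one row per node.
#' @export
nodal_metrics <- function(net, atlas = NULL) {
  b <- betweenness(net)
  nb <- if (mean(b) > 0) b / mean(b) else rep(NA_real_, length(b))
  out <- data.frame(
    region_id = seq_along(b) - 1L,
    betweenness = b,
    normalized_betweenness = nb,
    regional_efficiency = regional_efficiency(net),
    vulnerability = vulnerability(net)
  )
  if (!is.null(atlas)) {
    out$name <- atlas$name
    out$hemisphere <- atlas$hemisphere
    out$lobe <- atlas$lobe
  }
  out
}

#' Summarize hubs by hemisphere and lobe
#'
#' Tabulates a hub set (and optionally a second group's hub set) against
#' the atlas: counts per hemisphere, counts per lobe, and - when two sets
#' are given - the shared and group-exclusive hubs.
#'
#' @param hubs integer hub node indices (1-based), e.g. from
#'   [identify_hubs()].
#' @param atlas a [region_atlas()] covering all hub nodes.
#' @param hubs2 optional second hub set for a two-group comparison.
#' @return list with `n_hubs`, `by_hemisphere`, `by_lobe`, `regions`, and,
#'   if `hubs2` is given, the same summaries for the second set plus
#'   `shared`, `only1`, `only2` region-name vectors.
#' @export
summarize_hubs <- function(hubs, atlas, hubs2 = NULL) {
  if (length(hubs) && max(hubs) > nrow(atlas))
    stop_covnet("hub index outside the atlas")
  tab_one <- function(h) {
    hemi <- table(factor(atlas$hemisphere[h], levels = c("left", "right")))
    lobe <- table(factor(atlas$lobe[h], levels = covnet_lobes()))
    list(n_hubs = length(h),
         by_hemisphere = as.list(setNames(as.integer(hemi), names(hemi))),
         by_lobe = as.list(setNames(as.integer(lobe), names(lobe))),
         regions = atlas$name[h])
  }
  out <- tab_one(hubs)
  if (!is.null(hubs2)) {
    out <- list(group1 = out, group2 = tab_one(hubs2))
    out$shared <- atlas$name[intersect(hubs, hubs2)]
    out$only1 <- atlas$name[setdiff(hubs, hubs2)]
    out$only2 <- atlas$name[setdiff(hubs2, hubs)]
  }
  out
}
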