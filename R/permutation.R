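#' Random group relabeling
#'
#' Pools the subjects of both datasets and reassigns them uniformly at
#' random (without replacement) to two groups of the original sizes,
#' preserving each subject's age. Used to build the permutation null of
#' any group-difference statistic.
#'
#' @param data1,data2 [thickness_dataset()]s over the same atlas.
#' @param seed RNG seed; the relabeling is deterministic given the seed.
#' @return list of two relabeled `thickness_dataset`s with the original
#'   group sizes and labels.
#' @export
permute_groups <- function(data1, data2, seed = NULL) {
  check_compatible(data1, data2)
  n1 <- nrow(data1$thickness)
  n2 <- nrow(data2$thickness)
  thick <- rbind(data1$thickness, data2$thickness)
  age <- c(data1$age, data2$age)
  ids <- c(data1$subject_id, data2$subject_id)
  pick <- with_seed(seed, sample.int(n1 + n2, n1))
  rest <- setdiff(seq_len(n1 + n2), pick)
  list(
    thickness_dataset(thick[pick, , drop = FALSE], age[pick],
                      data1$group[1], data1$atlas, ids[pick]),
    thickness_dataset(thick[rest, , drop = FALSE], age[rest],
                      data2$group[1], data2$atlas, ids[rest])
  )
}

check_compatible <- function(data1, data2) {
  stopifnot(inherits(data1, "thickness_dataset"),
            inherits(data2, "thickness_dataset"))
  if (!identical(data1$atlas$name, data2$atlas$name))
    stop_covnet("datasets use different atlases")
  invisible(TRUE)
}

# Metrics of one group's network from raw matrices:
# residualize -> correlate -> binarize at sparsity -> graph metrics.
group_network_metrics <- function(thick, age, sparsity, ranking,
                                  global_metrics, nodal_metrics) {
  res <- residualize_matrix(thick, age)$residuals
  sds <- matrixStats_colSds(res)
  if (any(sds == 0)) stop_covnet("zero-variance residual column")
  r <- stats::cor(res)
  diag(r) <- 1
  net <- binarize_at_sparsity(r, sparsity, ranking)
  adj <- net$adjacency
  d <- cpp_bfs_distances(adj)
  n <- nrow(adj)
  out <- list(global = numeric(0), nodal = list())
  inv <- 1 / d
  diag(inv) <- 0
  b <- NULL
  if ("E_glob" %in% global_metrics)
    out$global[["E_glob"]] <- sum(inv) / (n * (n - 1))
  if ("E_loc" %in% global_metrics)
    out$global[["E_loc"]] <- local_efficiency(net)
  if ("B" %in% global_metrics || "betweenness" %in% nodal_metrics)
    b <- cpp_betweenness(adj)
  if ("B" %in% global_metrics)
    out$global[["B"]] <- mean(b)
  if ("V_glob" %in% global_metrics)
    out$global[["V_glob"]] <- max(vulnerability(net))
  if ("betweenness" %in% nodal_metrics)
    out$nodal[["betweenness"]] <- b
  if ("regional_efficiency" %in% nodal_metrics)
    out$nodal[["regional_efficiency"]] <- rowSums(inv) / (n - 1)
  out
}

matrixStats_colSds <- function(m) {
  sqrt(colSums(sweep(m, 2, colMeans(m))^2) / (nrow(m) - 1))
}

#' Permutation inference engine for group differences in network metrics
#'
#' Computes observed group differences (group 1 minus group 2) of the
#' requested global and nodal metrics at one sparsity, then repeats the
#' entire estimation chain (residualization, correlation, binarization at
#' the same sparsity, metric computation) on `n_perm` random relabelings
#' of the pooled subjects. One relabeling stream drives all metrics and
#' nodes, preserving their dependence.
#'
#' P-values use the add-one convention
#' `p = (1 + #\{null >= observed\}) / (n_perm + 1)` (upper tail; mirrored
#' for the lower tail), which is exact under exchangeability and never 0.
#' The 95th and 99th empirical percentile points of each null distribution
#' are reported as critical values. A permutation on which a metric is
#' undefined is recorded as extreme for both tails (conservative), with a
#' warning.
#'
#' @param data1,data2 [thickness_dataset()]s over the same atlas.
#' @param sparsity network sparsity used for every (re)estimated network.
#' @param global_metrics subset of `c("E_glob", "E_loc", "B", "V_glob")`.
#' @param nodal_metrics subset of
#'   `c("betweenness", "regional_efficiency")`.
#' @param n_perm number of permutations (>= 100).
#' @param seed master seed for the relabeling stream.
#' @param tail pre-declared tail for `p_one_tailed` (`"upper"`: tests
#'   whether group 1 exceeds group 2).
#' @param ranking edge ranking passed to [binarize_at_sparsity()].
#' @return a `permutation_inference` list: per global metric a
#'   `permutation_result` (observed difference, null differences,
#'   `critical_value_95`/`_99`, `p_one_tailed`, both tail p-values), and
#'   per nodal metric a per-node table plus the null-difference matrix.
#' @export
permutation_inference <- function(data1, data2, sparsity,
                                  global_metrics = c("E_glob", "E_loc", "B", "V_glob"),
                                  nodal_metrics = c("betweenness", "regional_efficiency"),
                                  n_perm = 1000, seed = NULL,
                                  tail = c("upper", "lower"),
                                  ranking = c("signed", "absolute")) {
  tail <- match.arg(tail)
  ranking <- match.arg(ranking)
  check_compatible(data1, data2)
  if (n_perm < 100) stop_covnet("n_perm must be >= 100")
  if (length(global_metrics))
    global_metrics <- match.arg(global_metrics, several.ok = TRUE)
  if (length(nodal_metrics))
    nodal_metrics <- match.arg(nodal_metrics, several.ok = TRUE)
  if (!length(global_metrics) && !length(nodal_metrics))
    stop_covnet("request at least one metric")

  thick <- rbind(data1$thickness, data2$thickness)
  age <- c(data1$age, data2$age)
  n1 <- nrow(data1$thickness)
  n_tot <- nrow(thick)
  n_nodes <- ncol(thick)

  eval_split <- function(idx1) {
    idx2 <- setdiff(seq_len(n_tot), idx1)
    m1 <- group_network_metrics(thick[idx1, , drop = FALSE], age[idx1],
                                sparsity, ranking, global_metrics, nodal_metrics)
    m2 <- group_network_metrics(thick[idx2, , drop = FALSE], age[idx2],
                                sparsity, ranking, global_metrics, nodal_metrics)
    list(global = if (length(global_metrics)) m1$global - m2$global,
         nodal = setNames(lapply(nodal_metrics, function(m)
           m1$nodal[[m]] - m2$nodal[[m]]), nodal_metrics))
  }

  obs <- eval_split(seq_len(n1))
  null_global <- matrix(NA_real_, n_perm, length(global_metrics),
                        dimnames = list(NULL, global_metrics))
  null_nodal <- lapply(nodal_metrics, function(m) matrix(NA_real_, n_perm, n_nodes))
  names(null_nodal) <- nodal_metrics
  n_failed <- 0L
  with_seed(seed %||% 1L, {
    for (t in seq_len(n_perm)) {
      idx1 <- sample.int(n_tot, n1)
      perm <- tryCatch(eval_split(idx1), error = function(e) NULL)
      if (is.null(perm)) { n_failed <- n_failed + 1L; next }
      if (length(global_metrics)) null_global[t, ] <- perm$global
      for (m in nodal_metrics) null_nodal[[m]][t, ] <- perm$nodal[[m]]
    }
  })
  if (n_failed > 0)
    warning(sprintf("%d permutation(s) had undefined metrics; counted as extreme",
                    n_failed), call. = FALSE)

  out_global <- lapply(global_metrics, function(m)
    permutation_result(m, sparsity, obs$global[[m]], null_global[, m],
                       n_perm, seed, tail))
  names(out_global) <- global_metrics
  out_nodal <- lapply(nodal_metrics, function(m) {
    nulls <- null_nodal[[m]]
    tab <- do.call(rbind, lapply(seq_len(n_nodes), function(i) {
      r <- permutation_result(m, sparsity, obs$nodal[[m]][i], nulls[, i],
                              n_perm, seed, tail)
      data.frame(region_id = i - 1L, observed_diff = r$observed_diff,
                 critical_value_95 = r$critical_value_95,
                 critical_value_99 = r$critical_value_99,
                 p_one_tailed = r$p_one_tailed)
    }))
    list(metric = m, sparsity = sparsity, table = tab, null_diffs = nulls,
         tail = tail, n_permutations = n_perm, seed = seed)
  })
  names(out_nodal) <- nodal_metrics

  structure(list(global = out_global, nodal = out_nodal, sparsity = sparsity,
                 tail = tail, n_permutations = as.integer(n_perm), seed = seed,
                 n_failed = n_failed),
            class = "permutation_inference")
}

# Assemble one metric's permutation result from its null differences.
permutation_result <- function(metric, sparsity, observed, null_diffs,
                               n_perm, seed, tail) {
  up <- ifelse(is.na(null_diffs), Inf, null_diffs)    # failures: extreme
  lo <- ifelse(is.na(null_diffs), -Inf, null_diffs)
  p_upper <- (1 + sum(up >= observed)) / (n_perm + 1)
  p_lower <- (1 + sum(lo <= observed)) / (n_perm + 1)
  structure(list(
    metric = metric, sparsity = sparsity, observed_diff = observed,
    null_diffs = null_diffs,
    critical_value_95 = stats::quantile(up, 0.95, type = 1, names = FALSE),
    critical_value_99 = stats::quantile(up, 0.99, type = 1, names = FALSE),
    p_upper = p_upper, p_lower = p_lower,
    p_one_tailed = if (tail == "upper") p_upper else p_lower,
    tail = tail, n_permutations = as.integer(n_perm), seed = seed
  ), class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf(
    "<permutation_result> %s at sparsity %.2f: observed diff %.4g, one-tailed (%s) p = %.4g (%d permutations)\n",
    x$metric, x$sparsity, x$observed_diff, x$tail, x$p_one_tailed,
    x$n_permutations))
  invisible(x)
}

#' Permutation test of an overall graph characteristic
#'
#' One-tailed label-permutation test of the group difference in a global
#' network metric at one sparsity, with the whole network-estimation chain
#' re-run per permutation. The 95th percentile point of the null
#' distribution is the conventional critical value for overall graph
#' characteristics (type I error 0.05).
#'
#' @inheritParams permutation_inference
#' @param metric one of `"E_glob"`, `"E_loc"`, `"B"` (mean betweenness),
#'   `"V_glob"`.
#' @return a `permutation_result`.
#' @export
permutation_test_global <- function(data1, data2,
                                    metric = c("E_glob", "E_loc", "B", "V_glob"),
                                    sparsity = 0.4, n_perm = 1000, seed = NULL,
                                    tail = c("upper", "lower"),
                                    ranking = c("signed", "absolute")) {
  metric <- match.arg(metric)
  res <- permutation_inference(data1, data2, sparsity,
                               global_metrics = metric, nodal_metrics = character(0),
                               n_perm = n_perm, seed = seed, tail = tail,
                               ranking = ranking)
  res$global[[metric]]
}

#' Permutation test of regional nodal characteristics
#'
#' Per-node one-tailed permutation test of the group difference in nodal
#' betweenness or regional efficiency; a single relabeling stream drives
#' all nodes, preserving their dependence. The 99th percentile points of
#' the per-node null distributions are the conventional critical values
#' for regional nodal characteristics (type I error 0.01). P-values are
#' reported uncorrected across nodes.
#'
#' @inheritParams permutation_inference
#' @param metric `"betweenness"` or `"regional_efficiency"`.
#' @return list with the per-node results `table`, the null-difference
#'   matrix and the test settings.
#' @export
permutation_test_nodal <- function(data1, data2,
                                   metric = c("betweenness", "regional_efficiency"),
                                   sparsity = 0.4, n_perm = 1000, seed = NULL,
                                   tail = c("upper", "lower"),
                                   ranking = c("signed", "absolute")) {
  metric <- match.arg(metric)
  res <- permutation_inference(data1, data2, sparsity,
                               global_metrics = character(0), nodal_metrics = metric,
                               n_perm = n_perm, seed = seed, tail = tail,
                               ranking = ranking)
  res$nodal[[metric]]
}

#' Permutation inference across a sparsity grid
#'
#' Runs [permutation_inference()] at every grid sparsity and summarizes
#' each metric's p-value per sparsity together with its mean across the
#' grid (the sweep's reporting statistic for nodal effects).
#'
#' @inheritParams permutation_inference
#' @param grid a [sparsity_grid()].
#' @return a `sparsity_profile`: `global` data.frame (metric x sparsity
#'   p-values plus `mean_p`), `nodal` list of node x sparsity p-value
#'   matrices with per-node `mean_p`, and the per-sparsity results.
#' @export
sweep_inference <- function(data1, data2, grid = sparsity_grid(),
                            global_metrics = c("E_glob", "E_loc", "B", "V_glob"),
                            nodal_metrics = c("betweenness", "regional_efficiency"),
                            n_perm = 1000, seed = NULL,
                            tail = c("upper", "lower"),
                            ranking = c("signed", "absolute")) {
  tail <- match.arg(tail)
  ranking <- match.arg(ranking)
  seed <- seed %||% 1L
  runs <- lapply(seq_along(grid), function(k)
    permutation_inference(data1, data2, grid[k],
                          global_metrics = global_metrics,
                          nodal_metrics = nodal_metrics,
                          n_perm = n_perm, seed = derive_seed(seed, k),
                          tail = tail, ranking = ranking))
  names(runs) <- formatC(grid, format = "f", digits = 4)

  global_p <- vapply(runs, function(r)
    vapply(r$global, function(g) g$p_one_tailed, 0),
    numeric(length(global_metrics)))
  global_p <- matrix(global_p, nrow = length(global_metrics),
                     dimnames = list(global_metrics, names(runs)))
  global_tab <- data.frame(metric = rownames(global_p), global_p,
                           mean_p = rowMeans(global_p),
                           check.names = FALSE, row.names = NULL)

  nodal_tabs <- lapply(nodal_metrics, function(m) {
    pmat <- vapply(runs, function(r) r$nodal[[m]]$table$p_one_tailed,
                   numeric(nrow(runs[[1]]$nodal[[m]]$table)))
    pmat <- matrix(pmat, ncol = length(runs),
                   dimnames = list(NULL, names(runs)))
    data.frame(region_id = seq_len(nrow(pmat)) - 1L, pmat,
               mean_p = rowMeans(pmat), check.names = FALSE, row.names = NULL)
  })
  names(nodal_tabs) <- nodal_metrics

  structure(list(grid = grid, global = global_tab, nodal = nodal_tabs,
                 runs = runs, tail = tail,
                 n_permutations = as.integer(n_perm), seed = seed),
            class = "sparsity_profile")
}
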