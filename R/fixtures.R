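#' Named graph fixtures
#'
#' Small deterministic graphs used as closed-form oracles for the
#' efficiency, betweenness and vulnerability metrics, plus the
#' Watts-Strogatz ring-lattice construction used as the positive control
#' for the small-world criteria.
#'
#' Available names:
#' * `"path3"`: 3-node path.
#' * `"star4"`: 4-node star (one center, three leaves).
#' * `"ring"`: cycle on `n` nodes.
#' * `"complete"`: complete graph on `n` nodes.
#' * `"lattice_rewired"`: ring lattice with `k` neighbours per side,
#'   each clockwise edge rewired with probability `p` (rejecting self-loops
#'   and duplicates); `p = 0` gives the regular lattice, small `p` the
#'   classical small-world regime.
#'
#' @param name one of `"path3"`, `"star4"`, `"ring"`, `"complete"`,
#'   `"lattice_rewired"`.
#' @param n node count for `ring`, `complete`, `lattice_rewired` (<= 200).
#' @param k neighbours per side for `lattice_rewired` (degree `2k` at `p = 0`).
#' @param p rewiring probability in `[0, 1]`.
#' @param seed RNG seed for the rewiring draws.
#' @return a [binary_network()].
#' @examples
#' make_fixture_graph("star4")
#' make_fixture_graph("lattice_rewired", n = 100, k = 3, p = 0.05, seed = 1)
#' @export
make_fixture_graph <- function(name, n = NULL, k = NULL, p = NULL, seed = NULL) {
  adj <- switch(name,
    path3 = {
      a <- matrix(0L, 3, 3); a[1, 2] <- a[2, 3] <- 1L; a + t(a)
    },
    star4 = {
      a <- matrix(0L, 4, 4); a[1, 2:4] <- 1L; a + t(a)
    },
    ring = {
      check_fixture_n(n)
      a <- matrix(0L, n, n)
      for (i in seq_len(n)) a[i, i %% n + 1L] <- 1L
      pmin(a + t(a), 1L)
    },
    complete = {
      check_fixture_n(n)
      a <- matrix(1L, n, n); diag(a) <- 0L; a
    },
    lattice_rewired = {
      check_fixture_n(n)
      if (is.null(k) || is.null(p)) stop_covnet("lattice_rewired needs n, k, p")
      if (2 * k >= n) stop_covnet("lattice_rewired needs 2k < n")
      ws_rewire(n, k, p, seed)
    },
    stop_covnet("unknown fixture graph name: ", name)
  )
  binary_network(adj)
}

check_fixture_n <- function(n) {
  if (is.null(n) || n < 3 || n > 200) stop_covnet("fixture n must be in [3, 200]")
  invisible(n)
}

# Watts-Strogatz construction: ring lattice (k neighbours per side), then
# each clockwise edge (i, i+d) is rewired to (i, random) with probability p,
# skipping rewires that would create a self-loop or duplicate edge.
ws_rewire <- function(n, k, p, seed) {
  adj <- matrix(0L, n, n)
  for (i in seq_len(n)) for (d in seq_len(k)) {
    j <- (i + d - 1L) %% n + 1L
    adj[i, j] <- adj[j, i] <- 1L
  }
  if (p > 0) {
    with_seed(seed, {
      for (d in seq_len(k)) for (i in seq_len(n)) {
        if (runif(1) < p) {
          j <- (i + d - 1L) %% n + 1L
          if (adj[i, j] == 0L) next  # already rewired away
          cand <- which(adj[i, ] == 0L)
          cand <- cand[cand != i]
          if (!length(cand)) next
          new_j <- cand[floor(runif(1) * length(cand)) + 1L]
          adj[i, j] <- adj[j, i] <- 0L
          adj[i, new_j] <- adj[new_j, i] <- 1L
        }
      }
    })
  }
  adj
}
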