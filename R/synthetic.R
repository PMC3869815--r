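#' Block-structured baseline covariance for synthetic cohorts
#'
#' Regions are grouped into communities ("blocks"); correlations are
#' `r_within` inside a block, `r_between` between adjacent blocks (blocks
#' arranged on a ring) and 0 otherwise, then scaled to covariance by a
#' common regional SD. Thresholding such a matrix yields clustered graphs
#' with short inter-community bridges, i.e. small-world-like topology.
#'
#' @param n_regions number of regions.
#' @param sd regional thickness SD in mm (default 0.2).
#' @param block_size regions per community.
#' @param r_within,r_between within-block and adjacent-block correlations.
#' @return a positive-definite `n_regions x n_regions` covariance matrix.
#' @export
default_base_covariance <- function(n_regions, sd = 0.2, block_size = 8,
                                    r_within = 0.55, r_between = 0.25) {
  block <- (seq_len(n_regions) - 1L) %/% block_size
  n_blocks <- max(block) + 1L
  R <- diag(n_regions)
  for (i in seq_len(n_regions - 1L)) for (j in (i + 1L):n_regions) {
    db <- abs(block[i] - block[j])
    db <- min(db, n_blocks - db)  # blocks on a ring
    r <- if (db == 0) r_within else if (db == 1 && n_blocks > 2) r_between else 0
    R[i, j] <- R[j, i] <- r
  }
  sigma <- R * sd^2
  clip_positive_definite(sigma)
}

# Project a symmetric matrix to the nearest (in eigenvalue terms)
# positive-definite matrix by flooring its eigenvalues.
clip_positive_definite <- function(sigma, floor_frac = 1e-6) {
  e <- eigen(sigma, symmetric = TRUE)
  floor_val <- floor_frac * mean(diag(sigma))
  if (min(e$values) >= floor_val) return(sigma)
  v <- pmax(e$values, floor_val)
  out <- e$vectors %*% (v * t(e$vectors))
  (out + t(out)) / 2
}

#' Specification of a two-group synthetic thickness cohort
#'
#' Describes the generative model used by [generate_cohort()]: each
#' subject's regional thickness vector is
#' `baseline + age_effect * age + global offset + correlated Gaussian draw
#' + iid measurement noise`, with the correlated component drawn from
#' `base_covariance` after planting the group-specific target correlations
#' of `planted_edges`.
#'
#' Defaults emulate an adolescent cortical-thickness cohort: baseline
#' 2.5 mm with 0.2 mm regional SD, ages uniform on 12-18 years, a mild
#' cortical thinning of -0.02 mm/year, a 0.1 mm SD subject-level global
#' thickness offset, and 0.02 mm iid measurement noise (regional means
#' average many vertices, so measurement noise is small relative to the
#' between-subject SD).
#'
#' @param n_subjects pair of per-group subject counts (each >= 5).
#' @param n_regions region count.
#' @param age_range ages are drawn uniformly over this range (years).
#' @param age_effect per-region thickness change per year (mm/year); scalar
#'   or length-`n_regions` vector.
#' @param global_effect_sd SD of the subject-level global offset (mm).
#' @param base_covariance positive-definite region covariance (mm^2);
#'   default [default_base_covariance()].
#' @param planted_edges `NULL` or a data.frame with columns `i`, `j`
#'   (0-based region ids, as in the atlas), `r1`, `r2`: the population
#'   correlation of the correlated component for that region pair is forced
#'   to `r1` in group 1 and `r2` in group 2.
#' @param noise_sd iid measurement noise SD (mm).
#' @param baseline mean regional thickness (mm).
#' @param group_labels labels for the two groups.
#' @param seed integer seed; generation is bit-reproducible given the seed.
#' @return a `cohort_spec` list.
#' @seealso [generate_cohort()]
#' @export
cohort_spec <- function(n_subjects = c(42L, 41L), n_regions = 154L,
                        age_range = c(12, 18), age_effect = -0.02,
                        global_effect_sd = 0.1, base_covariance = NULL,
                        planted_edges = NULL, noise_sd = 0.02,
                        baseline = 2.5, group_labels = c("group1", "group2"),
                        seed = 1L) {
  if (length(n_subjects) != 2 || any(n_subjects < 5))
    stop_covnet("n_subjects must be two counts, each >= 5")
  base_covariance <- base_covariance %||% default_base_covariance(n_regions)
  if (nrow(base_covariance) != n_regions)
    stop_covnet("base_covariance dimension must match n_regions")
  if (!isTRUE(all.equal(base_covariance, t(base_covariance))))
    stop_covnet("base_covariance must be symmetric")
  if (min(eigen(base_covariance, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop_covnet("base_covariance must be positive-definite")
  if (!is.null(planted_edges)) {
    planted_edges <- as.data.frame(planted_edges)
    req <- c("i", "j", "r1", "r2")
    if (!all(req %in% names(planted_edges)))
      stop_covnet("planted_edges needs columns i, j, r1, r2")
    if (any(planted_edges$i == planted_edges$j) ||
        any(planted_edges$i < 0 | planted_edges$i >= n_regions) ||
        any(planted_edges$j < 0 | planted_edges$j >= n_regions))
      stop_covnet("planted_edges region ids must be distinct, in [0, n_regions)")
    if (any(abs(c(planted_edges$r1, planted_edges$r2)) >= 1))
      stop_covnet("planted target correlations must be in (-1, 1)")
  }
  if (length(age_effect) == 1) age_effect <- rep(age_effect, n_regions)
  if (length(age_effect) != n_regions)
    stop_covnet("age_effect must be scalar or length n_regions")
  structure(list(
    n_subjects = as.integer(n_subjects), n_regions = as.integer(n_regions),
    age_range = age_range, age_effect = age_effect,
    global_effect_sd = global_effect_sd, base_covariance = base_covariance,
    planted_edges = planted_edges, noise_sd = noise_sd, baseline = baseline,
    group_labels = group_labels, seed = as.integer(seed)
  ), class = "cohort_spec")
}

#' Subject-by-region thickness dataset
#'
#' @param thickness subject x region matrix (mm), finite and positive.
#' @param age per-subject ages (years).
#' @param group single group label or per-subject labels.
#' @param atlas a [region_atlas()] with one row per thickness column.
#' @param subject_id optional subject identifiers (default `S001`, ...).
#' @return a `thickness_dataset` object.
#' @export
thickness_dataset <- function(thickness, age, group, atlas, subject_id = NULL) {
  thickness <- as.matrix(thickness)
  n_sub <- nrow(thickness)
  if (length(group) == 1) group <- rep(group, n_sub)
  if (length(age) != n_sub || length(group) != n_sub)
    stop_covnet("age and group must have one entry per subject")
  if (ncol(thickness) != nrow(atlas))
    stop_covnet("thickness column count must equal atlas size")
  if (!all(is.finite(thickness)) || any(thickness <= 0))
    stop_covnet("thickness values must be finite and > 0")
  subject_id <- subject_id %||% sprintf("S%03d", seq_len(n_sub))
  colnames(thickness) <- atlas$name
  rownames(thickness) <- subject_id
  structure(list(thickness = thickness, age = as.numeric(age),
                 group = as.character(group), atlas = validate_atlas(atlas),
                 subject_id = subject_id),
            class = "thickness_dataset")
}

#' @export
print.thickness_dataset <- function(x, ...) {
  cat(sprintf("<thickness_dataset> %d subjects x %d regions (group: %s)\n",
              nrow(x$thickness), ncol(x$thickness),
              paste(unique(x$group), collapse = ", ")))
  invisible(x)
}

# Force the population correlation of each planted pair, then restore
# positive-definiteness by eigenvalue flooring if planting broke it.
plant_covariance <- function(sigma, planted, which_group) {
  if (is.null(planted) || nrow(planted) == 0) return(sigma)
  target <- if (which_group == 1) planted$r1 else planted$r2
  s <- sqrt(diag(sigma))
  for (k in seq_len(nrow(planted))) {
    i <- planted$i[k] + 1L
    j <- planted$j[k] + 1L
    sigma[i, j] <- sigma[j, i] <- target[k] * s[i] * s[j]
  }
  ev <- eigen(sigma, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) {
    sigma <- clip_positive_definite(sigma)
    achieved <- stats::cov2cor(sigma)
    off <- vapply(seq_len(nrow(planted)), function(k)
      abs(achieved[planted$i[k] + 1L, planted$j[k] + 1L] - target[k]), 0)
    worst <- which.max(off)
    if (off[worst] > 0.05)
      stop_covnet(sprintf(
        "planted covariance is not positive-definite; edge (%d, %d) cannot reach target correlation %.3f (off by %.3f after projection)",
        planted$i[worst], planted$j[worst], target[worst], off[worst]))
  }
  sigma
}

#' Generate a two-group synthetic thickness cohort
#'
#' Draws one [thickness_dataset()] per group under the model described in
#' [cohort_spec()]. Group 1 is generated first, then group 2, from a single
#' RNG stream seeded with `spec$seed`, so the whole cohort is
#' bit-reproducible given the seed.
#'
#' @param spec a [cohort_spec()].
#' @param atlas optional [region_atlas()]; default [synthetic_atlas()].
#' @return list with elements `group1` and `group2` (thickness datasets).
#' @examples
#' cohort <- generate_cohort(cohort_spec(n_subjects = c(10, 10), n_regions = 16))
#' cohort$group1
#' @export
generate_cohort <- function(spec, atlas = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  atlas <- atlas %||% synthetic_atlas(spec$n_regions)
  sigmas <- lapply(1:2, function(g)
    plant_covariance(spec$base_covariance, spec$planted_edges, g))
  with_seed(spec$seed, {
    datasets <- lapply(1:2, function(g) {
      n <- spec$n_subjects[g]
      p <- spec$n_regions
      age <- runif(n, spec$age_range[1], spec$age_range[2])
      glob <- rnorm(n, 0, spec$global_effect_sd)
      z <- matrix(rnorm(n * p), n, p)
      corr_part <- z %*% chol(sigmas[[g]])
      noise <- if (spec$noise_sd > 0) matrix(rnorm(n * p, 0, spec$noise_sd), n, p)
               else matrix(0, n, p)
      thick <- spec$baseline +
        outer(age, spec$age_effect) + glob + corr_part + noise
      thickness_dataset(thick, age, spec$group_labels[g], atlas,
                        subject_id = sprintf("G%d_S%03d", g, seq_len(n)))
    })
  })
  names(datasets) <- c("group1", "group2")
  datasets
}
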