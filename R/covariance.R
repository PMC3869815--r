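#' Residualize regional thickness for age and mean cortical thickness
#'
#' For every region, fits ordinary least squares of thickness on an
#' intercept, subject age and the subject's mean cortical thickness (the
#' mean over all atlas regions for that subject) and keeps the residuals.
#' The residuals replace the raw thickness values before any correlation
#' is computed, so inter-regional correlations are not driven by age or by
#' global thickness differences between subjects.
#'
#' If age is constant across subjects the age regressor is dropped with a
#' warning (the fit would be rank-deficient).
#'
#' @param data a [thickness_dataset()] with at least 4 subjects.
#' @return a `residual_dataset`: list with `residuals` (subject x region
#'   matrix), `atlas`, `group`, `n_subjects` and the dropped-regressor flag.
#' @export
residualize <- function(data) {
  stopifnot(inherits(data, "thickness_dataset"))
  thick <- data$thickness
  n <- nrow(thick)
  if (n < 4) stop_covnet("residualize needs >= 4 subjects")
  res <- residualize_matrix(thick, data$age)
  structure(list(residuals = res$residuals, atlas = data$atlas,
                 group = data$group, n_subjects = n,
                 n_partialled = if (res$age_dropped) 1L else 2L,
                 age_dropped = res$age_dropped),
            class = "residual_dataset")
}

# Fast path shared with the permutation engine: raw matrices in and out.
residualize_matrix <- function(thick, age) {
  mean_thick <- rowMeans(thick)
  age_dropped <- stats::sd(age) < .Machine$double.eps^0.5
  if (age_dropped) {
    warning("age is constant across subjects; dropping the age regressor",
            call. = FALSE)
    x <- cbind(1, mean_thick)
  } else {
    x <- cbind(1, age, mean_thick)
  }
  res <- qr.resid(qr(x), thick)
  list(residuals = res, age_dropped = age_dropped)
}

#' Inter-regional Pearson correlation matrix
#'
#' Pearson correlation between the residual thickness of every region pair,
#' computed across subjects.
#'
#' When built from a [residualize()] output, the correlations are partial
#' correlations (age and mean thickness partialled out), so the object
#' also records the effective sample size `n_eff = n_subjects - k`, where
#' `k` is the number of partialled covariates. Downstream z-tests use
#' `n_eff`; ignoring the lost degrees of freedom makes the far tail of
#' the Fisher z-test anti-conservative.
#'
#' @param res a `residual_dataset` from [residualize()] (a bare
#'   subject x region matrix is also accepted, in which case
#'   `n_eff = n_subjects`).
#' @return a `correlation_matrix`: list with `r` (symmetric, unit
#'   diagonal), `n_subjects` and `n_eff`.
#' @export
correlation_matrix <- function(res) {
  is_resid <- inherits(res, "residual_dataset")
  m <- if (is_resid) res$residuals else as.matrix(res)
  if (nrow(m) < 4) stop_covnet("correlation_matrix needs >= 4 subjects")
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(m)[which(sds == 0)] %||% which(sds == 0)
    stop_covnet("zero-variance region(s): ", paste(bad, collapse = ", "))
  }
  r <- stats::cor(m)
  diag(r) <- 1
  n <- nrow(m)
  n_eff <- if (is_resid) n - res$n_partialled else n
  structure(list(r = r, n_subjects = n, n_eff = as.integer(n_eff)),
            class = "correlation_matrix")
}

#' @export
print.correlation_matrix <- function(x, ...) {
  cat(sprintf("<correlation_matrix> %d regions, n = %d subjects\n",
              nrow(x$r), x$n_subjects))
  invisible(x)
}

#' Fisher r-to-z transform
#'
#' `z = atanh(r)`; variance-stabilizes Pearson correlations so two of them
#' can be compared with a normal test.
#'
#' @param r correlation(s), `|r| < 1`.
#' @return z value(s).
#' @examples
#' fisher_z(0.5)
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) stop_covnet("fisher_z requires |r| < 1")
  atanh(r)
}

#' Benjamini-Hochberg step-up significance mask
#'
#' Marks the p-values rejected by the step-up FDR procedure at level `q`:
#' reject all p <= p_(k*) where k* is the largest k with
#' p_(k) <= k q / m. Wraps `stats::p.adjust(method = "BH")`.
#'
#' @param p_values numeric p-values in `[0, 1]`.
#' @param q FDR level.
#' @return logical mask, `TRUE` where rejected (empty input -> empty mask).
#' @examples
#' bh_fdr(c(0.01, 0.02, 0.03, 0.04), q = 0.05)
#' @export
bh_fdr <- function(p_values, q = 0.05) {
  if (!length(p_values)) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop_covnet("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH") <= q
}

#' Edge-wise comparison of two correlation matrices
#'
#' For every region pair `i < j`, the two groups' correlations are
#' compared with the Fisher z statistic
#' `z = (atanh(r1) - atanh(r2)) / sqrt(1/(n1-3) + 1/(n2-3))`,
#' a two-tailed p-value from the standard normal, and Benjamini-Hochberg
#' control at level `q` over all `n(n-1)/2` edges as one family. The
#' sample sizes are the matrices' effective sizes: for correlations of
#' residuals these are the subject counts minus the partialled covariates
#' (partial-correlation degrees of freedom).
#' Correlations at exactly +/-1 (possible on degenerate toy input) are
#' clipped to `1 - 1e-12` with a warning before the transform.
#'
#' @param c1,c2 [correlation_matrix()]s over the same regions, each with
#'   more than 3 subjects; `direction` is `"increased"` where
#'   `r1 > r2` (group 1 relative to group 2), `"decreased"` otherwise.
#' @param q FDR level (default 0.05).
#' @return an `edge_comparison` data.frame with one row per edge:
#'   `i`, `j` (0-based region ids), `r1`, `r2`, `z`, `p`,
#'   `fdr_significant`, `direction`.
#' @export
compare_edges <- function(c1, c2, q = 0.05) {
  stopifnot(inherits(c1, "correlation_matrix"), inherits(c2, "correlation_matrix"))
  if (nrow(c1$r) != nrow(c2$r))
    stop_covnet("correlation matrices have different region counts")
  n1 <- c1$n_eff %||% c1$n_subjects
  n2 <- c2$n_eff %||% c2$n_subjects
  if (n1 <= 3 || n2 <= 3)
    stop_covnet("compare_edges needs more than 3 effective subjects per group")
  ut <- which(upper.tri(c1$r), arr.ind = TRUE)
  r1 <- c1$r[ut]; r2 <- c2$r[ut]
  if (any(abs(c(r1, r2)) >= 1)) {
    warning("correlations at |r| = 1 clipped before the r-to-z transform",
            call. = FALSE)
    clip <- 1 - 1e-12
    r1 <- pmin(pmax(r1, -clip), clip)
    r2 <- pmin(pmax(r2, -clip), clip)
  }
  se <- sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  z <- (atanh(r1) - atanh(r2)) / se
  p <- 2 * stats::pnorm(-abs(z))
  out <- data.frame(
    i = ut[, 1] - 1L, j = ut[, 2] - 1L,
    r1 = r1, r2 = r2, z = z, p = p,
    fdr_significant = bh_fdr(p, q),
    direction = ifelse(z >= 0, "increased", "decreased"),
    stringsAsFactors = FALSE
  )
  attr(out, "q") <- q
  attr(out, "n_subjects") <- c(n1, n2)
  class(out) <- c("edge_comparison", "data.frame")
  out
}
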