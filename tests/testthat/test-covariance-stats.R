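make_toy_dataset <- function(thick, age, group = "g") {
  thickness_dataset(thick, age, group, synthetic_atlas(ncol(thick)))
}

test_that("residualization removes age and mean-thickness effects exactly", {
  set.seed(2)
  age <- c(12, 13, 15, 16, 18)
  base <- matrix(2.5 + rnorm(15, 0, 0.1), 5, 3)
  thick <- base
  thick[, 1] <- 2 * age / 10  # a column fully explained by age
  d <- make_toy_dataset(thick, age)
  res <- residualize(d)
  expect_lt(max(abs(res$residuals[, 1])), 1e-10)

  # residual columns have no remaining age slope (OLS idempotence)
  for (j in 1:3)
    expect_lt(abs(coef(lm(res$residuals[, j] ~ age))[2]), 1e-10)

  # and match an independent normal-equations solve
  x <- cbind(1, age, rowMeans(thick))
  beta <- solve(t(x) %*% x, t(x) %*% thick)
  expect_equal(res$residuals, thick - x %*% beta,
               ignore_attr = TRUE, tolerance = 1e-10)
})

test_that("constant age drops the regressor with a warning", {
  set.seed(8)
  thick <- matrix(2.5 + rnorm(20, 0, 0.1), 5, 4)
  d <- make_toy_dataset(thick, rep(14, 5))
  expect_warning(res <- residualize(d), "constant")
  expect_true(res$age_dropped)
  expect_equal(colMeans(res$residuals), rep(0, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("correlation matrix follows the Pearson definition", {
  m <- cbind(a = c(1, 2, 3, 4), b = c(1, 2, 4, 3), c = c(4, 3, 2, 1))
  cm <- correlation_matrix(m)
  expect_equal(cm$r["a", "b"], 0.8)      # hand computation
  expect_equal(cm$r["a", "c"], -1)       # exact reversal
  expect_equal(diag(cm$r), rep(1, 3), ignore_attr = TRUE)
  expect_equal(cm$r, t(cm$r))
  expect_equal(cm$n_subjects, 4L)
  expect_error(correlation_matrix(cbind(m, d = rep(2, 4))), "zero-variance")
})

test_that("fisher transform is atanh with its symmetries", {
  expect_equal(fisher_z(0), 0)
  expect_equal(fisher_z(0.5), 0.5493, tolerance = 1e-4)
  r <- seq(-0.95, 0.95, by = 0.19)
  expect_equal(fisher_z(-r), -fisher_z(r))
  expect_equal(tanh(fisher_z(r)), r, tolerance = 1e-12)
  expect_error(fisher_z(1), "\\|r\\| < 1")
})

test_that("edge comparison reproduces the two-sample z statistic", {
  # synthetic correlation matrices with controlled entries
  fake_cm <- function(r12, n) {
    r <- diag(3)
    r[1, 2] <- r[2, 1] <- r12
    structure(list(r = r, n_subjects = n), class = "correlation_matrix")
  }
  ec <- compare_edges(fake_cm(0.8, 42), fake_cm(0.2, 41))
  row <- ec[ec$i == 0 & ec$j == 1, ]
  expect_equal(row$z, (atanh(0.8) - atanh(0.2)) / sqrt(1 / 39 + 1 / 38),
               tolerance = 1e-12)
  expect_equal(row$z, 3.93, tolerance = 1e-3)
  expect_equal(row$p, 8.5e-5, tolerance = 2e-2)
  expect_equal(row$direction, "increased")

  eq <- compare_edges(fake_cm(0.6, 42), fake_cm(0.6, 41))
  expect_equal(eq$z[eq$i == 0 & eq$j == 1], 0)
  expect_equal(eq$p[eq$i == 0 & eq$j == 1], 1)

  expect_error(compare_edges(fake_cm(0.5, 3), fake_cm(0.5, 41)),
               "3 effective subjects")
})

test_that("edge comparison is antisymmetric in the group order", {
  cohort <- small_null_cohort(404, n_per_group = 15, n_regions = 12)
  c1 <- correlation_matrix(residualize(cohort$group1))
  c2 <- correlation_matrix(residualize(cohort$group2))
  ab <- compare_edges(c1, c2)
  ba <- compare_edges(c2, c1)
  expect_equal(ab$z, -ba$z)
  expect_equal(ab$p, ba$p)
  flip <- c(increased = "decreased", decreased = "increased")
  nz <- ab$z != 0
  expect_equal(unname(flip[ab$direction[nz]]), ba$direction[nz])
})

test_that("BH step-up matches the hand-rolled oracle and its examples", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04), 0.05), rep(TRUE, 4))
  expect_equal(bh_fdr(rep(1, 5), 0.05), rep(FALSE, 5))
  expect_true(bh_fdr(0.04, 0.05))
  expect_identical(bh_fdr(numeric(0), 0.05), logical(0))

  set.seed(99)
  for (rep in 1:20) {
    p <- runif(sample(1:40, 1))^sample(1:3, 1)
    q <- sample(c(0.01, 0.05, 0.1), 1)
    expect_identical(bh_fdr(p, q), oracle_bh_stepup(p, q))
  }
})

test_that("edge p-values are approximately uniform under the global null", {
  cohort <- small_null_cohort(2024, n_per_group = 30, n_regions = 40)
  ec <- compare_edges(correlation_matrix(residualize(cohort$group1)),
                      correlation_matrix(residualize(cohort$group2)))
  expect_equal(nrow(ec), 40 * 39 / 2)
  d_ks <- suppressWarnings(ks.test(ec$p, "punif")$statistic)
  expect_lt(unname(d_ks), 0.1)
})
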