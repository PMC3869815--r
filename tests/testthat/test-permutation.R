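test_that("group relabeling preserves sizes, subjects and determinism", {
  cohort <- small_null_cohort(51, n_per_group = 12, n_regions = 10)
  cohort$group2 <- generate_cohort(cohort_spec(n_subjects = c(12, 9),
                                               n_regions = 10, seed = 52))$group2
  perm <- permute_groups(cohort$group1, cohort$group2, seed = 3)
  expect_equal(nrow(perm[[1]]$thickness), 12)
  expect_equal(nrow(perm[[2]]$thickness), 9)
  pooled_ids <- sort(c(cohort$group1$subject_id, cohort$group2$subject_id))
  expect_equal(sort(c(perm[[1]]$subject_id, perm[[2]]$subject_id)), pooled_ids)

  again <- permute_groups(cohort$group1, cohort$group2, seed = 3)
  expect_identical(perm[[1]]$thickness, again[[1]]$thickness)

  # each subject lands in group 1 with frequency ~ n1 / (n1 + n2)
  n_draws <- 400
  hits <- numeric(21)
  for (s in seq_len(n_draws)) {
    p <- permute_groups(cohort$group1, cohort$group2, seed = s)
    hits[match(p[[1]]$subject_id, pooled_ids)] <-
      hits[match(p[[1]]$subject_id, pooled_ids)] + 1
  }
  expect_lt(max(abs(hits / n_draws - 12 / 21)), 0.12)
})

test_that("permutation inference is bit-reproducible given the master seed", {
  cohort <- small_null_cohort(61, n_per_group = 14, n_regions = 16)
  run <- function() permutation_inference(
    cohort$group1, cohort$group2, sparsity = 0.4,
    global_metrics = "E_glob", nodal_metrics = "betweenness",
    n_perm = 120, seed = 7)
  a <- run(); b <- run()
  expect_identical(a$global$E_glob$null_diffs, b$global$E_glob$null_diffs)
  expect_identical(a$nodal$betweenness$table, b$nodal$betweenness$table)
  expect_identical(a$global$E_glob$p_one_tailed, b$global$E_glob$p_one_tailed)
})

test_that("identical duplicated cohorts give zero observed difference and no rejection", {
  cohort <- small_null_cohort(71, n_per_group = 12, n_regions = 12)
  res <- permutation_inference(cohort$group1, cohort$group1, sparsity = 0.4,
                               global_metrics = "E_glob",
                               nodal_metrics = "regional_efficiency",
                               n_perm = 150, seed = 5)
  expect_equal(res$global$E_glob$observed_diff, 0)
  expect_gt(res$global$E_glob$p_one_tailed, 0.2)
  expect_equal(res$nodal$regional_efficiency$table$observed_diff,
               rep(0, 12), ignore_attr = TRUE)
  expect_true(all(res$nodal$regional_efficiency$table$p_one_tailed > 0.2))
})

test_that("p-values follow the add-one convention and tails mirror", {
  cohort <- small_null_cohort(81, n_per_group = 12, n_regions = 12)
  res <- permutation_test_global(cohort$group1, cohort$group2,
                                 metric = "E_glob", sparsity = 0.4,
                                 n_perm = 100, seed = 2)
  null <- res$null_diffs
  expect_equal(res$p_upper, (1 + sum(null >= res$observed_diff)) / 101)
  expect_equal(res$p_lower, (1 + sum(null <= res$observed_diff)) / 101)
  expect_equal(res$p_one_tailed, res$p_upper)
  expect_equal(res$critical_value_95,
               quantile(null, 0.95, type = 1, names = FALSE))
  expect_gte(res$p_upper + res$p_lower, 1)  # add-one overlap at ties
})

test_that("permutation p-value is uniform on its support under exchangeability", {
  # small cohorts, many replicate null datasets, few permutations each
  n_rep <- 60
  p_vals <- vapply(seq_len(n_rep), function(k) {
    cohort <- small_null_cohort(900 + k, n_per_group = 10, n_regions = 8)
    permutation_test_global(cohort$group1, cohort$group2, "E_glob",
                            sparsity = 0.5, n_perm = 100,
                            seed = 1000 + k)$p_one_tailed
  }, 0)
  expect_gt(mean(p_vals), 0.35)
  expect_lt(mean(p_vals), 0.65)
  expect_gt(min(p_vals), 0)
  expect_lte(max(p_vals), 1)
})

test_that("sweeps report per-sparsity p-values and their mean", {
  cohort <- small_null_cohort(91, n_per_group = 12, n_regions = 12)
  grid <- sparsity_grid(0.4, 0.48, 0.04)
  prof <- sweep_inference(cohort$group1, cohort$group2, grid,
                          global_metrics = c("E_glob", "B"),
                          nodal_metrics = "betweenness",
                          n_perm = 100, seed = 12)
  expect_equal(nrow(prof$global), 2)
  expect_equal(ncol(prof$global), 1 + 3 + 1)  # metric, 3 sparsities, mean
  pm <- as.matrix(prof$global[, 2:4])
  expect_equal(unname(prof$global$mean_p), unname(rowMeans(pm)))
  expect_equal(nrow(prof$nodal$betweenness), 12)
  expect_equal(unname(prof$nodal$betweenness$mean_p),
               unname(rowMeans(as.matrix(prof$nodal$betweenness[, 2:4]))))
})
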