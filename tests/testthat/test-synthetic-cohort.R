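test_that("cohort generation is bit-reproducible given the seed", {
  spec <- cohort_spec(n_subjects = c(8, 8), n_regions = 12, seed = 101)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a$group1$thickness, b$group1$thickness)
  expect_identical(a$group2$thickness, b$group2$thickness)
  expect_identical(a$group1$age, b$group1$age)
  c_ <- generate_cohort(cohort_spec(n_subjects = c(8, 8), n_regions = 12, seed = 102))
  expect_false(identical(a$group1$thickness, c_$group1$thickness))
})

test_that("generated datasets satisfy their structural invariants", {
  spec <- cohort_spec(n_subjects = c(10, 7), n_regions = 20, seed = 5)
  cohort <- generate_cohort(spec)
  for (d in cohort) {
    expect_true(all(is.finite(d$thickness)) && all(d$thickness > 0))
    expect_equal(ncol(d$thickness), nrow(d$atlas))
    expect_equal(length(d$age), nrow(d$thickness))
    expect_true(all(d$age >= 12 & d$age <= 18))
  }
  expect_equal(nrow(cohort$group1$thickness), 10)
  expect_equal(nrow(cohort$group2$thickness), 7)
})

test_that("planted correlations are recovered at large n", {
  # isolate the correlated component: no age/global/noise contributions
  spec <- cohort_spec(
    n_subjects = c(500, 500), n_regions = 12, age_effect = 0,
    global_effect_sd = 0, noise_sd = 0,
    base_covariance = diag(0.04, 12),
    planted_edges = data.frame(i = 1, j = 8, r1 = 0.9, r2 = 0.0),
    seed = 77)
  cohort <- generate_cohort(spec)
  r1 <- cor(cohort$group1$thickness)[2, 9]   # region ids 1, 8 are columns 2, 9
  r2 <- cor(cohort$group2$thickness)[2, 9]
  expect_lt(abs(r1 - 0.9), 0.05)
  expect_lt(abs(r2 - 0.0), 0.1)
})

test_that("sample covariance converges to the base covariance", {
  sigma <- default_base_covariance(8, block_size = 4)
  spec <- cohort_spec(n_subjects = c(3000, 5), n_regions = 8,
                      age_effect = 0, global_effect_sd = 0, noise_sd = 0,
                      base_covariance = sigma, seed = 31)
  cohort <- generate_cohort(spec)
  s_hat <- cov(cohort$group1$thickness)
  expect_lt(max(abs(s_hat - sigma)), 0.006)
})

test_that("with no planted edges both groups share one population", {
  spec <- cohort_spec(n_subjects = c(800, 800), n_regions = 10, seed = 13)
  cohort <- generate_cohort(spec)
  d <- cor(cohort$group1$thickness) - cor(cohort$group2$thickness)
  expect_lt(max(abs(d)), 0.12)  # pure sampling noise at n = 800
})

test_that("infeasible planted covariance is rejected with the offending edge", {
  # r(0,1) = r(0,2) = 0.95 while r(1,2) = -0.9 is not a valid correlation
  # structure; projection cannot honour the targets
  sigma <- diag(0.04, 6)
  planted <- data.frame(i = c(0, 0, 1), j = c(1, 2, 2),
                        r1 = c(0.95, 0.95, -0.9), r2 = c(0, 0, 0))
  spec <- cohort_spec(n_subjects = c(10, 10), n_regions = 6,
                      base_covariance = sigma, planted_edges = planted, seed = 1)
  expect_error(generate_cohort(spec), "positive-definite")
})

test_that("synthetic atlas splits hemispheres evenly with round-robin lobes", {
  atlas <- synthetic_atlas(154)
  expect_equal(nrow(atlas), 154)
  expect_equal(sum(atlas$hemisphere == "left"), 77)
  expect_equal(atlas$region_id, 0:153)
  expect_true(all(table(atlas$lobe) >= 1))
  expect_error(validate_atlas(data.frame(region_id = c(0, 2), name = c("a", "b"),
                                         hemisphere = c("left", "right"),
                                         lobe = c("frontal", "frontal"))),
               "contiguous")
})

test_that("fixture graphs have the advertised shapes", {
  k4 <- make_fixture_graph("complete", 4)
  expect_equal(k4$n_edges, 6L)
  expect_equal(k4$sparsity, 1)
  expect_equal(colSums(make_fixture_graph("path3")$adjacency), c(1, 2, 1),
               ignore_attr = TRUE)
  lat <- make_fixture_graph("lattice_rewired", n = 100, k = 2, p = 0)
  expect_true(all(colSums(lat$adjacency) == 4))
  expect_equal(make_fixture_graph("ring", 6)$n_edges, 6L)
  expect_error(make_fixture_graph("hypercube"), "unknown fixture")

  # rewiring preserves edge count and is seed-deterministic
  a <- make_fixture_graph("lattice_rewired", n = 50, k = 3, p = 0.2, seed = 4)
  b <- make_fixture_graph("lattice_rewired", n = 50, k = 3, p = 0.2, seed = 4)
  expect_identical(a$adjacency, b$adjacency)
  expect_equal(a$n_edges, 150L)
})
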