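test_that("binomial index inversion matches an exhaustive CDF scan", {
  # independent oracle: direct scan of P(K <= k | n, p) over n
  scan_upper <- function(k, p, alpha, n_max = 500) {
    max(which(vapply(seq(k, n_max), function(n)
      stats::pbinom(k, n, p) >= alpha, logical(1)))) + k - 1
  }
  for (case in list(c(10, 0.5, 0.01), c(5, 0.3, 0.05), c(0, 0.2, 0.01),
                    c(25, 0.8, 0.005))) {
    expect_identical(binom_n_upper(case[1], case[2], case[3]),
                     as.integer(scan_upper(case[1], case[2], case[3])))
  }
  # the normal-approximation sanity value for k=10, p=0.5, alpha=0.01
  expect_identical(binom_n_upper(10, 0.5, 0.01), 34L)
  # K = n exactly when detection is certain
  expect_identical(binom_n_upper(5, 1, 0.01), 5L)
})

test_that("clone-count bound is exact at certain detection and monotone", {
  plan_all <- sampling_plan(1, cutoff = 1e-9)
  rect1 <- nuisance_rectangle(c(0.5, 0.5), c(1, 1))
  b <- upper_bound_total_clones(5, rect1, plan_all, tumor_size = 10)
  expect_identical(b$n_upper, 5L)
  expect_gte(b$n_upper, b$k_observed)

  plan <- sampling_plan(0.1, cutoff = 6e-4)
  rect <- nuisance_rectangle(c(exp(-13), exp(-11)), c(0.05, 0.2))
  b10 <- upper_bound_total_clones(10, rect, plan, tumor_size = 1.5e6)
  b20 <- upper_bound_total_clones(20, rect, plan, tumor_size = 1.5e6,
                                  p_det_grid = b10$p_det_grid)
  expect_gte(b20$n_upper, b10$n_upper)   # monotone in k
  # nonincreasing in the lower end of the detection range: a rectangle
  # with weaker possible detection can only raise the bound
  rect_lo <- nuisance_rectangle(c(exp(-13), exp(-9)), c(0.02, 0.2))
  b_lo <- upper_bound_total_clones(10, rect_lo, plan, tumor_size = 1.5e6)
  expect_gte(b_lo$n_upper, b10$n_upper)
  expect_lte(b_lo$p_det_range[1], b10$p_det_range[1])
})

test_that("seeding efficiency converts bounds to percentage intervals", {
  plan_all <- sampling_plan(1, cutoff = 1e-9)
  rect1 <- nuisance_rectangle(c(0.5, 0.5), c(1, 1))
  b <- upper_bound_total_clones(100, rect1, plan_all, tumor_size = 200)
  eff <- seeding_efficiency(b, 1e4)
  expect_equal(eff$interval_pct[2], 1.0)
  expect_equal(eff$interval_pct[1], 1.0)
  expect_error(seeding_efficiency(b, 50), "n_marked")
})

test_that("supremum p-values dominate the pointwise p at every node", {
  rect <- nuisance_rectangle(c(exp(-6.5), exp(-5.5)), c(0.07, 0.15))
  set.seed(41)
  k <- stats::rgeom(20, exp(-6)) + 1
  s <- pmax(1, stats::rbinom(20, k, 0.1))
  r <- test_equal_proliferation(s / sum(s), sum(s), rect,
                                mc_replicates = 99, grid_resolution = 3,
                                seed = 7)
  expect_true(all(r$p_supremum >= r$p_grid$p))
  expect_gte(r$p_supremum, 0)
  expect_lte(r$p_supremum, 1)
})

test_that("degenerate inputs yield flagged trivial results", {
  rect <- nuisance_rectangle(c(0.1, 0.3), c(0.05, 0.2))
  expect_warning(r1 <- test_equal_proliferation(0.5, 100, rect), "fewer than 2")
  expect_equal(r1$p_supremum, 1)
  expect_warning(
    r2 <- test_constant_growth(c(a = 0.6, b = 0.4), c(zz = 1), 0.4,
                               1000, 1000, rect),
    "degenerates")
  expect_true(r2$degenerate)
  r3 <- test_equal_seeding(c(10, 20, 30), c(TRUE, TRUE, TRUE))
  expect_equal(r3$p_supremum, 1)
  expect_true(r3$degenerate)
})

test_that("propagated parent shares give a central constant-growth p-value", {
  rect <- nuisance_rectangle(c(exp(-6.5), exp(-5.5)), c(0.07, 0.15))
  sh <- setNames(c(0.4, 0.3, 0.2, 0.1), letters[1:4])
  r <- test_constant_growth(sh, sh, 0.4, 1e4, 1e4, rect,
                            mc_replicates = 399, grid_resolution = 3,
                            seed = 17)
  expect_gt(r$p_supremum, 0.5)
})

test_that("Monte-Carlo p-values are reproducible under fixed seeds", {
  rect <- nuisance_rectangle(c(exp(-6.5), exp(-5.5)), c(0.07, 0.15))
  sh <- c(0.5, 0.3, 0.2)
  a <- test_equal_proliferation(sh, 5000, rect, mc_replicates = 99,
                                grid_resolution = 3, seed = 5)
  b <- test_equal_proliferation(sh, 5000, rect, mc_replicates = 99,
                                grid_resolution = 3, seed = 5)
  expect_identical(a$p_grid, b$p_grid)
  s1 <- test_equal_seeding(c(5, 50, 500, 17, 80), c(TRUE, TRUE, FALSE, FALSE, TRUE),
                           mc_replicates = 99, seed = 9)
  s2 <- test_equal_seeding(c(5, 50, 500, 17, 80), c(TRUE, TRUE, FALSE, FALSE, TRUE),
                           mc_replicates = 99, seed = 9)
  expect_identical(s1$p_supremum, s2$p_supremum)
})

test_that("bound recovers a known seeding rate in a forward simulation", {
  # known truth: n = 150 engrafted clones out of 1e5 marked transplanted
  plan <- sampling_plan(0.1, cutoff = 6e-4)
  q0 <- exp(-12)
  rect <- nuisance_rectangle(c(q0 / 3, q0 * 3), c(0.05, 0.2))
  p_true <- detection_probability(birth_params(12, 1), plan, 1.5e6)
  set.seed(53)
  ks <- stats::rbinom(200, 150, p_true)
  first <- upper_bound_total_clones(ks[1], rect, plan, 1.5e6)
  bounds <- vapply(ks, function(k)
    upper_bound_total_clones(k, rect, plan, 1.5e6,
                             p_det_grid = first$p_det_grid)$n_upper,
    numeric(1))
  expect_gte(mean(bounds >= 150), 0.99)
  # seeding-efficiency interval contains the true 0.15%
  covered <- vapply(seq_along(ks), function(i) {
    eff <- seeding_efficiency(
      structure(list(k_observed = ks[i], n_upper = bounds[i]),
                class = "clone_count_bound"), 1e5)
    eff$interval_pct[1] <= 0.15 && 0.15 <= eff$interval_pct[2]
  }, logical(1))
  expect_gte(mean(covered), 0.99)
})
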