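# Residual bootstrap, structural-change permutation test, changepoint.

test_that("zero-residual bootstrap reproduces the point fit exactly", {
  w <- demo_world(years = 1:8, sigma = 0)        # noiseless world
  fit <- suppressWarnings(
    fit_sourcesink(w$Y, w$expo, w$basis, lambda = 0, n_starts = 1,
                   tol = 1e-14, max_iter = 20000))
  boot <- suppressWarnings(
    residual_bootstrap(fit, w$Y, w$expo, w$basis, B = 15, seed = 3,
                       keep_draws = TRUE))
  # every replicate equals the original fit (to the solver's noise floor)
  for (b in 1:15) {
    expect_lt(max(abs(boot$draws$w[b, ] - fit$w)), 1e-3)
    expect_lt(max(abs(boot$draws$theta[b, , ] - fit$theta)), 1e-3)
    expect_lt(max(abs(boot$draws$f[b, , ] - fit$f)), 1e-3)
  }
  # clearly nonzero parameters are never zero across replicates, and their
  # intervals are degenerate around the point estimate
  nz <- fit$theta > 1e-3
  expect_true(all(boot$pi0$theta[nz] == 0))
  expect_lt(max(boot$ci$theta_hi[nz] - boot$ci$theta_lo[nz]), 1e-3)
  expect_equal(boot$ci$theta_hi[nz], fit$theta[nz], tolerance = 1e-3)
})

test_that("bootstrap summaries are counting identities over the draws", {
  w <- demo_world(years = 1:8, sigma = 0.25, seed = 2)
  om <- adaptive_weights(w$Y, w$expo, w$basis, n_starts = 1)$omega
  fit <- tune_sourcesink(w$Y, w$expo, w$basis,
                         c(0, 0.01, 0.1), omega = om, n_starts = 1)
  boot <- residual_bootstrap(fit, w$Y, w$expo, w$basis, B = 40, seed = 9,
                             keep_draws = TRUE)
  expect_equal(boot$pi0$theta, apply(boot$draws$theta, c(2, 3),
                                     function(x) mean(x == 0)))
  expect_true(all(boot$ci$theta_lo <= boot$ci$theta_hi + 1e-12))
  # pinning rule: lower end 0 exactly when pi0 >= 5%
  pinned <- boot$pi0$theta >= 0.05
  expect_true(all(boot$ci$theta_lo[pinned] == 0))
  q05 <- apply(boot$draws$theta, c(2, 3), quantile, 0.05)
  expect_equal(boot$ci$theta_lo[!pinned], q05[!pinned], ignore_attr = TRUE)
  # reproducibility
  boot2 <- residual_bootstrap(fit, w$Y, w$expo, w$basis, B = 40, seed = 9)
  expect_identical(boot$pi0, boot2$pi0)
  expect_identical(boot$ci, boot2$ci)
})

test_that("bootstrap table emits Est/pi0/CI columns with asterisks", {
  w <- demo_world(years = 1:8, sigma = 0.25, seed = 2)
  fit <- fit_sourcesink(w$Y, w$expo, w$basis, lambda = 0.01, n_starts = 1)
  # force one structural zero to exercise the asterisk path
  fit$fixed_zero_mask[1, 2] <- TRUE
  boot <- residual_bootstrap(fit, w$Y, w$expo, w$basis, B = 10, seed = 1)
  tab <- fit_table(fit, boot)
  expect_equal(nrow(tab), 1 + 4)       # w row + one row per sink
  expect_equal(ncol(tab), 1 + 2 * 3)   # est, pi0, ci per source
  expect_equal(tab$source_1_est[1 + 2], "*")
  expect_match(tab$source_1_ci[1], "^[\\[(][0-9.]+,[0-9.]+\\)$")
})

test_that("permutation test keeps the +1 convention and validates periods", {
  w <- demo_world(years = 1:10, sigma = 0.25, seed = 3)
  grid <- c(0, 0.01, 0.1)
  pt <- permutation_test(w$Y, w$expo, w$basis, t0 = 5, B = 9, seed = 4,
                         lambda_grid = grid, n_starts = 1, tol = 1e-6)
  expect_length(pt$permuted_stats, 9)
  expect_gt(pt$p_value, 0)
  expect_lte(pt$p_value, 1)
  expect_equal(pt$p_value,
               (1 + sum(pt$permuted_stats <= pt$observed_stat)) / 10)
  # determinism
  pt2 <- permutation_test(w$Y, w$expo, w$basis, t0 = 5, B = 9, seed = 4,
                          lambda_grid = grid, n_starts = 1, tol = 1e-6)
  expect_identical(pt$permuted_stats, pt2$permuted_stats)
  expect_error(permutation_test(w$Y, w$expo, w$basis, t0 = 2, B = 3,
                                lambda_grid = grid), "4 years")
})

test_that("changepoint estimation returns the admissible profile and minimiser", {
  # two-period world: same drift world, theta change halfway through
  cfg <- demo_design(years = 1:12, sigma = 0.1, seed = 5)
  traj <- simulate_trajectories(cfg)
  expo <- compute_exposure(traj, config_partition(cfg), cfg$schedule)
  mu1 <- true_mean(expo, cfg)
  cfg2 <- cfg
  cfg2$true$theta <- rbind(c(0, 0.6, 0.4, 0), c(0.7, 0, 0, 0.3))
  mu2 <- true_mean(expo, cfg2)
  set.seed(77)
  y <- cbind(mu1[, 1:6], mu2[, 7:12]) +
    matrix(rnorm(48, 0, 0.1), 4, 12)
  Y <- abundance_matrix(y, years = 1:12)
  grid <- c(0, 0.01, 0.1)
  cp <- estimate_changepoint(Y, expo, build_basis(10, 4),
                             min_years = 4, lambda_grid = grid,
                             n_starts = 1, tol = 1e-6)
  expect_equal(nrow(cp$profile), length(4:8))
  expect_true(cp$changepoint %in% 4:8)
  expect_equal(cp$changepoint, 6)
  # single admissible candidate is returned trivially
  cp1 <- estimate_changepoint(Y, expo, build_basis(10, 4), candidates = 6,
                              min_years = 4, lambda_grid = 0,
                              n_starts = 1, tol = 1e-6)
  expect_equal(cp1$changepoint, 6)
  expect_error(estimate_changepoint(Y, expo, build_basis(10, 4),
                                    candidates = 1, min_years = 4,
                                    lambda_grid = grid), "admissible")
})
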