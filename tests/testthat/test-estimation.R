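# Penalized constrained fitting: design precomputation, adaptive weights,
# the block-relaxation optimiser and its oracles, AIC and tuning.

test_that("structural_zero_mask flags exactly the never-visited pairs", {
  ex <- random_exposure(3, 4, 3, 5)
  ex$G[2, , 3, ] <- 0
  mask <- structural_zero_mask(ex)
  expect_true(mask[2, 3])
  expect_equal(sum(mask), 1L)
  ex$G[2, 2, 3, 4] <- 1e-9   # a single positive entry anywhere clears it
  expect_false(structural_zero_mask(ex)[2, 3])
})

test_that("precompute_design matches the brute-force triple sum", {
  ex <- random_exposure(2, 5, 3, 4, seed = 3)
  basis <- build_basis(5, 4)
  Z <- precompute_design(ex, basis)
  # K = 1 collapses to sum over releases
  Z1 <- precompute_design(ex, build_basis(5, 1))
  expect_equal(Z1[1, 1, , ], apply(ex$G[1, , , ], c(2, 3), sum))
  # single nonzero entry picks out Phi[d, k] * g
  G0 <- array(0, dim = c(1, 5, 2, 2)); G0[1, 3, 2, 1] <- 0.7
  Zs <- precompute_design(G0, basis)
  expect_equal(Zs[1, , 2, 1], basis$Phi[3, ] * 0.7)
  expect_true(all(Zs[1, , 1, ] == 0))
  # full brute force
  oracle <- array(0, dim = dim(Z))
  for (j in 1:2) for (k in 1:4) for (i in 1:3) for (t in 1:4)
    oracle[j, k, i, t] <- sum(basis$Phi[, k] * ex$G[j, , i, t])
  expect_equal(Z, oracle, tolerance = 1e-12)
  expect_error(precompute_design(ex, build_basis(6, 4)), "mismatch")
})

test_that("adaptive weights follow the inverse-pilot rule with flooring and masking", {
  ex <- random_exposure(2, 4, 3, 8, seed = 5, p_zero = 0.25)
  mask <- structural_zero_mask(ex)
  basis <- build_basis(4, 2)
  set.seed(8)
  y <- matrix(rnorm(3 * 8, 1, 0.3), 3, 8)
  aw <- adaptive_weights(y, ex, basis, n_starts = 1)
  us <- aw$pilot$u * aw$pilot$u_scale
  for (j in 1:2) for (i in 1:3) for (k in 1:2) {
    if (mask[j, i]) {
      expect_identical(aw$omega[j, i, k], Inf)
    } else {
      expect_equal(aw$omega[j, i, k],
                   1 / (abs(us[j, i] * aw$pilot$v[j, k]) + 1e-6))
    }
  }
  # floor: zero pilot product -> 1e6; larger products -> smaller weights
  prods <- abs(outer(us[1, ], aw$pilot$v[1, ]))
  om <- aw$omega[1, , ]
  expect_true(all(om[prods == 0] == 1e6))
  ord <- order(prods)
  expect_true(all(diff(om[ord]) <= 1e-9))
})

test_that("huge lambda shrinks everything to zero; a finite lambda_max exists", {
  w <- demo_world(years = 1:6, sigma = 0.2)
  fit <- fit_sourcesink(w$Y, w$expo, w$basis, lambda = 1e12, n_starts = 1)
  expect_true(all(fit$u == 0) && all(fit$w == 0))
  expect_equal(fit$rss, sum(w$Y$y^2))
  # doubling search for a finite full-shrinkage threshold
  lam <- 1
  while (lam < 1e12) {
    f <- fit_sourcesink(w$Y, w$expo, w$basis, lambda = lam, n_starts = 1)
    if (all(f$u == 0)) break
    lam <- lam * 4
  }
  expect_lt(lam, 1e12)
})

test_that("noiseless single-source model is recovered exactly at lambda = 0", {
  # J=1, I=2, D=3, K=1: with the constant basis, f is uniform over releases
  set.seed(99)
  G <- array(runif(1 * 3 * 2 * 6, 0.1, 0.4), dim = c(1, 3, 2, 6))
  basis <- build_basis(3, 1)
  u_true <- matrix(c(1.4, 0.6), 1, 2)
  v_true <- matrix(1, 1, 1)
  y <- oracle_mean(u_true, v_true, G, basis$Phi)
  fit <- fit_sourcesink(y, G, basis, lambda = 0, tol = 1e-14,
                        max_iter = 5000, n_starts = 1)
  expect_lt(max(abs(predict(fit, G) - y)), 1e-6)
  expect_equal(fit$theta[1, ], u_true[1, ] / sum(u_true), tolerance = 1e-6)
  expect_equal(fit$f[1, ], rep(1 / 3, 3), tolerance = 1e-8)
  expect_equal(fit$w[1], sum(u_true) * 3, tolerance = 1e-6)
  expect_lt(fit$rss, 1e-10)
})

test_that("lambda = 0 fit matches an independent box-constrained optimiser", {
  # smooth objective on the non-negative orthant -> L-BFGS-B multistart oracle
  set.seed(21)
  for (case in 1:8) {
    J <- sample(1:2, 1); I <- sample(2:3, 1); D <- sample(2:4, 1)
    K <- sample(1:min(2, D), 1); TT <- sample(4:6, 1)
    G <- array(runif(J * D * I * TT, 0, 0.5), dim = c(J, D, I, TT))
    basis <- build_basis(D, K)
    u0 <- matrix(rexp(J * I), J, I)
    v0 <- matrix(rexp(J * K), J, K)
    y <- oracle_mean(u0, v0, G, basis$Phi) +
      matrix(rnorm(I * TT, 0, 0.1), I, TT)
    fit <- fit_sourcesink(y, G, basis, lambda = 0, tol = 1e-12,
                          max_iter = 5000, n_starts = 3)
    obj <- function(par) {
      u <- matrix(par[seq_len(J * I)], J, I)
      v <- matrix(par[-seq_len(J * I)], J, K)
      oracle_objective(u, v, y, G, basis$Phi, lambda = 0)
    }
    best <- Inf
    for (s in 1:12) {
      start <- c(rexp(J * I), rexp(J * K))
      o <- stats::optim(start, obj, method = "L-BFGS-B", lower = 0,
                        control = list(maxit = 500, factr = 1e3))
      best <- min(best, o$value)
    }
    expect_lt(fit$objective, best + 1e-6)
  }
})

test_that("the fit is coordinate-wise optimal against a brute-force 1-D scan", {
  set.seed(33)
  ex <- random_exposure(2, 3, 3, 6, seed = 13)
  basis <- build_basis(3, 2)
  y <- matrix(rnorm(18, 0.8, 0.4), 3, 6)
  omega <- array(rexp(2 * 3 * 2, 1), dim = c(2, 3, 2))
  fit <- fit_sourcesink(y, ex, basis, lambda = 0.05, omega = omega,
                        tol = 1e-12, max_iter = 5000, n_starts = 1)
  base <- oracle_objective(fit$u, fit$v, y, ex$G, basis$Phi, 0.05, omega)
  expect_equal(base, fit$objective, tolerance = 1e-7)
  for (j in 1:2) for (i in 1:3) {
    u2 <- fit$u
    grid <- seq(max(0, fit$u[j, i] - 0.3), fit$u[j, i] + 0.3, length.out = 121)
    vals <- vapply(grid, function(g) {
      u2[j, i] <- g
      oracle_objective(u2, fit$v, y, ex$G, basis$Phi, 0.05, omega)
    }, 0)
    expect_gte(min(vals), base - 1e-6)
  }
  for (j in 1:2) for (k in 1:2) {
    v2 <- fit$v
    grid <- seq(max(0, fit$v[j, k] - 0.3), fit$v[j, k] + 0.3, length.out = 121)
    vals <- vapply(grid, function(g) {
      v2[j, k] <- g
      oracle_objective(fit$u, v2, y, ex$G, basis$Phi, 0.05, omega)
    }, 0)
    expect_gte(min(vals), base - 1e-6)
  }
})

test_that("normalisation, trace monotonicity and rescaling invariance hold", {
  w <- demo_world(years = 1:8, sigma = 0.15)
  fit <- fit_sourcesink(w$Y, w$expo, w$basis, lambda = 0.01, n_starts = 2)
  active <- which(fit$w > 0)
  expect_equal(rowSums(fit$theta)[active], rep(1, length(active)))
  expect_equal(rowSums(fit$f)[active], rep(1, length(active)))
  expect_true(all(fit$theta >= 0) && all(fit$f >= 0) && all(fit$w >= 0))
  expect_true(all(diff(fit$objective_trace) <= 1e-8))
  # predictions invariant under the internal (u, v) -> (cu, v/c) rescaling
  mu1 <- predict(fit, w$expo)
  fit2 <- fit
  fit2$u <- fit$u * 3; fit2$v <- fit$v / 3
  expect_equal(predict(fit2, w$expo), mu1, tolerance = 1e-12)
  # predict() on training data reproduces rss
  expect_equal(sum((w$Y$y - mu1)^2), fit$rss, tolerance = 1e-8)
  expect_equal(source_productivity(fit), fit$w)
})

test_that("AIC follows the profiled-Gaussian closed form and degenerates at rss 0", {
  fake <- structure(list(rss = 12, n_obs = 12, df = 3), class = "ss_fit")
  expect_equal(AIC(fake), 12 * log(1) + 6)
  fake$rss <- 0
  expect_warning(expect_identical(AIC(fake), -Inf), "degenerate")
})

test_that("predict validates dimensions and handles zero exposure", {
  w <- demo_world(years = 1:4)
  fit <- fit_sourcesink(w$Y, w$expo, w$basis, lambda = 0, n_starts = 1,
                        max_iter = 50)
  G0 <- w$expo$G * 0
  expect_equal(predict(fit, G0), matrix(0, 4, 4))
  expect_error(predict(fit, w$expo$G[, , 1:2, , drop = FALSE]), "dimensions")
  # hand arithmetic: w=2, theta=(1,0), f point mass at d 2, G entry 0.5
  hand <- structure(list(
    u = matrix(c(2, 0), 1, 2), v = matrix(c(1), 1, 1),
    dims = list(J = 1L, D = 3L, I = 2L, TT = 1L, K = 1L),
    basis = build_basis(3, 1)), class = "ss_fit")
  # single exposed release event with G = 0.5; the normalized equivalent
  # (w = 2, theta = (1,0), f a point mass there) predicts 2 * 1 * 0.5 = 1
  G1 <- array(0, dim = c(1, 3, 2, 1)); G1[1, 2, 1, 1] <- 0.5
  expect_equal(predict(hand, G1)[1, 1], 1.0)
  expect_equal(predict(hand, G1)[2, 1], 0)
})

test_that("doubling the response doubles productivity at lambda = 0", {
  w <- demo_world(years = 1:6, sigma = 0.1)
  f1 <- fit_sourcesink(w$Y, w$expo, w$basis, lambda = 0, n_starts = 1,
                       tol = 1e-11, max_iter = 3000)
  y2 <- w$Y$y * 2
  f2 <- fit_sourcesink(y2, w$expo, w$basis, lambda = 0, n_starts = 1,
                       tol = 1e-11, max_iter = 3000)
  expect_equal(f2$w, 2 * f1$w, tolerance = 1e-3)
  expect_equal(f2$theta, f1$theta, tolerance = 1e-3)
})

test_that("tune_sourcesink reproduces the grid, warm-starts and is deterministic", {
  w <- demo_world(years = 1:8, sigma = 0.15)
  f0 <- fit_sourcesink(w$Y, w$expo, w$basis, lambda = 0, n_starts = 1)
  t0 <- tune_sourcesink(w$Y, w$expo, w$basis, lambda_grid = 0, n_starts = 1)
  expect_equal(t0$objective, f0$objective)
  expect_equal(t0$theta, f0$theta)

  grid <- c(0, 10^seq(-3, 0, length.out = 5))
  ta <- tune_sourcesink(w$Y, w$expo, w$basis, grid, n_starts = 1)
  tb <- tune_sourcesink(w$Y, w$expo, w$basis, grid, n_starts = 1)
  expect_identical(attr(ta, "path"), attr(tb, "path"))
  expect_identical(ta$theta, tb$theta)
  path <- attr(ta, "path")
  expect_equal(nrow(path), length(grid))
  expect_equal(min(path$aic), ta$aic)
  expect_error(tune_sourcesink(w$Y, w$expo, w$basis, numeric(0)), "empty")
})

test_that("AIC-tuned adaptive fits zero out true zeros more than lambda = 0", {
  # dense exposure (no structural zeros), sparse truth in u: the estimable
  # true zeros must be produced by the penalty, not by the mask
  ex <- random_exposure(2, 4, 4, 12, seed = 17)
  basis <- build_basis(4, 2)
  u_true <- rbind(c(1.2, 0.8, 0, 0), c(0, 0, 0.9, 1.1))
  v_true <- matrix(c(1, 2, 2, 1), 2, 2, byrow = TRUE)
  mu <- oracle_mean(u_true, v_true, ex$G, basis$Phi)
  true_zero <- u_true == 0
  grid <- c(0, 10^seq(-3, 0.5, length.out = 7))
  zeros_tuned <- zeros_ls <- 0
  set.seed(41)
  for (r in 1:5) {
    y <- mu + matrix(rnorm(length(mu), 0, 0.1), nrow(mu))
    om <- adaptive_weights(y, ex, basis, n_starts = 1)$omega
    ft <- tune_sourcesink(y, ex, basis, grid, omega = om, n_starts = 1)
    fl <- fit_sourcesink(y, ex, basis, lambda = 0, n_starts = 1)
    zeros_tuned <- zeros_tuned + sum(ft$theta[true_zero] == 0)
    zeros_ls <- zeros_ls + sum(fl$theta[true_zero] == 0)
  }
  expect_gt(zeros_tuned, zeros_ls)
})
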