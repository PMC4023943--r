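# Uncertainty and structural-change inference for source-sink fits:
# residual bootstrap, permutation test for a change in the source-sink
# dynamics at a given year, and changepoint estimation by two-period AIC.

#' Residual bootstrap for a source-sink fit
#'
#' Centred residuals over the observed cells are resampled with replacement,
#' added back to the fitted mean, and the model is refitted with the original
#' tuning parameter and adaptive weights held fixed (warm-started at the
#' original solution). For every parameter the probability of being exactly
#' zero across replicates (`pi0`) and a 90% interval are reported: when
#' `pi0 >= pin_threshold` the interval is `[0, q95)` with the lower end
#' pinned at zero, otherwise the 5th and 95th percentiles `(q05, q95)`.
#'
#' @param fit A converged `ss_fit`.
#' @param Y,exposure,basis The training data the fit was produced from.
#' @param B Number of bootstrap replicates (default 400).
#' @param seed Integer seed.
#' @param pin_threshold Zero-probability threshold pinning the lower interval
#'   end at 0 (default 0.05).
#' @param keep_draws Keep the per-replicate parameter draws (default FALSE).
#' @return Object of class `ss_bootstrap`: `B`, `pi0` (lists with `w`,
#'   `theta`, `f`), `ci` (5th/95th percentile bounds), `n_dropped`
#'   (non-converged replicates), `seed`, and optionally `draws`.
#' @export
residual_bootstrap <- function(fit, Y, exposure, basis, B = 400L, seed = 1L,
                               pin_threshold = 0.05, keep_draws = FALSE) {
  stopifnot(inherits(fit, "ss_fit"), B >= 1L)
  ab <- if (inherits(Y, "ss_abundance")) Y else abundance_matrix(as.matrix(Y))
  M <- !ab$mask
  mu <- predict(fit, exposure)
  e <- (ab$y - mu)[M]
  e <- e - mean(e)
  J <- fit$dims$J; I <- fit$dims$I; D <- fit$dims$D
  w_d <- matrix(NA_real_, B, J)
  th_d <- array(NA_real_, c(B, J, I))
  f_d <- array(NA_real_, c(B, J, D))
  seeds <- .child_seeds(seed, B)
  n_dropped <- 0L
  Z <- precompute_design(exposure, basis)
  for (bi in seq_len(B)) {
    ystar <- ab$y
    ystar[M] <- mu[M] + .with_seed(seeds[bi],
                                   sample(e, sum(M), replace = TRUE))
    rep_fit <- tryCatch(
      fit_sourcesink(abundance_matrix(ystar, ab$n_obs, ab$years),
                     exposure, basis, lambda = fit$lambda,
                     omega = fit$omega, mask = fit$fixed_zero_mask,
                     init = list(u = fit$u, v = fit$v), n_starts = 1L,
                     design = Z),
      error = function(e) NULL)
    if (is.null(rep_fit)) { n_dropped <- n_dropped + 1L; next }
    w_d[bi, ] <- rep_fit$w
    th_d[bi, , ] <- rep_fit$theta
    f_d[bi, , ] <- rep_fit$f
  }
  if (n_dropped > 0.1 * B)
    warning(n_dropped, " of ", B, " bootstrap replicates failed to converge")
  ok <- !is.na(w_d[, 1L])
  Bok <- sum(ok)
  if (Bok == 0L) stop("all bootstrap replicates failed")

  q <- function(x, p) unname(stats::quantile(x, p, type = 7, na.rm = TRUE))
  pz <- function(x) mean(x == 0, na.rm = TRUE)
  pi0 <- list(
    w = apply(w_d, 2L, pz),
    theta = apply(th_d, c(2L, 3L), pz),
    f = apply(f_d, c(2L, 3L), pz))
  lo <- function(x, p0) if (p0 >= pin_threshold) 0 else q(x, 0.05)
  ci <- list(
    w_lo = vapply(seq_len(J), function(j) lo(w_d[, j], pi0$w[j]), 0),
    w_hi = vapply(seq_len(J), function(j) q(w_d[, j], 0.95), 0),
    theta_lo = matrix(0, J, I), theta_hi = matrix(0, J, I),
    f_lo = matrix(0, J, D), f_hi = matrix(0, J, D))
  for (j in seq_len(J)) {
    for (i in seq_len(I)) {
      ci$theta_lo[j, i] <- lo(th_d[, j, i], pi0$theta[j, i])
      ci$theta_hi[j, i] <- q(th_d[, j, i], 0.95)
    }
    for (d in seq_len(D)) {
      ci$f_lo[j, d] <- lo(f_d[, j, d], pi0$f[j, d])
      ci$f_hi[j, d] <- q(f_d[, j, d], 0.95)
    }
  }
  structure(list(B = B, n_used = Bok, n_dropped = n_dropped,
                 pi0 = pi0, ci = ci, pin_threshold = pin_threshold,
                 seed = seed,
                 draws = if (keep_draws)
                   list(w = w_d, theta = th_d, f = f_d) else NULL),
            class = "ss_bootstrap")
}

#' @export
print.ss_bootstrap <- function(x, ...) {
  cat(sprintf("Residual bootstrap: %d replicates (%d dropped)\n",
              x$B, x$n_dropped))
  invisible(x)
}

# Tuned two-period AIC sum for a given ordering of year indices. G and the
# precomputed design Zfull are sliced per period (the design is linear in G
# along the release axis only, so year-slicing commutes with precomputation).
.two_period_aic <- function(ab, G, Zfull, basis, n_pre, order_idx,
                            lambda_grid, adaptive = TRUE, ...) {
  pre <- order_idx[seq_len(n_pre)]
  post <- order_idx[-seq_len(n_pre)]
  tot <- 0
  for (idx in list(pre, post)) {
    Yk <- abundance_matrix(ab$y[, idx, drop = FALSE],
                           ab$n_obs[, idx, drop = FALSE], ab$years[idx])
    Gk <- G[, , , idx, drop = FALSE]
    Zk <- Zfull[, , , idx, drop = FALSE]
    mask <- structural_zero_mask(Gk)
    init <- NULL
    omega <- if (adaptive) {
      pilot <- fit_sourcesink(Yk, Gk, basis, lambda = 0, mask = mask,
                              design = Zk, ridge = 1, ...)
      init <- list(u = pilot$u, v = pilot$v)
      .omega_from_pilot(pilot, mask)
    } else NULL
    fit <- tune_sourcesink(Yk, Gk, basis, lambda_grid, omega = omega,
                           mask = mask, design = Zk, init = init, ...)
    tot <- tot + fit$aic
  }
  tot
}

#' Permutation test for structural change in the source-sink dynamics
#'
#' Tests whether the source-sink parameters differ between the years up to
#' `t0` and the years after `t0`. The statistic is the sum of the AIC of the
#' model fitted (and tuned independently) to the pre-period and to the
#' post-period. Under the null of no change, years are exchangeable: each
#' replicate permutes the year labels (moving abundance and exposure
#' year-slices jointly), re-splits at the same pre/post sizes and recomputes
#' the statistic. A *small* statistic means the two-period model fits well,
#' so evidence of change is a lower-tail event:
#' `p = (1 + #\{permuted <= observed\}) / (B + 1)`.
#'
#' @param Y An `ss_abundance`.
#' @param exposure An `ss_exposure` over the same years.
#' @param basis An `ss_basis`.
#' @param t0 Split year (last year of the pre-period).
#' @param B Number of permutations (default 500).
#' @param seed Integer seed.
#' @param lambda_grid Tuning grid used for every period fit.
#' @param min_years Minimum years required in each period (default 4).
#' @param adaptive Recompute adaptive weights per period fit (default TRUE).
#' @param ... Passed to the underlying fits.
#' @return Object of class `ss_permtest`: `t0`, `observed_stat`,
#'   `permuted_stats` (length B), `p_value`, `B`, `seed`.
#' @export
permutation_test <- function(Y, exposure, basis, t0, B = 500L, seed = 1L,
                             lambda_grid = c(0, 10^seq(-3, 1, length.out = 5)),
                             min_years = 4L, adaptive = TRUE, ...) {
  ab <- Y
  stopifnot(inherits(ab, "ss_abundance"), inherits(exposure, "ss_exposure"))
  years <- ab$years
  n_pre <- sum(years <= t0)
  n_post <- sum(years > t0)
  if (n_pre < min_years || n_post < min_years)
    stop(sprintf("need >= %d years in each period; got %d pre and %d post",
                 min_years, n_pre, n_post))
  TT <- length(years)
  G <- exposure$G
  Zfull <- precompute_design(G, basis)
  obs <- .two_period_aic(ab, G, Zfull, basis, n_pre, seq_len(TT),
                         lambda_grid, adaptive = adaptive, ...)
  seeds <- .child_seeds(seed, B)
  perm <- vapply(seq_len(B), function(bi) {
    ord <- .with_seed(seeds[bi], sample.int(TT))
    .two_period_aic(ab, G, Zfull, basis, n_pre, ord, lambda_grid,
                    adaptive = adaptive, ...)
  }, 0)
  p <- (1 + sum(perm <= obs)) / (B + 1)
  structure(list(t0 = t0, observed_stat = obs, permuted_stats = perm,
                 p_value = p, B = B, seed = seed),
            class = "ss_permtest")
}

#' @export
print.ss_permtest <- function(x, ...) {
  cat(sprintf("Structural-change permutation test at t0=%s: stat=%.3f, p=%.4f (B=%d)\n",
              x$t0, x$observed_stat, x$p_value, x$B))
  invisible(x)
}

#' Estimate the changepoint year of the source-sink dynamics
#'
#' Profiles the two-period AIC sum over candidate split years and returns the
#' minimiser, subject to both periods containing at least `min_years` years.
#'
#' @inheritParams permutation_test
#' @param candidates Candidate split years (default: all years admitting
#'   `min_years` on both sides).
#' @return List with `changepoint` (the AIC-minimising year) and `profile`
#'   (data.frame of candidate year and two-period AIC).
#' @export
estimate_changepoint <- function(Y, exposure, basis, candidates = NULL,
                                 min_years = 4L,
                                 lambda_grid = c(0, 10^seq(-3, 1, length.out = 5)),
                                 adaptive = TRUE, ...) {
  ab <- Y
  years <- ab$years
  TT <- length(years)
  if (is.null(candidates))
    candidates <- years[seq_len(TT - min_years)][-seq_len(min_years - 1L)]
  ok <- vapply(candidates, function(t0)
    sum(years <= t0) >= min_years && sum(years > t0) >= min_years, TRUE)
  candidates <- candidates[ok]
  if (!length(candidates)) stop("no admissible changepoint candidates")
  G <- exposure$G
  Zfull <- precompute_design(G, basis)
  prof <- vapply(candidates, function(t0)
    .two_period_aic(ab, G, Zfull, basis, sum(years <= t0), seq_len(TT),
                    lambda_grid, adaptive = adaptive, ...), 0)
  list(changepoint = candidates[which.min(prof)],
       profile = data.frame(year = candidates, aic2 = prof))
}
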