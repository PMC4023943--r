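# Sparse multi-component multivariate regression for source-sink
# reconstruction.
#
# Model: for sink region i and year t,
#   y[i,t] = sum_j w[j] * theta[j,i] * sum_d f[j,d] * G[j,d,i,t] + eps[i,t]
# with theta[j,] >= 0 summing to 1 (sink effects), f[j,] = Phi %*% b[j] >= 0
# summing to 1 (release-time curve), w[j] >= 0 (source productivity), and
# eps uncorrelated with mean 0 and constant variance.
#
# Internally the mean is parameterised bilinearly as
#   mu[i,t] = sum_j sum_k u[j,i] * v[j,k] * Z[j,k,i,t],
# where Z[j,k,i,t] = sum_d Phi[d,k] * G[j,d,i,t], u[j,i] = scale * theta[j,i]
# and v[j,] are non-negative spline coefficients. Estimation minimises
#   Q(u,v) = sum_obs (y - mu)^2
#          + sum_j lambda[j] * sum_{i,k} omega[j,i,k] * u[j,i] * v[j,k]
# subject to u, v >= 0 and hard zeros where the exposure tensor is
# identically zero, by cyclic block relaxation with closed-form non-negative
# soft-thresholding coordinate updates. Sparsity in u gives sparse sink
# effects; sparsity in v gives smooth release curves.

#' Structural-zero mask
#'
#' A (source, region) pair whose exposure is identically zero over all
#' release events and years can never receive propagules under the drift
#' model; its sink effect is fixed at zero (the asterisk convention of the
#' reconstruction tables).
#'
#' @param exposure An `ss_exposure` object (or bare 4-d array).
#' @return Logical `J x I` matrix, `TRUE` where the sink effect is fixed to 0.
#' @export
structural_zero_mask <- function(exposure) {
  G <- if (inherits(exposure, "ss_exposure")) exposure$G else exposure
  apply(G, c(1, 3), function(x) all(x == 0))
}

#' Collapse the exposure tensor against the spline basis
#'
#' Precomputes `Z[j,k,i,t] = sum_d Phi[d,k] * G[j,d,i,t]`, making the model
#' mean bilinear in the sink-effect and spline-coefficient blocks.
#'
#' @param exposure An `ss_exposure` object (or 4-d array `[J,D,I,T]`).
#' @param basis An `ss_basis` whose `D` matches the release axis.
#' @return 4-d array `[J, K, I, T]`.
#' @export
precompute_design <- function(exposure, basis) {
  G <- if (inherits(exposure, "ss_exposure")) exposure$G else exposure
  stopifnot(inherits(basis, "ss_basis"))
  dg <- dim(G)
  if (dg[2L] != basis$D)
    stop(sprintf("release axis mismatch: exposure has D=%d, basis has D=%d",
                 dg[2L], basis$D))
  J <- dg[1L]; D <- dg[2L]; I <- dg[3L]; TT <- dg[4L]
  K <- basis$K
  Z <- array(0, dim = c(J, K, I, TT))
  for (j in seq_len(J)) {
    Gj <- matrix(G[j, , , ], nrow = D)          # D x (I*T)
    Z[j, , , ] <- crossprod(basis$Phi, Gj)      # K x (I*T)
  }
  Z
}

#' Adaptive penalty weights
#'
#' Weights in the spirit of the adaptive lasso: a pilot unpenalized
#' non-negative fit provides magnitudes, and each outer-product entry is
#' penalised inversely to its pilot magnitude,
#' `omega[j,i,k] = 1 / (|u0[j,i] * v0[j,k]| + floor)`. Structurally masked
#' (source, region) pairs get `+Inf` (they never enter the model).
#'
#' @param Y An `ss_abundance` object (or matrix).
#' @param exposure An `ss_exposure` object.
#' @param basis An `ss_basis`.
#' @param mask Optional structural-zero mask (default from `exposure`).
#' @param floor_eps Magnitude floor (default `1e-6`).
#' @param ridge_pilot L2 penalty applied to the pilot's standardized
#'   coefficients (default 1). A plain least-squares pilot can assign large
#'   coefficients to nearly-unexposed source-region cells purely to absorb
#'   noise, which the adaptive weights would then endorse; mild ridge
#'   shrinkage keeps the pilot bounded (adaptive-lasso-with-ridge-pilot, the
#'   standard remedy under collinearity).
#' @param ... Options passed to the pilot [fit_sourcesink()] call.
#' @return List with `omega` (`J x I x K` array) and `pilot` (the pilot fit).
#' @export
adaptive_weights <- function(Y, exposure, basis, mask = NULL,
                             floor_eps = 1e-6, ridge_pilot = 1, ...) {
  if (is.null(mask)) mask <- structural_zero_mask(exposure)
  pilot <- fit_sourcesink(Y, exposure, basis, lambda = 0, mask = mask,
                          ridge = ridge_pilot, ...)
  list(omega = .omega_from_pilot(pilot, mask, floor_eps), pilot = pilot)
}

# Weights are formed from the pilot coefficients on the standardized
# covariate scale (u * u_scale), the scale the penalty itself acts on.
.omega_from_pilot <- function(pilot, mask, floor_eps = 1e-6) {
  us <- pilot$u * pilot$u_scale
  J <- nrow(us); I <- ncol(us); K <- ncol(pilot$v)
  omega <- array(NA_real_, dim = c(J, I, K))
  for (j in seq_len(J))
    omega[j, , ] <- 1 / (abs(outer(us[j, ], pilot$v[j, ])) + floor_eps)
  if (all(us == 0)) {
    warning("degenerate all-zero pilot fit; using uniform weights")
    omega[] <- 1
  }
  for (j in seq_len(J)) omega[j, mask[j, ], ] <- Inf
  omega
}

# ---- core optimiser ---------------------------------------------------------

# One full optimisation run from a given start (compiled coordinate descent;
# see src/fit_core.cpp). y0: I x T with NA -> 0; M: logical I x T observed
# mask; Z: [J,K,I,T] design array; omega0: omega with Inf (masked) replaced
# by 0 -- masked u are hard zeros so their penalty terms never enter the
# objective.
.fit_run <- function(y0, M, Z, lambda, omega0, mask, u, v,
                     tol = 1e-8, max_iter = 500L, ridge = 0) {
  .cd_fit(y0, M, Z, lambda, omega0, mask, u, v, tol, as.integer(max_iter),
          ridge)
}

# marginal initialisation: v uniform; u from per-(j,i) non-negative
# single-covariate regression of y on the source-j aggregate covariate
.init_uv <- function(y0, M, Z, mask, J, I, K, TT) {
  v <- matrix(1 / K, J, K)
  u <- matrix(0, J, I)
  Mn <- M * 1
  for (j in seq_len(J)) {
    Zj <- array(Z[j, , , ], dim = c(K, I, TT))
    for (i in seq_len(I)) {
      if (mask[j, i]) next
      cvec <- colMeans(matrix(Zj[, i, ], nrow = K)) * Mn[i, ]
      den <- sum(cvec^2)
      if (den > 0) u[j, i] <- max(0, sum(y0[i, ] * cvec) / den)
    }
  }
  list(u = u, v = v)
}

#' Fit the source-sink reconstruction model
#'
#' Minimises the penalized constrained least-squares objective (sum of
#' squared errors plus, per source, a tuning parameter times the weighted
#' entrywise L1 norm of the outer product of the sink-effect and
#' spline-coefficient blocks) subject to non-negativity and structural
#' zeros, then normalises to the identifiable parameterisation
#' (`w`, `theta`, `f`).
#'
#' As in standard lasso practice, the penalty acts on coefficients of
#' standardized covariates: each (source, region) design slice
#' `Z[j,,i,]` is scaled to unit root-mean-square inside the optimiser
#' (`u_scale[j,i]`), so that exposure cells of very different magnitude
#' face comparable shrinkage; estimates are mapped back to the original
#' scale on return. At `lambda = 0` this has no effect on the solution.
#'
#' @param Y An `ss_abundance` object, or a bare `I x T` matrix (NA = missing).
#' @param exposure An `ss_exposure` object or 4-d array `[J,D,I,T]`.
#' @param basis An `ss_basis`.
#' @param lambda Tuning parameter, scalar (shared across sources) or length-J.
#' @param omega Adaptive weight array `J x I x K`; default all-ones
#'   (unweighted penalty). `Inf` entries denote structural zeros.
#' @param mask Optional logical `J x I` structural-zero mask; default derived
#'   from `exposure` via [structural_zero_mask()].
#' @param n_starts Number of seeded multi-starts (the objective is bilinear,
#'   hence non-convex); the best objective wins. Default 3.
#' @param init Optional list with `u`, `v` start values (overrides the
#'   marginal initialisation; multi-start perturbs whichever is used).
#' @param tol Relative objective-decrease convergence tolerance.
#' @param max_iter Maximum block-relaxation cycles per start.
#' @param seed Seed for the multi-start perturbations.
#' @param design Optional precomputed design array from
#'   [precompute_design()] (avoids recomputation along tuning grids).
#' @param ridge Optional L2 penalty on the standardized coefficient blocks
#'   (default 0). Used by the adaptive-weight pilot, where it prevents
#'   near-zero-exposure cells from absorbing noise with unbounded
#'   coefficients; the final penalized fit runs with `ridge = 0`.
#' @return Object of class `ss_fit`; see Details.
#' @details The returned fit contains the normalized parameters `w` (length-J
#'   productivity multipliers), `theta` (`J x I` sink effects, rows of active
#'   sources sum to 1), `f` (`J x D` release-curve masses, rows of active
#'   sources sum to 1), `b` (`J x K` spline coefficients), the unnormalized
#'   internals `u`, `v`, the penalty state (`lambda`, `omega`, `mask`), and
#'   diagnostics: `rss`, `df` (count of strictly positive entries of `u` and
#'   `v` minus two per active source), `aic`, `objective`, `objective_trace`
#'   (non-increasing), `converged`, `iterations`, `n_obs` and `seed`. For an
#'   inactive source (`w[j] = 0`) the `theta` and `f` rows are reported as
#'   zero: it is not meaningful to estimate a release curve for a source that
#'   produces nothing.
#' @export
fit_sourcesink <- function(Y, exposure, basis, lambda = 0, omega = NULL,
                           mask = NULL, n_starts = 3L, init = NULL,
                           tol = 1e-8, max_iter = 500L, seed = 1L,
                           design = NULL, ridge = 0) {
  ab <- if (inherits(Y, "ss_abundance")) Y else abundance_matrix(as.matrix(Y))
  G <- if (inherits(exposure, "ss_exposure")) exposure$G else exposure
  dg <- dim(G)
  J <- dg[1L]; D <- dg[2L]; I <- dg[3L]; TT <- dg[4L]
  if (nrow(ab$y) != I || ncol(ab$y) != TT)
    stop(sprintf("abundance is %d x %d but exposure implies %d regions x %d years",
                 nrow(ab$y), ncol(ab$y), I, TT))
  K <- basis$K
  if (length(lambda) == 1L) lambda <- rep(lambda, J)
  if (length(lambda) != J) stop("lambda must be scalar or length J")
  if (any(lambda < 0)) stop("lambda must be >= 0")
  if (is.null(mask)) mask <- structural_zero_mask(G)
  if (is.null(omega)) omega <- array(1, dim = c(J, I, K))
  stopifnot(identical(dim(omega), c(J, I, K)))
  omega0 <- omega
  for (j in seq_len(J)) omega0[j, mask[j, ], ] <- 0  # u hard-zeroed there

  Z <- if (is.null(design)) precompute_design(G, basis) else design

  # standardize the u-covariates: each (j,i) design slice is scaled to unit
  # root-mean-square, so the L1 penalty acts on comparable coefficient
  # scales (near-zero-exposure cells would otherwise carry huge, nearly
  # free coefficients); estimates are mapped back to the original scale
  u_scale <- sqrt(apply(Z^2, c(1, 3), mean))
  u_scale[u_scale == 0] <- 1
  Zs <- Z
  for (i in seq_len(I)) Zs[, , i, ] <- Z[, , i, ] / u_scale[, i]

  M <- !ab$mask
  y0 <- ab$y; y0[!M] <- 0

  start0 <- if (is.null(init)) .init_uv(y0, M, Zs, mask, J, I, K, TT)
            else list(u = init$u * u_scale, v = init$v)
  start0$u[mask] <- 0
  seeds <- .child_seeds(seed, max(1L, n_starts - 1L))
  best <- NULL
  for (s in seq_len(max(1L, n_starts))) {
    st <- if (s == 1L) start0 else .with_seed(seeds[s - 1L], {
      u <- start0$u * matrix(stats::runif(J * I, 0.25, 1.75), J, I)
      v <- start0$v * matrix(stats::runif(J * K, 0.25, 1.75), J, K)
      u[mask] <- 0
      list(u = u, v = v)
    })
    run <- .fit_run(y0, M, Zs, lambda, omega0, mask, st$u, st$v,
                    tol = tol, max_iter = max_iter, ridge = ridge)
    if (is.null(best) || run$objective < best$objective - 1e-12) best <- run
  }

  u <- best$u / u_scale; v <- best$v
  Phi <- basis$Phi
  w <- numeric(J)
  theta <- matrix(0, J, I)
  f <- matrix(0, J, D)
  b <- matrix(0, J, K)
  for (j in seq_len(J)) {
    su <- sum(u[j, ])
    fj_raw <- as.vector(Phi %*% v[j, ])
    sf <- sum(fj_raw)
    w[j] <- su * sf
    if (w[j] > 0) {
      theta[j, ] <- u[j, ] / su
      f[j, ] <- fj_raw / sf
      b[j, ] <- v[j, ] / sf
    }
  }
  theta <- round(theta, 10)
  f <- round(f, 10)

  n_obs <- sum(M)
  rss <- sum(best$R[M]^2)
  active <- which(w > 0)
  df <- sum(u > 0) + sum(v[active, , drop = FALSE] > 0) - 2L * length(active)
  structure(list(
    w = w, theta = theta, f = f, b = b, u = u, v = v, u_scale = u_scale,
    lambda = lambda, omega = omega, fixed_zero_mask = mask,
    rss = rss, df = df, n_obs = n_obs,
    aic = .aic(rss, n_obs, df),
    objective = best$objective, objective_trace = best$trace,
    converged = best$converged, iterations = best$iterations,
    dims = list(J = J, D = D, I = I, TT = TT, K = K),
    basis = basis, seed = seed
  ), class = "ss_fit")
}

.aic <- function(rss, n, df) {
  if (rss <= 0) {
    warning("zero residual sum of squares; AIC is -Inf (degenerate fit)")
    return(-Inf)
  }
  n * log(rss / n) + 2 * df
}

#' Akaike information criterion of a source-sink fit
#'
#' Gaussian working likelihood with the error variance profiled out:
#' `AIC = N log(rss / N) + 2 df`, `N` the number of observed cells and `df`
#' the count of strictly positive parameters minus the two normalisation
#' constraints per active source.
#'
#' @param object An `ss_fit`.
#' @param ... Ignored.
#' @param k Ignored (fixed at the classical 2).
#' @return Numeric AIC value (`-Inf` with a warning if `rss = 0`).
#' @export
AIC.ss_fit <- function(object, ..., k = 2) {
  .aic(object$rss, object$n_obs, object$df)
}

#' Predict the model mean
#'
#' @param object An `ss_fit`.
#' @param exposure Exposure tensor to predict from (default: refuse — pass
#'   the training or new `ss_exposure`).
#' @param ... Ignored.
#' @return `I x T` matrix of model means.
#' @export
predict.ss_fit <- function(object, exposure, ...) {
  G <- if (inherits(exposure, "ss_exposure")) exposure$G else exposure
  d <- object$dims
  dg <- dim(G)
  if (dg[1L] != d$J || dg[2L] != d$D || dg[3L] != d$I)
    stop("exposure dimensions do not match the fitted model")
  Z <- precompute_design(G, object$basis)
  TT <- dg[4L]
  mu <- matrix(0, d$I, TT)
  for (j in seq_len(d$J)) {
    Zj <- array(Z[j, , , ], dim = c(d$K, d$I, TT))
    for (i in seq_len(d$I))
      mu[i, ] <- mu[i, ] + object$u[j, i] *
        as.vector(object$v[j, ] %*% Zj[, i, ])
  }
  mu
}

#' Per-source annual productivity index
#'
#' Since the release curve sums to one, `w[j]` is the per-source annual
#' production index on the response scale (the first row of the
#' reconstruction tables).
#' @param fit An `ss_fit`.
#' @return Numeric vector of length J.
#' @export
source_productivity <- function(fit) {
  stopifnot(inherits(fit, "ss_fit"))
  fit$w
}

#' Tune the penalty by AIC over a grid
#'
#' Fits every value of a shared tuning-parameter grid (warm-started along the
#' increasing grid) and returns the AIC-minimising fit, with the full
#' `(lambda, aic, df, rss)` path attached as attribute `path`.
#'
#' @inheritParams fit_sourcesink
#' @param lambda_grid Non-empty vector of candidate values `>= 0`.
#' @param init Optional warm start for the first grid point (e.g. the
#'   adaptive-weight pilot solution); later grid points warm-start from
#'   their predecessor.
#' @param ... Passed to [fit_sourcesink()].
#' @return The best `ss_fit` (attribute `path` holds a data.frame of the
#'   whole grid).
#' @export
tune_sourcesink <- function(Y, exposure, basis, lambda_grid, omega = NULL,
                            mask = NULL, design = NULL, init = NULL, ...) {
  if (!length(lambda_grid)) stop("empty lambda grid")
  if (any(lambda_grid < 0)) stop("lambda grid values must be >= 0")
  lambda_grid <- sort(unique(lambda_grid))
  if (is.null(design)) design <- precompute_design(exposure, basis)
  best <- NULL
  warm <- init
  path <- data.frame(lambda = lambda_grid, aic = NA_real_, df = NA_integer_,
                     rss = NA_real_)
  for (gi in seq_along(lambda_grid)) {
    fit <- fit_sourcesink(Y, exposure, basis, lambda = lambda_grid[gi],
                          omega = omega, mask = mask, init = warm,
                          design = design, ...)
    warm <- list(u = fit$u, v = fit$v)
    path$aic[gi] <- fit$aic
    path$df[gi] <- fit$df
    path$rss[gi] <- fit$rss
    if (is.null(best) || fit$aic < best$aic) best <- fit
  }
  attr(best, "path") <- path
  best
}

#' @export
print.ss_fit <- function(x, ...) {
  d <- x$dims
  cat(sprintf("Source-sink fit: J=%d sources, I=%d regions, T=%d years (K=%d df)\n",
              d$J, d$I, d$TT, d$K))
  cat(sprintf("  lambda=%s  rss=%.4g  df=%d  AIC=%.3f  %s\n",
              paste(signif(unique(x$lambda), 3), collapse = "/"),
              x$rss, x$df, x$aic,
              if (x$converged) "converged" else "NOT converged"))
  cat("  productivity w:", paste(sprintf("%.3f", x$w), collapse = " "), "\n")
  invisible(x)
}

#' Reconstruction-table export
#'
#' Emits the table layout of the study's reconstruction tables: one block per
#' source with the productivity estimate in the first row and the per-sink
#' effects below; structural zeros are shown as `"*"`.
#'
#' @param fit An `ss_fit`.
#' @param boot Optional [residual_bootstrap()] result; adds zero-probability
#'   and 90% interval columns.
#' @param path Optional CSV output path.
#' @return A data.frame (written to `path` when given), invisibly if written.
#' @export
fit_table <- function(fit, boot = NULL, path = NULL) {
  J <- fit$dims$J; I <- fit$dims$I
  rows <- c("w", paste0("theta_", seq_len(I)))
  out <- data.frame(parameter = rows)
  fmt <- function(x) sprintf("%.2f", x)
  for (j in seq_len(J)) {
    est <- c(fmt(fit$w[j]), ifelse(fit$fixed_zero_mask[j, ], "*",
                                   fmt(fit$theta[j, ])))
    out[[paste0("source_", j, "_est")]] <- est
    if (!is.null(boot)) {
      pi0 <- c(boot$pi0$w[j], boot$pi0$theta[j, ])
      lo <- c(boot$ci$w_lo[j], boot$ci$theta_lo[j, ])
      hi <- c(boot$ci$w_hi[j], boot$ci$theta_hi[j, ])
      star <- c(FALSE, fit$fixed_zero_mask[j, ])
      out[[paste0("source_", j, "_pi0")]] <-
        ifelse(star, "*", sprintf("%.0f%%", 100 * pi0))
      out[[paste0("source_", j, "_ci")]] <-
        ifelse(star, "*", sprintf("%s%.2f,%.2f)",
                                  ifelse(pi0 >= boot$pin_threshold, "[", "("),
                                  lo, hi))
    }
  }
  if (!is.null(path)) {
    utils::write.csv(out, path, row.names = FALSE)
    return(invisible(out))
  }
  out
}
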