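# Robustness experiments against systematic (trajectory shifting) and random
# (covariate perturbation) drift-model error.

#' Sparsity-pattern misclassification rate
#'
#' Fraction of comparable entries whose zero/nonzero status differs between
#' two sink-effect patterns. Structurally fixed zeros can never flip and are
#' excluded from the denominator.
#'
#' @param pattern_a,pattern_b Logical matrices (`TRUE` = nonzero), same shape.
#' @param exclude Optional logical matrix of entries to exclude (structural
#'   zeros).
#' @return Proportion in `[0, 1]`.
#' @export
misclassification_rate <- function(pattern_a, pattern_b, exclude = NULL) {
  pattern_a <- as.matrix(pattern_a); pattern_b <- as.matrix(pattern_b)
  if (!identical(dim(pattern_a), dim(pattern_b)))
    stop("patterns must have the same shape")
  keep <- if (is.null(exclude)) rep(TRUE, length(pattern_a)) else {
    if (!identical(dim(as.matrix(exclude)), dim(pattern_a)))
      stop("exclude mask must match the pattern shape")
    !as.matrix(exclude)
  }
  if (!any(keep)) stop("no comparable entries after exclusion")
  mean(pattern_a[keep] != pattern_b[keep])
}

# nonzero pattern of the sink effects of a fit
.theta_pattern <- function(fit) fit$theta > 0

#' Trajectory-shifting sensitivity experiment
#'
#' For each shift rate `a`, the propagule positions are shifted forward along
#' their own tracks (emulating a `100*a`% underestimation of current speed),
#' the exposure covariates recomputed, and the model refitted with fresh
#' tuning. Reports, per rate, the fitted parameters, the sink-effect sparsity
#' pattern, and whether the pattern changed relative to the unshifted
#' baseline.
#'
#' @param traj An `ss_trajectories` table.
#' @param partition An `ss_regions` partition.
#' @param schedule An `ss_schedule`.
#' @param Y An `ss_abundance` over the same years.
#' @param basis An `ss_basis`.
#' @param a_values Shift rates; default `c(0.05, 0.10, 0.15, 0.20)` (5% to
#'   20% in 5% increments, the range typical of drift-model speed bias).
#' @param lambda_grid Tuning grid (shared by baseline and shifted refits).
#' @param adaptive Use adaptive weights (default TRUE).
#' @param ... Passed to the underlying fits.
#' @return Object of class `ss_shift_report`: `baseline` fit, per-rate list
#'   `fits`, logical `pattern_changed` per rate, and `misclassification` per
#'   rate (vs. baseline, structural zeros excluded).
#' @export
shift_experiment <- function(traj, partition, schedule, Y, basis,
                             a_values = c(0.05, 0.10, 0.15, 0.20),
                             lambda_grid = c(0, 10^seq(-3, 1, length.out = 5)),
                             adaptive = TRUE, ...) {
  if (any(a_values < 0 | a_values > 0.5))
    stop("shift rates must lie in [0, 0.5]")
  tune1 <- function(expo) {
    omega <- if (adaptive) adaptive_weights(Y, expo, basis, ...)$omega else NULL
    tune_sourcesink(Y, expo, basis, lambda_grid, omega = omega, ...)
  }
  base_expo <- compute_exposure(traj, partition, schedule, years = Y$years)
  baseline <- tune1(base_expo)
  base_pat <- .theta_pattern(baseline)
  fits <- list()
  changed <- logical(length(a_values))
  mis <- numeric(length(a_values))
  for (ai in seq_along(a_values)) {
    a <- a_values[ai]
    expo_a <- if (a == 0) base_expo else
      compute_exposure(shift_trajectories(traj, a), partition, schedule,
                       years = Y$years)
    fit_a <- if (a == 0) baseline else tune1(expo_a)
    fits[[ai]] <- fit_a
    mis[ai] <- misclassification_rate(base_pat, .theta_pattern(fit_a),
                                      exclude = baseline$fixed_zero_mask)
    changed[ai] <- mis[ai] > 0
  }
  structure(list(a_values = a_values, baseline = baseline, fits = fits,
                 pattern_changed = changed, misclassification = mis),
            class = "ss_shift_report")
}

#' @export
print.ss_shift_report <- function(x, ...) {
  cat("Shift sensitivity: rate -> pattern changed?\n")
  for (i in seq_along(x$a_values))
    cat(sprintf("  a=%.2f  %s (misclassification %.3f)\n", x$a_values[i],
                if (x$pattern_changed[i]) "CHANGED" else "unchanged",
                x$misclassification[i]))
  invisible(x)
}

#' Random covariate-perturbation sensitivity experiment
#'
#' Repeatedly perturbs every exposure entry by `+/- 100*frac`% (each sign
#' with probability 1/2), refits with fresh tuning, and contrasts the
#' estimated sink-effect sparsity pattern with the unperturbed baseline.
#'
#' @param exposure An `ss_exposure`.
#' @param Y An `ss_abundance`.
#' @param basis An `ss_basis`.
#' @param frac Perturbation fraction (default 0.05, i.e. +/- 5%).
#' @param n_reps Number of perturbation replicates (default 300).
#' @param seed Integer seed.
#' @param lambda_grid Tuning grid.
#' @param adaptive Use adaptive weights (default TRUE).
#' @param ... Passed to the underlying fits.
#' @return Object of class `ss_perturb_report`: per-replicate
#'   `misclassification` vector plus its `mean` and `sd`, and the `baseline`
#'   fit.
#' @export
perturbation_experiment <- function(exposure, Y, basis, frac = 0.05,
                                    n_reps = 300L, seed = 1L,
                                    lambda_grid = c(0, 10^seq(-3, 1, length.out = 5)),
                                    adaptive = TRUE, ...) {
  stopifnot(n_reps >= 1L)
  tune1 <- function(expo) {
    omega <- if (adaptive) adaptive_weights(Y, expo, basis, ...)$omega else NULL
    tune_sourcesink(Y, expo, basis, lambda_grid, omega = omega, ...)
  }
  baseline <- tune1(exposure)
  base_pat <- .theta_pattern(baseline)
  seeds <- .child_seeds(seed, n_reps)
  mis <- vapply(seq_len(n_reps), function(r) {
    pert <- perturb_exposure(exposure, frac = frac, seed = seeds[r])
    fit_r <- tune1(pert)
    misclassification_rate(base_pat, .theta_pattern(fit_r),
                           exclude = baseline$fixed_zero_mask)
  }, 0)
  structure(list(frac = frac, n_reps = n_reps, seed = seed,
                 misclassification = mis, mean = mean(mis), sd = stats::sd(mis),
                 baseline = baseline),
            class = "ss_perturb_report")
}

#' @export
print.ss_perturb_report <- function(x, ...) {
  cat(sprintf(
    "Perturbation sensitivity (+/-%.0f%%, %d reps): mean misclassification %.2f%% (sd %.2f%%)\n",
    100 * x$frac, x$n_reps, 100 * x$mean, 100 * x$sd))
  invisible(x)
}
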