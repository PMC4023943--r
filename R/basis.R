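# Cubic B-spline basis for the release-time (strobilation) curves.
#
# The basis is evaluated at the release-event indices 1..D. Non-negativity of
# the basis plus non-negative coefficients is the feasibility device that
# keeps the fitted curve f = Phi %*% b >= 0 with simple bound constraints;
# smoothness comes from sparsity of b, not from a roughness penalty.

#' Build a release-curve spline basis
#'
#' Cubic (order-4) B-spline basis on the release-index range `[1, D]` with
#' `K - 4` equally spaced interior knots (boundary knots clamped) for
#' `K >= 4`; for `K < 4` a Bernstein polynomial basis of degree `K - 1`
#' (non-negative, partition of unity) is used instead, so every row of the
#' basis matrix sums to 1 for all admissible `K`.
#'
#' @param D Number of release events (columns of the exposure tensor).
#' @param K Degrees of freedom, `1 <= K <= min(D, cap)`.
#' @param cap Upper cap on `K` (default 10, the study's maximum).
#' @return Object of class `ss_basis`: list with `Phi` (`D x K` matrix),
#'   `K`, `D` and the `knots` vector (`NULL` for the Bernstein case).
#' @examples
#' b <- build_basis(40, 10)
#' range(rowSums(b$Phi))  # 1 1
#' @export
build_basis <- function(D, K, cap = 10L) {
  D <- as.integer(D); K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1")
  if (K > D) stop("K must not exceed the number of release events D")
  if (K > cap) stop("K exceeds the cap of ", cap, " degrees of freedom")
  x <- seq_len(D)
  if (K >= 4L) {
    n_int <- K - 4L
    interior <- if (n_int > 0L)
      seq(1, D, length.out = n_int + 2L)[-c(1L, n_int + 2L)] else numeric(0)
    knots <- c(rep(1, 4L), interior, rep(D, 4L))
    Phi <- splines::splineDesign(knots, x, ord = 4L)
  } else if (D == 1L) {
    Phi <- matrix(1, 1L, 1L)
    knots <- NULL
  } else {
    # Bernstein basis of degree K-1 on [0, 1]
    tt <- (x - 1) / (D - 1)
    deg <- K - 1L
    Phi <- sapply(0:deg, function(k)
      choose(deg, k) * tt^k * (1 - tt)^(deg - k))
    Phi <- matrix(Phi, nrow = D)
    knots <- NULL
  }
  stopifnot(all(Phi >= -1e-12), max(abs(rowSums(Phi) - 1)) < 1e-10)
  Phi[Phi < 0] <- 0
  structure(list(Phi = Phi, K = K, D = D,
                 knots = if (K >= 4L) knots else NULL),
            class = "ss_basis")
}

#' @export
print.ss_basis <- function(x, ...) {
  cat(sprintf("Cubic spline basis: %d release events x %d df\n", x$D, x$K))
  invisible(x)
}
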