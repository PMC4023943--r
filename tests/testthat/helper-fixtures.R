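# Shared fixtures: all built in code, no stored data.

# two unit squares side by side: region 1 = [0,1]x[0,1], region 2 = [1,2]x[0,1]
two_squares <- function() {
  region_partition(list(
    cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)),
    cbind(c(1, 2, 2, 1), c(0, 0, 1, 1))))
}

# a schedule with a single release event and a long tracked span
one_release_schedule <- function(span = 30L) {
  release_schedule(window_start = 60L, window_length = 1L, step = 1L,
                   tracking_end = 60L + span)
}

# trajectory table for a single propagule following `pos` (matrix, cols
# lon/lat), day offsets 0..nrow-1
single_track <- function(pos, year = 2000L, source_id = 1L, site_id = 1L,
                         depth_level = 1L, release_index = 1L) {
  as_trajectories(data.frame(
    year = year, source_id = source_id, site_id = site_id,
    depth_level = depth_level, release_index = release_index,
    day_offset = seq_len(nrow(pos)) - 1L, lon = pos[, 1], lat = pos[, 2]))
}

# small random exposure tensor with controlled zero pattern
random_exposure <- function(J, D, I, TT, seed = 1, p_zero = 0) {
  set.seed(seed)
  G <- array(runif(J * D * I * TT, 0, 1 / I), dim = c(J, D, I, TT))
  if (p_zero > 0) {
    zero <- array(runif(J * I) < p_zero, dim = c(J, I))
    for (j in seq_len(J)) for (i in seq_len(I)) if (zero[j, i]) G[j, , i, ] <- 0
  }
  exposure_tensor(G)
}

# model mean computed from first principles (independent of
# precompute_design): mu[i,t] = sum_j sum_d u[j,i] * (Phi v)[d] * G[j,d,i,t]
oracle_mean <- function(u, v, G, Phi) {
  J <- dim(G)[1]; D <- dim(G)[2]; I <- dim(G)[3]; TT <- dim(G)[4]
  mu <- matrix(0, I, TT)
  for (j in seq_len(J)) {
    fj <- as.vector(Phi %*% v[j, ])
    for (i in seq_len(I)) for (t in seq_len(TT))
      mu[i, t] <- mu[i, t] + u[j, i] * sum(fj * G[j, , i, t])
  }
  mu
}

# full objective from first principles, on the standardized-coefficient
# scale the package documents (u_scale = RMS of each (j,i) design slice)
oracle_objective <- function(u, v, y, G, Phi, lambda, omega = NULL,
                             mask = NULL) {
  J <- dim(G)[1]; I <- dim(G)[3]
  K <- ncol(Phi)
  mu <- oracle_mean(u, v, G, Phi)
  rss <- sum((y - mu)^2, na.rm = TRUE)
  if (length(lambda) == 1) lambda <- rep(lambda, J)
  if (is.null(omega)) omega <- array(1, dim = c(J, I, K))
  pen <- 0
  if (any(lambda > 0)) {
    Z <- array(0, dim = c(J, K, I, dim(G)[4]))
    for (j in seq_len(J)) for (k in seq_len(K)) for (i in seq_len(I))
      Z[j, k, i, ] <- colSums(Phi[, k] * G[j, , i, ])
    s <- sqrt(apply(Z^2, c(1, 3), mean))
    s[s == 0] <- 1
    for (j in seq_len(J)) for (i in seq_len(I)) {
      if (!is.null(mask) && mask[j, i]) next
      pen <- pen + lambda[j] *
        sum(omega[j, i, ] * abs(u[j, i] * s[j, i] * v[j, ]))
    }
  }
  rss + pen
}

# small cached demo world (trajectories are expensive enough to share)
demo_world <- local({
  cache <- NULL
  function(years = 1:10, sigma = 0, seed = 1) {
    key <- paste(max(years), sigma, seed)
    if (is.null(cache[[key]])) {
      cfg <- demo_design(years = years, sigma = sigma, seed = seed)
      traj <- simulate_trajectories(cfg)
      part <- config_partition(cfg)
      expo <- compute_exposure(traj, part, cfg$schedule)
      Y <- simulate_abundance(expo, cfg)
      cache[[key]] <<- list(cfg = cfg, traj = traj, part = part,
                            expo = expo, Y = Y,
                            basis = build_basis(cfg$schedule$n_releases, 4))
    }
    cache[[key]]
  }
})
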