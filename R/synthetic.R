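# Synthetic drift world: a toy advection field with the study's release
# design, plus abundance generated from the source-sink model with known
# sparse parameters. Every stage of the pipeline is testable with no
# external ocean-model output.

#' Synthetic-scenario configuration
#'
#' @param bounds Domain rectangle `c(lon_min, lon_max, lat_min, lat_max)`.
#' @param grid List `(rows, cols, exclude)` describing the sink partition (a
#'   rows x cols grid of rectangles with `exclude` cells dropped).
#' @param sources List of J sources, each
#'   `list(center = c(lon, lat), n_sites, scatter)`; sites are drawn once
#'   around the center with isotropic Gaussian scatter (degrees).
#' @param n_depths Number of release depth levels (default 3; depths act as
#'   exchangeable ensemble replicates, as in the 20/30/40 m design).
#' @param schedule An [release_schedule()].
#' @param years Integer vector of simulated years.
#' @param velocity List `(drift = c(dlon, dlat), rot_amp, rw_sd, year_sd)`:
#'   mean daily drift vector (degrees/day), amplitude of a weak rotational
#'   component about the domain center (1/day), sd of the daily Gaussian
#'   random-walk step (degrees), and fractional sd of a yearly multiplier on
#'   the mean drift (interannual circulation contrast; default 0.2).
#' @param true List of true model parameters: `w` (length J, >= 0), `theta`
#'   (`J x I`, rows non-negative summing to 1) and either `f` (length D,
#'   or `J x D` matrix, each row a probability mass function) or `b`
#'   (non-negative spline coefficients, combined with `basis_K` to form f).
#' @param basis_K Spline df used when `true$b` is given.
#' @param sigma Error sd on the log(CPUE+1) scale.
#' @param seed Integer seed for site placement and trajectory noise.
#' @return Object of class `ss_config`.
#' @export
sim_config <- function(bounds, grid, sources, n_depths = 3L,
                       schedule = release_schedule(), years = 1:10,
                       velocity = list(drift = c(-0.08, 0.04),
                                       rot_amp = 0.002, rw_sd = 0.05,
                                       year_sd = 0.2),
                       true = NULL, basis_K = NULL, sigma = 0.15, seed = 1L) {
  J <- length(sources)
  if (!is.null(true)) {
    stopifnot(length(true$w) == J, all(true$w >= 0))
    th <- as.matrix(true$theta)
    stopifnot(nrow(th) == J, all(th >= 0),
              max(abs(rowSums(th) - 1)) < 1e-8)
    if (!is.null(true$f)) {
      fm <- if (is.matrix(true$f)) true$f else
        matrix(true$f, J, length(true$f), byrow = TRUE)
      stopifnot(all(fm >= 0), max(abs(rowSums(fm) - 1)) < 1e-8)
      true$f <- fm
    }
  }
  stopifnot(sigma >= 0)
  structure(list(bounds = bounds, grid = grid, sources = sources,
                 n_depths = as.integer(n_depths), schedule = schedule,
                 years = as.integer(years), velocity = velocity,
                 true = true, basis_K = basis_K, sigma = sigma,
                 seed = as.integer(seed)),
            class = "ss_config")
}

#' Sink partition implied by a configuration
#' @param config An `ss_config`.
#' @return An `ss_regions` partition.
#' @export
config_partition <- function(config) {
  grid_partition(config$grid$rows, config$grid$cols, config$bounds,
                 exclude = config$grid$exclude)
}

#' Release plan of a configuration
#'
#' Enumerates every (year, source, site, depth, release event) without
#' simulating positions; useful for design counts and as the simulation
#' skeleton.
#' @param config An `ss_config`.
#' @return data.table with columns `year, source_id, site_id, depth_level,
#'   release_index, release_doy`.
#' @export
release_plan <- function(config) {
  src <- data.table::rbindlist(lapply(seq_along(config$sources), function(j)
    data.table::data.table(source_id = j,
                           site_id = seq_len(config$sources[[j]]$n_sites))))
  plan <- data.table::CJ(year = config$years,
                         depth_level = seq_len(config$n_depths),
                         release_index = seq_len(config$schedule$n_releases),
                         srow = seq_len(nrow(src)))
  plan <- cbind(plan[, c("year", "depth_level", "release_index")],
                src[plan$srow])
  plan$release_doy <- config$schedule$release_doys[plan$release_index]
  data.table::setcolorder(plan, c("year", "source_id", "site_id",
                                  "depth_level", "release_index",
                                  "release_doy"))
  data.table::setorderv(plan, c("year", "source_id", "site_id", "depth_level",
                                "release_index"))
  plan[]
}

# site coordinates, drawn once per config (seeded); sites are fixed across
# years, as the polyp-bed locations are
.site_table <- function(config) {
  .with_seed(config$seed, {
    data.table::rbindlist(lapply(seq_along(config$sources), function(j) {
      s <- config$sources[[j]]
      data.table::data.table(
        source_id = j, site_id = seq_len(s$n_sites),
        site_lon = s$center[1L] + stats::rnorm(s$n_sites, 0, s$scatter),
        site_lat = s$center[2L] + stats::rnorm(s$n_sites, 0, s$scatter))
    }))
  })
}

#' Simulate propagule trajectories from the toy advection field
#'
#' Daily forward-Euler positions from each release date to the tracking end:
#' `x[s+1] = x[s] + drift + rot_amp * R90 (x[s] - center) + N(0, rw_sd^2)`,
#' where `R90` rotates by 90 degrees (a weak cyclonic component about the
#' domain center). One propagule per (year, site, depth, release event);
#' bit-reproducible given `config$seed`.
#'
#' @param config An `ss_config`.
#' @return An `ss_trajectories` table.
#' @export
simulate_trajectories <- function(config) {
  plan <- release_plan(config)
  plan <- merge(plan, .site_table(config), by = c("source_id", "site_id"),
                sort = FALSE)
  sch <- config$schedule
  ctr <- c(mean(config$bounds[1:2]), mean(config$bounds[3:4]))
  vel <- config$velocity
  n <- nrow(plan)
  out <- vector("list", length(config$years))
  seeds <- .child_seeds(config$seed + 1L, length(config$years))
  for (yi in seq_along(config$years)) {
    yr <- config$years[yi]
    py <- plan[plan$year == yr, ]
    m <- nrow(py)
    lon <- py$site_lon
    lat <- py$site_lat
    released <- rep(FALSE, m)
    rec <- vector("list", sch$tracking_end - sch$window_start + 1L)
    ri <- 0L
    ysd <- if (is.null(vel$year_sd)) 0 else vel$year_sd
    .with_seed(seeds[yi], {
      # independent zonal/meridional/rotational multipliers: interannual
      # variation in strength, direction and curvature of the mean flow, so
      # different sources see genuinely different dispersal years
      mult <- 1 + stats::rnorm(3L, 0, ysd)
      for (doy in sch$window_start:sch$tracking_end) {
        newly <- !released & py$release_doy == doy
        released <- released | newly
        act <- which(released)
        if (length(act)) {
          step_on <- which(released & py$release_doy < doy)
          if (length(step_on)) {
            dx <- lon[step_on] - ctr[1L]
            dy <- lat[step_on] - ctr[2L]
            lon[step_on] <- lon[step_on] + mult[1L] * vel$drift[1L] -
              mult[3L] * vel$rot_amp * dy +
              stats::rnorm(length(step_on), 0, vel$rw_sd)
            lat[step_on] <- lat[step_on] + mult[2L] * vel$drift[2L] +
              mult[3L] * vel$rot_amp * dx +
              stats::rnorm(length(step_on), 0, vel$rw_sd)
          }
          ri <- ri + 1L
          rec[[ri]] <- data.table::data.table(
            year = yr, source_id = py$source_id[act],
            site_id = py$site_id[act], depth_level = py$depth_level[act],
            release_index = py$release_index[act],
            day_offset = doy - py$release_doy[act],
            lon = lon[act], lat = lat[act])
        }
      }
    })
    out[[yi]] <- data.table::rbindlist(rec[seq_len(ri)])
  }
  as_trajectories(data.table::rbindlist(out))
}

#' True release-curve matrix of a configuration
#'
#' Resolves `config$true` into a `J x D` matrix of release-time probability
#' masses: either the stored `f`, or `Phi %*% b` normalised per source, or
#' the default smooth unimodal (discretised beta) curve shared by all
#' sources.
#' @param config An `ss_config`.
#' @return `J x D` matrix, rows summing to 1.
#' @export
true_release_curves <- function(config) {
  D <- config$schedule$n_releases
  J <- length(config$sources)
  tr <- config$true
  if (!is.null(tr$f)) return(tr$f)
  if (!is.null(tr$b)) {
    bb <- build_basis(D, config$basis_K)
    f <- t(apply(as.matrix(tr$b), 1L, function(b) {
      fr <- as.vector(bb$Phi %*% b)
      fr / sum(fr)
    }))
    return(f)
  }
  fr <- stats::dbeta((seq_len(D) - 0.5) / D, 2.5, 3.5)
  matrix(fr / sum(fr), J, D, byrow = TRUE)
}

#' Model mean implied by the true parameters
#' @param exposure An `ss_exposure`.
#' @param config An `ss_config` with `true` parameters.
#' @return `I x T` matrix of model means.
#' @export
true_mean <- function(exposure, config) {
  G <- exposure$G
  dg <- dim(G)
  J <- dg[1L]; D <- dg[2L]; I <- dg[3L]; TT <- dg[4L]
  tr <- config$true
  if (is.null(tr)) stop("config carries no true parameters")
  f <- true_release_curves(config)
  stopifnot(ncol(f) == D, nrow(as.matrix(tr$theta)) == J)
  mu <- matrix(0, I, TT)
  for (j in seq_len(J)) {
    fG <- apply(array(G[j, , , ], dim = c(D, I, TT)), c(2, 3),
                function(g) sum(f[j, ] * g))
    mu <- mu + tr$w[j] * as.matrix(tr$theta)[j, ] * fG
  }
  mu
}

#' Simulate an abundance matrix from the source-sink model
#'
#' `y[i,t] = sum_j w[j] theta[j,i] sum_d f[j,d] G[j,d,i,t] + eps[i,t]` with
#' `eps ~ iid N(0, sigma^2)`; no cells are masked.
#'
#' @param exposure An `ss_exposure`.
#' @param config An `ss_config` with `true` parameters.
#' @param seed Seed for the noise draws (default `config$seed + 1000`).
#' @return An `ss_abundance`.
#' @export
simulate_abundance <- function(exposure, config, seed = NULL) {
  mu <- true_mean(exposure, config)
  if (is.null(seed)) seed <- config$seed + 1000L
  eps <- .with_seed(seed, matrix(stats::rnorm(length(mu), 0, config$sigma),
                                 nrow(mu)))
  y <- mu + eps
  colnames(y) <- exposure$years
  abundance_matrix(y, years = exposure$years)
}
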