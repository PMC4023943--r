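# Exposure covariates G[j, d, i, t]: mean fraction of tracked time a
# propagule from source j, released at event d of year t, spent inside sink
# region i before the tracking end date.

#' Assign points to sink regions
#'
#' Returns, for each point, the id of the first region (in increasing
#' `region_id` order) whose polygon contains it, boundary inclusive; `NA` for
#' points outside all regions. On a shared boundary the lowest id wins
#' (deterministic, documented tie-break).
#'
#' @param lon,lat Numeric vectors of coordinates (degrees).
#' @param partition An `ss_regions` partition.
#' @return Integer vector of region ids, `NA` where unassigned.
#' @export
assign_region <- function(lon, lat, partition) {
  stopifnot(inherits(partition, "ss_regions"))
  out <- rep(NA_integer_, length(lon))
  todo <- rep(TRUE, length(lon))
  for (i in partition$region_ids) {
    if (!any(todo)) break
    hit <- .point_in_ring(lon[todo], lat[todo], partition$rings[[i]],
                          boundary = TRUE)
    idx <- which(todo)[hit]
    out[idx] <- i
    todo[idx] <- FALSE
  }
  out
}

#' Construct an exposure tensor
#' @param G 4-d array `[source j, release d, region i, year t]`, entries in
#'   \[0, 1\] with `sum_i G[j,d,i,t] <= 1`.
#' @param years Year labels for the 4th axis.
#' @param coverage Optional integer array `[J, D, T]` of propagule counts per
#'   ensemble cell (0 means the cell had no propagules and G is 0 there).
#' @return Object of class `ss_exposure`.
#' @export
exposure_tensor <- function(G, years = NULL, coverage = NULL) {
  stopifnot(length(dim(G)) == 4L)
  if (any(G < -1e-12) || any(G > 1 + 1e-12))
    stop("exposure entries must lie in [0, 1]")
  sums <- apply(G, c(1, 2, 4), sum)
  if (any(sums > 1 + 1e-8))
    stop("sum over regions of G[j,d,,t] exceeds 1")
  if (is.null(years)) years <- seq_len(dim(G)[4L])
  structure(list(G = G, years = as.integer(years), coverage = coverage),
            class = "ss_exposure")
}

#' @export
print.ss_exposure <- function(x, ...) {
  d <- dim(x$G)
  cat(sprintf("Exposure tensor: %d sources x %d releases x %d regions x %d years\n",
              d[1L], d[2L], d[3L], d[4L]))
  invisible(x)
}

#' Compute exposure covariates from trajectories
#'
#' For each propagule, the occupancy fraction in region `i` is the number of
#' recorded daily positions falling in `i`, from day offset 0 through the
#' offset corresponding to the tracking end date, divided by the number of
#' recorded positions in that span. `G[j,d,i,t]` is the mean of these
#' fractions over all propagules sharing (source, release, year) — i.e. over
#' sites and depth levels. Ensemble cells with no propagules get 0 and are
#' visible in the coverage array.
#'
#' @param traj An `ss_trajectories` table.
#' @param partition An `ss_regions` partition.
#' @param schedule An `ss_schedule`.
#' @param years Optional year axis (defaults to years present, sorted).
#' @param n_sources,n_releases Optional axis sizes (default from data /
#'   schedule).
#' @return An `ss_exposure` object.
#' @export
compute_exposure <- function(traj, partition, schedule, years = NULL,
                             n_sources = NULL, n_releases = NULL) {
  stopifnot(inherits(traj, "ss_trajectories"), inherits(schedule, "ss_schedule"))
  if (nrow(traj) == 0L) stop("empty trajectory table")
  year <- source_id <- release_index <- day_offset <- NULL # NSE
  if (is.null(years)) years <- sort(unique(traj$year))
  J <- if (is.null(n_sources)) max(traj$source_id) else n_sources
  D <- if (is.null(n_releases)) schedule$n_releases else n_releases
  I <- n_regions(partition)
  TT <- length(years)

  dt <- traj[year %in% years]
  # keep positions inside the tracked span of each release event
  dt <- dt[day_offset <= max_offset(schedule, release_index)]
  if (nrow(dt) == 0L)
    stop("no positions remain before tracking_end; check the schedule")
  rid <- assign_region(dt$lon, dt$lat, partition)

  region <- npos <- nd <- f <- ok <- NULL # NSE
  g <- data.table::data.table(
    j = dt$source_id, d = dt$release_index,
    t = match(dt$year, years),
    site = dt$site_id, depth = dt$depth_level,
    region = rid)
  # per-propagule fraction of recorded days in each region
  ndays <- g[, list(nd = .N), by = c("j", "d", "t", "site", "depth")]
  frac <- g[!is.na(region),
            list(npos = .N), by = c("j", "d", "t", "site", "depth", "region")]
  frac <- merge(frac, ndays, by = c("j", "d", "t", "site", "depth"))
  frac[, f := npos / nd]
  npart <- ndays[, list(n = .N), by = c("j", "d", "t")]
  # ensemble mean over propagules (sites x depths); propagules with zero days
  # in region i contribute 0, so divide the sum of fractions by the full count
  cellsum <- frac[, list(fsum = sum(f)), by = c("j", "d", "t", "region")]
  cellsum <- merge(cellsum, npart, by = c("j", "d", "t"))

  G <- array(0, dim = c(J, D, I, TT))
  if (nrow(cellsum))
    G[cbind(cellsum$j, cellsum$d, cellsum$region, cellsum$t)] <-
      cellsum$fsum / cellsum$n
  coverage <- array(0L, dim = c(J, D, TT))
  coverage[cbind(npart$j, npart$d, npart$t)] <- npart$n
  exposure_tensor(G, years = years, coverage = coverage)
}

#' Shift trajectories forward along their own tracks
#'
#' Emulates a systematic underestimation of current speed of `100 * a` percent:
#' the position at day offset `s` is replaced by the recorded position at
#' offset `(1 + a) * s`, linearly interpolated in lon and lat between the two
#' bracketing integer offsets when `(1 + a) * s` is not an integer. Beyond the
#' last recorded offset the last recorded position is used (truncation). The
#' output keeps the original day-offset grid.
#'
#' @param traj An `ss_trajectories` table.
#' @param a Shift rate in `[0, 0.5]`; `a = 0` is the identity.
#' @return A shifted `ss_trajectories` table.
#' @export
shift_trajectories <- function(traj, a) {
  stopifnot(inherits(traj, "ss_trajectories"))
  if (!is.numeric(a) || length(a) != 1L || a < 0)
    stop("shift rate a must be a single number >= 0")
  if (a > 0.5) stop("shift rate a must be <= 0.5")
  if (a == 0) return(data.table::copy(traj))
  day_offset <- lon <- lat <- NULL # NSE
  out <- data.table::copy(traj)
  out[, c("lon", "lat") := {
    # rows within a propagule are sorted by day_offset = 0..S
    target <- (1 + a) * day_offset
    S <- length(day_offset) - 1L
    lo <- pmin(floor(target), S)
    hi <- pmin(lo + 1, S)
    wt <- target - lo
    wt[lo == S] <- 0
    list(lon[lo + 1L] * (1 - wt) + lon[hi + 1L] * wt,
         lat[lo + 1L] * (1 - wt) + lat[hi + 1L] * wt)
  }, by = c("year", "source_id", "site_id", "depth_level", "release_index")]
  out[]
}

#' Randomly perturb an exposure tensor
#'
#' Each entry independently becomes `g * (1 + frac)` or `g * (1 - frac)` with
#' probability 1/2, emulating random drift-model error. The scheme is
#' multiplicative, so zeros stay exactly zero and no entry can become
#' negative; an entry equal to 1 may marginally exceed 1.
#'
#' @param exposure An `ss_exposure` object.
#' @param frac Perturbation fraction in `[0, 1)`; default 0.05.
#' @param seed Integer seed driving the sign draws.
#' @return A perturbed `ss_exposure` object.
#' @export
perturb_exposure <- function(exposure, frac = 0.05, seed = 1L) {
  stopifnot(inherits(exposure, "ss_exposure"))
  if (frac < 0 || frac >= 1) stop("frac must be in [0, 1)")
  G <- exposure$G
  signs <- .with_seed(seed, array(sample(c(-1, 1), length(G), replace = TRUE),
                                  dim = dim(G)))
  out <- exposure
  out$G <- G * (1 + frac * signs)
  out
}

#' Write an exposure tensor to long-format CSV
#'
#' Columns `j, d, i, year, g`; zero entries are omitted.
#' @param exposure An `ss_exposure` object.
#' @param path Output CSV path.
#' @param dims Whether to prepend a `#dims J D I T` comment line (always on;
#'   argument kept for clarity).
#' @return `path`, invisibly.
#' @export
write_exposure <- function(exposure, path, dims = TRUE) {
  stopifnot(inherits(exposure, "ss_exposure"))
  G <- exposure$G
  idx <- which(G != 0, arr.ind = TRUE)
  dt <- data.table::data.table(
    j = idx[, 1L], d = idx[, 2L], i = idx[, 3L],
    year = exposure$years[idx[, 4L]], g = G[idx])
  data.table::setorderv(dt, c("j", "d", "i", "year"))
  con <- file(path, "w")
  writeLines(c(sprintf("#dims %d %d %d %d", dim(G)[1L], dim(G)[2L],
                       dim(G)[3L], dim(G)[4L]),
               paste("#years", paste(exposure$years, collapse = " "))), con)
  close(con)
  data.table::fwrite(dt, path, append = TRUE, col.names = TRUE)
  invisible(path)
}

#' Read an exposure tensor written by [write_exposure()]
#' @param path CSV path.
#' @return An `ss_exposure` object.
#' @export
read_exposure <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  hdr <- readLines(path, n = 2L)
  if (!startsWith(hdr[1L], "#dims")) stop("missing #dims header in ", path)
  dims <- as.integer(strsplit(trimws(sub("#dims", "", hdr[1L])), "\\s+")[[1L]])
  years <- as.integer(strsplit(trimws(sub("#years", "", hdr[2L])), "\\s+")[[1L]])
  dt <- data.table::fread(path, skip = 2L)
  G <- array(0, dim = dims)
  G[cbind(dt$j, dt$d, dt$i, match(dt$year, years))] <- dt$g
  exposure_tensor(G, years = years)
}
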