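# Trajectory tables: per-propagule daily positions from a drift simulation.
# A propagule is identified by (year, source_id, site_id, depth_level,
# release_index); its positions are recorded at contiguous day offsets
# 0, 1, ..., S since release.

.TRAJ_COLS <- c("year", "source_id", "site_id", "depth_level",
                "release_index", "day_offset", "lon", "lat")
.TRAJ_KEY <- .TRAJ_COLS[1:5]

#' Construct and validate a trajectory table
#'
#' @param x A data.frame/data.table with columns `year`, `source_id`,
#'   `site_id`, `depth_level`, `release_index`, `day_offset`, `lon`, `lat`.
#' @return A `data.table` of class `ss_trajectories`, sorted by propagule key
#'   and day offset.
#' @details Day offsets of each propagule must form a contiguous run
#'   `0, 1, ..., S`; a gap or duplicate offset is a validation error.
#' @export
as_trajectories <- function(x) {
  missing_cols <- setdiff(.TRAJ_COLS, names(x))
  if (length(missing_cols))
    stop("trajectory table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  dt <- data.table::as.data.table(x)[, .TRAJ_COLS, with = FALSE]
  for (cl in .TRAJ_COLS[1:6]) data.table::set(dt, j = cl, value = as.integer(dt[[cl]]))
  data.table::setkeyv(dt, c(.TRAJ_KEY, "day_offset"))
  .check_contiguity(dt)
  data.table::setattr(dt, "class", c("ss_trajectories", class(dt)))
  dt[]
}

.check_contiguity <- function(dt) {
  day_offset <- NULL # NSE
  bad <- dt[, {
    s <- day_offset
    list(ok = length(s) == max(s) + 1L && !anyDuplicated(s) && min(s) == 0L)
  }, by = .TRAJ_KEY][ok == FALSE]
  if (nrow(bad)) {
    k <- bad[1L]
    stop(sprintf(
      "day offsets not contiguous from 0 for propagule (year=%d, source=%d, site=%d, depth=%d, release=%d)",
      k$year, k$source_id, k$site_id, k$depth_level, k$release_index))
  }
  invisible(TRUE)
}

#' Read a trajectory table from CSV
#'
#' @param path Path to a CSV file with the eight trajectory columns.
#' @return An `ss_trajectories` table.
#' @seealso [write_trajectories()]
#' @export
read_trajectories <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  as_trajectories(data.table::fread(path))
}

#' Write a trajectory table to CSV
#' @param traj An `ss_trajectories` table.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(traj, path) {
  stopifnot(inherits(traj, "ss_trajectories"))
  data.table::fwrite(data.table::as.data.table(unclass(traj))[, .TRAJ_COLS, with = FALSE], path)
  invisible(path)
}

#' Number of distinct propagules in a trajectory table
#' @param traj An `ss_trajectories` table.
#' @return Integer count of distinct (year, source, site, depth, release) keys.
#' @export
n_propagules <- function(traj) {
  nrow(unique(traj, by = .TRAJ_KEY))
}
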