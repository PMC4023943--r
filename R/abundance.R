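# Region x year abundance on the log(CPUE + 1) scale.

#' Construct an abundance matrix
#'
#' @param y Numeric matrix, regions x years, on the transformed
#'   `log(CPUE + 1)` scale; `NA` where no observation exists.
#' @param n_obs Integer matrix of station counts per cell (same shape);
#'   defaults to 1 where `y` is finite, 0 where `NA`.
#' @param years Year labels (defaults to column names or `1..T`).
#' @return Object of class `ss_abundance`: list with `y`, `n_obs`,
#'   `mask` (`TRUE` where a cell has no data), `years` and a `transformed`
#'   flag recording that the log(x+1) transform has been applied.
#' @export
abundance_matrix <- function(y, n_obs = NULL, years = NULL) {
  y <- as.matrix(y)
  if (is.null(n_obs)) n_obs <- matrix(ifelse(is.finite(y), 1L, 0L), nrow(y))
  n_obs <- as.matrix(n_obs)
  stopifnot(identical(dim(y), dim(n_obs)))
  mask <- n_obs == 0L
  if (any(!mask & !is.finite(y)))
    stop("y must be finite wherever n_obs > 0")
  y[mask] <- NA_real_
  if (is.null(years)) {
    years <- colnames(y)
    years <- if (is.null(years)) seq_len(ncol(y)) else as.integer(years)
  }
  structure(list(y = y, n_obs = n_obs, mask = mask,
                 years = as.integer(years), transformed = TRUE),
            class = "ss_abundance")
}

#' @export
print.ss_abundance <- function(x, ...) {
  cat(sprintf("Abundance matrix: %d regions x %d years (%d missing cells)\n",
              nrow(x$y), ncol(x$y), sum(x$mask)))
  invisible(x)
}

#' Aggregate station CPUE records to a region x year abundance matrix
#'
#' Each station record is assigned to the sink region containing it; the cell
#' value is the arithmetic mean over its stations of `log(cpue + 1)`
#' (variance-stabilising transform applied per station, before averaging).
#' Cells with no stations are masked. Stations falling outside every region
#' are excluded and counted.
#'
#' @param stations data.frame with columns `year`, `lon`, `lat`, `cpue`
#'   (non-negative, kg/ha).
#' @param partition An `ss_regions` partition.
#' @param years Optional integer vector fixing the year axis (defaults to the
#'   sorted unique years present).
#' @return An `ss_abundance` object; the number of excluded stations is
#'   attached as attribute `n_outside`.
#' @export
aggregate_abundance <- function(stations, partition, years = NULL) {
  stations <- as.data.frame(stations)
  need <- c("year", "lon", "lat", "cpue")
  miss <- setdiff(need, names(stations))
  if (length(miss)) stop("stations table is missing column(s): ",
                         paste(miss, collapse = ", "))
  if (any(stations$cpue < 0)) stop("cpue values must be non-negative")
  if (is.null(years)) years <- sort(unique(as.integer(stations$year)))
  I <- n_regions(partition)
  TT <- length(years)
  rid <- assign_region(stations$lon, stations$lat, partition)
  outside <- is.na(rid)
  if (any(outside))
    message(sum(outside), " station(s) outside all regions; excluded")
  keep <- !outside & stations$year %in% years
  val <- log(stations$cpue[keep] + 1)
  ri <- rid[keep]
  ti <- match(as.integer(stations$year)[keep], years)
  ysum <- matrix(0, I, TT)
  nobs <- matrix(0L, I, TT)
  for (s in seq_along(val)) {
    ysum[ri[s], ti[s]] <- ysum[ri[s], ti[s]] + val[s]
    nobs[ri[s], ti[s]] <- nobs[ri[s], ti[s]] + 1L
  }
  y <- ifelse(nobs > 0L, ysum / pmax(nobs, 1L), NA_real_)
  colnames(y) <- years
  out <- abundance_matrix(y, nobs, years)
  attr(out, "n_outside") <- sum(outside)
  out
}

#' Write an abundance matrix to CSV
#'
#' Region rows, year columns; masked cells are written empty.
#' @param ab An `ss_abundance` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_abundance <- function(ab, path) {
  stopifnot(inherits(ab, "ss_abundance"))
  df <- data.frame(region = seq_len(nrow(ab$y)), ab$y, check.names = FALSE)
  names(df) <- c("region", ab$years)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read an abundance matrix written by [write_abundance()]
#' @param path CSV path.
#' @return An `ss_abundance` object.
#' @export
read_abundance <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  years <- as.integer(names(df)[-1L])
  y <- as.matrix(df[, -1L, drop = FALSE])
  colnames(y) <- years
  abundance_matrix(y, years = years)
}
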