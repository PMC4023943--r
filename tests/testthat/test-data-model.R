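# Containers and readers: schedules, trajectory tables, region partitions,
# abundance aggregation.

test_that("release schedule reproduces the study design and validates dates", {
  sch <- release_schedule()
  expect_equal(sch$n_releases, 40L)
  expect_equal(sch$window_start, 74L)          # March 15
  expect_equal(sch$tracking_end, 273L)         # September 30
  expect_equal(diff(sch$release_doys), rep(2L, 39L))
  expect_equal(max_offset(sch, 1L), 199L)
  expect_equal(max_offset(sch, 40L), 199L - 78L)
  expect_error(release_schedule(window_start = "03-15", window_length = 80,
                                step = 2, tracking_end = "03-20"),
               "tracking_end")
  expect_error(release_schedule(step = 0), "step")
  expect_error(.doy <- sourcesink:::.doy("13-01"), "MM-DD")
})

test_that("trajectory tables validate shape, keys and contiguity", {
  df <- data.frame(year = 2000L, source_id = 1L, site_id = 1L,
                   depth_level = 1L, release_index = 1L,
                   day_offset = 0:1, lon = c(0, 0.1), lat = c(0, 0.2))
  tr <- as_trajectories(df)
  expect_s3_class(tr, "ss_trajectories")
  expect_equal(n_propagules(tr), 1L)
  expect_equal(max(tr$day_offset), 1L)

  gap <- df; gap$day_offset <- c(0L, 2L)
  expect_error(as_trajectories(gap), "contiguous")
  expect_error(as_trajectories(df[, -8]), "lat")
})

test_that("trajectory CSV round trip is exact", {
  w <- demo_world(years = 1:2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(w$traj, path)
  back <- read_trajectories(path)
  expect_equal(as.data.frame(back), as.data.frame(w$traj))
})

test_that("region partitions validate ids and geometry", {
  p <- two_squares()
  expect_equal(n_regions(p), 2L)
  # closure enforced
  expect_equal(p$rings[[1]][1, ], p$rings[[1]][nrow(p$rings[[1]]), ])
  expect_error(region_partition(list(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))),
                                region_ids = 2L), "consecutive")
  bowtie <- cbind(c(0, 1, 0, 1), c(0, 1, 1, 0))
  expect_error(region_partition(list(bowtie)), "self-intersecting")
  big <- cbind(c(0, 3, 3, 0), c(0, 0, 3, 3))
  inner <- cbind(c(1, 2, 2, 1), c(1, 1, 2, 2))
  expect_warning(region_partition(list(big, inner)), "overlap")
})

test_that("an 8-sink partition arises from a 3x3 grid minus one cell", {
  p <- grid_partition(3, 3, c(0, 3, 0, 3), exclude = 9L)
  expect_equal(n_regions(p), 8L)
})

test_that("GeoJSON round trip preserves the partition; bad files error", {
  p <- grid_partition(2, 2, c(-5, -1, 50, 54))
  path <- withr::local_tempfile(fileext = ".geojson")
  write_regions(p, path)
  back <- read_regions(path)
  expect_equal(back$region_ids, p$region_ids)
  expect_equal(back$rings, p$rings)

  gj <- jsonlite::read_json(path)
  gj$features[[2]]$properties$region_id <- 1L
  bad <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, bad, auto_unbox = TRUE, digits = NA)
  expect_error(read_regions(bad), "duplicate")
  gj2 <- jsonlite::read_json(path)
  gj2$features[[1]]$geometry$type <- "Point"
  bad2 <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj2, bad2, auto_unbox = TRUE, digits = NA)
  expect_error(read_regions(bad2), "non-polygon")
})

test_that("aggregate_abundance applies log(x+1) per station, means, masks", {
  p <- two_squares()
  st <- data.frame(year = c(2000, 2000, 2000, 2001),
                   lon = c(0.5, 0.5, 1.5, 0.5),
                   lat = c(0.5, 0.6, 0.5, 0.5),
                   cpue = c(exp(1) - 1, exp(2) - 1, 0, 3))
  ab <- aggregate_abundance(st, p)
  expect_equal(unname(ab$y[1, "2000"]), 1.5)  # mean(log(e), log(e^2))
  expect_equal(unname(ab$y[2, "2000"]), 0)    # log(0 + 1)
  expect_true(ab$mask[2, 2])                  # region 2 unobserved in 2001
  expect_equal(ab$n_obs[1, 1], 2L)

  # permutation invariance in station order
  ab2 <- aggregate_abundance(st[sample(4), ], p)
  expect_equal(ab2$y, ab$y)

  outside <- rbind(st, data.frame(year = 2000, lon = 9, lat = 9, cpue = 1))
  expect_message(ab3 <- aggregate_abundance(outside, p), "outside")
  expect_equal(attr(ab3, "n_outside"), 1L)
  expect_equal(ab3$y, ab$y)
  expect_error(aggregate_abundance(transform(st, cpue = -1), p),
               "non-negative")
})

test_that("abundance CSV round trip keeps values, years and mask", {
  y <- matrix(c(0.5, NA, 1.2, 0.3), 2, 2)
  ab <- abundance_matrix(y, years = c(1995L, 1996L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_abundance(ab, path)
  back <- read_abundance(path)
  expect_equal(back$years, ab$years)
  expect_equal(back$y, ab$y, ignore_attr = TRUE)
  expect_equal(back$mask, ab$mask, ignore_attr = TRUE)
})
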