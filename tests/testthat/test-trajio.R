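test_that("TrackMate CSV parsing handles units, multiple tracks and gaps", {
  f <- withr::local_tempfile(fileext = ".csv")
  rows <- expand.grid(FRAME = 0:4, TRACK_ID = c(1, 2))
  rows$POSITION_X <- seq_len(nrow(rows)) * 10   # px
  rows$POSITION_Y <- rev(seq_len(nrow(rows))) * 10
  write.csv(rows[, c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")],
            f, row.names = FALSE)

  ts <- read_trackmate_csv(f, dt_s = 1 / 30)
  expect_equal(n_tracks(ts), 2)
  expect_equal(unname(track_lengths(ts)), c(5L, 5L))

  ts_px <- read_trackmate_csv(f, dt_s = 1 / 30, units = "px",
                              pixel_size_um = 0.072)
  expect_equal(ts_px$tracks$x, ts$tracks$x * 0.072)
  expect_equal(ts_px$tracks$y, ts$tracks$y * 0.072)

  # a gap in a track's frames is a data error naming the track
  bad <- rows
  bad$FRAME[bad$TRACK_ID == 2] <- c(3, 5, 6, 7, 8)
  write.csv(bad[, c("TRACK_ID", "FRAME", "POSITION_X", "POSITION_Y")],
            f, row.names = FALSE)
  expect_error(read_trackmate_csv(f, dt_s = 1 / 30), "track '2'")

  # missing columns are a format error
  write.csv(rows[, c("TRACK_ID", "FRAME", "POSITION_X")], f, row.names = FALSE)
  expect_error(read_trackmate_csv(f, dt_s = 1 / 30), "POSITION_Y")
})

test_that("duration filtering keeps tracks at or above the threshold", {
  tab <- do.call(rbind, lapply(seq_along(c(2, 3, 10)), function(i) {
    L <- c(2, 3, 10)[i]
    data.frame(track_id = paste0("t", i), frame = seq_len(L),
               x = cumsum(runif(L)), y = 0)
  }))
  ts <- traj_set(tab, dt = 1 / 30)
  expect_equal(sort(unname(track_lengths(
    suppressMessages(filter_min_duration(ts, 3))))), c(3L, 10L))
  expect_equal(filter_min_duration(ts, 2)$tracks, ts$tracks)
  empty <- suppressMessages(filter_min_duration(ts, 11))
  expect_equal(nrow(empty$tracks), 0L)
})

test_that("displacement extraction is Euclidean, pooled and count-conserving", {
  tab <- data.frame(track_id = "a", frame = 1:2, x = c(0, 3), y = c(0, 4))
  ts <- traj_set(tab, dt = 0.1)
  expect_equal(displacements(ts)$steps$dr, 5)

  k <- 7
  ts0 <- traj_set(data.frame(track_id = "s", frame = 1:k, x = 2, y = -1),
                  dt = 0.1)
  expect_equal(displacements(ts0)$steps$dr, rep(0, k - 1))

  tab2 <- rbind(
    data.frame(track_id = "a", frame = 1:4, x = rnorm(4), y = rnorm(4)),
    data.frame(track_id = "b", frame = 1:6, x = rnorm(6), y = rnorm(6))
  )
  ts2 <- traj_set(tab2, dt = 0.1)
  ds <- displacements(ts2)
  expect_equal(nrow(ds$steps), 8L)
  expect_equal(nrow(ds$steps), sum(track_lengths(ts2) - 1L))
})

test_that("internal trajectory format round-trips losslessly", {
  gen <- control_hmm()
  ts <- simulate_hmm_trajectories(gen, n = 150, len = 20,
                                  eps_um = control_eps(), seed = 42)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trajectories(ts, f)
  back <- read_trajectories(f)
  expect_identical(back$tracks$track_id, ts$tracks$track_id)
  expect_equal(back$tracks$x, ts$tracks$x, tolerance = 0)
  expect_equal(back$tracks$y, ts$tracks$y, tolerance = 0)
  expect_equal(back$dt, ts$dt)
  expect_equal(back$provenance, ts$provenance)
})

test_that("pixel-size conversion is a pure scale on displacements", {
  f <- withr::local_tempfile(fileext = ".csv")
  rows <- data.frame(TRACK_ID = 1, FRAME = 0:9,
                     POSITION_X = cumsum(rnorm(10)),
                     POSITION_Y = cumsum(rnorm(10)))
  write.csv(rows, f, row.names = FALSE)
  d1 <- displacements(read_trackmate_csv(f, 1 / 30, units = "px",
                                         pixel_size_um = 0.072))$steps$dr
  d2 <- displacements(read_trackmate_csv(f, 1 / 30, units = "px",
                                         pixel_size_um = 0.144))$steps$dr
  expect_equal(d2, 2 * d1)
})
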