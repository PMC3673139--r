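write_csv_lines <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("recordings parse from CSV with and without a header", {
  rows <- c("0.00,0.01,-0.02,0.98", "0.04,0.02,0.00,1.01",
            "0.08,0.03,0.01,0.99", "0.12,0.01,-0.01,1.00")
  p1 <- write_csv_lines(rows)
  rec <- read_recording(p1, 25)
  expect_s3_class(rec, "accel_recording")
  expect_equal(nrow(rec), 4L)
  expect_equal(attr(rec, "sampling_rate"), 25)
  expect_equal(rec$az, c(0.98, 1.01, 0.99, 1.00))

  p2 <- write_csv_lines(c("t,ax,ay,az", rows))
  expect_equal(as.data.frame(read_recording(p2, 25)), as.data.frame(rec))
})

test_that("malformed recordings are rejected with useful errors", {
  expect_error(read_recording(tempfile(), 25), "not found")
  p_short <- write_csv_lines("0.0,0,0,1")
  expect_error(read_recording(p_short, 25), "fewer than 2")
  p_dup <- write_csv_lines(c("0.00,0,0,1", "0.04,0,0,1", "0.04,0,0,1"))
  expect_error(read_recording(p_dup, 25), "row 3")
  p_junk <- write_csv_lines(c("0.00,0,0,1", "0.04,oops,0,1", "0.08,0,0,1",
                              "0.12,0,0,1", "0.16,0,0,1"))
  expect_warning(rec <- read_recording(p_junk, 25), "non-numeric")
  expect_equal(nrow(rec), 4L)
  # rate inconsistent with timestamps
  p_ok <- write_csv_lines(c("0.0,0,0,1", "1.0,0,0,1", "2.0,0,0,1"))
  expect_error(read_recording(p_ok, 25), "inconsistent with sampling_rate")
})

test_that("write/read round trip preserves samples to the stated precision", {
  log <- simulate_log("A3", seed = 21)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording(log$recording, path, digits = 6)
  back <- read_recording(path, device_profile("htc_desire"))
  expect_equal(back$ax, log$recording$ax, tolerance = 1e-6)
  expect_equal(back$t, log$recording$t, tolerance = 1e-6)
})

test_that("windows are centred with the documented sample arithmetic", {
  log25 <- simulate_log("A2", device_profile("htc_desire"), seed = 1)
  expect_equal(segment_window(log25, 3)$n, 75L)   # 3 s at 25 Hz
  expect_equal(segment_window(log25, 9)$n, 225L)  # the full log
  log16 <- simulate_log("A2", device_profile("nexus_one"), seed = 1)
  expect_equal(segment_window(log16, 5)$n, 80L)   # round(5 * 16)
  # full-length window is the identity
  w9 <- segment_window(log25, 9)
  expect_equal(w9$x, log25$recording$ax)
  expect_equal(w9$label, "A2")
})

test_that("shorter windows are contiguous centred subsets of longer ones", {
  log <- simulate_log("A4", seed = 3)
  w_all <- segment_window(log, 9)
  for (len in c(1, 2.5, 3, 5, 7)) {
    w <- segment_window(log, len)
    # both windows share the centre sample, so the offset is the difference
    # of the floor(N/2) half-widths
    start <- w_all$n %/% 2L - w$n %/% 2L + 1L
    expect_equal(w_all$x[start:(start + w$n - 1)], w$x,
                 label = sprintf("window of %g s nested", len))
    expect_equal(w_all$z[start:(start + w$n - 1)], w$z)
  }
})

test_that("window length outside the log span is a range error", {
  log <- simulate_log("A1", seed = 4)
  expect_error(segment_window(log, 9.5), "must be in")
  expect_error(segment_window(log, 0), "must be in")
  # off-centre annotation can make even a fitting length fall outside
  log_edge <- activity_log(log$recording, "A1", activity_center = 0.5)
  expect_error(segment_window(log_edge, 5), "does not fit")
})

test_that("activity logs validate span, label and centre", {
  log <- simulate_log("A5", seed = 6)
  expect_error(activity_log(log$recording, "A8"), "A1..A7")
  expect_error(activity_log(log$recording, "A1", activity_center = 10),
               "outside")
  short <- accel_recording((0:49) / 25, rnorm(50), rnorm(50), rnorm(50),
                           sampling_rate = 25)
  expect_error(activity_log(short, "A1"), "9 seconds")
})

test_that("log collections round trip through the CSV sidecar format", {
  logs <- simulate_dataset(n_per_activity = 2, seed = 9)
  dir <- withr::local_tempdir()
  write_activity_logs(logs, dir)
  back <- read_activity_logs(dir)
  expect_length(back, length(logs))
  expect_equal(vapply(back, function(l) l$label, ""),
               vapply(logs, function(l) l$label, ""))
  expect_equal(back[[5]]$recording$az, logs[[5]]$recording$az,
               tolerance = 1e-6)
  # windows dataset export
  ws <- lapply(logs[seq(2, 14, by = 2)], segment_window, length = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_windows(ws, path)
  flat <- utils::read.csv(path, check.names = FALSE)
  expect_equal(nrow(flat), 7L)
  expect_equal(flat$label, vapply(ws, function(w) w$label, ""))
})
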