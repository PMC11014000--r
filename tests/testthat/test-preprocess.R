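write_fixture <- function(lines, ext = ".csv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_recording parses a delimited fixture against its schema", {
  path <- write_fixture(c(
    "t,x,y,z,label",
    "0.00,0.1,9.8,0.2,walking",
    "0.02,0.2,9.7,0.1,walking",
    "0.04,0.1,9.9,0.3,walking"
  ))
  schema <- recording_schema(sampling_rate = 50, units = "m_per_s2")
  rec <- read_recording(path, schema, subject_id = "S01")
  expect_s3_class(rec, "sensor_recording")
  expect_identical(nrow(rec$samples), 3L)
  expect_identical(unique(rec$labels), "walking")
  expect_identical(rec$subject_id, "S01")
  expect_equal(unname(rec$samples[2, "y"]), 9.7)
})

test_that("schema mismatches and empty files raise errors; bad rows are dropped", {
  path <- write_fixture(c("t,x,y,z", "0,1,2,3"))
  expect_error(read_recording(path, recording_schema()), "label")

  header_only <- write_fixture("t,x,y,z,label")
  expect_error(
    suppressWarnings(read_recording(header_only, recording_schema())),
    "empty|no parseable"
  )

  with_bad <- write_fixture(c(
    "t,x,y,z,label",
    "0.00,0.1,9.8,0.2,walking",
    "0.02,oops,9.7,0.1,walking",
    "0.04,0.1,9.9,0.3,walking"
  ))
  expect_warning(rec <- read_recording(with_bad, recording_schema()),
                 "dropped 1")
  expect_identical(nrow(rec$samples), 2L)
})

test_that("dataset schema presets exist for the eight public layouts", {
  presets <- c("wisdm", "harsense", "harth", "har70plus", "mhealth",
               "pamap2", "realdisp", "daliac")
  for (p in presets) {
    expect_s3_class(dataset_schema(p), "recording_schema")
  }
  expect_identical(dataset_schema("wisdm")$sampling_rate, 20)
  expect_identical(dataset_schema("daliac")$units, "g")
  expect_error(dataset_schema("nosuch"), "unknown dataset")
})

test_that("resampling honours the length contract and is identity at the native rate", {
  set.seed(81)
  rec <- sensor_recording(matrix(rnorm(3000), ncol = 3),
                         labels = rep("walking", 1000),
                         sampling_rate = 100)
  same <- resample_recording(rec, 100)
  expect_identical(same$samples, rec$samples)

  half <- resample_recording(rec, 50)
  expect_identical(half$sampling_rate, 50)
  expect_lte(abs(nrow(half$samples) - 500L), 1L)
  expect_identical(length(half$labels), nrow(half$samples))
  expect_warning(resample_recording(rec, 200), "upsampling")
})

test_that("a pure tone survives resampling at its analytic frequency", {
  rate0 <- 204.8; dur <- 10
  t0 <- seq(0, dur - 1 / rate0, by = 1 / rate0)
  rec <- sensor_recording(
    matrix(sin(2 * pi * 2 * t0), nrow = length(t0), ncol = 3),
    labels = rep("a", length(t0)), sampling_rate = rate0
  )
  out <- resample_recording(rec, 50)
  x <- out$samples[, 1]
  spec <- Mod(fft(x))[1:(length(x) %/% 2)]
  f_axis <- (seq_along(spec) - 1) * 50 / length(x)
  expect_lt(abs(f_axis[which.max(spec)] - 2), 50 / length(x) * 1.5)
})

test_that("resampling at the same target is idempotent", {
  set.seed(91)
  rec <- sensor_recording(matrix(rnorm(3072), ncol = 3),
                         labels = rep("a", 1024), sampling_rate = 100)
  once <- resample_recording(rec, 50)
  twice <- resample_recording(once, 50)
  expect_equal(twice$samples, once$samples, tolerance = 1e-8)
})

test_that("segmentation emits exactly the label-pure fixed windows", {
  set.seed(101)
  # 10 s at 50 Hz, single label -> 4 windows of 125
  rec <- sensor_recording(matrix(rnorm(1500), ncol = 3),
                         labels = rep("walking", 500), sampling_rate = 50)
  segs <- segment_recording(rec)
  expect_length(segs, 4L)
  expect_true(all(vapply(segs, function(s) s$window_length, integer(1)) == 125L))
  expect_identical(segs[[2]]$samples, rec$samples[126:250, ])

  # label change at 5 s -> 2 + 2 windows, none straddling
  rec2 <- sensor_recording(matrix(rnorm(1500), ncol = 3),
                          labels = rep(c("walk", "run"), each = 250),
                          sampling_rate = 50)
  segs2 <- segment_recording(rec2)
  expect_length(segs2, 4L)
  expect_identical(vapply(segs2, function(s) s$label, character(1)),
                   c("walk", "walk", "run", "run"))

  # shorter than one window -> empty, not an error
  rec3 <- sensor_recording(matrix(rnorm(360), ncol = 3),
                          labels = rep("a", 120), sampling_rate = 50)
  expect_length(segment_recording(rec3), 0L)
})

test_that("segmentation is exhaustive over label-pure runs", {
  set.seed(111)
  labels <- rep(c("a", "b", "a", "c"), times = c(301, 207, 414, 95))
  rec <- sensor_recording(matrix(rnorm(3 * length(labels)), ncol = 3),
                         labels = labels, sampling_rate = 50)
  segs <- segment_recording(rec)
  runs <- rle(labels)
  expected <- sum(runs$lengths %/% 125L)
  expect_length(segs, expected)
})

test_that("majority-vote labelling and window overlap are available", {
  labels <- c(rep("a", 100), rep("b", 400))
  rec <- sensor_recording(matrix(0, 500, 3), labels = labels,
                         sampling_rate = 50)
  segs <- segment_recording(rec, label_policy = "majority")
  expect_length(segs, 4L)
  expect_identical(segs[[1]]$label, "a")  # first window: 100 a vs 25 b
  expect_identical(segs[[2]]$label, "b")
  segs50 <- segment_recording(
    sensor_recording(matrix(0, 500, 3), rep("a", 500), 50),
    overlap = 0.5
  )
  expect_length(segs50, 7L)  # starts 1, 64, 127, ..., step 62-63
})

test_that("unit conversion multiplies by 9.80665 and is reversible", {
  rec <- sensor_recording(matrix(1, 4, 3), rep("a", 4), 50, units = "g")
  ms2 <- convert_units(rec, "m_per_s2")
  expect_equal(unname(ms2$samples[1, 1]), 9.80665)
  back <- convert_units(ms2, "g")
  expect_equal(back$samples, rec$samples, tolerance = 1e-12)
  expect_identical(convert_units(rec, "g"), rec)
})

test_that("segments serialize to a manifest-indexed directory", {
  segs <- lapply(1:3, function(i) make_test_segment(i, label = "walk"))
  dir <- withr::local_tempdir()
  manifest <- write_segments(segs, dir)
  tab <- read.csv(manifest)
  expect_identical(nrow(tab), 3L)
  seg1 <- read.csv(file.path(dir, tab$file[1]))
  expect_equal(as.matrix(seg1), segs[[1]]$samples, ignore_attr = TRUE)
})
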