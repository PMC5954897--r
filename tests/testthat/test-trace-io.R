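test_that("trap_trace validates its grid and metadata", {
  md <- list(trap_stiffness = 0.02, sampling_rate = 2000)
  tr <- trap_trace((0:1999) / 2000, rnorm(2000), metadata = md)
  expect_s3_class(tr, "trap_trace")
  expect_equal(max(tr$time_s) + 1 / 2000, 1.0) # 2000 samples at 2 kHz = 1 s

  expect_error(trap_trace(c(0, 1e-3, 3e-3), rnorm(3), metadata = md),
               "uniform grid")
  expect_error(trap_trace(0.5, 1, metadata = md), "at least 2 samples")
  expect_error(trap_trace(numeric(0), numeric(0), metadata = md),
               "at least 2 samples")
  expect_error(trap_trace((0:9) / 2000, rnorm(10),
                          metadata = list(sampling_rate = 2000)),
               "trap_stiffness")
})

test_that("trace files round-trip with exact numeric content", {
  md <- list(trap_stiffness = 0.037, sampling_rate = 2000,
             temperature = 295, cargo_diameter = 750, trace_id = "rt")
  set.seed(7)
  tr <- trap_trace((0:499) / 2000, rnorm(500, sd = 14) + pi,
                   y = rnorm(500, sd = 14), metadata = md)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, f)
  tr2 <- read_trace(f)
  expect_identical(tr2$x_nm, tr$x_nm)
  expect_identical(tr2$y_nm, tr$y_nm)
  expect_identical(tr2$time_s, tr$time_s)
  expect_equal(trace_metadata(tr2)$trap_stiffness, 0.037)
  expect_equal(trace_metadata(tr2)$trace_id, "rt")
})

test_that("a missing perpendicular channel stays absent", {
  md <- list(trap_stiffness = 0.02, sampling_rate = 2000)
  tr <- trap_trace((0:99) / 2000, rnorm(100), metadata = md)
  f <- withr::local_tempfile(fileext = ".csv")
  write_trace(tr, f)
  expect_false("y_nm" %in% names(read_trace(f)))
})

test_that("malformed trace files are rejected with named keys", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("# sampling_rate: 2000", "time_s,x_nm", "0,1", "5e-4,2"), f)
  expect_error(read_trace(f), "trap_stiffness")
  expect_error(read_trace(file.path(tempdir(), "nope.csv")), "no such")
})
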