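# Core model objects and file round-trips.

test_that("marker_series validates shape and masks invalid frames", {
  pos <- matrix(rnorm(30), ncol = 3)
  s <- marker_series("LHEE", pos, rate_hz = 100)
  expect_s3_class(s, "marker_series")
  expect_true(all(s$valid_mask))
  pos[4, 2] <- NA
  s2 <- marker_series("LHEE", pos, rate_hz = 100)
  expect_false(s2$valid_mask[4])
  expect_error(marker_series("X", matrix(1, 2, 2)), "3")
})

test_that("trial_recording rejects markers with mismatched lengths or rates", {
  a <- marker_series("LHEE", matrix(0, 10, 3), rate_hz = 100)
  b <- marker_series("RHEE", matrix(0, 12, 3), rate_hz = 100)
  expect_error(trial_recording(list(LHEE = a, RHEE = b)))
  c <- marker_series("RHEE", matrix(0, 10, 3), rate_hz = 50)
  expect_error(trial_recording(list(LHEE = a, RHEE = c)))
})

test_that("metric_table enforces column set and key uniqueness", {
  row <- data.frame(subject_id = "S1", group = "pd", protocol = "fmap",
                    trial_index = 1L, task = "turn",
                    metric_name = "abs_yaw_trunk", value = 170, units = "deg")
  tab <- metric_table(row)
  expect_s3_class(tab, "metric_table")
  expect_error(metric_table(rbind(row, row)), "duplicate")
  expect_error(metric_table(row[, -7]))
})

test_that("metric table CSV round-trips including the phase column", {
  row <- data.frame(subject_id = c("S1", "S1"), group = "pd",
                    protocol = "fmap", phase = c("Pre", "Post"),
                    trial_index = 1L, task = "turn",
                    metric_name = "abs_yaw_trunk", value = c(170, 172),
                    units = "deg")
  tab <- metric_table(row)
  path <- tempfile(fileext = ".csv")
  write_metric_table(tab, path)
  back <- read_metric_table(path)
  df <- as.data.frame(back)
  expect_equal(df$value, c(170, 172))
  expect_equal(df$phase, c("Pre", "Post"))
})

test_that("C3D files round-trip positions, validity and rate", {
  sim <- simulate_trial(avatar_params(seed = 31), "tug")
  path <- tempfile(fileext = ".c3d")
  write_c3d_trial(sim$trial, path)
  back <- read_c3d_trial(path, protocol = "tug")
  expect_equal(names(back$markers), names(sim$trial$markers))
  expect_equal(n_frames(back), n_frames(sim$trial))
  expect_equal(trial_rate(back), trial_rate(sim$trial))
  for (nm in c("LHEE", "RWRA", "C7")) {
    expect_lt(max(abs(get_marker(back, nm)$positions -
                      get_marker(sim$trial, nm)$positions), na.rm = TRUE),
              1e-6)
    expect_identical(get_marker(back, nm)$valid_mask,
                     get_marker(sim$trial, nm)$valid_mask)
  }
})

test_that("C3D preserves occlusion gaps as invalid frames", {
  p <- avatar_params(seed = 31, gap_script = data.frame(
    marker = "RWRA", start_frame = 200, length = 12))
  sim <- simulate_trial(p, "tug")
  path <- tempfile(fileext = ".c3d")
  write_c3d_trial(sim$trial, path)
  back <- read_c3d_trial(path, protocol = "tug")
  expect_true(all(!get_marker(back, "RWRA")$valid_mask[201:212]))
  expect_true(all(is.na(get_marker(back, "RWRA")$positions[201:212, ])))
})

test_that("pressure-mat CSV export round-trips COP and footfalls", {
  sim <- simulate_trial(avatar_params(seed = 8), "fmap")
  path <- tempfile(fileext = ".csv")
  write_gaitmat_export(sim$trial$mat, path)
  back <- read_gaitmat_export(path, rate_hz = 100)
  expect_equal(back$cop, sim$trial$mat$cop, tolerance = 1e-6)
  expect_equal(back$footfalls$on_frame, sim$trial$mat$footfalls$on_frame)
  expect_equal(back$footfalls$foot, sim$trial$mat$footfalls$foot)
})

test_that("marker CSV export round-trips", {
  sim <- simulate_trial(avatar_params(seed = 8), "standing")
  path <- tempfile(fileext = ".csv")
  write_marker_csv(sim$trial, path)
  back <- read_marker_csv(path, rate_hz = 100, protocol = "standing")
  expect_equal(sort(names(back$markers)), sort(names(sim$trial$markers)))
  expect_equal(get_marker(back, "LHEE")$positions,
               get_marker(sim$trial, "LHEE")$positions,
               tolerance = 1e-6, ignore_attr = TRUE)
})

test_that("run configuration rejects unknown keys and empty subject lists", {
  path <- tempfile(fileext = ".yaml")
  writeLines(c("output: out.csv", "bogus_key: 1",
               "subjects:", "  - id: S1"), path)
  expect_error(read_run_config(path), "bogus_key")
  writeLines(c("output: out.csv"), path)
  expect_error(read_run_config(path), "subject")
})
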