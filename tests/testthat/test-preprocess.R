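# Gap filling, despiking, COP filtering, exclusion rules.

mk_series <- function(pos, rate = 100) marker_series("T", pos, rate_hz = rate)

test_that("polynomial fill reconstructs a cubic trajectory exactly", {
  t <- seq(0, 1, length.out = 101)
  truth <- cbind(2 + t - 0.5 * t^2 + 0.25 * t^3, t^2, 1 - t^3)
  pos <- truth
  pos[40:47, ] <- NA                       # 8-frame gap: polynomial regime
  out <- fill_gaps(mk_series(pos))
  expect_equal(out$series$positions[40:47, ], truth[40:47, ], tolerance = 1e-8)
  expect_equal(out$report$method, "polynomial")
  expect_equal(out$report$gap_start, 39L)  # 0-based
  expect_equal(out$report$gap_len, 8L)
})

test_that("spline fill handles medium gaps and long gaps are excluded", {
  t <- seq(0, 4, length.out = 401)
  truth <- cbind(sin(t), cos(t), 0.1 * t)
  pos <- truth
  pos[100:170, ] <- NA                     # 71 frames: spline regime
  out <- fill_gaps(mk_series(pos))
  expect_equal(out$report$method, "spline")
  expect_lt(max(abs(out$series$positions[100:170, ] - truth[100:170, ])), 1e-3)
  pos2 <- truth
  pos2[100:220, ] <- NA                    # 121 frames: beyond spline limit
  out2 <- fill_gaps(mk_series(pos2))
  expect_equal(out2$report$method, "excluded")
  expect_true(all(!out2$series$valid_mask[100:220]))
})

test_that("gaps touching a boundary are never filled", {
  pos <- matrix(rnorm(300), ncol = 3)
  pos[1:5, ] <- NA
  out <- fill_gaps(mk_series(pos))
  expect_equal(out$report$method, "excluded")
  expect_true(all(!out$series$valid_mask[1:5]))
})

test_that("fill_gaps never modifies originally valid frames", {
  t <- seq(0, 2, length.out = 201)
  truth <- cbind(t, t^2, sin(t))
  pos <- truth
  pos[50:55, ] <- NA
  out <- fill_gaps(mk_series(pos))
  keep <- setdiff(seq_len(201), 50:55)
  expect_identical(out$series$positions[keep, ], truth[keep, ])
})

test_that("despike is the declared 15-sample moving average", {
  pos <- matrix(0, 100, 3)
  pos[50, 1] <- 10                         # isolated 10-unit spike
  s <- despike(mk_series(pos))
  # a spike of height h survives as h/window at its center
  expect_equal(s$positions[50, 1], 10 / 15, tolerance = 1e-10)
  # linear trends pass through a centered moving average unchanged (interior)
  lin <- matrix(seq_len(100), 100, 3)
  s2 <- despike(mk_series(lin))
  expect_equal(s2$positions[20:80, 2], lin[20:80, 2], tolerance = 1e-9)
})

test_that("COP filter is zero-lag: time reversal commutes with filtering", {
  set.seed(4)
  n <- 600
  cop <- cbind(cumsum(rnorm(n)), cumsum(rnorm(n)))
  m1 <- filter_cop(mat_recording(cop, rate_hz = 100))
  m2 <- filter_cop(mat_recording(cop[n:1, ], rate_hz = 100))
  i <- 50:(n - 50)              # frame i maps to reversed frame n + 1 - i
  expect_equal(m1$cop[i, ], m2$cop[n + 1 - i, ], tolerance = 1e-6)
})

test_that("preprocess_trial fills scripted gaps and attenuates scripted spikes", {
  p <- avatar_params(
    seed = 13,
    gap_script = data.frame(marker = "LHEE", start_frame = 400, length = 6),
    spike_script = data.frame(marker = "C7", frame = 500, magnitude_m = 0.05))
  sim <- simulate_trial(p, "fmap")
  out <- preprocess_trial(sim$trial)
  expect_true(all(out$trial$markers$LHEE$valid_mask[401:406]))
  # same seed without the spike: by linearity of the moving average the
  # preprocessed trajectories differ by exactly magnitude/15 at the spike
  p0 <- avatar_params(
    seed = 13,
    gap_script = data.frame(marker = "LHEE", start_frame = 400, length = 6))
  out0 <- preprocess_trial(simulate_trial(p0, "fmap")$trial)
  d <- get_marker(out$trial, "C7")$positions[501, 1] -
       get_marker(out0$trial, "C7")$positions[501, 1]
  expect_equal(d, 0.05 / 15, tolerance = 1e-6)
})

test_that("exclusion_check flags unfillable spans only inside task windows", {
  pos <- matrix(rnorm(1500), ncol = 3)
  pos[200:350, ] <- NA                     # 151 frames: unfillable
  out <- fill_gaps(mk_series(pos))
  exc <- exclusion_check(out$series, out$report)
  expect_false(exc$usable)
  expect_match(exc$reason, "invalid")
  # same series, but the task window avoids the gap
  ok <- exclusion_check(out$series, out$report,
                        task_windows = data.frame(start_frame = 0L,
                                                  end_frame = 150L))
  expect_true(ok$usable)
})
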