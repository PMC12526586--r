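# Kinematic metric definitions on scripted trials.

fixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_trial(avatar_params(seed = 2), "fmap")
      tr <- preprocess_trial(sim$trial)$trial
      cache <<- list(sim = sim, trial = tr, sg = segment_trial(tr))
    }
    cache
  }
})

test_that("ASA symmetry-angle form hits the analytic mid anchor", {
  # ratio 0.5 -> |45 - atan(0.5)|/90 * 100
  expect_equal(asa(30, 15), abs(45 - atan(0.5) * 180 / pi) / 90 * 100,
               tolerance = 1e-12)
  expect_equal(asa(30, 15), 20.48, tolerance = 0.005)
  # symmetric in argument order (dominant = larger |swing|)
  expect_equal(asa(15, 30), asa(30, 15))
})

test_that("ASA difference form is available but distinct", {
  expect_false(isTRUE(all.equal(asa(30, 15), asa(30, 15, form = "difference"))))
})

test_that("spatiotemporal gait matches the schedule-derived truth", {
  cc <- fixture()
  g <- spatiotemporal_gait(cc$sg$events, cc$trial, cc$sg$segments$walk_out,
                           min_strides = 1)
  tg <- cc$sim$truth$gait
  expect_equal(g$stride_time_s, 1.09, tolerance = 1e-6)
  expect_equal(g$double_support_pct, tg$double_support_pct, tolerance = 0.02)
})

test_that("arm swing is signed and anti-phase arms cancel in ASA", {
  cc <- fixture()
  aw <- arm_swing(cc$sg$segments$walk_out, cc$trial, cc$sg$kin, cc$sg$events)
  tp <- cc$sim$truth$params
  expect_equal(aw$total_swing_dominant, tp$total_swing_dominant,
               tolerance = 0.05 * abs(tp$total_swing_dominant))
  expect_equal(aw$asa_percent, tp$asa_percent, tolerance = 1)
})

test_that("yaw turning profile: craniocaudal sequence, head leads", {
  cc <- fixture()
  yp <- yaw_turning_profile(cc$sg$segments$turn, cc$sg$kin, cc$sg$events)
  expect_equal(names(yp$rel_yaw), c("head_trunk", "trunk_pelvis", "head_pelvis"))
  # the avatar scripts head before trunk before pelvis
  expect_lt(yp$onset_pct[["head"]], yp$onset_pct[["trunk"]])
  expect_lt(yp$onset_pct[["trunk"]], yp$onset_pct[["pelvis"]])
  tp <- cc$sim$truth$params
  for (s in c("head", "trunk", "pelvis"))
    expect_equal(yp$abs_yaw[[s]], tp$abs_yaw[[s]], tolerance = 1.5)
})

test_that("turn yaw is sign-normalized: clockwise turns read like counterclockwise", {
  sim <- simulate_trial(avatar_params(seed = 55, turn_direction = "CW"), "fmap")
  sg <- segment_trial(preprocess_trial(sim$trial)$trial)
  yp <- yaw_turning_profile(sg$segments$turn, sg$kin, sg$events)
  expect_gt(yp$abs_yaw[["trunk"]], 150)  # positive excursion toward 180
})

test_that("foot angles recover the scripted toe-off and heel-strike pitch", {
  cc <- fixture()
  fa <- foot_angles(cc$trial, cc$sg$events, cc$sg$segments$walk_out)
  tp <- cc$sim$truth$params
  expect_equal(fa$to_angle, tp$to_angle_deg, tolerance = 1)
  expect_equal(fa$hs_angle, tp$hs_angle_deg, tolerance = 1)
})

test_that("trunk inclination peaks at the scripted bend", {
  cc <- fixture()
  ti <- trunk_inclination(cc$sg$segments$sit_to_stand, cc$sg$kin)
  expect_equal(ti$peak_ap, cc$sim$truth$params$peak_trunk_inclination_ap,
               tolerance = 1)
})

test_that("COP displacement uses millimeters and respects the segment", {
  cc <- fixture()
  cp <- cop_displacement(cc$sg$segments$sit_to_stand, cc$trial$mat, cc$trial)
  expect_true(is.finite(cp$mean_ap_mm))
  expect_lt(abs(cp$mean_ml_mm), 100)
})

test_that("simultaneity index is (P+L+M)/MT with validation", {
  expect_equal(simultaneity_index(2, 5, 3, 10), 1)
  expect_equal(simultaneity_index(1, 2, 1, 8), 0.5)
  expect_error(simultaneity_index(1, 2, 1, 0), "MT")
  expect_error(simultaneity_index(-1, 2, 1, 8), ">= 0")
  expect_error(simultaneity_index(9, 2, 1, 8), ">=")
})

test_that("freezing-like events respect threshold and minimum duration", {
  rate <- 100
  speed <- rep(1, 500)
  speed[101:170] <- 0.05        # 0.7 s below 10% of baseline 1.0
  speed[301:330] <- 0.05        # 0.3 s: too short
  ev <- fle_from_speed(speed, rate, baseline_speed = 1)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$start_frame, 100)
  expect_equal(ev$end_frame, 170)
  expect_equal(ev$duration_s, 0.7)
})

test_that("detect_fle attributes doorway-overlapping freezes to the doorway", {
  p <- avatar_params(seed = 3, fle_script = data.frame(
    bout = "walk_out", at_frac = 0.5, duration_s = 1.0))
  sim <- simulate_trial(p, "fmap")
  tr <- preprocess_trial(sim$trial)$trial
  sg <- segment_trial(tr)
  fe <- detect_fle(tr, sim$truth$baseline_speed_m_s, sg$segments, kin = sg$kin)
  expect_equal(nrow(fe), 1)
  expect_equal(fe$location, "doorway")
  expect_equal(fe$duration_s, 1.0, tolerance = 0.3)
})
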