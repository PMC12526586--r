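# Gait events and task segmentation against the simulator's schedule.

sim_cached <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sim <- simulate_trial(avatar_params(seed = 42), "fmap")
      tr <- preprocess_trial(sim$trial)$trial
      cache <<- list(sim = sim, trial = tr, sg = segment_trial(tr))
    }
    cache
  }
})

test_that("mat footfalls override marker events: HS = onset, TO = release", {
  cc <- sim_cached()
  ev <- cc$sg$events
  expect_equal(ev$source, "mat")
  ff <- cc$sim$truth$footfalls
  for (side in c("L", "R")) {
    f <- ff[ff$foot == side, ]
    n <- n_frames(cc$trial)
    expect_equal(ev[[side]]$hs, sort(f$on_frame[f$on_frame > 0]))
    expect_equal(ev[[side]]$to, sort(f$off_frame[f$off_frame < n - 1]))
  }
})

test_that("a stance present at recording start is not a heel strike", {
  cc <- sim_cached()
  ev <- cc$sg$events
  expect_false(0 %in% c(ev$L$hs, ev$R$hs))
})

test_that("strides pair consecutive ipsilateral heel strikes with one toe-off between", {
  cc <- sim_cached()
  ev <- cc$sg$events
  st <- ev$strides
  expect_gt(nrow(st), 5)
  for (i in seq_len(nrow(st))) {
    tos <- ev[[st$foot[i]]]$to
    between <- tos[tos > st$start_hs[i] & tos < st$end_hs[i]]
    expect_length(between, 1)
    expect_equal(between, st$to_frame[i])
  }
})

test_that("marker-only event detection approximates the mat events", {
  cc <- sim_cached()
  trial <- cc$trial
  trial$mat <- NULL
  ev <- detect_gait_events(trial)
  expect_equal(ev$source, "markers")
  mat_ev <- cc$sg$events
  # every walking-phase mat heel strike has a marker event within 10 frames
  for (side in c("L", "R")) {
    hs_mat <- mat_ev[[side]]$hs
    hs_mat <- hs_mat[hs_mat > 250 & hs_mat < 500]  # clean walk_out window
    for (h in hs_mat)
      expect_lte(min(abs(ev[[side]]$hs - h)), 10)
  }
})

test_that("task segmentation matches the scripted timeline", {
  cc <- sim_cached()
  segs <- cc$sg$segments
  gt <- cc$sim$truth$segments
  gtrow <- function(task) gt[gt$task == task, ]
  for (task in c("sit_to_stand", "walk_out", "turn", "functional_reach")) {
    g <- gtrow(task)
    expect_lte(abs(segs[[task]]$start_frame - g$start_frame), 10)
    expect_lte(abs(segs[[task]]$end_frame - g$end_frame), 10)
  }
  g <- gtrow("stand_to_sit")
  expect_lte(abs(segs$stand_to_sit$start_frame - g$start_frame), 10)
})

test_that("turn segmentation is invariant to turn direction", {
  for (dir in c("CCW", "CW")) {
    sim <- simulate_trial(avatar_params(seed = 77, turn_direction = dir), "fmap")
    sg <- segment_trial(preprocess_trial(sim$trial)$trial)
    gt <- sim$truth$segments
    g <- gt[gt$task == "turn", ]
    expect_lte(abs(sg$segments$turn$start_frame - g$start_frame), 10)
    expect_lte(abs(sg$segments$turn$end_frame - g$end_frame), 10)
    expect_equal(sg$segments$turn$events$turning_foot,
                 if (dir == "CW") "R" else "L")
  }
})

test_that("the walkway doorframe yields one doorway passage per crossing", {
  cc <- sim_cached()
  doors <- cc$sg$segments[grepl("^doorway_pass", names(cc$sg$segments))]
  expect_length(doors, 2)           # out and back
  expect_lt(doors[[1]]$end_frame, doors[[2]]$start_frame)
})

test_that("functional reach counts a single grab as one attempt", {
  cc <- sim_cached()
  expect_equal(cc$sg$segments$functional_reach$events$attempts, 1L)
})

test_that("the tug protocol has no functional reach segment", {
  sim <- simulate_trial(avatar_params(seed = 42), "tug")
  sg <- segment_trial(preprocess_trial(sim$trial)$trial)
  expect_null(sg$segments$functional_reach)
  expect_false(is.null(sg$segments$walk_back))
})

test_that("standing segmentation picks a 10-second quiet window", {
  sim <- simulate_trial(avatar_params(seed = 5), "standing")
  sg <- segment_trial(preprocess_trial(sim$trial)$trial)
  seg <- sg$segments$standing
  expect_equal(seg$end_frame - seg$start_frame, 1000)
})
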