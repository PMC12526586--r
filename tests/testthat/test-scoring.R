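# Observational scoring: sheets, aggregation, rater reconciliation.

test_that("performance sheets validate their ordinal items", {
  expect_error(performance_sheet(1, rep(3, 9)), "10")
  expect_error(performance_sheet(1, c(rep(3, 9), 4)), "0, 1, 2, 3")
  s <- performance_sheet(1, rep(2, 10), rater_id = "rA")
  expect_s3_class(s, "performance_sheet")
  expect_length(s$descriptions, 4)
})

test_that("aggregation is per-item trial means summed, bounded by 30", {
  sheets <- list(performance_sheet(1, c(0, 1, 2, 3, 0, 1, 2, 3, 0, 1)),
                 performance_sheet(2, c(1, 1, 1, 1, 1, 1, 1, 1, 1, 1)),
                 performance_sheet(3, c(2, 3, 0, 1, 2, 3, 0, 1, 2, 3)))
  agg <- aggregate_performance(sheets)
  expect_equal(agg$item_means[1], mean(c(0, 1, 2)))
  expect_equal(agg$total, sum(colMeans(rbind(c(0, 1, 2, 3, 0, 1, 2, 3, 0, 1),
                                             rep(1, 10),
                                             c(2, 3, 0, 1, 2, 3, 0, 1, 2, 3)))))
  expect_lte(agg$total, 30)
  expect_length(agg$flags, 0)
})

test_that("fewer trials than expected is computed but flagged", {
  sheets <- list(performance_sheet(1, rep(1, 10)),
                 performance_sheet(2, rep(2, 10)))
  agg <- aggregate_performance(sheets)
  expect_equal(agg$total, 15)
  expect_match(agg$flags, "2 of 3")
})

test_that("rater reconciliation lists only disagreeing items with deltas", {
  a <- list(performance_sheet(1, rep(1, 10), rater_id = "rA"),
            performance_sheet(2, rep(2, 10), rater_id = "rA"))
  b1 <- list(performance_sheet(1, rep(1, 10), rater_id = "rB"),
             performance_sheet(2, rep(2, 10), rater_id = "rB"))
  expect_equal(nrow(reconcile_raters(a, b1)), 0)
  b2 <- b1
  b2[[2]] <- performance_sheet(2, c(rep(2, 9), 0), rater_id = "rB")
  d <- reconcile_raters(a, b2)
  expect_equal(nrow(d), 1)
  expect_equal(d$item, "i10")
  expect_equal(d$delta, 2)
  expect_error(reconcile_raters(a, b1[1]), "different trial sets")
})

test_that("performance sheets round-trip through CSV", {
  sheets <- list(performance_sheet(1, c(0:3, 0:3, 0:1), rater_id = "rA"),
                 performance_sheet(2, rep(3, 10), rater_id = "rA"))
  path <- tempfile(fileext = ".csv")
  write_performance_sheets(sheets, path)
  back <- read_performance_sheets(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$item_scores, sheets[[1]]$item_scores)
  expect_equal(back[[2]]$trial_index, 2L)
  expect_equal(aggregate_performance(back, 2)$total,
               aggregate_performance(sheets, 2)$total)
})
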