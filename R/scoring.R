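# Observational scoring: the Simultaneity Index for
# postural-locomotion-manual sequences, and ordinal Performance Score
# aggregation across trials and raters.

#' Simultaneity Index
#'
#' `SI = (P + L + M) / MT` where P is the postural phase duration (grasp
#' to upright), L the locomotion phase, M the manual (aim-and-place)
#' phase, and MT the total movement time from first grasp to placement.
#' With perfectly tiled, non-overlapping phases SI = 1; a lower SI
#' reflects increased movement time and greater functional disability.
#'
#' @param p,l,m Phase durations, seconds (all >= 0).
#' @param mt Total movement time, seconds (> 0, >= each phase).
#' @return SI, dimensionless.
#' @export
simultaneity_index <- function(p, l, m, mt) {
  if (mt <= 0) stop("MT must be > 0")
  if (any(c(p, l, m) < 0)) stop("phase durations must be >= 0")
  if (mt < max(p, l, m)) stop("MT must be >= each phase duration")
  (p + l + m) / mt
}

#' Construct a performance sheet
#'
#' One rater's scoring of one trial: ten items on a four-point ordinal
#' scale (0 = no problems with the task, 3 = difficulties with the task)
#' plus four free-text descriptions. The item texts are
#' deployment-specific; items are addressed as i1..i10.
#'
#' @param trial_index Trial number.
#' @param item_scores Integer vector of 10 scores, each in {0, 1, 2, 3}.
#' @param descriptions Character vector of up to 4 free-text fields.
#' @param rater_id Rater identifier.
#' @return Object of class `performance_sheet`.
#' @export
performance_sheet <- function(trial_index, item_scores, descriptions = character(4),
                              rater_id = "r1") {
  item_scores <- as.integer(item_scores)
  if (length(item_scores) != 10) stop("exactly 10 scored items required")
  if (!all(item_scores %in% 0:3)) stop("item scores must be in {0, 1, 2, 3}")
  length(descriptions) <- 4
  structure(list(trial_index = as.integer(trial_index),
                 item_scores = item_scores,
                 descriptions = as.character(descriptions),
                 rater_id = rater_id),
            class = "performance_sheet")
}

#' Aggregate performance sheets into item means and a total
#'
#' Per item, the mean score across trials; the final score is the sum of
#' the ten item means, bounded by 0 and 30.
#'
#' @param sheets List of [performance_sheet()] from one participant/session.
#' @param trials_expected Expected number of trials (default 3); fewer is
#'   computed but flagged.
#' @return List with `item_means` (length 10), `total` (0-30), `n_trials`
#'   and `flags`.
#' @export
aggregate_performance <- function(sheets, trials_expected = 3) {
  if (!length(sheets)) stop("at least one sheet required")
  mat <- do.call(rbind, lapply(sheets, function(s) {
    if (!inherits(s, "performance_sheet")) stop("sheets must be performance_sheet objects")
    s$item_scores
  }))
  item_means <- colMeans(mat)
  flags <- character()
  if (nrow(mat) < trials_expected)
    flags <- sprintf("only %d of %d expected trials", nrow(mat), trials_expected)
  list(item_means = unname(item_means), total = sum(item_means),
       n_trials = nrow(mat), flags = flags)
}

#' Compare two raters' sheets item by item
#'
#' Flags per-item disagreements with their deltas. No automatic
#' resolution: differences are discussed by the raters.
#'
#' @param a,b Lists of [performance_sheet()] from the two raters covering
#'   the same trials.
#' @return Data frame with `trial_index`, `item`, `score_a`, `score_b`,
#'   `delta` (only disagreeing items; zero rows when identical).
#' @export
reconcile_raters <- function(a, b) {
  ta <- vapply(a, function(s) s$trial_index, integer(1))
  tb <- vapply(b, function(s) s$trial_index, integer(1))
  if (!setequal(ta, tb) || length(ta) != length(tb))
    stop("raters scored different trial sets")
  out <- NULL
  for (tr in sort(ta)) {
    sa <- a[[which(ta == tr)]]$item_scores
    sb <- b[[which(tb == tr)]]$item_scores
    diff_at <- which(sa != sb)
    if (length(diff_at))
      out <- rbind(out, data.frame(trial_index = tr,
                                   item = paste0("i", diff_at),
                                   score_a = sa[diff_at], score_b = sb[diff_at],
                                   delta = sa[diff_at] - sb[diff_at]))
  }
  if (is.null(out))
    out <- data.frame(trial_index = integer(), item = character(),
                      score_a = integer(), score_b = integer(),
                      delta = integer())
  out
}

#' Read performance sheets from CSV
#'
#' Columns: `rater_id, trial, i1..i10, d1..d4` (descriptions optional).
#'
#' @param path CSV path.
#' @return List of [performance_sheet()].
#' @export
read_performance_sheets <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  items <- paste0("i", 1:10)
  if (!all(items %in% names(df))) stop("sheet CSV needs columns i1..i10")
  descs <- intersect(paste0("d", 1:4), names(df))
  lapply(seq_len(nrow(df)), function(r) {
    performance_sheet(df$trial[r], as.integer(df[r, items]),
                      as.character(unlist(df[r, descs])),
                      rater_id = if ("rater_id" %in% names(df)) df$rater_id[r] else "r1")
  })
}

#' Write performance sheets to CSV
#'
#' @param sheets List of [performance_sheet()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_performance_sheets <- function(sheets, path) {
  df <- do.call(rbind, lapply(sheets, function(s) {
    row <- data.frame(rater_id = s$rater_id, trial = s$trial_index)
    for (i in 1:10) row[[paste0("i", i)]] <- s$item_scores[i]
    for (i in 1:4) row[[paste0("d", i)]] <- s$descriptions[i]
    row
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
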