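# Statistical conventions: Bonferroni families, ICC, PMM imputation,
# group and phase analyses.

test_that("bonferroni_alpha returns the exact division and a 2-signif report", {
  b <- bonferroni_alpha(6)
  expect_equal(b$alpha, 0.05 / 6)
  expect_equal(b$reported, signif(0.05 / 6, 2))
  expect_equal(bonferroni_alpha(4)$alpha * 4, 0.05)
  expect_equal(bonferroni_alpha(11, base = 0.05)$reported, 0.0045)
})

test_that("family_spec attaches the corrected alpha to its members", {
  fs <- family_spec("gait", c("stride_length_m", "stride_time_s"), 0.05)
  expect_equal(fs$corrected_alpha, rep(0.025, 2))
  expect_equal(fs$metric_name, c("stride_length_m", "stride_time_s"))
  expect_equal(fs$n_members, rep(2L, 2), ignore_attr = TRUE)
})

test_that("default families reproduce the declared family sizes", {
  fam <- default_families()
  count <- function(task, family)
    sum(fam$task == task & fam$family == family)
  expect_equal(count("sit_to_stand", "upper_kinematic"), 7)
  expect_equal(count("sit_to_stand", "cop"), 2)
  expect_equal(count("turn", "kinematic"), 11)
  expect_equal(count("locomotion_lap", "gait"), 19)
})

test_that("ICC matches a hand-computed one-way table and its identities", {
  # subjects at 1, 2, 3; per-trial offsets 0, +0.1, -0.1
  r <- rbind(c(1, 1.1, 0.9), c(2, 2.1, 1.9), c(3, 3.1, 2.9))
  got <- icc_oneway(r)
  bms <- 3 * stats::var(rowMeans(r))                     # 3.0
  wms <- sum((r - rowMeans(r))^2) / (3 * 2)              # 0.01
  expect_equal(got$icc_single, (bms - wms) / (bms + 2 * wms), tolerance = 1e-9)
  expect_equal(got$icc_avg, (bms - wms) / bms, tolerance = 1e-9)
  # Spearman-Brown consistency
  k <- 3
  expect_equal(got$icc_avg,
               k * got$icc_single / (1 + (k - 1) * got$icc_single),
               tolerance = 1e-9)
})

test_that("identical repeated trials give ICC 1; degenerate input is flagged", {
  r <- matrix(rep(c(1, 5, 9), 3), ncol = 3)
  expect_equal(icc_oneway(r)$icc_single, 1)
  flat <- matrix(2, 4, 3)
  out <- icc_oneway(flat)
  expect_true("degenerate_variance" %in% out$flags)
  expect_true(out$icc_single >= 0 && out$icc_single <= 1)
})

test_that("PMM imputation is seed-reproducible and donates observed values", {
  ch <- simulate_cohort(n_per_group = 8, seed = 21, missing_frac = 0.08)
  i1 <- suppressWarnings(impute_pmm(ch$table, seed = 7))
  i2 <- suppressWarnings(impute_pmm(ch$table, seed = 7))
  expect_identical(as.data.frame(i1$table), as.data.frame(i2$table))
  i3 <- suppressWarnings(impute_pmm(ch$table, seed = 8))
  expect_false(identical(as.data.frame(i1$table)$value,
                         as.data.frame(i3$table)$value))
  # every imputed draw is an observed donor value of the same variable
  src <- as.data.frame(ch$table)
  expect_gt(length(i1$draws), 0)
  for (key in names(i1$draws)) {
    v <- strsplit(key, "::", fixed = TRUE)[[1]][2]
    parts <- strsplit(v, "|", fixed = TRUE)[[1]]
    obs <- src$value[src$task == parts[1] & src$metric_name == parts[2] &
                     !is.na(src$value)]
    expect_true(all(vapply(c(i1$draws[[key]]), function(x)
      any(abs(obs - x) < 1e-12), logical(1))))
  }
})

test_that("imputation report brackets the 5-20% recommended band", {
  ch <- simulate_cohort(n_per_group = 8, seed = 22, missing_frac = 0.10)
  imp <- suppressWarnings(impute_pmm(ch$table, seed = 1))
  expect_true(all(c("cluster", "variable", "missing_pct", "flags") %in%
                  names(imp$report)))
  pct <- imp$report$missing_pct
  fl <- imp$report$flags
  in_band <- pct > 5 & pct <= 20
  expect_true(all(grepl("in_recommended_band", fl[in_band])))
  expect_true(all(grepl("missing_above_20pct", fl[pct > 20])))
})

test_that("group analysis bookkeeping: foot metrics require foot length", {
  ch <- simulate_cohort(n_per_group = 8, seed = 30)
  res <- run_group_analysis(ch$table, ch$covariates)
  expect_true("to_angle_deg" %in% res$parameter)       # foot metric present
  cov2 <- ch$covariates[, setdiff(names(ch$covariates), "foot_length_m")]
  res2 <- run_group_analysis(ch$table, cov2)
  expect_false("to_angle_deg" %in% res2$parameter)     # excluded without it
  expect_true("abs_yaw_trunk" %in% res2$parameter)     # others unaffected
})

test_that("group analysis output carries family alphas and diagnostics", {
  ch <- simulate_cohort(n_per_group = 8, seed = 31)
  res <- run_group_analysis(ch$table, ch$covariates)
  expect_true(all(c("task", "parameter", "effect", "F", "p",
                    "partial_eta_sq", "family", "corrected_alpha",
                    "significant", "shapiro_p", "mauchly_p") %in% names(res)))
  expect_setequal(unique(res$effect), c("group", "protocol", "group:protocol"))
  fam <- default_families()
  for (i in seq_len(nrow(res))) {
    f <- fam[fam$task == res$task[i] & fam$metric_name == res$parameter[i], ]
    expect_equal(res$corrected_alpha[i], f$corrected_alpha[1])
  }
  expect_true(all(res$partial_eta_sq >= 0 & res$partial_eta_sq <= 1))
})

test_that("phase post hocs use the Bonferroni rule p_adj = min(1, 3p)", {
  ch <- simulate_cohort(n_per_group = 10, design = "phase",
                        effects = list(phase = list(
                          stride_velocity_m_s = c(Post = 0.3))), seed = 32)
  rp <- run_phase_analysis(ch$table)
  expect_true(nrow(rp$posthoc) >= 3)
  expect_equal(rp$posthoc$p_adjusted, pmin(1, 3 * rp$posthoc$p_raw))
  om <- rp$effects
  expect_true(all(c("mauchly_p", "p_gg", "p", "partial_eta_sq") %in% names(om)))
  # GG-corrected p is the reported p whenever Mauchly rejects
  viol <- is.finite(om$mauchly_p) & om$mauchly_p < 0.05 & is.finite(om$p_gg)
  expect_equal(om$p[viol], om$p_gg[viol])
})
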