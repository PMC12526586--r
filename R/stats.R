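# Study-level statistics: cluster-wise predictive-mean-matching multiple
# imputation with mean pooling, Bonferroni family-alpha bookkeeping,
# one-way random-effects ICC, group-by-protocol ANCOVA, and
# repeated-measures phase analysis with Bonferroni post hocs.

#' Bonferroni-corrected alpha for a parameter family
#'
#' `base / n_members`; families with a single member get no correction.
#' The reporting form follows the convention of printing 2 significant
#' digits.
#'
#' @param n_members Number of parameters in the family (>= 1).
#' @param base Family-wise alpha (default 0.05).
#' @return List with `alpha` (exact) and `reported` (rounded form).
#' @export
bonferroni_alpha <- function(n_members, base = 0.05) {
  if (n_members < 1) stop("n_members must be >= 1")
  a <- base / n_members
  list(alpha = a, reported = signif(a, 2))
}

#' Define a parameter family for alpha correction
#'
#' @param family_name Family label (e.g. `"upper_kinematic"`).
#' @param members Character vector of metric names in the family.
#' @param base_alpha Family-wise alpha (default 0.05).
#' @return Data frame mapping each member to the family and its corrected
#'   alpha.
#' @export
family_spec <- function(family_name, members, base_alpha = 0.05) {
  data.frame(family = family_name, metric_name = members,
             n_members = length(members),
             corrected_alpha = bonferroni_alpha(length(members), base_alpha)$alpha,
             stringsAsFactors = FALSE)
}

#' Default parameter families
#'
#' Family membership by parameter type (spatiotemporal, kinetic/COP,
#' upper/lower kinematics) for each task, mirroring the reported family
#' sizes: 7 upper-body kinematic + 2 COP parameters for chair
#' transitions, 11 kinematic + 2 gait + 2 COP for turning, and 19 gait +
#' 4 upper-body parameters for locomotion.
#'
#' @return Data frame with `task`, `family`, `metric_name`,
#'   `n_members`, `corrected_alpha`.
#' @export
default_families <- function() {
  fam <- function(task, name, members)
    cbind(task = task, family_spec(name, members))
  trans_kin <- c("peak_trunk_inclination_ap", "peak_trunk_inclination_ml",
                 "peak_trunk_velocity_ap", "rms_trunk_accel_ap",
                 "mean_trunk_jerk", "peak_pelvis_flexion", "peak_knee_flexion")
  trans_cop <- c("mean_cop_ap_mm", "mean_cop_ml_mm")
  turn_kin <- c("abs_yaw_head", "abs_yaw_trunk", "abs_yaw_pelvis",
                "rel_yaw_head_trunk", "rel_yaw_trunk_pelvis", "rel_yaw_head_pelvis",
                "onset_head_pct", "onset_trunk_pct", "onset_pelvis_pct",
                "peak_trunk_inclination_ap", "peak_trunk_inclination_ml")
  turn_gait <- c("to_angle_deg", "hs_angle_deg")
  loco_gait <- c("stride_length_m", "stride_width_m", "stride_time_s",
                 "stride_velocity_m_s", "double_support_pct",
                 "to_angle_deg", "hs_angle_deg", "min_foot_clearance_m",
                 "asym_length", "asym_time", "asym_velocity", "asym_width",
                 "asym_double_support",
                 "cv_length", "cv_time", "cv_velocity", "cv_width",
                 "cv_double_support", "fle_count")
  loco_upper <- c("total_swing_dominant", "total_swing_nondominant",
                  "asa_percent", "mean_arm_velocity")
  rbind(
    fam("sit_to_stand", "upper_kinematic", trans_kin),
    fam("sit_to_stand", "cop", trans_cop),
    fam("stand_to_sit", "upper_kinematic", trans_kin),
    fam("stand_to_sit", "cop", trans_cop),
    fam("turn", "kinematic", turn_kin),
    fam("turn", "gait", turn_gait),
    fam("turn", "cop", trans_cop),
    fam("locomotion_lap", "gait", loco_gait),
    fam("locomotion_lap", "upper_kinematic", loco_upper))
}

# Metrics whose models additionally adjust for foot length.
foot_length_metrics <- function() {
  c("to_angle_deg", "hs_angle_deg", "min_foot_clearance_m")
}

#' Predictive-mean-matching multiple imputation with mean pooling
#'
#' Within each cluster (by default group x protocol, or phase), `m`
#' imputed datasets are generated by PMM: for each incomplete variable a
#' linear model on the cluster's complete variables is fitted on a
#' bootstrap resample of complete cases, and each missing cell receives
#' the observed value of one of its `donor_k` nearest predicted-mean
#' donors. The final value is the mean of the `m` draws. Missing
#' fractions between 5% and 20% are noted as the band where multiple
#' imputation is recommended; above 20% a caution is emitted.
#'
#' @param table A [metric_table()] with `NA` values to impute.
#' @param cluster_keys Character vector of columns defining clusters
#'   (default `c("group", "protocol")`; use `"phase"` for the
#'   intervention design).
#' @param m Number of imputations (default 5).
#' @param donor_k Donor pool size (default 5).
#' @param seed RNG seed; imputation is fully reproducible given the seed.
#' @return List with `table` (completed [metric_table()]) and `report`
#'   (per variable: missing %, flags, and the per-cell draws, which are
#'   always observed donor values).
#' @export
impute_pmm <- function(table, cluster_keys = c("group", "protocol"),
                       m = 5, donor_k = 5, seed = 1) {
  if (m < 2) stop("m must be >= 2")
  df <- as.data.frame(table)
  set.seed(seed)
  df$..var <- paste(df$task, df$metric_name, sep = "|")
  df$..unit <- do.call(paste, c(df[c("subject_id", "protocol", "phase",
                                     "trial_index")], sep = "|"))
  df$..cluster <- do.call(paste, c(df[cluster_keys], sep = "|"))
  report <- NULL
  draws_log <- list()
  for (cl in unique(df$..cluster)) {
    rows <- which(df$..cluster == cl)
    wide <- stats::reshape(df[rows, c("..unit", "..var", "value")],
                           idvar = "..unit", timevar = "..var",
                           direction = "wide")
    units <- wide$..unit
    vmat <- as.matrix(wide[, -1, drop = FALSE])
    colnames(vmat) <- sub("^value\\.", "", colnames(wide)[-1])
    complete_vars <- colnames(vmat)[colSums(is.na(vmat)) == 0]
    for (v in colnames(vmat)) {
      miss <- which(is.na(vmat[, v]))
      pct <- 100 * length(miss) / nrow(vmat)
      flags <- character()
      if (pct > 20) flags <- c(flags, "missing_above_20pct")
      else if (pct > 5) flags <- c(flags, "in_recommended_band_5_20pct")
      if (length(miss)) {
        obs <- which(!is.na(vmat[, v]))
        if (!length(obs)) {
          flags <- c(flags, "no_donors")
        } else {
          preds <- setdiff(complete_vars, v)
          X <- cbind(`(Intercept)` = 1,
                     vmat[, preds, drop = FALSE])
          # guard against p >= n
          if (ncol(X) >= length(obs)) X <- X[, seq_len(max(1, length(obs) - 1)), drop = FALSE]
          draws <- matrix(NA_real_, length(miss), m)
          for (im in seq_len(m)) {
            boot <- sample(obs, length(obs), replace = TRUE)
            beta <- tryCatch(stats::lm.fit(X[boot, , drop = FALSE],
                                           vmat[boot, v])$coefficients,
                             error = function(e) NULL)
            if (is.null(beta)) beta <- c(mean(vmat[boot, v]), rep(0, ncol(X) - 1))
            beta[is.na(beta)] <- 0
            yhat <- drop(X %*% beta)
            for (j in seq_along(miss)) {
              dist <- abs(yhat[obs] - yhat[miss[j]])
              pool <- obs[order(dist)][seq_len(min(donor_k, length(obs)))]
              donor <- pool[sample.int(length(pool), 1)]
              draws[j, im] <- vmat[donor, v]
            }
          }
          pooled <- rowMeans(draws)
          vmat[miss, v] <- pooled
          draws_log[[paste(cl, v, sep = "::")]] <- draws
          # write back into df
          for (j in seq_along(miss)) {
            tgt <- rows[df$..unit[rows] == units[miss[j]] & df$..var[rows] == v]
            df$value[tgt] <- pooled[j]
          }
        }
      }
      report <- rbind(report, data.frame(cluster = cl, variable = v,
                                         missing_pct = pct,
                                         flags = paste(flags, collapse = ";"),
                                         stringsAsFactors = FALSE))
    }
  }
  if (any(grepl("missing_above_20pct", report$flags)))
    warning("variables with more than 20% missing: imputation may bias results")
  df$..var <- df$..unit <- df$..cluster <- NULL
  list(table = metric_table(df), report = report, draws = draws_log)
}

#' One-way random-effects intraclass correlation
#'
#' ICC(1,1) and ICC(1,k) from the one-way ANOVA mean squares:
#' `ICC(1,1) = (BMS - WMS) / (BMS + (k-1) WMS)`,
#' `ICC(1,k) = (BMS - WMS) / BMS`.
#'
#' @param ratings Numeric matrix, subjects x k trials, no missing cells.
#' @return List with `icc_single`, `icc_avg`, `F`, `df1`, `df2`, `p`,
#'   and `flags`.
#' @export
icc_oneway <- function(ratings) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  if (n < 2 || k < 2) stop("need >= 2 subjects and >= 2 trials")
  if (anyNA(ratings)) stop("no missing cells allowed")
  row_m <- rowMeans(ratings)
  grand <- mean(ratings)
  bms <- k * sum((row_m - grand)^2) / (n - 1)
  wms <- sum((ratings - row_m)^2) / (n * (k - 1))
  flags <- character()
  if (bms <= 0 || (bms + (k - 1) * wms) == 0) {
    flags <- "degenerate_variance"
    icc1 <- 0; icck <- 0
  } else {
    icc1 <- (bms - wms) / (bms + (k - 1) * wms)
    icck <- if (bms > 0) (bms - wms) / bms else 0
  }
  Fv <- if (wms > 0) bms / wms else Inf
  p <- stats::pf(Fv, n - 1, n * (k - 1), lower.tail = FALSE)
  list(icc_single = icc1, icc_avg = icck, F = Fv,
       df1 = n - 1, df2 = n * (k - 1), p = p, flags = flags)
}

#' Group-by-protocol ANCOVA across all metrics
#'
#' For each (task, metric): values averaged per subject and protocol and
#' fitted as a mixed design -- protocol as the within-subject factor,
#' group plus the covariates (`age`, `sex`, `height`) between subjects,
#' type-III tests with sum-to-zero contrasts; foot-dependent metrics
#' (toe-off angle, heel-strike angle, foot clearance) additionally adjust
#' for foot length. Treating protocol as within-subject keeps the group
#' test calibrated when the two protocol measurements of a subject are
#' correlated. Significance is judged against the metric's
#' family-corrected alpha; Shapiro-Wilk residual normality is attached.
#' With a two-level within factor sphericity holds trivially, so the
#' Mauchly diagnostic is reported as `NA` and no correction applies.
#'
#' @param table A complete [metric_table()] (post-imputation).
#' @param covariates Data frame with `subject_id`, `age`, `sex`,
#'   `height_m` and `foot_length_m`.
#' @param families Family mapping as from [default_families()].
#' @return Tidy data frame: `task`, `parameter`, `effect`, `F`, `df1`,
#'   `df2`, `p`, `partial_eta_sq`, `mauchly_p`, `family`,
#'   `corrected_alpha`, `significant`, `shapiro_p`.
#' @export
run_group_analysis <- function(table, covariates,
                               families = default_families()) {
  df <- as.data.frame(table)
  agg <- stats::aggregate(value ~ subject_id + group + protocol + task + metric_name,
                          df, mean, na.action = stats::na.omit)
  out <- NULL
  for (key in unique(paste(agg$task, agg$metric_name, sep = "|"))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    d <- agg[agg$task == parts[1] & agg$metric_name == parts[2], ]
    protos <- sort(unique(d$protocol))
    if (length(unique(d$group)) < 2 || length(protos) != 2) next
    needs_foot <- parts[2] %in% foot_length_metrics()
    if (needs_foot && !"foot_length_m" %in% names(covariates)) next
    # one row per subject: both protocol measurements side by side
    w <- merge(d[d$protocol == protos[1], c("subject_id", "group", "value")],
               d[d$protocol == protos[2], c("subject_id", "value")],
               by = "subject_id", suffixes = c("_1", "_2"))
    w <- merge(w, covariates, by = "subject_id")
    w <- w[stats::complete.cases(w[c("value_1", "value_2", "age", "sex",
                                     "height_m")]), , drop = FALSE]
    if (nrow(w) < 4 || length(unique(w$group)) < 2) next
    w$group <- factor(w$group); w$sex <- factor(w$sex)
    form <- cbind(value_1, value_2) ~ group + age + sex + height_m
    if (needs_foot) form <- stats::update(form, . ~ . + foot_length_m)
    fit <- tryCatch(stats::lm(form, data = w,
                              contrasts = list(group = "contr.sum",
                                               sex = "contr.sum")),
                    error = function(e) NULL)
    if (is.null(fit)) next
    idata <- data.frame(protocol = factor(protos))
    ut <- tryCatch({
      av <- car::Anova(fit, idata = idata, idesign = ~protocol, type = 3)
      summary(av, multivariate = FALSE)$univariate.tests
    }, error = function(e) NULL)
    if (is.null(ut)) next
    sw <- tryCatch(stats::shapiro.test(c(stats::residuals(fit)))$p.value,
                   error = function(e) NA_real_)
    fam <- families[families$task == parts[1] &
                    families$metric_name == parts[2], , drop = FALSE]
    fam_name <- if (nrow(fam)) fam$family[1] else "unfamilied"
    alpha <- if (nrow(fam)) fam$corrected_alpha[1] else 0.05
    for (eff in c("group", "protocol", "group:protocol")) {
      i <- which(rownames(ut) == eff)
      if (!length(i)) next
      ss <- ut[i, "Sum Sq"]; sse <- ut[i, "Error SS"]
      p <- ut[i, "Pr(>F)"]
      out <- rbind(out, data.frame(
        task = parts[1], parameter = parts[2], effect = eff,
        F = ut[i, "F value"], df1 = ut[i, "num Df"], df2 = ut[i, "den Df"],
        p = p, partial_eta_sq = ss / (ss + sse),
        mauchly_p = NA_real_,            # two within levels: trivially spherical
        family = fam_name, corrected_alpha = alpha,
        significant = p < alpha,
        shapiro_p = sw, stringsAsFactors = FALSE))
    }
  }
  out
}

#' Repeated-measures phase analysis with Bonferroni post hocs
#'
#' For each (task, metric): subjects' per-phase means arranged
#' Baseline/Pre/Post (incomplete subjects dropped and reported), a
#' repeated-measures ANOVA on the phase factor with Mauchly's sphericity
#' test and Greenhouse-Geisser correction on violation, and -- when the
#' phase effect is significant -- all three pairwise paired comparisons
#' with Bonferroni-adjusted p-values (`min(1, 3p)`), mean differences and
#' 95% confidence intervals.
#'
#' @param table A [metric_table()] with `phase` in Baseline/Pre/Post.
#' @param alpha Significance level for the phase effect (default 0.05).
#' @return List with `effects` (per metric: F, df, p, GG-corrected p,
#'   Mauchly p, partial eta squared, n) and `posthoc` (pairwise rows).
#' @export
run_phase_analysis <- function(table, alpha = 0.05) {
  df <- as.data.frame(table)
  phases <- c("Baseline", "Pre", "Post")
  agg <- stats::aggregate(value ~ subject_id + phase + task + metric_name,
                          df, mean, na.action = stats::na.omit)
  effects <- NULL; posthoc <- NULL
  for (key in unique(paste(agg$task, agg$metric_name, sep = "|"))) {
    parts <- strsplit(key, "|", fixed = TRUE)[[1]]
    d <- agg[agg$task == parts[1] & agg$metric_name == parts[2], ]
    wide <- stats::reshape(d[, c("subject_id", "phase", "value")],
                           idvar = "subject_id", timevar = "phase",
                           direction = "wide")
    cols <- paste0("value.", phases)
    if (!all(cols %in% names(wide))) next
    n_all <- nrow(wide)
    wide <- wide[stats::complete.cases(wide[, cols]), , drop = FALSE]
    if (nrow(wide) < 3) next
    Y <- as.matrix(wide[, cols])
    colnames(Y) <- phases
    fit <- stats::lm(Y ~ 1)
    idata <- data.frame(phase = factor(phases, levels = phases))
    av <- car::Anova(fit, idata = idata, idesign = ~phase, type = 3)
    s <- withCallingHandlers(
      summary(av, multivariate = FALSE),
      warning = function(w) {
        # Huynh-Feldt epsilon above 1 is routinely clamped; not actionable
        if (grepl("HF eps", conditionMessage(w))) invokeRestart("muffleWarning")
      })
    ut <- s$univariate.tests
    i <- which(rownames(ut) == "phase")
    ssn <- ut[i, "Sum Sq"]; sse <- ut[i, "Error SS"]
    p_unc <- ut[i, "Pr(>F)"]
    mau <- s$sphericity.tests
    mau_p <- if (!is.null(mau) && nrow(mau)) mau[1, "p-value"] else NA_real_
    pva <- s$pval.adjustments
    gg_p <- if (!is.null(pva) && "phase" %in% rownames(pva))
      pva["phase", "Pr(>F[GG])"] else NA_real_
    p_use <- if (is.finite(mau_p) && mau_p < 0.05 && is.finite(gg_p)) gg_p else p_unc
    effects <- rbind(effects, data.frame(
      task = parts[1], parameter = parts[2],
      F = ut[i, "F value"], df1 = ut[i, "num Df"], df2 = ut[i, "den Df"],
      p_uncorrected = p_unc, mauchly_p = mau_p, p_gg = gg_p, p = p_use,
      partial_eta_sq = ssn / (ssn + sse),
      n = nrow(wide), n_dropped = n_all - nrow(wide),
      significant = p_use < alpha, stringsAsFactors = FALSE))
    if (is.finite(p_use) && p_use < alpha) {
      combs <- list(c("Baseline", "Pre"), c("Baseline", "Post"), c("Pre", "Post"))
      for (cb in combs) {
        tt <- stats::t.test(Y[, cb[1]], Y[, cb[2]], paired = TRUE)
        posthoc <- rbind(posthoc, data.frame(
          task = parts[1], parameter = parts[2],
          comparison = paste(cb, collapse = "-"),
          mean_difference = unname(tt$estimate),
          ci_lo = tt$conf.int[1], ci_hi = tt$conf.int[2],
          t = unname(tt$statistic),
          p_raw = tt$p.value,
          p_adjusted = min(1, 3 * tt$p.value), stringsAsFactors = FALSE))
      }
    }
  }
  list(effects = effects, posthoc = posthoc)
}
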