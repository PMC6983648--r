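test_that("mixed-design sums of squares match the cell-means oracle", {
  df <- balanced_toy_table()
  an <- rm_anova(df, check_assumptions = FALSE)
  oracle <- anova_ss_oracle(df)

  eff <- an$effects
  get_ss <- function(e) eff$SS[eff$effect == e]
  expect_equal(get_ss("group"), oracle$group, tolerance = 1e-8)
  expect_equal(get_ss("day"), oracle$day, tolerance = 1e-8)
  expect_equal(get_ss("day:group"), oracle$day_group, tolerance = 1e-8)
  expect_equal(get_ss("side"), oracle$side, tolerance = 1e-8)
  expect_equal(get_ss("group:side"), oracle$side_group, tolerance = 1e-8)
  expect_equal(get_ss("day:side"), oracle$day_side, tolerance = 1e-8)
  expect_equal(get_ss("group:day:side"), oracle$day_group_side,
               tolerance = 1e-8)
  err_ss <- unique(eff[c("error_stratum", "SS_error")])$SS_error
  expect_equal(sort(err_ss),
               sort(c(oracle$subj_err, oracle$day_subj_err,
                      oracle$side_subj_err, oracle$day_side_subj_err)),
               tolerance = 1e-8)
  # full decomposition recovers the total sum of squares
  expect_equal(sum(eff$SS) + sum(err_ss), oracle$total, tolerance = 1e-8)
})

test_that("the 12-animal design reproduces the expected df structure", {
  tab <- aggregate_measurements(generate_cohort_study(seed = 2))
  an <- rm_anova(tab, check_assumptions = FALSE)
  eff <- an$effects
  pick <- function(e) eff[eff$effect == e, ]
  expect_equal(unname(unlist(pick("group")[c("df", "df_error")])), c(1, 10))
  expect_equal(unname(unlist(pick("day")[c("df", "df_error")])), c(5, 50))
  expect_equal(unname(unlist(pick("day:group")[c("df", "df_error")])),
               c(5, 50))
  expect_equal(unname(unlist(pick("side")[c("df", "df_error")])), c(1, 10))
  expect_equal(unname(unlist(pick("day:side")[c("df", "df_error")])),
               c(5, 50))
  expect_true(all(eff$partial_eta_sq >= 0 & eff$partial_eta_sq <= 1))
})

test_that("constant responses yield zero SS and flagged F statistics", {
  df <- balanced_toy_table()
  df$bf <- 7
  an <- rm_anova(df, check_assumptions = FALSE)
  expect_lt(max(abs(an$effects$SS)), 1e-10)
  expect_true(all(is.nan(an$effects$F)))
  expect_true(all(an$effects$partial_eta_sq == 0))
})

test_that("unaggregated repeats are rejected with guidance", {
  tab <- generate_cohort_study(seed = 2)
  expect_error(rm_anova(tab), "aggregate")
})

test_that("Mauchly test matches a direct contrast-covariance computation", {
  set.seed(31)
  n <- 10; days <- paste0("d", 1:3)
  df <- expand.grid(animal = sprintf("A%02d", 1:n), day = days,
                    side = c("L", "R"), stringsAsFactors = FALSE)
  df$group <- ifelse(as.integer(sub("A", "", df$animal)) <= 5, "g1", "g2")
  df$bf <- rnorm(nrow(df), 10, 2) +
    rep(rnorm(n * 3, 0, 1.5), 2)  # correlated within animal-day
  mres <- mauchly_sphericity(df, "time")

  # oracle: orthonormal day contrasts of the per-animal cell vectors
  # (constant within day across sides), pooled residual covariance after
  # removing group means
  cells <- tapply(df$bf, list(df$animal, df$day, df$side), mean)
  Ysum <- cells[, , "L"] + cells[, , "R"]
  H <- cbind(c(1, -1, 0) / sqrt(2), c(-1, -1, 2) / sqrt(6))
  Z <- (Ysum %*% H) / sqrt(2)
  grp <- tapply(df$group, df$animal, function(x) x[1])[rownames(Z)]
  R <- stats::residuals(stats::lm(Z ~ grp))
  nd <- n - 2
  S <- crossprod(R) / nd
  k <- 2
  W <- det(S) / (sum(diag(S)) / k)^k
  expect_equal(mres$W, W, tolerance = 1e-8)
  dfw <- k * (k + 1) / 2 - 1
  fac <- 1 - (2 * k^2 + k + 2) / (6 * k * nd)
  p_ref <- pchisq(-nd * fac * log(W), dfw, lower.tail = FALSE)
  expect_equal(mres$p, p_ref, tolerance = 1e-6)
})

test_that("two-level within effects are trivially spherical", {
  tab <- aggregate_measurements(generate_cohort_study(seed = 2))
  m <- mauchly_sphericity(tab, "side")
  expect_equal(m$p, 1)
  expect_equal(m$W, 1)
  expect_match(m$note, "trivially")
})

test_that("near-identity contrast covariance gives W close to 1", {
  set.seed(7)
  n <- 80
  df <- expand.grid(animal = sprintf("A%02d", 1:n), day = paste0("d", 1:3),
                    side = c("L", "R"), stringsAsFactors = FALSE)
  df$group <- "g1"
  df$bf <- rnorm(nrow(df))
  m <- mauchly_sphericity(df, "time")
  expect_gt(m$W, 0.85)
  expect_true(m$p >= 0 && m$p <= 1)
})

test_that("Tukey comparisons reproduce a hand-computed studentized range", {
  # 4 subjects x 3 days, one group, one side
  set.seed(12)
  y <- matrix(rnorm(12, 10, 2), 4, 3)
  y[, 3] <- y[, 3] + 5
  df <- data.frame(animal = rep(sprintf("A%d", 1:4), 3),
                   group = "g1",
                   day = rep(paste0("d", 1:3), each = 4),
                   side = "L", bf = as.vector(y))
  # duplicate side so the frame matches the two-side layout
  df <- rbind(df, transform(df, side = "R"))
  tk <- tukey_hsd_time(df)

  means <- colMeans(y)
  resid <- y - rowMeans(y) - rep(means, each = 4) + mean(y)
  ms_e <- sum(resid^2) / (3 * 2)
  q13 <- abs(means[3] - means[1]) / sqrt(ms_e / 4)
  row <- tk[tk$day_a == "d1" & tk$day_b == "d3", ]
  expect_equal(row$q, q13, tolerance = 1e-10)
  expect_equal(row$p_adj, ptukey(q13, 3, 6, lower.tail = FALSE),
               tolerance = 1e-10)
})

test_that("equal time means produce no significant Tukey pairs", {
  tab <- aggregate_measurements(generate_cohort_study(
    study_design(time_effect = setNames(rep(0, 11), study_design()$timepoints),
                 group_effect = setNames(rep(0, 11), study_design()$timepoints),
                 cohort_day_sd = 0),
    seed = 14))
  tk <- tukey_hsd_time(tab)
  expect_equal(nrow(tk), choose(6, 2))
  expect_true(all(!tk$significant[tk$p_adj > 0.05]))
  expect_lt(mean(tk$significant), 0.2)
})

test_that("a planted day-10 elevation is flagged against the first baseline", {
  hits <- vapply(1:60, function(s) {
    tab <- aggregate_measurements(generate_cohort_study(seed = 400 + s))
    tk <- tukey_hsd_time(tab)
    tk$significant[tk$day_a == "B1" & tk$day_b == "10"]
  }, logical(1))
  expect_gte(mean(hits), 0.8)
})

test_that("heart-rate confound correlation matches closed-form arithmetic", {
  # proportional HR: every animal-day correlation is exactly 1
  rec <- expand.grid(animal = c("A1", "A2"), day = c("d1", "d2"),
                     side = c("L", "R"), rep = 1:2,
                     stringsAsFactors = FALSE)
  set.seed(3)
  rec$bf <- rnorm(nrow(rec), 10, 2)
  rec$hr <- 300 + 5 * rec$bf
  hc <- hr_confound(rec)
  expect_equal(hc$average_r, 1, tolerance = 1e-12)
  expect_equal(hc$n_coefficients, 4L)

  # fixed 4-point closed form
  rec1 <- rec[rec$animal == "A1" & rec$day == "d1", ]
  rec1$hr <- c(310, 305, 330, 318)
  rec_mix <- rbind(rec1, rec[!(rec$animal == "A1" & rec$day == "d1"), ])
  hc2 <- hr_confound(rec_mix)
  r_manual <- cor(rec1$bf, rec1$hr)
  expect_equal(hc2$per_day$r[hc2$per_day$animal == "A1" &
                               hc2$per_day$day == "d1"],
               r_manual, tolerance = 1e-12)
})

test_that("independent heart rate gives near-zero average correlation", {
  des <- study_design(hr_bf_slope = 0, missing_repeat_prob = 0,
                      hep_hazard = 0)
  rs <- vapply(1:8, function(s)
    hr_confound(generate_cohort_study(des, seed = 600 + s))$average_r,
    numeric(1))
  n_terms <- 8 * 12 * 11  # replicates x animals x days
  expect_lt(abs(mean(rs)), 3 / sqrt(3) / sqrt(n_terms))
})

test_that("well-separated cohorts are recovered and order-invariant", {
  skip_if_not_installed("mclust")
  # simplex-like planting: each experimental cohort elevated on its own
  # timepoint, so the four clusters are equidistant and well separated
  des <- study_design(cohort_effect_sd = 0, cohort_severity_sd = 0,
                      cohort_day_sd = 0, animal_effect_sd = 0.5,
                      within_animal_sd = 1, hr_bf_slope = 0,
                      hep_hazard = 0, missing_repeat_prob = 0,
                      time_effect = setNames(rep(0, 11),
                                             study_design()$timepoints),
                      group_effect = setNames(rep(0, 11),
                                              study_design()$timepoints))
  tab <- generate_cohort_study(des, seed = 77)
  sig_day <- c(C2 = "B2", C3 = "5", C4 = "10", C5 = "15")
  sel <- tab$group == "experimental" & tab$day == sig_day[tab$cohort]
  tab$bf[sel] <- tab$bf[sel] + 8
  agg <- aggregate_measurements(tab)
  cl <- cohort_clustering(agg, seed = 5)
  expect_equal(cl$k, 4L)

  truth <- attr(tab, "ground_truth")
  coh <- truth$cohort[match(names(cl$partition), truth$animal)]
  ari <- mclust::adjustedRandIndex(cl$partition, coh)
  expect_gt(ari, 0.9)
  expect_equal(cl$kmeans_agreement, 1)
  expect_true(cl$stable)

  # explicit row permutation of the input table
  set.seed(9)
  perm_tab <- agg[sample(nrow(agg)), ]
  cl2 <- cohort_clustering(perm_tab, seed = 5)
  expect_equal(cl2$k, cl$k)
  expect_equal(cl2$partition[names(cl$partition)], cl$partition)
})

test_that("identical feature rows collapse to a single cluster", {
  tab <- aggregate_measurements(generate_cohort_study(
    study_design(cohort_effect_sd = 0, cohort_severity_sd = 0,
                 cohort_day_sd = 0, animal_effect_sd = 0,
                 within_animal_sd = 0, hr_bf_slope = 0,
                 missing_repeat_prob = 0, hep_hazard = 0), seed = 1))
  cl <- cohort_clustering(tab)
  expect_equal(cl$k, 1L)
})
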