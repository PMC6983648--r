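test_that("arterial input function has bolus shape, zero before injection", {
  ca <- generate_airf()
  expect_true(all(ca$values[ca$times < 10] == 0))
  expect_true(all(ca$values >= 0))
  # exactly one global maximum
  expect_equal(sum(ca$values == max(ca$values)), 1L)

  z <- generate_airf(bolus_model(dose_amplitude = 0))
  expect_true(all(z$values == 0))

  expect_error(generate_airf(times = c(0, 2, 1)), "increasing")
})

test_that("gamma-variate first-pass area matches the closed form", {
  m <- bolus_model(recirculation_fraction = 0)
  # closed form of amp * (t / (a b))^a * exp(a - t / b) integrated over t>0
  a <- m$alpha; b <- m$beta
  analytic <- m$dose_amplitude * exp(a) / (a * b)^a * b^(a + 1) * gamma(a + 1)
  quad <- stats::integrate(function(t)
    m$dose_amplitude * (t / (a * b))^a * exp(a - t / b), 0, Inf,
    rel.tol = 1e-10)$value
  expect_equal(quad, analytic, tolerance = 1e-3)
  # and the sampled curve integrates to the same area on a fine grid
  tt <- seq(0, 400, by = 0.01)
  ca <- generate_airf(m, times = tt + m$injection_time)
  expect_equal(sum(ca$values) * 0.01, analytic, tolerance = 1e-3)
})

test_that("tissue curve is a causal, delayed, low-amplitude copy", {
  pr <- noiseless_pair(15)
  expect_equal(pr$q$values[1], 0)
  expect_true(all(pr$q$values >= 0))
  expect_gte(which.max(pr$q$values), which.max(pr$ca$values))
  ratio <- max(pr$ca$values) / max(pr$q$values)
  expect_gt(ratio, 50)
  expect_lt(ratio, 200)

  z <- generate_tissue_curve(pr$ca, perfusion_truth(bf_true = 0))
  expect_true(all(z$values == 0))
  expect_error(perfusion_truth(bf_true = -1), "nonnegative")
})

test_that("delta-like arterial input reproduces the scaled residue", {
  times <- seq(0, 60, by = 0.5)
  spike <- concentration_curve(times, c(0, 5, rep(0, length(times) - 2)),
                               role = "arterial")
  truth <- perfusion_truth(bf_true = 20)
  q <- generate_tissue_curve(spike, truth)
  f <- truth$bf_true * truth$tissue_density / 6000
  expected <- 0.5 * 5 * f * residue_function(truth, times - times[2])
  expect_equal(q$values, expected, tolerance = 1e-10)
})

test_that("DTOF generator is deterministic and monotone in absorption", {
  sc <- small_scene()
  irf <- synthetic_irf(sc)
  mua <- seq(0.15, 0.19, length.out = 5)

  s1 <- generate_dtof_series(sc, mua, irf, counts_per_frame = 1e4, seed = 11)
  s2 <- generate_dtof_series(sc, mua, irf, counts_per_frame = 1e4, seed = 11)
  expect_identical(s1$counts, s2$counts)
  expect_true(all(s1$counts >= 0))
  expect_true(all(s1$counts == round(s1$counts)))

  # expected total counts strictly decrease as absorption rises
  s0 <- generate_dtof_series(sc, mua, irf, counts_per_frame = 1e5,
                             seed = 1, noise = FALSE)
  expect_true(all(diff(rowSums(s0$counts)) < 0))

  # identical absorption, noise off: identical frames
  sflat <- generate_dtof_series(sc, rep(0.15, 4), irf, seed = 1, noise = FALSE)
  expect_equal(max(abs(sweep(sflat$counts, 2, sflat$counts[1, ]))), 0)

  expect_error(generate_dtof_series(sc, c(0.1, 0), irf), "> 0")
})

test_that("phantom titration follows the dilution arithmetic and spans the range", {
  ser <- generate_phantom_series(n_steps = 3, frames_per_step = 2,
                                 counts_per_frame = 1e3, seed = 1)
  v <- ser$increment_volume; V0 <- ser$base_volume; cs <- ser$ink_stock_conc
  for (k in 1:3)
    expect_equal(ser$steps$cumulative_ink_conc[k],
                 k * v * cs / (V0 + k * v), tolerance = 1e-12)

  full <- generate_phantom_series(n_steps = 10, frames_per_step = 2,
                                  counts_per_frame = 1e3, seed = 1)
  expect_true(all(diff(full$steps$expected_delta_mua) > 0))
  expect_lte(min(full$steps$expected_delta_mua), 0.005 + 1e-12)
  expect_gte(max(full$steps$expected_delta_mua), 0.040)

  expect_error(generate_phantom_series(n_steps = 0), ">= 1")
})

test_that("study generator honors degenerate and missing-data settings", {
  des0 <- study_design(cohort_effect_sd = 0, cohort_severity_sd = 0,
                       cohort_day_sd = 0,
                       animal_effect_sd = 0, within_animal_sd = 0,
                       hr_bf_slope = 0, missing_repeat_prob = 0,
                       hep_hazard = 0,
                       time_effect = setNames(rep(0, 11),
                                              study_design()$timepoints),
                       group_effect = setNames(rep(0, 11),
                                               study_design()$timepoints))
  tab <- generate_cohort_study(des0, seed = 3)
  expect_true(all(tab$bf == tab$bf[1]))
  expect_equal(tab$bf[1], des0$bf_baseline)

  expect_error(study_design(n_control = 0, n_experimental = 0))

  t1 <- generate_cohort_study(seed = 9)
  t2 <- generate_cohort_study(seed = 9)
  expect_identical(t1$bf, t2$bf)
})

test_that("missing-repeat fraction matches the binomial expectation", {
  # large design for a tight binomial check: many ankle-days
  des <- study_design(n_control = 20, n_experimental = 40,
                      hep_hazard = 0, missing_repeat_prob = 0.1)
  tab <- generate_cohort_study(des, seed = 21)
  key <- interaction(tab$animal, tab$day, tab$side, drop = TRUE)
  n_rep <- tabulate(key)
  n_ad <- nlevels(key)
  frac_single <- mean(n_rep == 1)
  se <- sqrt(0.1 * 0.9 / n_ad)
  expect_lt(abs(frac_single - 0.1), 3 * se)
})

test_that("study generator marginal means match the design within MC error", {
  des <- study_design(hep_hazard = 0, missing_repeat_prob = 0)
  nrep <- 60
  day5_ctrl <- day5_exp <- numeric(nrep)
  for (i in seq_len(nrep)) {
    tab <- generate_cohort_study(des, seed = 1000 + i)
    d5 <- tab[tab$day == "5", ]
    day5_ctrl[i] <- mean(d5$bf[d5$group == "control"])
    day5_exp[i] <- mean(d5$bf[d5$group == "experimental"])
  }
  sev_gain <- exp(des$cohort_severity_sd^2 / 2)  # lognormal severity mean
  exp_ctrl <- des$bf_baseline + des$time_effect[["5"]]
  exp_exp <- exp_ctrl + sev_gain * des$group_effect[["5"]]
  expect_lt(abs(mean(day5_ctrl) - exp_ctrl),
            3 * sd(day5_ctrl) / sqrt(nrep))
  expect_lt(abs(mean(day5_exp) - exp_exp),
            3 * sd(day5_exp) / sqrt(nrep))
})

test_that("experimental dropout leaves the day-15 window complete", {
  tab <- generate_cohort_study(seed = 4)
  agg <- aggregate_measurements(tab)
  days <- complete_timepoints(agg)
  expect_true(all(c("B1", "B2", "B3", "5", "10", "15") %in% days))
  # hazard 0.5 per interval: some experimental animal leaves before day 40
  gt <- attr(tab, "ground_truth")
  expect_true(any(is.finite(gt$hep_day)))
  expect_true(all(gt$hep_day > 15, na.rm = TRUE))
})
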