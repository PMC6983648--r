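test_that("mean time of flight is the count-weighted bin-center mean", {
  d <- dtof(c(0, 0, 5, 0), bin_width = 1.0, t0 = 0.5)
  expect_equal(mean_time_of_flight(d), 2.5)

  d2 <- dtof(c(1, 2, 1), bin_width = 1.0, t0 = 1.0)
  expect_equal(mean_time_of_flight(d2), 2.0)

  d3 <- dtof(c(3, 0, 1), bin_width = 1.0, t0 = 1.0)
  expect_equal(mean_time_of_flight(d3), 1.5)

  expect_error(mean_time_of_flight(dtof(c(0, 0), 1)), "total counts")
  tm <- mean_time_of_flight(d2)
  expect_gte(tm, d2$bin_centers[1])
  expect_lte(tm, d2$bin_centers[3])
})

test_that("pathlength follows (c/n) times the mean-time difference", {
  irf <- dtof(c(10, 0, 0, 0), bin_width = 0.5, t0 = 0.25, role = "IRF")
  same <- dtof(c(10, 0, 0, 0), bin_width = 0.5, t0 = 0.25)
  expect_equal(pathlength(same, irf)$p, 0)

  shifted <- dtof(c(0, 10, 0, 0), bin_width = 0.5, t0 = 0.25)
  pl <- pathlength(shifted, irf, n_tissue = 1.4)
  expect_equal(pl$p, 29.9792458 / 1.4 * 0.5, tolerance = 1e-12)
  expect_equal(pl$n_tissue, 1.4)

  expect_warning(pathlength(irf, shifted), "nonphysical")
  expect_equal(suppressWarnings(pathlength(irf, shifted)$p),
               -29.9792458 / 1.4 * 0.5)
})

test_that("absorption-change inversion matches the Beer-Lambert arithmetic", {
  # point-mass histograms engineered for a known baseline pathlength
  bw <- 0.1
  nb <- 40L
  dt_bin <- function(at, scale = 1) {
    cts <- numeric(nb); cts[at] <- 1e6 * scale; cts
  }
  # IRF at bin 5, baseline DTOF at bin 5 + k so p = (c/n) * k * bw
  k <- round(20 * 1.4 / 29.9792458 / bw)  # p close to 20 cm
  p_true <- 29.9792458 / 1.4 * k * bw
  counts <- rbind(dt_bin(5 + k), dt_bin(5 + k),
                  dt_bin(5 + k, exp(-0.2)))
  stack <- list(counts = counts, bin_centers = bw * (seq_len(nb) - 0.5),
                bin_width = bw, times = c(0, 1, 11))
  irf <- dtof(dt_bin(5), bw, role = "IRF")
  ac <- delta_mua_timecourse(stack, irf, baseline_window = c(0, 10))
  expect_equal(ac$delta_mua[1:2], c(0, 0))
  expect_equal(ac$delta_mua[3], 0.2 / p_true, tolerance = 1e-12)
  expect_equal(ac$pathlength_used, p_true, tolerance = 1e-12)
})

test_that("baseline delta_mua is zero-mean and linear in attenuation", {
  sc <- small_scene()
  irf <- synthetic_irf(sc)
  dm <- c(rep(0, 20), seq(0, 0.01, length.out = 30))
  st <- generate_dtof_series(sc, sc$mu_a_baseline + dm, irf,
                             frame_period = 0.3, seed = 1, noise = FALSE)
  ac <- delta_mua_timecourse(st, irf, baseline_window = c(0, 6))
  expect_equal(mean(ac$delta_mua[st$times < 6]), 0, tolerance = 1e-10)

  # attenuation scaled by alpha scales delta_mua by alpha (noise off)
  att <- log(ac$I0 / ac$intensity)
  I_scaled <- ac$I0 * exp(-2 * att)
  st2 <- st
  st2$counts <- st$counts * (I_scaled / rowSums(st$counts))
  ac2 <- delta_mua_timecourse(st2, irf, baseline_window = c(0, 6))
  expect_equal(ac2$delta_mua, 2 * ac$delta_mua, tolerance = 1e-8)
})

test_that("injected absorption changes are recovered across the probed range", {
  sc <- small_scene()
  irf <- synthetic_irf(sc)
  dm <- c(rep(0, 10), seq(0.005, 0.040, by = 0.005))
  st <- generate_dtof_series(sc, sc$mu_a_baseline + dm, irf,
                             frame_period = 1, seed = 1, noise = FALSE)
  # chord pathlength removes the linearization curvature: 1% everywhere
  acc <- delta_mua_timecourse(st, irf, baseline_window = c(0, 10),
                              pathlength_mode = "chord")
  rec <- acc$delta_mua[st$times >= 10]
  expect_lt(max(abs(rec - dm[-(1:10)]) / dm[-(1:10)]), 0.01)

  # fixed baseline pathlength: accurate at in-vivo amplitudes, with the
  # documented negative curvature bias growing toward 0.04 per cm
  acb <- delta_mua_timecourse(st, irf, baseline_window = c(0, 10))
  recb <- acb$delta_mua[st$times >= 10]
  rel <- (recb - dm[-(1:10)]) / dm[-(1:10)]
  expect_lt(max(abs(rel[dm[-(1:10)] <= 0.0151]))  , 0.016)
  expect_true(all(rel < 0))
  expect_true(all(abs(rel) < 0.06))
})

test_that("zero-count frames are masked and interpolated with a warning", {
  sc <- small_scene()
  irf <- synthetic_irf(sc)
  st <- generate_dtof_series(sc, rep(sc$mu_a_baseline, 30), irf,
                             seed = 1, noise = FALSE)
  st$counts[15, ] <- 0
  expect_warning(ac <- delta_mua_timecourse(st, irf, baseline_window = c(0, 3)),
                 "masked")
  expect_true(all(is.finite(ac$delta_mua)))
  expect_equal(ac$masked, 15L)
})

test_that("shot-noise on recovered delta_mua scales as one over root counts", {
  sc <- small_scene()
  irf <- synthetic_irf(sc)
  levels <- c(1e4, 1e5, 1e6)
  sds <- vapply(seq_along(levels), function(i) {
    st <- generate_dtof_series(sc, rep(sc$mu_a_baseline, 220), irf,
                               counts_per_frame = levels[i],
                               seed = 100 + i)
    ac <- delta_mua_timecourse(st, irf, baseline_window = c(0, 6))
    sd(ac$delta_mua[st$times >= 6])
  }, numeric(1))
  slope <- coef(lm(log(sds) ~ log(levels)))[2]
  expect_lt(abs(slope + 0.5), 0.05)
})

test_that("ink and ICG conversions use consistent decadic conventions", {
  expect_equal(expected_ink_delta_mua(0, 0.25), 0)
  # eps * conc = 0.01 in decadic units
  expect_equal(expected_ink_delta_mua(0.04, 0.25),
               log(10) * 0.885 * 0.01, tolerance = 1e-12)
  expect_equal(expected_ink_delta_mua(0.04, 0.25), 0.0203784,
               tolerance = 1e-4)
  expect_error(expected_ink_delta_mua(-1, 0.25), "nonnegative")

  ac <- structure(list(times = 0:2, delta_mua = c(0, 0.00857, 0.02)),
                  class = "absorption_curve")
  q <- to_icg_concentration(ac, eps_icg = 0.186)
  expect_equal(q$values[2], 0.00857 / (log(10) * 0.186), tolerance = 1e-12)
  expect_equal(q$values[1], 0)
  # round trip is the identity to machine precision
  back <- icg_concentration_to_delta_mua(q, eps_icg = 0.186)
  expect_equal(back, ac$delta_mua, tolerance = 1e-15)
})
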