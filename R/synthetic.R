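#' Optical scene description for the slab forward model
#'
#' Defaults describe a rat ankle joint in transmission at 805 nm: about 1 cm
#' of moderately scattering, moderately absorbing tissue measured with a
#' TCSPC system running at 80 MHz (12.5 ns histogram window).
#'
#' @param mu_a_baseline Baseline absorption coefficient, per cm.
#' @param mu_s_prime Reduced scattering coefficient, per cm.
#' @param thickness Slab thickness, cm.
#' @param n_tissue Refractive index (>= 1).
#' @param bin_width Histogram bin width, ns.
#' @param n_bins Number of histogram bins.
#' @return Object of class `optical_scene`.
#' @export
optical_scene <- function(mu_a_baseline = 0.15, mu_s_prime = 10,
                          thickness = 1.0, n_tissue = 1.4,
                          bin_width = 0.0125, n_bins = 1000L) {
  stopifnot(mu_a_baseline > 0, mu_s_prime > 0, thickness > 0,
            n_tissue >= 1, bin_width > 0, n_bins >= 10)
  structure(list(mu_a_baseline = mu_a_baseline, mu_s_prime = mu_s_prime,
                 thickness = thickness, n_tissue = n_tissue,
                 bin_width = bin_width, n_bins = as.integer(n_bins)),
            class = "optical_scene")
}

#' Tissue-mimicking phantom scene (0.8% Intralipid in a 1 cm cuvette)
#' @param ... Overrides passed to [optical_scene()].
#' @export
phantom_scene <- function(...) {
  defaults <- list(mu_a_baseline = 0.02, mu_s_prime = 8, thickness = 1.0)
  do.call(optical_scene, utils::modifyList(defaults, list(...)))
}

#' Bolus kinetics model for the arterial input function
#'
#' Gamma-variate first pass plus a delayed, scaled copy for recirculation;
#' the standard indicator-dilution parameterization. Defaults emulate a rat
#' tail-vein ICG bolus injected 10 s into a 120 s acquisition, with a peak
#' arterial concentration of a few uM (0.2 mg/kg dose scale).
#'
#' @param injection_time Injection time, s.
#' @param dose_amplitude Peak arterial concentration of the first pass, uM.
#' @param alpha Gamma-variate shape (> 0).
#' @param beta Gamma-variate scale, s (> 0).
#' @param recirculation_fraction Amplitude fraction of the recirculation
#'   bump, in [0, 1).
#' @param recirculation_delay Delay of the recirculation bump, s.
#' @return Object of class `bolus_model`.
#' @export
bolus_model <- function(injection_time = 10, dose_amplitude = 4,
                        alpha = 3, beta = 1.8,
                        recirculation_fraction = 0.15,
                        recirculation_delay = 12) {
  stopifnot(injection_time >= 0, dose_amplitude >= 0, alpha > 0, beta > 0,
            recirculation_fraction >= 0, recirculation_fraction < 1,
            recirculation_delay >= 0)
  structure(as.list(environment()), class = "bolus_model")
}

#' Ground-truth perfusion state for forward simulation
#'
#' The impulse residue function R(t) is the fraction of an ideal
#' instantaneous bolus still inside the tissue at time t; R(0) = 1 and R is
#' non-increasing. The default family has a minimum-transit-time plateau
#' followed by exponential washout: `R(t) = 1` for `t <= t_plateau`,
#' `exp(-(t - t_plateau) / tau)` after. The flow-scaled unknown recovered by
#' deconvolution is `h(t) = f * R(t)` with
#' `f = bf_true * tissue_density / 6000` in 1/s.
#'
#' @param bf_true Blood flow, mL/min/100 g (>= 0).
#' @param residue_shape List with `family` (`"plateau_exp"` or `"exp"`) and
#'   its parameters (`t_plateau`, `tau` in s).
#' @param tissue_density Tissue density, g/mL.
#' @return Object of class `perfusion_truth`.
#' @export
perfusion_truth <- function(bf_true = 15,
                            residue_shape = list(family = "plateau_exp",
                                                 t_plateau = 2, tau = 4),
                            tissue_density = nirs_constants$rho_tissue) {
  if (bf_true < 0) stop("'bf_true' must be nonnegative")
  stopifnot(tissue_density > 0)
  structure(list(bf_true = bf_true, residue_shape = residue_shape,
                 tissue_density = tissue_density),
            class = "perfusion_truth")
}

#' Evaluate the impulse residue function of a ground-truth state
#' @param truth A [perfusion_truth()].
#' @param t Times, s.
#' @return R(t), dimensionless in [0, 1].
#' @export
residue_function <- function(truth, t) {
  rs <- truth$residue_shape
  switch(rs$family,
    plateau_exp = ifelse(t < 0, 0,
                         ifelse(t <= rs$t_plateau, 1,
                                exp(-(t - rs$t_plateau) / rs$tau))),
    exp = ifelse(t < 0, 0, exp(-t / rs$tau)),
    stop("unknown residue family: ", rs$family)
  )
}

#' Generate a synthetic arterial input function
#'
#' @param model A [bolus_model()].
#' @param times Strictly increasing time grid, s.
#' @return An arterial [concentration_curve()].
#' @export
generate_airf <- function(model = bolus_model(), times = seq(0, 119.7, by = 0.3)) {
  if (is.unsorted(times, strictly = TRUE))
    stop("time grid must be strictly increasing")
  gv <- function(tr) {
    out <- numeric(length(tr))
    pos <- tr > 0
    tp <- model$alpha * model$beta
    out[pos] <- (tr[pos] / tp)^model$alpha * exp(model$alpha - tr[pos] / model$beta)
    out
  }
  tr <- times - model$injection_time
  v <- model$dose_amplitude *
    (gv(tr) + model$recirculation_fraction * gv(tr - model$recirculation_delay))
  concentration_curve(times, v, role = "arterial")
}

# shared causal quadrature: q_k = dt * sum_{j<=k} ca_j * h_{k-j+1}.
# The deconvolution stage discretizes the convolution with the same rule, so
# noiseless generation followed by deconvolution is exact.
convolve_causal <- function(ca, h, dt) {
  n <- length(ca)
  full <- stats::convolve(ca, rev(h), type = "open")
  dt * full[seq_len(n)]
}

#' Generate a tissue ICG concentration curve from an arterial curve
#'
#' Forward model `Q(t) = f * (Ca (*) R)(t)` with `f = bf * rho / 6000` per
#' second, discretized with the same causal quadrature the deconvolution
#' inverts.
#'
#' @param airf Arterial [concentration_curve()] on a uniform grid.
#' @param truth A [perfusion_truth()].
#' @return A tissue [concentration_curve()].
#' @export
generate_tissue_curve <- function(airf, truth = perfusion_truth()) {
  dt <- diff(airf$times)
  if (max(abs(dt - dt[1])) > 1e-8 * dt[1])
    stop("arterial curve must be sampled on a uniform grid")
  f <- truth$bf_true * truth$tissue_density / 6000
  h <- f * residue_function(truth, airf$times - airf$times[1])
  q <- convolve_causal(airf$values, h, dt[1])
  concentration_curve(airf$times, pmax(q, 0), role = "tissue")
}

#' Synthetic instrument response function
#'
#' Gaussian pulse (detector timing jitter) with a weak exponential tail,
#' typical of a hybrid PMT. Deterministic shape; counts scale is nominal.
#'
#' @param scene [optical_scene()] supplying the histogram geometry.
#' @param t_center Pulse center, ns.
#' @param fwhm Full width at half maximum, ns.
#' @param tail_frac Fraction of counts in the exponential tail.
#' @param tail_tau Tail time constant, ns.
#' @param total_counts Total counts in the histogram.
#' @return A [dtof()] with role `"IRF"`.
#' @export
synthetic_irf <- function(scene = optical_scene(), t_center = 1.0,
                          fwhm = 0.15, tail_frac = 0.03, tail_tau = 0.3,
                          total_counts = 1e7) {
  tb <- scene$bin_width * (seq_len(scene$n_bins) - 0.5)
  core <- stats::dnorm(tb, t_center, fwhm / 2.3548)
  tail <- ifelse(tb > t_center, exp(-(tb - t_center) / tail_tau), 0)
  shape <- (1 - tail_frac) * core / sum(core) + tail_frac * tail / sum(tail)
  dtof(shape * total_counts, scene$bin_width, role = "IRF")
}

# linear convolution of the IRF shape with each frame's TPSF, column-wise FFT
convolve_irf_frames <- function(irf_shape, tpsf_mat) {
  nb <- length(irf_shape)
  npad <- stats::nextn(2 * nb, 2)
  fi <- stats::fft(c(irf_shape, rep(0, npad - nb)))
  padded <- rbind(tpsf_mat, matrix(0, npad - nb, ncol(tpsf_mat)))
  ff <- stats::mvfft(padded)
  out <- Re(stats::mvfft(ff * fi, inverse = TRUE)) / npad
  pmax(out[seq_len(nb), , drop = FALSE], 0)
}

#' Simulate a DTOF stack under a dynamic absorption time course
#'
#' Each frame's expected histogram is the slab TPSF at that frame's
#' absorption coefficient, convolved with the IRF and scaled so that a frame
#' at the scene's baseline absorption collects `counts_per_frame` photons in
#' expectation (fixed source intensity: frames with higher absorption
#' collect fewer photons). With `noise = TRUE` each frame is an independent
#' Poisson draw; with `noise = FALSE` the expected (non-integer) histograms
#' are returned, the infinite-count limit.
#'
#' @param scene [optical_scene()].
#' @param mua_timecourse Absorption coefficient per frame, per cm (> 0).
#' @param irf IRF [dtof()] on the same bin grid.
#' @param counts_per_frame Expected total counts of a baseline frame.
#' @param frame_period Frame spacing, s (default 120 s / 400 frames).
#' @param seed Integer seed for the Poisson noise.
#' @param noise Draw Poisson counts (`TRUE`) or return expectations.
#' @return Object of class `dtof_stack`: `counts` (frames x bins),
#'   `bin_centers`, `bin_width`, `times` (s), plus the generating `scene`.
#' @export
generate_dtof_series <- function(scene = optical_scene(), mua_timecourse,
                                 irf = synthetic_irf(scene),
                                 counts_per_frame = 3e5,
                                 frame_period = 0.3, seed = 1L,
                                 noise = TRUE) {
  if (any(mua_timecourse <= 0))
    stop("absorption coefficients must be > 0 everywhere")
  if (counts_per_frame <= 0) stop("'counts_per_frame' must be > 0")
  nf <- length(mua_timecourse)
  tb <- scene$bin_width * (seq_len(scene$n_bins) - 0.5)
  v <- nirs_constants$c_vacuum / scene$n_tissue

  # absorption factorizes out of the slab solution, so one base shape at a
  # reference mu_a is rescaled per frame
  base <- slab_tpsf(tb, scene$mu_a_baseline, scene$mu_s_prime,
                    scene$thickness, scene$n_tissue)
  tpsf <- outer(base * exp(scene$mu_a_baseline * v * tb),
                rep(1, nf)) *
    exp(-tb %o% (mua_timecourse * v))
  irf_shape <- irf$counts / sum(irf$counts)
  expect <- convolve_irf_frames(irf_shape, tpsf)

  ref <- sum(base)  # baseline-mu_a total (IRF convolution preserves totals)
  expect <- expect * (counts_per_frame / ref)

  counts <- if (noise) {
    set.seed(seed)
    matrix(stats::rpois(length(expect), lambda = expect),
           nrow = scene$n_bins, ncol = nf)
  } else expect

  # discrete convolution of two histograms sampled at bin centers places
  # output sample k at k * bin_width, half a bin later than the input
  # centers; the stack's time axis records that alignment
  structure(
    list(counts = t(counts), bin_centers = tb + scene$bin_width / 2,
         bin_width = scene$bin_width,
         times = frame_period * (seq_len(nf) - 1L), scene = scene,
         counts_per_frame = counts_per_frame, noise = noise),
    class = "dtof_stack"
  )
}

#' Simulate an India-ink titration phantom experiment
#'
#' Ink is added to a stirred cuvette in fixed-volume increments; each
#' addition both adds chromophore and dilutes what is already there, so the
#' cumulative in-cuvette concentration after k steps is
#' `k * v * c_stock / (V0 + k * v)`. The default stock concentration is
#' calibrated so the step-1 expected absorption change is 0.005 per cm,
#' which makes the 10-step series cover the 0.005-0.040 per cm range probed
#' in joint measurements.
#'
#' @param scene Phantom [optical_scene()] (defaults to [phantom_scene()]).
#' @param eps_e_ink Decadic extinction coefficient of the ink stock,
#'   per-uM per-cm.
#' @param ink_stock_conc Stock ink concentration, uM; `NULL` selects the
#'   step-1 = 0.005 per cm calibration.
#' @param increment_volume Volume of one addition, mL.
#' @param base_volume Initial cuvette volume, mL.
#' @param n_steps Number of ink additions (>= 1).
#' @param frames_per_step DTOFs per measurement set.
#' @param counts_per_frame Expected counts of a baseline frame.
#' @param seed Integer seed.
#' @param noise Poisson noise on the histograms.
#' @return Object of class `phantom_series`: `steps` data frame (step,
#'   cumulative concentration, expected delta_mua), `baseline_stack`,
#'   `step_stacks` (list), `irf`, `scene`, and the generating parameters.
#' @export
generate_phantom_series <- function(scene = phantom_scene(),
                                    eps_e_ink = 0.25,
                                    ink_stock_conc = NULL,
                                    increment_volume = 0.02,
                                    base_volume = 3.5,
                                    n_steps = 10L,
                                    frames_per_step = 100L,
                                    counts_per_frame = 3e5,
                                    seed = 1L, noise = TRUE) {
  if (n_steps < 1) stop("'n_steps' must be >= 1")
  stopifnot(increment_volume > 0, base_volume > 0, eps_e_ink > 0)
  if (is.null(ink_stock_conc)) {
    c1 <- 0.005 / (log(10) * nirs_constants$ink_absorption_ratio * eps_e_ink)
    ink_stock_conc <- c1 * (base_volume + increment_volume) / increment_volume
  }
  k <- seq_len(n_steps)
  cum_conc <- k * increment_volume * ink_stock_conc /
    (base_volume + k * increment_volume)
  expected <- expected_ink_delta_mua(cum_conc, eps_e_ink)

  irf <- synthetic_irf(scene)
  mk_stack <- function(mua, s) {
    generate_dtof_series(scene, rep(mua, frames_per_step), irf,
                         counts_per_frame = counts_per_frame,
                         frame_period = 0.3, seed = s, noise = noise)
  }
  baseline_stack <- mk_stack(scene$mu_a_baseline, seed)
  step_stacks <- lapply(k, function(i)
    mk_stack(scene$mu_a_baseline + expected[i], seed + i))

  structure(
    list(steps = data.frame(step = k, cumulative_ink_conc = cum_conc,
                            expected_delta_mua = expected),
         baseline_stack = baseline_stack, step_stacks = step_stacks,
         irf = irf, scene = scene, eps_e_ink = eps_e_ink,
         ink_stock_conc = ink_stock_conc,
         increment_volume = increment_volume, base_volume = base_volume),
    class = "phantom_series"
  )
}

#' Longitudinal study design
#'
#' Defaults emulate a 12-animal protocol: 4 controls in one cohort and 8
#' experimental animals in 4 cohorts of 2, measured at three baselines (B3
#' on the induction day) and then every 5 days to day 40, both ankles, two
#' repeats per ankle. Effect profiles are mL/min/100 g shifts per timepoint.
#'
#' @param n_control,n_experimental Group sizes.
#' @param exp_cohort_size Experimental animals per cohort.
#' @param timepoints Ordered day labels.
#' @param day_numbers Numeric day for each timepoint (baselines negative).
#' @param bf_baseline Baseline blood flow, mL/min/100 g.
#' @param time_effect Named per-timepoint shift shared by all animals.
#' @param group_effect Named per-timepoint additional shift for the
#'   experimental group.
#' @param cohort_effect_sd SD of the cohort random intercept.
#' @param cohort_severity_sd SD (log scale) of the multiplicative per-cohort
#'   disease-severity factor applied to `group_effect`; emulates
#'   heterogeneous arthritis induction between cohorts prepared with
#'   different adjuvant solutions.
#' @param cohort_day_sd SD of the cohort x timepoint random effect
#'   (trajectory-level cohort heterogeneity: animals in the same cohort
#'   share day-to-day excursions).
#' @param animal_effect_sd SD of the animal random intercept.
#' @param within_animal_sd SD of a single repeat measurement.
#' @param hr_mean,hr_sd Heart-rate marginal distribution, bpm.
#' @param hr_bf_slope Coupling of BF to HR fluctuation, (mL/min/100 g)/bpm;
#'   the default produces the weak positive per-day correlation (~0.14)
#'   seen in practice.
#' @param missing_repeat_prob Probability that an ankle-day loses one of its
#'   two repeats.
#' @param hep_hazard Per-5-day-interval hazard of reaching the humane
#'   endpoint, experimental animals, intervals starting after day 15.
#' @param symptom_mean,symptom_cohort_sd,symptom_within_sd First-symptom-day
#'   distribution for experimental animals (cohort-correlated).
#' @return Object of class `study_design`.
#' @export
study_design <- function(n_control = 4L, n_experimental = 8L,
                         exp_cohort_size = 2L,
                         timepoints = c("B1", "B2", "B3", "5", "10", "15",
                                        "20", "25", "30", "35", "40"),
                         day_numbers = c(-10, -5, 0, 5, 10, 15,
                                         20, 25, 30, 35, 40),
                         bf_baseline = 10,
                         time_effect = c(B1 = 0, B2 = 0, B3 = 0, `5` = 2,
                                         `10` = 6, `15` = 4, `20` = 4,
                                         `25` = 4, `30` = 3, `35` = 3, `40` = 3),
                         group_effect = c(B1 = 0, B2 = 0, B3 = 0, `5` = 8,
                                          `10` = 2, `15` = 2, `20` = 4,
                                          `25` = 3, `30` = 2, `35` = 2, `40` = 2),
                         cohort_effect_sd = 2,
                         cohort_severity_sd = 0.4,
                         cohort_day_sd = 1,
                         animal_effect_sd = 1.5,
                         within_animal_sd = 2.5,
                         hr_mean = 350, hr_sd = 20, hr_bf_slope = 0.017,
                         missing_repeat_prob = 0.1,
                         hep_hazard = 0.5,
                         symptom_mean = 11, symptom_cohort_sd = 2.2,
                         symptom_within_sd = 0.5) {
  stopifnot(n_control >= 0, n_experimental >= 0,
            n_control + n_experimental > 0,
            length(timepoints) == length(day_numbers),
            !is.unsorted(day_numbers, strictly = TRUE),
            missing_repeat_prob >= 0, missing_repeat_prob <= 1,
            hep_hazard >= 0, hep_hazard <= 1,
            cohort_effect_sd >= 0, cohort_severity_sd >= 0,
            cohort_day_sd >= 0, animal_effect_sd >= 0, within_animal_sd >= 0)
  time_effect <- time_effect[timepoints]
  group_effect <- group_effect[timepoints]
  if (anyNA(time_effect) || anyNA(group_effect))
    stop("effect profiles must name every timepoint")
  structure(as.list(environment()), class = "study_design")
}

#' Generate a longitudinal multi-cohort study table
#'
#' Produces one row per animal x day x side x repeat with blood flow and
#' heart rate, plus a ground-truth attribute recording every latent effect.
#' Experimental animals can leave the study early (humane endpoint), in
#' which case their rows stop; with probability `missing_repeat_prob` an
#' ankle-day loses one of its two repeats.
#'
#' @param design A [study_design()].
#' @param seed Integer seed.
#' @return A data frame of class `study_table` with columns `animal`,
#'   `group`, `cohort`, `day` (label), `day_num`, `side`, `rep`, `bf`, `hr`,
#'   `hep_day`, `first_symptom_day`. Attribute `ground_truth` holds the
#'   per-animal latent effects and per-cell expected BF.
#' @export
generate_cohort_study <- function(design = study_design(), seed = 1L) {
  set.seed(seed)
  d <- design
  n_animal <- d$n_control + d$n_experimental
  if (n_animal == 0) stop("design must contain at least one animal")

  # cohort layout: controls share one cohort, experimental animals split
  # into cohorts of exp_cohort_size
  n_exp_coh <- if (d$n_experimental > 0)
    ceiling(d$n_experimental / d$exp_cohort_size) else 0L
  animals <- data.frame(
    animal = sprintf("R%02d", seq_len(n_animal)),
    group = rep(c("control", "experimental"),
                c(d$n_control, d$n_experimental)),
    cohort = c(rep("C1", d$n_control),
               paste0("C", 1 + ceiling(seq_len(d$n_experimental) /
                                         d$exp_cohort_size)))
  )
  cohorts <- unique(animals$cohort)
  coh_eff <- stats::setNames(stats::rnorm(length(cohorts), 0, d$cohort_effect_sd),
                             cohorts)
  coh_sev <- stats::setNames(exp(stats::rnorm(length(cohorts), 0,
                                              d$cohort_severity_sd)), cohorts)
  animals$cohort_effect <- coh_eff[animals$cohort]
  animals$cohort_severity <- coh_sev[animals$cohort]
  coh_day <- matrix(stats::rnorm(length(cohorts) * length(d$timepoints), 0,
                                 d$cohort_day_sd),
                    length(cohorts), length(d$timepoints),
                    dimnames = list(cohorts, d$timepoints))
  animals$animal_effect <- stats::rnorm(n_animal, 0, d$animal_effect_sd)

  # disease timing: cohort-correlated symptom onset; humane endpoint drawn
  # per cohort as a geometric number of 5-day intervals survived past day 15
  animals$first_symptom_day <- NA_real_
  animals$hep_day <- NA_real_
  exp_coh <- unique(animals$cohort[animals$group == "experimental"])
  sym_coh <- stats::setNames(stats::rnorm(length(exp_coh), d$symptom_mean,
                                          d$symptom_cohort_sd), exp_coh)
  hep_coh <- stats::setNames(
    if (d$hep_hazard > 0) 16 + 5 * stats::rgeom(length(exp_coh), d$hep_hazard) +
      stats::runif(length(exp_coh), 0, 3) else rep(Inf, length(exp_coh)),
    exp_coh)
  is_exp <- animals$group == "experimental"
  animals$first_symptom_day[is_exp] <-
    round(sym_coh[animals$cohort[is_exp]] +
            stats::rnorm(sum(is_exp), 0, d$symptom_within_sd), 1)
  animals$hep_day[is_exp] <- round(hep_coh[animals$cohort[is_exp]] +
                                     stats::runif(sum(is_exp), 0, 1), 1)

  grid <- expand.grid(animal = animals$animal, tp = seq_along(d$timepoints),
                      side = c("L", "R"), rep = 1:2,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  grid <- merge(grid, animals, by = "animal", sort = FALSE)
  grid$day <- d$timepoints[grid$tp]
  grid$day_num <- d$day_numbers[grid$tp]

  # drop rows after the humane endpoint
  alive <- is.na(grid$hep_day) | grid$day_num < grid$hep_day
  grid <- grid[alive, ]

  mu <- d$bf_baseline + d$time_effect[grid$tp] +
    ifelse(grid$group == "experimental",
           grid$cohort_severity * d$group_effect[grid$tp], 0) +
    grid$cohort_effect + coh_day[cbind(grid$cohort, grid$day)] +
    grid$animal_effect
  hr <- stats::rnorm(nrow(grid), d$hr_mean, d$hr_sd)
  bf <- mu + d$hr_bf_slope * (hr - d$hr_mean) +
    stats::rnorm(nrow(grid), 0, d$within_animal_sd)
  grid$bf <- bf
  grid$hr <- hr
  grid$expected_bf <- mu

  # ankle-days that lose one of their two repeats
  key <- interaction(grid$animal, grid$day, grid$side, drop = TRUE)
  lost <- levels(key)[stats::runif(nlevels(key)) < d$missing_repeat_prob]
  if (length(lost)) {
    drop_rep <- sample(1:2, length(lost), replace = TRUE)
    kill <- key %in% lost &
      grid$rep == drop_rep[match(as.character(key), lost)]
    grid <- grid[!kill, ]
  }

  out <- grid[order(grid$animal, grid$tp, grid$side, grid$rep),
              c("animal", "group", "cohort", "day", "day_num", "side",
                "rep", "bf", "hr", "hep_day", "first_symptom_day")]
  rownames(out) <- NULL
  truth <- animals
  truth$expected_baseline <- d$bf_baseline + truth$cohort_effect +
    truth$animal_effect
  structure(out, class = c("study_table", "data.frame"),
            ground_truth = truth, design = d, seed = seed)
}
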