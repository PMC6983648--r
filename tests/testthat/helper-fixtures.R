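# shared fixtures, all generated in code

# coarser optical scene for fast DTOF tests (10 ns window, 400 bins)
small_scene <- function(...) {
  optical_scene(n_bins = 400L, bin_width = 0.025, ...)
}

# standard 400-frame acquisition grid (120 s at 0.3 s)
protocol_times <- function() seq(0, by = 0.3, length.out = 400L)

# noiseless arterial/tissue pair at a given true flow
noiseless_pair <- function(bf_true, times = protocol_times(), ...) {
  ca <- generate_airf(times = times)
  truth <- perfusion_truth(bf_true = bf_true, ...)
  list(ca = ca, q = generate_tissue_curve(ca, truth), truth = truth)
}

# concentration-level noise SD implied by Poisson counting at the given
# per-frame count level, pathlength and ICG extinction
conc_noise_sd <- function(counts_per_frame, p_cm,
                          eps = nirs_constants$eps_icg) {
  sqrt(2 / counts_per_frame) / p_cm / (log(10) * eps)
}

# typical in-vivo pathlength of the default scene, for noise calibration
DEFAULT_PATHLENGTH <- 5.6

# balanced small mixed-design table for ANOVA oracle comparisons
balanced_toy_table <- function(n_per_group = 3, n_days = 3, seed = 42) {
  set.seed(seed)
  df <- expand.grid(subj = seq_len(2 * n_per_group),
                    day = paste0("d", seq_len(n_days)),
                    side = c("L", "R"), stringsAsFactors = FALSE)
  df$animal <- sprintf("A%02d", df$subj)
  df$group <- ifelse(df$subj <= n_per_group, "g1", "g2")
  df$bf <- round(stats::rnorm(nrow(df), 10, 3), 3)
  df[c("animal", "group", "day", "side", "bf")]
}

# independent sums-of-squares oracle for the balanced two-group mixed
# design: every SS is a per-observation sum of squared cell-mean effect
# estimates
anova_ss_oracle <- function(df) {
  mn <- function(...) {
    key <- interaction(..., drop = FALSE)
    ave <- tapply(df$bf, key, mean)
    as.numeric(ave[key])
  }
  m <- mean(df$bf)
  g <- mn(df$group); s_ <- mn(df$animal); t_ <- mn(df$day); d <- mn(df$side)
  gt <- mn(df$group, df$day); gd <- mn(df$group, df$side)
  td <- mn(df$day, df$side); st <- mn(df$animal, df$day)
  sd_ <- mn(df$animal, df$side); gtd <- mn(df$group, df$day, df$side)

  list(
    group = sum((g - m)^2),
    subj_err = sum((s_ - g)^2),
    day = sum((t_ - m)^2),
    day_group = sum((gt - g - t_ + m)^2),
    day_subj_err = sum((st - s_ - gt + g)^2),
    side = sum((d - m)^2),
    side_group = sum((gd - g - d + m)^2),
    side_subj_err = sum((sd_ - s_ - gd + g)^2),
    day_side = sum((td - t_ - d + m)^2),
    day_group_side = sum((gtd - gt - gd - td + g + t_ + d - m)^2),
    day_side_subj_err = sum((df$bf - st - sd_ - gtd + s_ + gt + gd - g)^2),
    total = sum((df$bf - m)^2)
  )
}

# Patnaik central-F approximation to the noncentral-F tail
patnaik_tail <- function(fcrit, df1, df2, ncp) {
  h <- (df1 + ncp)^2 / (df1 + 2 * ncp)
  stats::pf(fcrit * df1 / (df1 + ncp), h, df2, lower.tail = FALSE)
}
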