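#' Write / read a concentration or absorption curve as CSV
#'
#' Unit-bearing headers: `time_s,value,unit`.
#'
#' @param curve `concentration_curve` or `absorption_curve`.
#' @param path Output path.
#' @export
write_curve_csv <- function(curve, path) {
  if (inherits(curve, "concentration_curve")) {
    df <- data.frame(time_s = curve$times, value = curve$values,
                     unit = "uM")
  } else if (inherits(curve, "absorption_curve")) {
    df <- data.frame(time_s = curve$times, value = curve$delta_mua,
                     unit = "per_cm")
  } else stop("unsupported curve class")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve_csv
#' @param role Role of the curve being read.
#' @return [concentration_curve()].
#' @export
read_curve_csv <- function(path, role = c("arterial", "tissue")) {
  df <- utils::read.csv(path)
  concentration_curve(df$time_s, df$value, role = match.arg(role))
}

#' Write / read a DTOF stack as CSV (one frame per row)
#'
#' First column is the frame time in seconds; remaining columns are the
#' per-bin counts. Bin width (ns) is stored in the header comment-free way:
#' a leading `bin_width_ns` column repeated per row.
#'
#' @param stack `dtof_stack`.
#' @param path Output path.
#' @export
write_dtof_csv <- function(stack, path) {
  df <- data.frame(time_s = stack$times, bin_width_ns = stack$bin_width,
                   stack$counts)
  names(df)[-(1:2)] <- paste0("bin", seq_len(ncol(stack$counts)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dtof_csv
#' @export
read_dtof_csv <- function(path) {
  df <- utils::read.csv(path)
  counts <- as.matrix(df[, grep("^bin[0-9]+$", names(df)), drop = FALSE])
  bw <- df$bin_width_ns[1]
  structure(list(counts = unname(counts),
                 bin_centers = bw * (seq_len(ncol(counts)) - 0.5),
                 bin_width = bw, times = df$time_s),
            class = "dtof_stack")
}

#' Default pipeline configuration
#'
#' Serializable list of every constant and stage parameter the end-to-end
#' run uses; the resolved configuration is written next to the outputs of
#' every run.
#'
#' @param seed Master seed; all stage randomness derives from it.
#' @param ... Overrides for any top-level entry.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, ...) {
  cfg <- list(
    seed = seed,
    constants = nirs_constants,
    scene = unclass(optical_scene()),
    bolus = unclass(bolus_model()),
    truth = list(bf_true = 15,
                 residue_shape = list(family = "plateau_exp",
                                      t_plateau = 2, tau = 4),
                 tissue_density = nirs_constants$rho_tissue),
    acquisition = list(n_frames = 400L, frame_period = 0.3,
                       counts_per_frame = 3e5,
                       baseline_window = c(0, 10)),
    phantom = list(n_steps = 10L, frames_per_step = 100L),
    power = list(alpha = 0.05, target_power = 0.8,
                 corr_rep_measures = 0.5, nonsphericity_eps = 1)
  )
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg <- utils::modifyList(cfg, over)
  }
  structure(cfg, class = "pipeline_config")
}

validate_config <- function(config) {
  need <- c("seed", "constants", "scene", "bolus", "truth", "acquisition",
            "phantom", "power")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("config validation error: missing field(s): ",
         paste(missing, collapse = ", "))
  invisible(TRUE)
}

#' Run the full synthetic end-to-end pipeline
#'
#' Simulate -> process -> quantify -> longitudinal statistics -> power, all
#' driven by one seed: a phantom titration with its zero-intercept
#' regression; one in-vivo-like measurement (DTOF stack + arterial curve)
#' processed to a blood-flow estimate with pathlength sensitivity; a
#' 12-animal longitudinal study analysed with the repeated-measures ANOVA,
#' Tukey HSD, heart-rate confound correlation, and cohort clustering; and
#' the post-hoc interaction power under both effect-size conventions.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created); resolved config, stage tables
#'   and curves are written there as CSV/JSON.
#' @return Invisible list with each stage's result objects.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("dcenirs_run_")) {
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- config$seed
  log_lines <- character()
  say <- function(...) {
    msg <- sprintf(...)
    message(msg)
    log_lines <<- c(log_lines, msg)
  }

  jsonlite::write_json(unclass(config), file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  ## stage 1: phantom validation
  scene_ph <- phantom_scene()
  series <- generate_phantom_series(scene_ph,
                                    n_steps = config$phantom$n_steps,
                                    frames_per_step = config$phantom$frames_per_step,
                                    counts_per_frame = config$acquisition$counts_per_frame,
                                    seed = seed)
  ph <- phantom_pipeline(series)
  say("[phantom] slope=%.4f R2=%.5f F(%d,%d)=%.0f",
      ph$regression$slope, ph$regression$r_squared, ph$regression$df1,
      ph$regression$df2, ph$regression$f_stat)
  utils::write.csv(ph$steps, file.path(out_dir, "phantom_steps.csv"),
                   row.names = FALSE)

  ## stage 2: one synthetic in-vivo measurement -> BF
  scene <- do.call(optical_scene, config$scene)
  bolus <- do.call(bolus_model, config$bolus)
  truth <- perfusion_truth(config$truth$bf_true, config$truth$residue_shape,
                           config$truth$tissue_density)
  times <- config$acquisition$frame_period *
    (seq_len(config$acquisition$n_frames) - 1L)
  ca <- generate_airf(bolus, times)
  qt <- generate_tissue_curve(ca, truth)
  mua_tc <- scene$mu_a_baseline +
    icg_concentration_to_delta_mua(qt, config$constants$eps_icg)
  irf <- synthetic_irf(scene)
  stack <- generate_dtof_series(scene, mua_tc, irf,
                                counts_per_frame = config$acquisition$counts_per_frame,
                                frame_period = config$acquisition$frame_period,
                                seed = seed + 1L)
  ac <- delta_mua_timecourse(stack, irf, config$acquisition$baseline_window)
  qm <- to_icg_concentration(ac, config$constants$eps_icg)
  est <- deconvolve_bf(ca, qm)
  sens <- pathlength_sensitivity(stack, irf, ca,
                                 baseline_window = config$acquisition$baseline_window,
                                 eps_icg = config$constants$eps_icg)
  say("[quantify] BF=%.2f mL/min/100g (truth %.1f), residual %.2e uM, pathlength sensitivity %.2f%%",
      est$bf, truth$bf_true, est$fit_residual, sens$percent_change)
  write_curve_csv(ca, file.path(out_dir, "arterial.csv"))
  write_curve_csv(qm, file.path(out_dir, "tissue_measured.csv"))

  ## stage 3: longitudinal study
  study <- generate_cohort_study(study_design(), seed = seed + 2L)
  agg <- aggregate_measurements(study)
  an <- rm_anova(agg)
  tk <- tukey_hsd_time(agg)
  hr <- hr_confound(study)
  cl <- cohort_clustering(agg, seed = seed + 3L)
  say("[study] %d complete timepoints; time F=%.2f p=%.3g; clustering k=%d",
      length(an$days_used),
      an$effects$F[an$effects$effect == "day"],
      an$effects$p[an$effects$effect == "day"], cl$k)
  utils::write.csv(an$effects, file.path(out_dir, "anova_effects.csv"),
                   row.names = FALSE)
  utils::write.csv(tk, file.path(out_dir, "tukey_time.csv"), row.names = FALSE)
  utils::write.csv(study, file.path(out_dir, "study_table.csv"),
                   row.names = FALSE)

  ## stage 4: power from the observed interaction effect size
  eta2 <- an$effects$partial_eta_sq[an$effects$effect == "day:group"]
  pw <- power_report(eta2, n_total = an$n_subjects,
                     n_measurements = length(an$days_used),
                     alpha = config$power$alpha,
                     corr_rep_measures = config$power$corr_rep_measures,
                     nonsphericity_eps = config$power$nonsphericity_eps,
                     target_power = config$power$target_power)
  say("[power] interaction eta_p^2=%.3f; power %.3f / %.3f (gpower/spss)",
      eta2, pw$power[1], pw$power[2])
  utils::write.csv(pw, file.path(out_dir, "power.csv"), row.names = FALSE)

  writeLines(log_lines, file.path(out_dir, "run.log"))
  invisible(list(phantom = ph, bf = est, sensitivity = sens, anova = an,
                 tukey = tk, hr = hr, clustering = cl, power = pw,
                 out_dir = out_dir))
}
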