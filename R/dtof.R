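#' Construct a photon time-of-flight histogram (DTOF)
#'
#' A DTOF is the raw time-correlated single-photon-counting measurement: a
#' histogram of photon arrival times over one acquisition frame. The same
#' container holds instrument response functions (IRFs), which are DTOFs
#' acquired without tissue in the light path.
#'
#' @param counts Nonnegative counts per bin.
#' @param bin_width Histogram bin width in ns.
#' @param t0 Center of the first bin in ns (defaults to `bin_width / 2`).
#' @param role Either `"measurement"` or `"IRF"`.
#' @return An object of class `dtof` with fields `counts`, `bin_centers`,
#'   `bin_width`, and `role`.
#' @export
dtof <- function(counts, bin_width, t0 = bin_width / 2,
                 role = c("measurement", "IRF")) {
  role <- match.arg(role)
  if (!is.numeric(counts) || length(counts) < 1L)
    stop("'counts' must be a non-empty numeric vector")
  if (any(counts < 0)) stop("'counts' must be nonnegative")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("'bin_width' must be > 0")
  structure(
    list(counts = as.numeric(counts),
         bin_centers = t0 + bin_width * (seq_along(counts) - 1L),
         bin_width = bin_width,
         role = role),
    class = "dtof"
  )
}

#' Mean photon time of flight of a DTOF
#'
#' Count-weighted mean of the bin centers, the first temporal moment used in
#' the pathlength computation.
#'
#' @param d A [dtof()] object (or a list with `counts` and `bin_centers`).
#' @return Mean time of flight in ns.
#' @export
mean_time_of_flight <- function(d) {
  if (is.null(d$counts) || sum(d$counts) <= 0)
    stop("empty histogram: total counts must be > 0")
  sum(d$counts * d$bin_centers) / sum(d$counts)
}

#' Optical pathlength from the mean time-of-flight difference
#'
#' The mean optical pathlength travelled by detected photons is the speed of
#' light in the medium times the mean time the photons spent in it:
#' `p = (c / n) * (<t>_DTOF - <t>_IRF)`, where the IRF mean time removes the
#' instrumental delay.
#'
#' A DTOF mean time earlier than the IRF mean time is nonphysical; the
#' negative pathlength is preserved for diagnostics but flagged with a
#' warning.
#'
#' @param d Measurement DTOF.
#' @param irf Instrument response function DTOF.
#' @param n_tissue Refractive index of the medium.
#' @return An object of class `pathlength_result` with fields `p` (cm),
#'   `t_mean_dtof`, `t_mean_irf` (ns), `n_tissue`, and `c_vacuum` (cm/ns).
#' @export
pathlength <- function(d, irf, n_tissue = nirs_constants$n_tissue) {
  if (!is.null(d$bin_width) && !is.null(irf$bin_width) &&
      abs(d$bin_width - irf$bin_width) > 1e-12 * d$bin_width)
    stop("DTOF and IRF must share the same bin width")
  tm_d <- mean_time_of_flight(d)
  tm_i <- mean_time_of_flight(irf)
  p <- nirs_constants$c_vacuum / n_tissue * (tm_d - tm_i)
  if (p < 0)
    warning("nonphysical pathlength: DTOF mean time earlier than IRF mean time")
  structure(
    list(p = p, t_mean_dtof = tm_d, t_mean_irf = tm_i,
         n_tissue = n_tissue, c_vacuum = nirs_constants$c_vacuum),
    class = "pathlength_result"
  )
}

#' Absorption-change time course from a DTOF stack (modified Beer-Lambert law)
#'
#' Per-frame light intensity is the total photon count of the frame. With
#' `I0` the mean intensity over the pre-contrast baseline window, the change
#' in the absorption coefficient is `delta_mua(t) = ln(I0 / I(t)) / p`, so
#' that increased absorption is positive. The pathlength `p` is computed once
#' from the summed baseline DTOF (mode `"baseline"`, the default, matching
#' the negligible pathlength drift observed in vivo), or per frame with a
#' chord correction `ln(I0/I) / ((p0 + p(t)) / 2)` (mode `"chord"`), which
#' removes the secant/tangent curvature of the Beer-Lambert linearization at
#' large absorption changes.
#'
#' Zero-count frames (probe-contact loss) are masked and linearly
#' interpolated over, with a warning.
#'
#' @param stack A `dtof_stack` as returned by [generate_dtof_series()], or a
#'   list with `counts` (frames x bins matrix), `bin_centers` and `times`.
#' @param irf IRF [dtof()].
#' @param baseline_window Two-element numeric, seconds; frames with
#'   `baseline_window[1] <= t < baseline_window[2]` form the baseline.
#' @param n_tissue Refractive index.
#' @param pathlength_mode `"baseline"` or `"chord"` (see Details).
#' @param pathlength_scale Multiplicative perturbation applied to the
#'   baseline pathlength (used by the sensitivity analysis; default 1).
#' @return Object of class `absorption_curve`: `times` (s), `delta_mua`
#'   (per cm), `intensity`, `I0`, `pathlength_used` (cm), `baseline_window`,
#'   `pathlength_mode`.
#' @export
delta_mua_timecourse <- function(stack, irf, baseline_window = c(0, 10),
                                 n_tissue = nirs_constants$n_tissue,
                                 pathlength_mode = c("baseline", "chord"),
                                 pathlength_scale = 1) {
  pathlength_mode <- match.arg(pathlength_mode)
  counts <- stack$counts
  times <- stack$times
  stopifnot(is.matrix(counts), length(times) == nrow(counts))
  intensity <- rowSums(counts)

  masked <- intensity <= 0
  if (all(masked)) stop("all frames have zero counts")
  if (any(masked)) {
    warning(sprintf("%d zero-count frame(s) masked and interpolated", sum(masked)))
    intensity[masked] <- stats::approx(times[!masked], intensity[!masked],
                                       xout = times[masked], rule = 2)$y
  }

  in_base <- times >= baseline_window[1] & times < baseline_window[2]
  if (sum(in_base & !masked) < 2L)
    stop("baseline window must contain at least 2 usable frames")
  I0 <- mean(intensity[in_base])

  base_hist <- list(counts = colSums(counts[in_base & !masked, , drop = FALSE]),
                    bin_centers = stack$bin_centers,
                    bin_width = stack$bin_width)
  p0 <- pathlength(base_hist, irf, n_tissue)$p * pathlength_scale
  if (p0 <= 0) stop("baseline pathlength is not positive")

  att <- log(I0 / intensity)
  if (pathlength_mode == "baseline") {
    dmua <- att / p0
    p_used <- p0
  } else {
    # chord mode: per-frame pathlength from each frame's own mean time of
    # flight; the trapezoid of baseline and instantaneous pathlength tracks
    # the secant of the attenuation-vs-absorption curve to third order
    tm_irf <- mean_time_of_flight(irf)
    tm_fr <- as.vector(counts %*% stack$bin_centers) / rowSums(counts)
    tm_fr[masked] <- NA
    p_fr <- nirs_constants$c_vacuum / n_tissue * (tm_fr - tm_irf) * pathlength_scale
    p_fr[masked] <- stats::approx(times[!masked], p_fr[!masked],
                                  xout = times[masked], rule = 2)$y
    dmua <- att / ((p0 + p_fr) / 2)
    p_used <- p0
  }

  structure(
    list(times = times, delta_mua = dmua, intensity = intensity, I0 = I0,
         pathlength_used = p_used, baseline_window = baseline_window,
         pathlength_mode = pathlength_mode, masked = which(masked)),
    class = "absorption_curve"
  )
}

#' Expected absorption change of an India-ink titration step
#'
#' `delta_mua_expected = ln(10) * 0.885 * eps_e_ink * conc`, where
#' `eps_e_ink` is the decadic extinction coefficient of the ink measured in
#' transmission and the 0.885 factor converts extinction (absorption plus
#' scattering) to pure absorption.
#'
#' @param cumulative_conc Ink concentration in the cuvette (uM), vectorized.
#' @param eps_e_ink Decadic extinction coefficient of the ink stock
#'   (per-uM per-cm).
#' @param absorption_ratio Absorption-to-extinction ratio of the ink.
#' @return Expected absorption change(s), per cm.
#' @export
expected_ink_delta_mua <- function(cumulative_conc, eps_e_ink,
                                   absorption_ratio = nirs_constants$ink_absorption_ratio) {
  if (eps_e_ink <= 0) stop("'eps_e_ink' must be > 0")
  if (any(cumulative_conc < 0)) stop("ink concentration must be nonnegative")
  log(10) * absorption_ratio * eps_e_ink * cumulative_conc
}

#' Construct a dye concentration curve
#'
#' @param times Time grid in seconds.
#' @param values Concentration values in uM.
#' @param role `"arterial"` or `"tissue"`.
#' @param extinction_used Decadic extinction coefficient used for the
#'   conversion (tissue role only).
#' @return Object of class `concentration_curve`.
#' @export
concentration_curve <- function(times, values, role = c("arterial", "tissue"),
                                extinction_used = NULL) {
  role <- match.arg(role)
  stopifnot(length(times) == length(values), all(is.finite(values)))
  if (is.unsorted(times, strictly = TRUE))
    stop("time grid must be strictly increasing")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 role = role, extinction_used = extinction_used),
            class = "concentration_curve")
}

#' Convert an absorption-change curve to an ICG concentration curve
#'
#' `Q(t) = delta_mua(t) / (ln(10) * eps_ICG)` in uM, with the decadic ICG
#' extinction coefficient at 805 nm.
#'
#' @param curve An `absorption_curve` from [delta_mua_timecourse()].
#' @param eps_icg Decadic ICG extinction coefficient, per-uM per-cm.
#' @return A tissue-role [concentration_curve()].
#' @export
to_icg_concentration <- function(curve, eps_icg = nirs_constants$eps_icg) {
  if (eps_icg <= 0) stop("'eps_icg' must be > 0")
  concentration_curve(curve$times, curve$delta_mua / (log(10) * eps_icg),
                      role = "tissue", extinction_used = eps_icg)
}

#' Inverse of [to_icg_concentration()]
#'
#' Maps a tissue concentration back to the absorption change it would
#' produce; the round trip is the identity.
#'
#' @param conc Concentration in uM (vector or `concentration_curve`).
#' @param eps_icg Decadic ICG extinction coefficient, per-uM per-cm.
#' @return Absorption change(s), per cm.
#' @export
icg_concentration_to_delta_mua <- function(conc, eps_icg = nirs_constants$eps_icg) {
  if (eps_icg <= 0) stop("'eps_icg' must be > 0")
  v <- if (inherits(conc, "concentration_curve")) conc$values else conc
  v * log(10) * eps_icg
}
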