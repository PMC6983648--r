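#' Options for the blood-flow deconvolution
#'
#' @param reg Regularization-parameter selection: `"gcv"` (generalized
#'   cross-validation, default), `"lcurve"` (maximum-curvature corner of the
#'   residual-vs-seminorm curve), or `"fixed"` (use `lambda`).
#' @param lambda Fixed regularization parameter (as a fraction of the
#'   largest singular value) when `reg = "fixed"`.
#' @param lambda_grid Candidate lambdas, as fractions of the largest
#'   singular value.
#' @param nonneg Clip the residue estimate at zero.
#' @param monotone Project the residue estimate onto the nonincreasing cone
#'   from its peak onward (pool-adjacent-violators); appropriate when the
#'   arterial-tissue delay is removed or negligible.
#' @param delay_grid Candidate arterial-to-tissue delays in seconds,
#'   evaluated by refit residual. The default fits no delay.
#' @param rho Tissue density, g/mL, for the flow unit bridge.
#' @return A list of class `deconv_opts`.
#' @export
deconv_opts <- function(reg = c("gcv", "lcurve", "fixed"), lambda = 1e-3,
                        lambda_grid = 10^seq(-6, -0.5, length.out = 45),
                        nonneg = TRUE, monotone = TRUE, delay_grid = 0,
                        rho = nirs_constants$rho_tissue) {
  reg <- match.arg(reg)
  stopifnot(all(delay_grid >= 0), all(delay_grid <= 5), rho > 0)
  structure(list(reg = reg, lambda = lambda, lambda_grid = lambda_grid,
                 nonneg = nonneg, monotone = monotone,
                 delay_grid = delay_grid, rho = rho),
            class = "deconv_opts")
}

# nonincreasing isotonic fit (least-squares projection), via isoreg on the
# reversed sequence
project_nonincreasing <- function(x) {
  rev(stats::isoreg(seq_along(x), rev(x))$yf)
}

gcv_lambda <- function(sv, q, lambda_grid) {
  b <- crossprod(sv$u, q)
  n <- length(q)
  lams <- lambda_grid * sv$d[1]
  score <- vapply(lams, function(l) {
    fil <- sv$d^2 / (sv$d^2 + l^2)
    n * sum(((1 - fil) * b)^2) / (n - sum(fil))^2
  }, numeric(1))
  lams[which.min(score)]
}

lcurve_lambda <- function(sv, q, lambda_grid) {
  b <- crossprod(sv$u, q)
  lams <- lambda_grid * sv$d[1]
  pts <- t(vapply(lams, function(l) {
    fil <- sv$d^2 / (sv$d^2 + l^2)
    rho2 <- sum(((1 - fil) * b)^2)
    eta2 <- sum((fil * b / sv$d)^2)
    c(log(rho2 + 1e-300), log(eta2 + 1e-300))
  }, numeric(2)))
  # discrete curvature of the L-curve; pick the corner
  k <- seq(2, length(lams) - 1)
  curv <- vapply(k, function(i) {
    d1 <- pts[i, ] - pts[i - 1, ]; d2 <- pts[i + 1, ] - pts[i, ]
    (d1[1] * d2[2] - d1[2] * d2[1]) /
      (sqrt(sum(d1^2)) * sqrt(sum(d2^2)) *
         sqrt(sum((pts[i + 1, ] - pts[i - 1, ])^2)) + 1e-300)
  }, numeric(1))
  lams[k[which.max(curv)]]
}

tikhonov_solve <- function(sv, q, lambda) {
  b <- crossprod(sv$u, q)
  as.vector(sv$v %*% (sv$d * b / (sv$d^2 + lambda^2)))
}

#' Estimate blood flow by regularized deconvolution
#'
#' Discretizes the indicator-dilution relation `Q = f * (Ca (*) R)` as a
#' lower-triangular Toeplitz system and solves for the flow-scaled residue
#' function `h = f * R(t)` by SVD-based Tikhonov regularization (lambda from
#' GCV by default) followed by projection onto the physiological constraint
#' set (nonnegative, nonincreasing after the peak). Blood flow is read from
#' the plateau maximum: `BF = max(h) * 6000 / rho` in mL/min/100 g.
#'
#' If the tissue curve is sampled on a different grid it is linearly
#' resampled onto the arterial grid.
#'
#' @param ca Arterial [concentration_curve()] on a uniform grid.
#' @param q Tissue [concentration_curve()].
#' @param opts A [deconv_opts()].
#' @return Object of class `residue_estimate`: `times`, `h` (1/s), `bf`
#'   (mL/min/100 g), `lambda`, `delay` (s), `fit_residual` (RMS uM),
#'   `regularization`, `rho`.
#' @export
deconvolve_bf <- function(ca, q, opts = deconv_opts()) {
  dt <- diff(ca$times)
  if (max(abs(dt - dt[1])) > 1e-6 * dt[1])
    stop("arterial curve must be on a uniform time grid")
  dt <- dt[1]
  if (sum(abs(ca$values)) * dt <= 0)
    stop("degenerate input function: arterial curve has zero area")

  qv <- if (isTRUE(all.equal(q$times, ca$times, tolerance = 1e-8))) q$values
  else stats::approx(q$times, q$values, xout = ca$times, rule = 2)$y
  n <- length(ca$times)

  if (all(qv == 0)) {
    return(structure(list(times = ca$times - ca$times[1], h = numeric(n),
                          bf = 0, lambda = NA_real_, delay = 0,
                          fit_residual = 0, regularization = opts$reg,
                          rho = opts$rho),
                     class = "residue_estimate"))
  }

  fit_one <- function(delay_s) {
    shift <- round(delay_s / dt)
    cav <- if (shift > 0) c(rep(0, shift), ca$values[seq_len(n - shift)])
    else ca$values
    A <- dt * stats::toeplitz(cav)
    A[upper.tri(A)] <- 0
    sv <- svd(A)
    lambda <- switch(opts$reg,
      gcv = gcv_lambda(sv, qv, opts$lambda_grid),
      lcurve = lcurve_lambda(sv, qv, opts$lambda_grid),
      fixed = opts$lambda * sv$d[1])
    h <- tikhonov_solve(sv, qv, lambda)
    if (opts$monotone) {
      ip <- which.max(h)
      h[ip:n] <- project_nonincreasing(h[ip:n])
    }
    if (opts$nonneg) h <- pmax(h, 0)
    resid <- sqrt(mean((as.vector(A %*% h) - qv)^2))
    list(h = h, lambda = lambda, resid = resid, delay = delay_s)
  }

  fits <- lapply(opts$delay_grid, fit_one)
  best <- fits[[which.min(vapply(fits, `[[`, numeric(1), "resid"))]]

  structure(
    list(times = ca$times - ca$times[1], h = best$h,
         bf = max(best$h) * 6000 / opts$rho, lambda = best$lambda,
         delay = best$delay, fit_residual = best$resid,
         regularization = opts$reg, rho = opts$rho),
    class = "residue_estimate"
  )
}

#' Refold a residue estimate through the arterial curve
#'
#' Convenience check of the fit: returns `Ca (*) h` on the arterial grid
#' using the same quadrature the deconvolution inverts.
#'
#' @param est A `residue_estimate`.
#' @param ca The arterial [concentration_curve()] used in the fit.
#' @return Numeric vector, refolded tissue curve (uM).
#' @export
refold <- function(est, ca) {
  dt <- diff(ca$times)[1]
  shift <- round(est$delay / dt)
  cav <- if (shift > 0)
    c(rep(0, shift), ca$values[seq_len(length(ca$values) - shift)])
  else ca$values
  convolve_causal(cav, est$h, dt)
}

#' Sensitivity of recovered blood flow to the baseline pathlength
#'
#' Re-runs the full absorption-change -> concentration -> deconvolution
#' chain with the baseline pathlength scaled by `1 - perturbation` and
#' `1 + perturbation`, and reports the maximum absolute percent change in
#' recovered blood flow relative to the unperturbed chain.
#'
#' @param stack Measurement `dtof_stack`.
#' @param irf IRF [dtof()].
#' @param ca Arterial [concentration_curve()] on the stack's frame grid.
#' @param perturbation Fractional pathlength perturbation (|x| < 0.1).
#' @param baseline_window,eps_icg,opts Passed to the chain stages.
#' @return List: `percent_change` (max |dBF|/BF x 100), `bf_ref`,
#'   `bf_minus`, `bf_plus`.
#' @export
pathlength_sensitivity <- function(stack, irf, ca, perturbation = 0.005,
                                   baseline_window = c(0, 10),
                                   eps_icg = nirs_constants$eps_icg,
                                   opts = deconv_opts()) {
  if (abs(perturbation) >= 0.1)
    stop("perturbation magnitude must be < 0.1")
  run_chain <- function(scale) {
    ac <- delta_mua_timecourse(stack, irf, baseline_window,
                               pathlength_scale = scale)
    qc <- to_icg_concentration(ac, eps_icg)
    deconvolve_bf(ca, qc, opts)$bf
  }
  bf_ref <- run_chain(1)
  bf_minus <- run_chain(1 - perturbation)
  bf_plus <- run_chain(1 + perturbation)
  pc <- if (bf_ref == 0) 0 else
    100 * max(abs(c(bf_minus, bf_plus) - bf_ref)) / bf_ref
  list(percent_change = pc, bf_ref = bf_ref,
       bf_minus = bf_minus, bf_plus = bf_plus)
}

#' Aggregate repeat blood-flow measurements per ankle and day
#'
#' The per-ankle-day value is the mean of the two repeats when both are
#' present, the single value when one is missing, and missing when none
#' remain. No imputation is performed across sides or days.
#'
#' @param records Data frame with columns `animal`, `day`, `side`, `rep`,
#'   `bf` (NA allowed); extra grouping columns (`group`, `cohort`,
#'   `day_num`, `hr`) are carried through.
#' @return Data frame with one row per animal x day x side and column
#'   `aggregated_bf` (plus `n_repeats`).
#' @export
aggregate_measurements <- function(records) {
  stopifnot(all(c("animal", "day", "side", "rep", "bf") %in% names(records)))
  key <- interaction(records$animal, records$day, records$side, drop = TRUE)
  if (any(tabulate(key) > 2))
    stop("more than 2 repeats for some animal x day x side")
  carry <- intersect(c("group", "cohort", "day_num", "hr"), names(records))
  split_idx <- split(seq_len(nrow(records)), key)
  rows <- lapply(split_idx, function(ix) {
    r <- records[ix, , drop = FALSE]
    vals <- r$bf[!is.na(r$bf)]
    out <- r[1, c("animal", "day", "side", setdiff(carry, "hr")), drop = FALSE]
    out$aggregated_bf <- if (length(vals)) mean(vals) else NA_real_
    out$n_repeats <- length(vals)
    if ("hr" %in% carry) out$hr <- mean(r$hr, na.rm = TRUE)
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
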