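#' Power of the repeated-measures within-between interaction test
#'
#' Noncentral-F power for the time x group interaction of a design with
#' `n_groups` between-subject groups and `n_measurements` repeated
#' measurements, from a partial eta-squared effect size. Cohen's
#' `f^2 = eta_p^2 / (1 - eta_p^2)`; the test has
#' `df1 = (g - 1) (m - 1) eps` and `df2 = (N - g) (m - 1) eps`.
#'
#' Two effect-size conventions are in circulation and give materially
#' different noncentrality for the same inputs, so both are implemented and
#' can be reported side by side (see [power_report()]):
#' \describe{
#'   \item{`gpower_default`}{`lambda = f^2 N m eps / (1 + (m - 1) rho)`:
#'     the effect size is understood as observed between-cell variance over
#'     within-cell variance, and the repeated-measures gain
#'     `m / (1 + (m - 1) rho)` with assumed correlation `rho` among the
#'     repeated measures is applied by the program.}
#'   \item{`spss_etasq`}{`lambda = f^2 N eps`: the effect size is taken "as
#'     is" from the ANOVA partial eta-squared, which already absorbs the
#'     error structure, and no correlation adjustment is applied.}
#' }
#'
#' @param partial_eta_sq Partial eta-squared of the interaction, in [0, 1).
#' @param n_total Total sample size N (> n_groups).
#' @param n_groups Number of between-subject groups g.
#' @param n_measurements Number of repeated measurements m.
#' @param alpha Significance level.
#' @param corr_rep_measures Assumed correlation among repeated measures
#'   (used by `gpower_default` only), in [0, 1).
#' @param nonsphericity_eps Nonsphericity correction epsilon in (0, 1].
#' @param convention `"gpower_default"` or `"spss_etasq"`.
#' @return Power in (0, 1).
#' @export
interaction_power <- function(partial_eta_sq, n_total, n_groups = 2,
                              n_measurements = 6, alpha = 0.05,
                              corr_rep_measures = 0.5,
                              nonsphericity_eps = 1,
                              convention = c("gpower_default", "spss_etasq")) {
  convention <- match.arg(convention)
  stopifnot(partial_eta_sq >= 0, partial_eta_sq < 1,
            alpha > 0, alpha < 1, n_total > n_groups,
            corr_rep_measures >= 0, corr_rep_measures < 1,
            nonsphericity_eps > 0, nonsphericity_eps <= 1)
  f2 <- partial_eta_sq / (1 - partial_eta_sq)
  g <- n_groups; m <- n_measurements; eps <- nonsphericity_eps
  lambda <- switch(convention,
    gpower_default = f2 * n_total * m * eps /
      (1 + (m - 1) * corr_rep_measures),
    spss_etasq = f2 * n_total * eps)
  df1 <- (g - 1) * (m - 1) * eps
  df2 <- (n_total - g) * (m - 1) * eps
  fcrit <- stats::qf(1 - alpha, df1, df2)
  stats::pf(fcrit, df1, df2, ncp = lambda, lower.tail = FALSE)
}

#' Smallest sample size reaching a target interaction power
#'
#' Searches integer total N upward until [interaction_power()] first
#' reaches `target_power` under the requested convention.
#'
#' @inheritParams interaction_power
#' @param target_power Desired power, in (alpha, 1).
#' @param n_max Search cap.
#' @return Smallest integer N with power >= `target_power`.
#' @export
required_n <- function(partial_eta_sq, target_power = 0.8, n_groups = 2,
                       n_measurements = 6, alpha = 0.05,
                       corr_rep_measures = 0.5, nonsphericity_eps = 1,
                       convention = c("gpower_default", "spss_etasq"),
                       n_max = 100000L) {
  convention <- match.arg(convention)
  if (target_power <= alpha || target_power >= 1)
    stop("'target_power' must be in (alpha, 1)")
  for (N in seq.int(n_groups + 1L, n_max)) {
    p <- interaction_power(partial_eta_sq, N, n_groups, n_measurements,
                           alpha, corr_rep_measures, nonsphericity_eps,
                           convention)
    if (p >= target_power) return(N)
  }
  stop("target power unreachable within n_max = ", n_max,
       " (power at cap: ",
       signif(interaction_power(partial_eta_sq, n_max, n_groups,
                                n_measurements, alpha, corr_rep_measures,
                                nonsphericity_eps, convention), 3), ")")
}

#' Post-hoc power and required sample size under both conventions
#'
#' @inheritParams interaction_power
#' @param target_power Target power for the sample-size search.
#' @return Data frame with one row per convention: `convention`, `power`
#'   (at `n_total`), `required_n` (for `target_power`).
#' @export
power_report <- function(partial_eta_sq, n_total, n_groups = 2,
                         n_measurements = 6, alpha = 0.05,
                         corr_rep_measures = 0.5, nonsphericity_eps = 1,
                         target_power = 0.8) {
  conv <- c("gpower_default", "spss_etasq")
  data.frame(
    convention = conv,
    power = vapply(conv, function(cv)
      interaction_power(partial_eta_sq, n_total, n_groups, n_measurements,
                        alpha, corr_rep_measures, nonsphericity_eps, cv),
      numeric(1)),
    required_n = vapply(conv, function(cv)
      required_n(partial_eta_sq, target_power, n_groups, n_measurements,
                 alpha, corr_rep_measures, nonsphericity_eps, cv),
      numeric(1)),
    row.names = NULL
  )
}
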