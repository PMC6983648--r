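#' @export
print.residue_estimate <- function(x, ...) {
  cat("Flow-scaled residue estimate\n")
  cat(sprintf("  BF: %.2f mL/min/100 g (rho = %.2f g/mL)\n", x$bf, x$rho))
  cat(sprintf("  regularization: %s, lambda = %.3g, delay = %.1f s\n",
              x$regularization, x$lambda, x$delay))
  cat(sprintf("  refolding residual (RMS): %.3g uM\n", x$fit_residual))
  invisible(x)
}

#' @export
print.rm_anova <- function(x, ...) {
  cat("Three-way repeated-measures ANOVA (", x$n_subjects, " subjects, ",
      length(x$days_used), " timepoints x 2 sides)\n", sep = "")
  eff <- x$effects
  for (i in seq_len(nrow(eff))) {
    cat(sprintf("  %-18s F(%d,%d) = %6.3f  p = %-8.3g eta_p^2 = %.3f\n",
                eff$effect[i], eff$df[i], eff$df_error[i], eff$F[i],
                eff$p[i], eff$partial_eta_sq[i]))
  }
  cat(sprintf("  Shapiro-Wilk p = %.3g; Mauchly p(time) = %.3g\n",
              x$shapiro_p, x$mauchly$time$p))
  invisible(x)
}

#' @export
print.origin_regression <- function(x, ...) {
  cat(sprintf("Zero-intercept regression: slope = %.4f, R2 = %.5f, F(%d,%d) = %.1f, Shapiro p = %.3g\n",
              x$slope, x$r_squared, x$df1, x$df2, x$f_stat, x$shapiro_p))
  invisible(x)
}

#' @export
print.cohort_clustering <- function(x, ...) {
  cat(sprintf("Ward clustering: k = %d, k-means agreement (Rand) = %.3f, order-stable = %s\n",
              x$k, x$kmeans_agreement, x$stable))
  print(x$partition)
  invisible(x)
}
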