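#' @export
print.mr_fit <- function(x, ...) {
  or <- odds_ratios(x)
  lab <- c(ivw_fixed = "IVW (fixed-effect)",
           ivw_random = "IVW (multiplicative random-effects)",
           weighted_median = "Weighted median")[x$method]
  cat("Two-sample MR fit:", lab, "\n")
  cat(sprintf("  instruments: %d\n", x$n_snps))
  cat(sprintf("  alpha (log-OR): %.4f  SE %.4f  95%% CI [%.4f, %.4f]\n",
              x$alpha, x$se_alpha, x$ci_low, x$ci_high))
  cat(sprintf("  OR: %.2f (%.2f-%.2f)  p = %.2g\n",
              or$rounded["or"], or$rounded["ci_low"], or$rounded["ci_high"],
              or$pvalue))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

#' Summarize a two-sample MR fit
#'
#' Adds the per-SNP Wald ratio table and heterogeneity diagnostics to the
#' headline estimate.
#'
#' @param object An `mr_fit` object.
#' @param ... Unused.
#' @return `object`, classed `"summary.mr_fit"`, printed with the Wald-ratio
#'   spread and Cochran's Q / I² when available.
#' @export
summary.mr_fit <- function(object, ...) {
  structure(object, class = c("summary.mr_fit", "mr_fit"))
}

#' @export
print.summary.mr_fit <- function(x, ...) {
  print.mr_fit(x)
  if (!is.null(x$heterogeneity)) {
    cat("Heterogeneity: ")
    print(x$heterogeneity)
  }
  cat("Per-SNP Wald ratios:\n")
  print(summary(x$wald$alpha))
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$alpha, "alpha")
}

#' @export
vcov.mr_fit <- function(object, ...) {
  matrix(object$se_alpha^2, 1, 1, dimnames = list("alpha", "alpha"))
}

#' @export
confint.mr_fit <- function(object, parm = "alpha", level = 0.95, ...) {
  if (level != 0.95)
    stop("only the 95% interval (1.96 normal multiplier) is defined")
  matrix(c(object$ci_low, object$ci_high), 1, 2,
         dimnames = list("alpha", c("2.5 %", "97.5 %")))
}

#' @export
fitted.mr_fit <- function(object, ...) {
  stats::setNames(object$alpha * object$data$gamma, object$data$snp_id)
}

#' Residuals of a two-sample MR fit
#'
#' Per-SNP deviations of the outcome effects from the fitted proportional
#' relationship, `beta_i - alpha_hat * gamma_i`; standardized residuals
#' divide by `se_beta_i`.
#'
#' @param object An `mr_fit` object.
#' @param type `"response"` (raw) or `"standardized"`.
#' @param ... Unused.
#' @return Named numeric vector, one element per instrument.
#' @export
residuals.mr_fit <- function(object, type = c("response", "standardized"),
                             ...) {
  type <- match.arg(type)
  r <- object$data$beta - object$alpha * object$data$gamma
  if (type == "standardized") r <- r / object$data$se_beta
  stats::setNames(r, object$data$snp_id)
}

#' Predict outcome effects from instrument-exposure effects
#'
#' @param object An `mr_fit` object.
#' @param newdata Optional data frame with a `gamma` column; defaults to the
#'   fitting data.
#' @param ... Unused.
#' @return Predicted instrument-outcome log-odds effects `alpha_hat * gamma`.
#' @export
predict.mr_fit <- function(object, newdata = NULL, ...) {
  g <- if (is.null(newdata)) object$data$gamma else newdata$gamma
  object$alpha * g
}

#' Scatter plot of instrument effects with the fitted slope
#'
#' Plots outcome effects against exposure effects with per-SNP 1-SE bars and
#' the fitted causal slope through the origin — the standard visual check
#' that instruments share one proportional effect.
#'
#' @param x An `mr_fit` object.
#' @param ... Passed to [plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  d <- x$data
  plot(d$gamma, d$beta,
       xlab = "SNP effect on exposure (log-odds)",
       ylab = "SNP effect on outcome (log-odds)",
       pch = 19, cex = 0.6, ...)
  segments(d$gamma, d$beta - d$se_beta, d$gamma, d$beta + d$se_beta,
           col = "grey60")
  abline(0, x$alpha, col = "firebrick", lwd = 2)
  abline(0, 0, lty = 3)
  invisible(x)
}

#' Parametric simulation from a fitted MR model
#'
#' Draws new instrument-outcome effects under the fitted proportional model:
#' `beta*_i ~ Normal(alpha_hat * gamma_i, se_beta_i)`. Exposure effects are
#' kept fixed. Useful for posterior-predictive style checks of the residual
#' spread.
#'
#' @param object An `mr_fit` object.
#' @param nsim Number of simulated datasets.
#' @param seed Integer RNG seed.
#' @param ... Unused.
#' @return A list of `mr_data` objects, length `nsim`.
#' @export
simulate.mr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  d <- object$data
  lapply(seq_len(nsim), function(i) {
    mr_data(snp_id = d$snp_id, gamma = d$gamma, se_gamma = d$se_gamma,
            beta = stats::rnorm(nrow(d), object$alpha * d$gamma, d$se_beta),
            se_beta = d$se_beta)
  })
}
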