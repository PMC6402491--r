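#' Per-SNP Wald ratio estimate and first-order variance
#'
#' The single-instrument causal estimate `alpha_i = beta_i / gamma_i` with
#' first-order variance `v_i = (se_beta_i / gamma_i)^2`. The exposure
#' standard error is accepted for interface completeness but does not enter
#' the first-order approximation.
#'
#' @param gamma,se_gamma Instrument-exposure effect and its SE (vectorized).
#' @param beta,se_beta Instrument-outcome effect and its SE.
#' @return A data frame with columns `alpha` and `v`.
#' @export
wald_ratio <- function(gamma, se_gamma = NULL, beta, se_beta) {
  if (any(gamma == 0)) stop("undefined ratio: gamma = 0")
  if (any(se_beta <= 0)) stop("se_beta must be positive")
  data.frame(alpha = beta / gamma, v = (se_beta / gamma)^2)
}

#' Fit a two-sample Mendelian randomization model
#'
#' The package's central fitting function. From a harmonized instrument set
#' it computes the causal log-odds effect of the exposure on the outcome by
#' one of three estimators:
#'
#' * `"ivw_fixed"` — inverse-variance-weighted average of the per-SNP Wald
#'   ratios, `alpha = sum(w_i alpha_i) / sum(w_i)` with `w_i = 1/v_i`, and
#'   the closed-form SE `(sum w_i)^(-1/2)`.
#' * `"ivw_random"` — same point estimate; multiplicative random-effects SE,
#'   the fixed-effect SE inflated by `max(1, sqrt(Q/(n-1)))` where Q is
#'   Cochran's heterogeneity statistic. This is the conventional
#'   random-effects flavor in summary-data MR software: under-dispersion
#'   never shrinks the SE below the fixed-effect value.
#' * `"weighted_median"` — the weighted 50th percentile of the ordered Wald
#'   ratios (inverse-variance weights), consistent when at least half the
#'   total instrument weight comes from valid instruments. Its SE is
#'   estimated by parametric bootstrap: `gamma` and `beta` are resampled
#'   from normal distributions centred on the observed values with the
#'   reported SEs, and the estimate's standard deviation across replicates
#'   is taken.
#'
#' Confidence intervals are `alpha +/- 1.96 SE` and p-values two-sided from
#' the standard normal. Cochran's Q, its p-value and the I² statistic are
#' attached whenever `n >= 2` (see [cochran_q()]).
#'
#' @param data An `mr_data` object (or data frame with columns `snp_id`,
#'   `gamma`, `se_gamma`, `beta`, `se_beta`). All `gamma` must be nonzero.
#' @param method Estimator; see above. A single SNP with `"ivw_random"`
#'   falls back to the fixed-effect formula with a message.
#' @param n_boot Bootstrap replicates for the weighted-median SE
#'   (default 1000, minimum 100).
#' @param seed Integer RNG seed; required for `"weighted_median"` so results
#'   are reproducible. Ignored by the deterministic IVW estimators.
#' @param conf_level Not a free parameter of the implemented methods; fixed
#'   95% intervals with the 1.96 normal multiplier.
#' @return An object of class `"mr_fit"`; see [summary.mr_fit()] and the
#'   usual accessors `coef()`, `confint()`, `fitted()`, `residuals()`.
#' @seealso [cochran_q()], [mr_presso()], [odds_ratios()]
#' @export
mr_fit <- function(data,
                   method = c("ivw_random", "ivw_fixed", "weighted_median"),
                   n_boot = 1000, seed = NULL) {
  method <- match.arg(method)
  n <- nrow(data)
  if (n == 0) stop("no instruments")
  wr <- wald_ratio(data$gamma, data$se_gamma, data$beta, data$se_beta)
  w <- 1 / wr$v
  alpha <- sum(wr$alpha * w) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))

  het <- if (n >= 2) cochran_q(data, alpha) else NULL
  note <- NULL

  if (method == "weighted_median") {
    if (n < 3) stop("weighted median requires at least 3 instruments")
    if (n_boot < 100) stop("n_boot must be at least 100")
    if (is.null(seed)) stop("seed is required for the weighted median bootstrap")
    alpha <- .weighted_median_point(wr$alpha, w)
    boot <- .wm_bootstrap(data, n_boot, seed)
    se <- stats::sd(boot)
  } else if (method == "ivw_fixed") {
    se <- se_fixed
  } else {  # ivw_random
    if (n == 1) {
      note <- "single instrument: random-effects mode falls back to fixed"
      message("mr_fit: ", note)
      se <- se_fixed
    } else {
      se <- se_fixed * max(1, sqrt(het$q / het$df))
    }
  }

  z <- alpha / se
  out <- list(
    method = method,
    alpha = alpha,
    se_alpha = se,
    ci_low = alpha - 1.96 * se,
    ci_high = alpha + 1.96 * se,
    pvalue = 2 * stats::pnorm(-abs(z)),
    n_snps = n,
    heterogeneity = het,
    wald = data.frame(snp_id = data$snp_id, alpha = wr$alpha, v = wr$v,
                      w = w, stringsAsFactors = FALSE),
    data = data,
    n_boot = if (method == "weighted_median") n_boot else NA_integer_,
    seed = if (method == "weighted_median") seed else NA_integer_,
    note = note,
    call = match.call()
  )
  class(out) <- "mr_fit"
  out
}

# weighted median by linear interpolation of the ordered ratios against the
# standardized cumulative weight s_j = (cumsum(w)_j - w_j/2) / sum(w)
.weighted_median_point <- function(alpha, w) {
  ord <- order(alpha)
  a <- alpha[ord]
  ww <- w[ord]
  s <- (cumsum(ww) - ww / 2) / sum(ww)
  if (0.5 <= s[1]) return(a[1])
  if (0.5 >= s[length(s)]) return(a[length(a)])
  stats::approx(s, a, xout = 0.5, ties = "ordered")$y
}

.wm_bootstrap <- function(data, n_boot, seed) {
  set.seed(seed)
  n <- nrow(data)
  vapply(seq_len(n_boot), function(b) {
    g <- stats::rnorm(n, data$gamma, data$se_gamma)
    bb <- stats::rnorm(n, data$beta, data$se_beta)
    g[g == 0] <- .Machine$double.eps  # guard: resampled instrument at zero
    .weighted_median_point(bb / g, (g / data$se_beta)^2)
  }, numeric(1))
}

#' Cochran's Q heterogeneity test and I-squared
#'
#' `Q = sum(w_i (alpha_i - alpha_hat)^2)` over the per-SNP Wald ratios with
#' inverse-variance weights, referred to a chi-square distribution with
#' `n - 1` degrees of freedom; `I² = max(0, (Q - df)/Q) * 100` measures the
#' fraction of variation in the ratio estimates attributable to
#' heterogeneity rather than sampling error.
#'
#' @param data An `mr_data` object with at least 2 instruments.
#' @param alpha_hat The pooled causal estimate around which residuals are
#'   measured (usually the IVW point estimate).
#' @return Object of class `"mr_het"`: list with `q`, `df`, `p_het`, `i2`.
#' @export
cochran_q <- function(data, alpha_hat) {
  n <- nrow(data)
  if (n < 2) stop("Cochran's Q requires at least 2 instruments")
  wr <- wald_ratio(data$gamma, data$se_gamma, data$beta, data$se_beta)
  w <- 1 / wr$v
  q <- sum(w * (wr$alpha - alpha_hat)^2)
  df <- n - 1
  out <- list(q = q, df = df,
              p_het = stats::pchisq(q, df, lower.tail = FALSE),
              i2 = if (q > 0) max(0, (q - df) / q) * 100 else 0)
  class(out) <- "mr_het"
  out
}

#' @export
print.mr_het <- function(x, ...) {
  cat(sprintf("Cochran's Q = %.3f on %d df, p = %.3g, I2 = %.0f%%\n",
              x$q, x$df, x$p_het, x$i2))
  invisible(x)
}

#' Causal estimate on the odds-ratio scale
#'
#' Exponentiates the log-odds estimate and CI bounds: the odds ratio on the
#' outcome per 1-unit increase in the log-odds of the exposure. Values are
#' reported rounded to 2 decimals (`digits` configurable); the unrounded
#' values are retained.
#'
#' @param fit An `mr_fit` object.
#' @param digits Decimal places for the displayed OR (default 2).
#' @return A list with `or`, `ci_low`, `ci_high` (unrounded), their rounded
#'   counterparts, and the fit's p-value at 2 significant figures.
#' @export
odds_ratios <- function(fit, digits = 2) {
  stopifnot(inherits(fit, "mr_fit"))
  or <- exp(c(or = fit$alpha, ci_low = fit$ci_low, ci_high = fit$ci_high))
  list(or = unname(or["or"]),
       ci_low = unname(or["ci_low"]),
       ci_high = unname(or["ci_high"]),
       rounded = round(or, digits),
       pvalue = signif(fit$pvalue, 2))
}
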