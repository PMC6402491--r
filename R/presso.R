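#' MR-PRESSO style pleiotropy residual-sum-of-squares test
#'
#' Simulation-based detection of horizontally pleiotropic instruments, in
#' three parts:
#'
#' 1. **Global test.** The observed weighted residual sum of squares
#'    `RSS = sum_i w_i (beta_i - alpha_(-i) gamma_i)^2`, where `alpha_(-i)`
#'    is the leave-one-out fixed-effect IVW estimate, is compared with a
#'    parametric null distribution: `n_sim` datasets are drawn with
#'    `gamma*_i ~ N(gamma_i, se_gamma_i)` and
#'    `beta*_i ~ N(alpha_(-i) gamma_i, se_beta_i)` and the RSS recomputed on
#'    each (with its own leave-one-out estimates). The empirical p-value
#'    carries the add-one correction, so it is never smaller than
#'    `1/(n_sim + 1)`.
#' 2. **Outlier test.** Each SNP's observed weighted squared residual is
#'    compared with its own simulated null; SNPs with empirical p below the
#'    Bonferroni threshold `alpha_level / n` are flagged.
#' 3. **Distortion test.** The change in the IVW estimate after removing the
#'    flagged SNPs is compared with a null of removing random subsets of the
#'    same size from the non-flagged SNPs (two-sided empirical p).
#'
#' @param data An `mr_data` object with at least 4 instruments.
#' @param n_sim Number of null simulations (minimum 1000; default 5000 so
#'   empirical p-values resolve Bonferroni thresholds around `0.05/170`).
#' @param seed Integer RNG seed (required; identical seed and input give a
#'   bit-identical report).
#' @param alpha_level Family-wise level for the Bonferroni outlier calls
#'   (default 0.05).
#' @param distortion Run the distortion test when outliers are found.
#' @return Object of class `"mr_presso"`: list with `global_rss_obs`,
#'   `global_p`, `outlier_ids`, `per_snp_p` (named vector), `distortion_p`
#'   (`NA` when no outliers or not run), `n_sim`, `seed`, `alpha_level`.
#' @export
mr_presso <- function(data, n_sim = 5000, seed, alpha_level = 0.05,
                      distortion = TRUE) {
  n <- nrow(data)
  if (n < 4) stop("MR-PRESSO requires at least 4 instruments")
  if (n_sim < 1000) stop("n_sim must be at least 1000")
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (any(data$se_gamma <= 0) || any(data$se_beta <= 0))
    stop("degenerate (non-positive) standard error")
  set.seed(seed)

  g <- data$gamma; b <- data$beta
  seg <- data$se_gamma; seb <- data$se_beta
  w <- g^2 / seb^2
  a <- b / g
  loo <- (sum(w * a) - w * a) / (sum(w) - w)  # alpha_(-i), fixed-effect IVW
  resid_obs <- w * (b - loo * g)^2
  rss_obs <- sum(resid_obs)

  # parametric null, vectorized: n_sim x n matrices
  G <- matrix(stats::rnorm(n_sim * n, rep(g, each = n_sim),
                           rep(seg, each = n_sim)), n_sim, n)
  B <- matrix(stats::rnorm(n_sim * n, rep(loo * g, each = n_sim),
                           rep(seb, each = n_sim)), n_sim, n)
  G[G == 0] <- .Machine$double.eps
  SEB2 <- matrix(rep(seb^2, each = n_sim), n_sim, n)
  W <- G^2 / SEB2
  WA <- W * (B / G)          # = G * B / seb^2
  LOO <- (rowSums(WA) - WA) / (rowSums(W) - W)
  RESID <- W * (B - LOO * G)^2
  rss_sim <- rowSums(RESID)

  global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
  per_snp_p <- (1 + colSums(RESID >= matrix(resid_obs, n_sim, n,
                                            byrow = TRUE))) / (n_sim + 1)
  names(per_snp_p) <- data$snp_id
  outlier_ids <- data$snp_id[per_snp_p < alpha_level / n]

  distortion_p <- NA_real_
  if (distortion && length(outlier_ids) > 0)
    distortion_p <- distortion_test(data, outlier_ids, n_sim = n_sim,
                                    seed = seed + 1L)

  structure(list(global_rss_obs = rss_obs, global_p = global_p,
                 outlier_ids = outlier_ids, per_snp_p = per_snp_p,
                 distortion_p = distortion_p, n_sim = n_sim, seed = seed,
                 alpha_level = alpha_level),
            class = "mr_presso")
}

#' MR-PRESSO distortion test
#'
#' Tests whether removing the flagged outliers changes the IVW causal
#' estimate more than removing random subsets of the same size drawn from
#' the non-flagged instruments.
#'
#' @param data An `mr_data` object.
#' @param outlier_ids Nonempty character vector of flagged snp ids.
#' @param n_sim Number of random subsets.
#' @param seed Integer RNG seed.
#' @return Two-sided empirical p-value (add-one corrected).
#' @export
distortion_test <- function(data, outlier_ids, n_sim = 5000, seed) {
  if (length(outlier_ids) == 0) stop("nothing to test: no outliers supplied")
  if (missing(seed) || is.null(seed)) stop("seed is required")
  set.seed(seed)
  is_out <- data$snp_id %in% outlier_ids
  k <- sum(is_out)
  inliers <- which(!is_out)
  if (length(inliers) <= k)
    stop("too few non-outlier instruments for the distortion null")
  alpha_all <- .ivw_point(data)
  alpha_no <- .ivw_point(data[!is_out, , drop = FALSE])
  d_obs <- alpha_no - alpha_all
  d_null <- vapply(seq_len(n_sim), function(s) {
    drop <- sample(inliers, k)
    .ivw_point(data[-drop, , drop = FALSE]) - alpha_all
  }, numeric(1))
  (1 + sum(abs(d_null) >= abs(d_obs))) / (n_sim + 1)
}

# fixed-effect IVW point estimate (shared internal)
.ivw_point <- function(data) {
  w <- data$gamma^2 / data$se_beta^2
  sum(w * (data$beta / data$gamma)) / sum(w)
}

#' @export
print.mr_presso <- function(x, ...) {
  cat("MR-PRESSO pleiotropy test (", x$n_sim, " simulations, seed ",
      x$seed, ")\n", sep = "")
  cat(sprintf("  global RSS = %.4f, empirical p = %.4g\n",
              x$global_rss_obs, x$global_p))
  if (length(x$outlier_ids) > 0) {
    cat("  outliers (Bonferroni ", format(x$alpha_level), "/",
        length(x$per_snp_p), "): ",
        paste(x$outlier_ids, collapse = ", "), "\n", sep = "")
    cat(sprintf("  distortion p = %.4g\n", x$distortion_p))
  } else {
    cat("  no outliers flagged\n")
  }
  invisible(x)
}

#' Write flagged outliers as a plain-text exclusion list
#'
#' One snp id per line; consumable by the pipeline's exclusion step.
#'
#' @param x An `mr_presso` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_exclusion_list <- function(x, path) {
  writeLines(x$outlier_ids, path)
  invisible(path)
}
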