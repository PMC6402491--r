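#' Simulate two-sample GWAS summary statistics with known causal truth
#'
#' Generates paired exposure/outcome summary-association tables under the
#' generative model the two-sample MR estimators assume, plus controlled
#' violations of it. Per SNP `i`:
#'
#' * true instrument effect `gamma_i = |N(gamma_mean, gamma_sd)|` (the
#'   exposure-increasing orientation convention);
#' * observed exposure effect `gamma_i + N(0, se_gamma)` with reported SE
#'   `se_gamma`;
#' * a pleiotropic direct effect `p_i`: 0 (`"none"`),
#'   `N(0, pleiotropy_sd)` (`"balanced"`, satisfying the InSIDE
#'   assumption by construction), or `N(pleiotropy_mean, pleiotropy_sd)`
#'   (`"directional"`);
#' * a random `outlier_fraction` of SNPs instead get
#'   `p_i = outlier_shift * se_beta` — gross horizontal pleiotropy of the
#'   kind the MR-PRESSO outlier test is built to flag;
#' * observed outcome effect `true_alpha * gamma_i + p_i + N(0, se_beta)`
#'   with reported SE `se_beta`.
#'
#' P-values come from the normal approximation; alleles, effect-allele
#' frequencies and imputation info scores are drawn within the configured
#' ranges. Defaults emulate the scale of a large psychiatric-disorder
#' exposure GWAS (~10^5 samples; instrument log-odds around 0.09, SE 0.01)
#' paired with a very large outcome GWAS (~2x10^5 samples; SE 0.008), with
#' balanced pleiotropy calibrated to give I-squared heterogeneity in the
#' 40-50% range — the regime of published schizophrenia-to-breast-cancer
#' instrument tables.
#'
#' @param n_snps Number of instruments (default 170).
#' @param true_alpha Causal log-odds effect of exposure on outcome
#'   (default 0.04).
#' @param gamma_mean,gamma_sd Instrument-strength distribution (log-odds).
#' @param se_gamma,se_beta Reported per-SNP standard errors (scalar or
#'   length-`n_snps`).
#' @param pleiotropy_mode `"balanced"` (default), `"none"`, or
#'   `"directional"`.
#' @param pleiotropy_sd SD of pleiotropic effects (log-odds).
#' @param pleiotropy_mean Mean pleiotropy under `"directional"`.
#' @param outlier_fraction Fraction of SNPs made gross outliers, in
#'   \[0, 0.5\] (default 0).
#' @param outlier_shift Outlier pleiotropy in units of `se_beta`
#'   (default 10).
#' @param maf_range Range for generated effect-allele frequencies.
#' @param info_range Support of generated outcome info scores. Scores are
#'   drawn skewed toward the upper end (`upper - (upper - lower) *
#'   Beta(1, 7)`), emulating well-imputed GWAS panels where only a few
#'   percent of variants fall below the conventional 0.8 quality cutoff.
#' @param palindromic If `FALSE` (default) allele pairs are drawn from
#'   non-complementary combinations only, so default harmonization is
#'   lossless; set `TRUE` to include A/T and C/G pairs.
#' @param seed Integer RNG seed (required; identical configuration gives a
#'   bit-identical dataset).
#' @return Object of class `"mr_sim"`: list with `exposure` and `outcome`
#'   (`gwas_sumstats` data frames in the dialect [read_summary_stats()]
#'   reads), `truth` (per-SNP `gamma_true`, `pleiotropy`, `is_outlier`),
#'   and `config`.
#' @export
simulate_mr_data <- function(n_snps = 170, true_alpha = 0.04,
                             gamma_mean = 0.09, gamma_sd = 0.025,
                             se_gamma = 0.01, se_beta = 0.008,
                             pleiotropy_mode = c("balanced", "none",
                                                 "directional"),
                             pleiotropy_sd = 0.007, pleiotropy_mean = 0.01,
                             outlier_fraction = 0, outlier_shift = 10,
                             maf_range = c(0.05, 0.5),
                             info_range = c(0.5, 1),
                             palindromic = FALSE, seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (missing(seed) || is.null(seed)) stop("seed is required")
  if (n_snps < 1) stop("invalid n_snps: must be >= 1")
  if (outlier_fraction < 0 || outlier_fraction > 0.5)
    stop("invalid outlier_fraction: must lie in [0, 0.5]")
  if (any(c(gamma_sd, se_gamma, se_beta, pleiotropy_sd) < 0))
    stop("invalid negative scale parameter (gamma_sd/se_gamma/se_beta/pleiotropy_sd)")
  if (any(se_gamma <= 0) || any(se_beta <= 0))
    stop("invalid se_gamma/se_beta: reported SEs must be positive")
  set.seed(seed)

  se_g <- rep_len(se_gamma, n_snps)
  se_b <- rep_len(se_beta, n_snps)
  ids <- sprintf("rs%07d", seq_len(n_snps))

  gamma_true <- abs(stats::rnorm(n_snps, gamma_mean, gamma_sd))
  gamma_obs <- gamma_true + stats::rnorm(n_snps, 0, se_g)

  pleio <- switch(pleiotropy_mode,
                  none = rep(0, n_snps),
                  balanced = stats::rnorm(n_snps, 0, pleiotropy_sd),
                  directional = stats::rnorm(n_snps, pleiotropy_mean,
                                             pleiotropy_sd))
  n_out <- round(outlier_fraction * n_snps)
  is_outlier <- rep(FALSE, n_snps)
  if (n_out > 0) {
    idx <- sample.int(n_snps, n_out)
    is_outlier[idx] <- TRUE
    pleio[idx] <- outlier_shift * se_b[idx]
  }
  beta_obs <- true_alpha * gamma_true + pleio + stats::rnorm(n_snps, 0, se_b)

  al <- .draw_alleles(n_snps, palindromic)
  eaf <- stats::runif(n_snps, maf_range[1], maf_range[2])
  eaf_out <- pmin(pmax(eaf + stats::rnorm(n_snps, 0, 0.01), 0.001), 0.999)
  info_exp <- stats::runif(n_snps, 0.9, 1)
  info_out <- info_range[2] -
    (info_range[2] - info_range[1]) * stats::rbeta(n_snps, 1, 7)

  exposure <- data.frame(
    snp_id = ids, effect_allele = al$ea, other_allele = al$oa, eaf = eaf,
    beta = gamma_obs, se = se_g,
    pvalue = pmax(2 * stats::pnorm(-abs(gamma_obs) / se_g),
                  .Machine$double.xmin),
    info = info_exp, stringsAsFactors = FALSE)
  class(exposure) <- c("gwas_sumstats", "data.frame")

  # a random half of the outcome records are stored on the swapped allele
  # orientation, exercising harmonization
  swap <- stats::runif(n_snps) < 0.5
  outcome <- data.frame(
    snp_id = ids,
    effect_allele = ifelse(swap, al$oa, al$ea),
    other_allele = ifelse(swap, al$ea, al$oa),
    eaf = ifelse(swap, 1 - eaf_out, eaf_out),
    beta = ifelse(swap, -beta_obs, beta_obs),
    se = se_b,
    pvalue = pmax(2 * stats::pnorm(-abs(beta_obs) / se_b),
                  .Machine$double.xmin),
    info = info_out, stringsAsFactors = FALSE)
  class(outcome) <- c("gwas_sumstats", "data.frame")

  truth <- data.frame(snp_id = ids, gamma_true = gamma_true,
                      pleiotropy = pleio, is_outlier = is_outlier,
                      stringsAsFactors = FALSE)
  structure(list(exposure = exposure, outcome = outcome, truth = truth,
                 config = list(n_snps = n_snps, true_alpha = true_alpha,
                               gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                               se_gamma = se_gamma, se_beta = se_beta,
                               pleiotropy_mode = pleiotropy_mode,
                               pleiotropy_sd = pleiotropy_sd,
                               pleiotropy_mean = pleiotropy_mean,
                               outlier_fraction = outlier_fraction,
                               outlier_shift = outlier_shift,
                               maf_range = maf_range,
                               info_range = info_range,
                               palindromic = palindromic, seed = seed)),
            class = "mr_sim")
}

.draw_alleles <- function(n, palindromic) {
  bases <- c("A", "C", "G", "T")
  pairs <- expand.grid(ea = bases, oa = bases, stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ea != pairs$oa, ]
  if (!palindromic) {
    comp <- c(A = "T", T = "A", C = "G", G = "C")
    pairs <- pairs[comp[pairs$ea] != pairs$oa, ]
  }
  k <- sample.int(nrow(pairs), n, replace = TRUE)
  list(ea = pairs$ea[k], oa = pairs$oa[k])
}

#' @export
print.mr_sim <- function(x, ...) {
  cfg <- x$config
  cat("Simulated two-sample MR dataset:", cfg$n_snps, "SNPs, true alpha =",
      cfg$true_alpha, "\n")
  cat("  pleiotropy:", cfg$pleiotropy_mode,
      if (cfg$outlier_fraction > 0)
        sprintf("+ %d outlier(s) at %g x se_beta",
                sum(x$truth$is_outlier), cfg$outlier_shift) else "", "\n")
  invisible(x)
}

#' Write a simulated dataset to disk
#'
#' Exposure and outcome tables in the summary-statistics TSV dialect of
#' [read_summary_stats()], plus the truth table.
#'
#' @param sim An `mr_sim` object.
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix.
#' @return Named character vector of the three paths, invisibly.
#' @export
write_mr_sim <- function(sim, dir, prefix = "sim") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(exposure = file.path(dir, paste0(prefix, "_exposure.tsv")),
             outcome = file.path(dir, paste0(prefix, "_outcome.tsv")),
             truth = file.path(dir, paste0(prefix, "_truth.tsv")))
  write_summary_stats(sim$exposure, paths["exposure"])
  write_summary_stats(sim$outcome, paths["outcome"])
  utils::write.table(sim$truth, paths["truth"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(paths)
}

#' Simulate a block of correlated genotype dosages
#'
#' Generates an individuals-by-SNPs dosage matrix whose adjacent-pair LD r²
#' approximates a target, for testing LD pruning. Each of the two haplotypes
#' per individual is a Markov chain over SNPs: the allele at SNP `k+1`
#' copies the allele at SNP `k` with probability `sqrt(correlation)` and is
#' otherwise drawn fresh at the allele frequency, giving adjacent allele
#' correlation `sqrt(correlation)` per haplotype and dosage r² close to
#' `correlation`; correlation decays geometrically with distance.
#'
#' @param n_individuals,n_snps Matrix dimensions.
#' @param correlation Target adjacent-pair r² in \[0, 1).
#' @param seed Integer RNG seed.
#' @param maf Allele frequency of the counted allele (default 0.3).
#' @return Numeric matrix (`n_individuals` x `n_snps`) of dosages in
#'   \{0, 1, 2\}, columns named `snp1..snpN`.
#' @export
simulate_ld_block <- function(n_individuals, n_snps, correlation, seed,
                              maf = 0.3) {
  stopifnot(correlation >= 0, correlation < 1)
  if (missing(seed) || is.null(seed)) stop("seed is required")
  set.seed(seed)
  q <- sqrt(correlation)
  hap <- function() {
    h <- matrix(0L, n_individuals, n_snps)
    h[, 1] <- stats::rbinom(n_individuals, 1, maf)
    if (n_snps > 1) for (k in 2:n_snps) {
      copy <- stats::runif(n_individuals) < q
      h[, k] <- ifelse(copy, h[, k - 1],
                       stats::rbinom(n_individuals, 1, maf))
    }
    h
  }
  g <- hap() + hap()
  colnames(g) <- paste0("snp", seq_len(n_snps))
  g
}
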